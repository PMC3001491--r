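---
title: "Recommending literature from the content of a personal library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending literature from the content of a personal library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litrec)
```

## The problem

A researcher's PDF folder is an implicit statement of interest: the papers
they chose to keep define, better than any saved query, what they want to
read next. `litrec` turns such a seed library into an explicit, inspectable
query against a background corpus of MEDLINE-style bibliographic records,
and ranks recently registered papers against it. Everything is
term-weighted and decomposable, so a user can always see *why* a paper was
recommended and tune the query (stop-terms, must-terms) accordingly.

## The model

### Key-term enrichment

The background corpus (size $N$) is indexed into a dictionary of word
N-grams, $1 \le n \le 5$, built over the tokenized title and abstract of
each record (N-grams never span the title/abstract boundary). Tokenization
is the single normalization used everywhere in the package: lowercase,
split on non-alphanumerics, drop single-digit tokens, remove a fixed
143-word English stop list, then apply the Porter (1980) stemmer. The
stemmer and stop list are pinned implementation choices: any deterministic
pair would do statistically, but golden test values and serialized indexes
depend on them, so they ship with the package rather than float with an
external dependency.

For a seed library of $n$ records, every N-gram present in at least one
seed record whose seed document count $x$ exceeds its expectation
$nK/N$ (with $K$ the term's background document count) is a candidate key
term, scored by the hypergeometric point probability

$$P(X = x), \qquad X \sim \mathrm{Hypergeometric}(N, K, n),$$

i.e. the probability of drawing exactly $x$ term-bearing papers when $n$
papers are drawn from a population of $N$ containing $K$ of them. The
$k = 75$ lowest-probability candidates form the query, each weighted
$w = -\log P$. Ties at the cut are broken lexicographically on the term so
that selection is deterministic and a smaller $k$ always yields a prefix of
a larger one.

Two modeling choices deserve comment:

* **Documents, not occurrences.** The urn model draws *papers*, so both
  $x$ and $K$ are document-level presence counts. Counting token
  occurrences instead would break exchangeability (a term repeated ten
  times in one abstract is one draw, not ten).
* **Point probability, not tail.** The score is $P(X = x)$ itself rather
  than the upper tail $P(X \ge x)$. For over-represented terms the two
  rank almost identically; the point form is kept as the default and an
  upper-tail option (`tail = "upper"`) is exposed for users who want a
  conservative enrichment p-value.

Overlapping and nested N-grams ("planted", "signature", "planted
signature") are scored independently; no subsumption rule is applied. This
over-counts correlated evidence slightly but keeps selection transparent
and monotone.

### The structured query

The recommendation target set is the corpus restricted to a recency window
of `window_months = 3` calendar months before the query date — half-open,
inclusive of the query date, with day-of-month clamping (the three months
before March 31 start after Feb 28). Seed records are excluded: a
recommendation service proposes papers you do not yet have. A candidate is
admitted if it contains at least one key term (and every must-term), and
scored

$$\mathrm{total} = \sum_{t \;\mathrm{matched}} w(t)\, b(t) \;+\;
  \tilde w \cdot |\mathrm{shared\ authors}| \;+\;
  \tilde w \cdot \mathbf 1\{\mathrm{scope\ overlap}\},$$

where $b(t)$ is `title_boost = 2` when $t$ matches in the title and 1
otherwise, and $\tilde w$ is the median key-term weight. Term matching is
contiguous-token-subsequence containment under the index normalization.

The additive form, the value of the title boost, and the author/scope
bonuses are design decisions: the underlying idea — more key terms with
greater weight score higher, titles outweigh abstracts, shared authors and
same-scope journals add significance — fixes only the signs and ordering,
not the functional form. The median-weight bonus was chosen so that one
context signal (an author in common, a same-scope journal) counts like one
typical term match and can never dominate strong term evidence; author
matches are count-scaled because sharing three authors with the seed
library is materially stronger evidence than sharing one. All three
coefficients are exposed as arguments.

### Associative search and tag suggestion

Within a personal library, related papers are found by cosine similarity
between sparse unigram vectors weighted by raw term frequency times
$\mathrm{idf}(t) = \log(N/\mathrm{df}(t))$ (natural log, no smoothing;
out-of-vocabulary terms get $\log N$, i.e. are treated as df = 1;
sub-linear tf is available via `tf_log`). Multiple seed papers are
combined by vector addition — equivalent to the centroid, since cosine
ranking is invariant to positive scaling of the query.

Tag suggestion applies the same hypergeometric enrichment to MeSH headings:
headings over-represented in a paper set (population $N$, successes the
heading's corpus document count, draws the set size) with
$P \le$ `prob_threshold` are suggested, most significant first, capped at
`max_suggestions`. Defaults — threshold 0.01, cap 10 — reflect the UI
framing of the output: a click-to-accept list should be short and should
only contain headings that would essentially never be this frequent by
chance. Suggested tag names reverse comma-inverted headings and lowercase
them ("Neoplasms, Experimental" → "experimental neoplasms"), the standard
reading of legibility-oriented word reordering for MeSH; the rule is
idempotent.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `max_n` | 5 | tokens | N-gram ceiling of the dictionary |
| `k_limit` | 75 | terms | query-size cap for key terms |
| `window_months` | 3 | calendar months | recency window (`NULL` = whole corpus) |
| `title_boost` | 2 | multiplier | weight factor for title matches |
| `author_bonus` | median $w$ | score | added per shared author |
| `scope_bonus` | median $w$ | score | added once on scope overlap |
| `prob_threshold` | 0.01 | probability | max pmf for a tag suggestion |
| `max_suggestions` | 10 | headings | tag-list cap |
| `min_title_tokens` | 4 | tokens | title-lookup match threshold |

## The synthetic corpus

`generate_corpus()` emulates exactly the structure the statistics exploit:
each record draws a topic; tokens come from a mixture placing the topic's
signature terms at `signature_rate = 0.30` per token, other topics'
signature terms at `background_rate = 0.02`, and a uniform background
vocabulary otherwise; authors come preferentially (p = 0.8) from a
per-topic community; the topic's journal scope is assigned with p = 0.9 and
each of its MeSH headings with p = 0.8, plus rare stray headings;
registration dates are uniform over 2010 so window filtering has
predictable survivor counts. A single RNG stream seeded from `config$seed`
drives all draws in document order, so corpora regenerate byte-identically;
the generator saves and restores the caller's RNG state. The rates were
chosen once to mimic a focused subfield — roughly a third of a paper's
informative tokens are field vocabulary, and field terms leak weakly into
other fields' papers — and are validated by a binomial 3σ calibration test
rather than tuned against downstream outcomes.

What the generator does **not** emulate: real word-frequency distributions
(Zipf tails), within-document burstiness, topic mixtures inside one paper,
citation structure, or MeSH hierarchy. Passing recovery tests on this
corpus therefore shows the pipeline is statistically sound and correctly
implemented, not that precision@10 on real MEDLINE would be comparable.

## Numerical and degenerate-input choices

* Hypergeometric probabilities come from `stats::dhyper`/`phyper`; tests
  cross-check them against exhaustive enumeration of all draws for
  populations up to 12.
* A seed set equal to the whole corpus has no over-represented terms
  (observation equals expectation everywhere) and yields an empty query;
  empty seed sets and unknown ids are hard errors.
* Cosine of a zero vector (empty record) is defined as 0; IDF-0 terms
  (present everywhere) drop out of vectors entirely.
* All rankings break score ties by ascending record id, making golden
  outputs stable under corpus permutation.
* The JSONL writer emits a canonical key order so read–write round-trips
  are byte-identical; the index file stores only counts (IDF is derived on
  read) under a format version field.
* The MEDLINE-subset XML dialect carries no Journal Subject Terms element,
  so XML-read records have empty scope sets; the JSONL dialect carries them
  explicitly.

## Problem sizes used in validation

The shipped tests and the acceptance script run on generated corpora of
20–500 records (vocabulary ≈ 400, abstracts ≈ 60 tokens), sizes at which
the full pipeline can be re-derived by brute-force loops and exhaustive
enumeration in seconds while still leaving the planted structure
statistically unambiguous. The same code paths scale to larger corpora
linearly in total token count; only the all-pairs brute-force *oracles* are
quadratic.

## Known limitations

* Term vectors use titles and abstracts; full-text vectors would sharpen
  associative search but require PDF text extraction, which is out of
  scope.
* The additive query score is one concretization of a natural-language
  ranking description; other monotone combinations (e.g. probabilistic IR
  scores) are plausible and would rank near-identically on strong signals
  but differ on weak ones.
* The hypergeometric model treats records as exchangeable; real corpora
  have time trends and journal effects the model ignores.
* No incremental index updates: `build_background_stats()` recomputes from
  the full corpus.
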
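# Key-term extraction: hypergeometric significance of seed-set N-grams
# against the background corpus, and selection of the k lowest-probability
# terms together with the seed's author and journal-scope lists.

#' Hypergeometric point probability
#'
#' Probability of observing exactly `seed_hits` term-bearing papers in a
#' draw of `seed_size` papers from a population of `bg_size` papers of which
#' `bg_hits` bear the term: `P[X = seed_hits]` with
#' `X ~ Hypergeometric(bg_size, bg_hits, seed_size)`.
#'
#' @param seed_hits Number of seed papers containing the term.
#' @param seed_size Number of seed papers (the draw).
#' @param bg_hits Number of background papers containing the term.
#' @param bg_size Number of background papers (the population).
#' @param tail If `"point"` (default) the point probability; if `"upper"`
#'   the upper-tail probability `P[X >= seed_hits]`, a conservative
#'   enrichment p-value.
#' @return Probability in `[0, 1]`.
#' @examples
#' hypergeom_point_prob(2, 2, 2, 4)  # 1/6
#' @export
hypergeom_point_prob <- function(seed_hits, seed_size, bg_hits, bg_size,
                                 tail = c("point", "upper")) {
  tail <- match.arg(tail)
  if (seed_hits < 0 || seed_hits > seed_size || seed_size > bg_size ||
      seed_hits > bg_hits || bg_hits > bg_size)
    stop("hypergeometric parameters violate 0 <= seed_hits <= seed_size <= ",
         "bg_size and seed_hits <= bg_hits <= bg_size", call. = FALSE)
  if (tail == "point") {
    stats::dhyper(seed_hits, bg_hits, bg_size - bg_hits, seed_size)
  } else {
    stats::phyper(seed_hits - 1, bg_hits, bg_size - bg_hits, seed_size,
                  lower.tail = FALSE)
  }
}

# document-level seed counts of every n-gram occurring in >= 1 seed record
.seed_term_doc_counts <- function(seed_records, max_n) {
  per <- lapply(seed_records, function(r) unique(.record_ngrams(r, max_n)))
  tab <- table(unlist(per, use.names = FALSE))
  cnt <- as.integer(tab); names(cnt) <- names(tab)
  cnt
}

#' Extract key terms from a seed set
#'
#' Candidate terms are the N-grams occurring in at least one seed record
#' whose seed document frequency exceeds the background expectation
#' `seed_size * bg_hits / bg_size`. Each candidate is scored with the
#' hypergeometric probability of its seed count; the `k_limit`
#' lowest-probability candidates become key terms with weight
#' `-log(probability)`. The profile also carries the union of the seed
#' records' authors and Journal Subject Terms.
#'
#' @param seed_ids Record ids of the seed set; all must exist in `corpus`.
#' @param corpus The background `biblio_corpus` (the seed records belong
#'   to it).
#' @param stats `background_stats` built from `corpus`.
#' @param k_limit Maximum number of key terms kept; default 75.
#' @param tail Passed to [hypergeom_point_prob()].
#' @return An object of class `seed_profile` with elements `key_terms`
#'   (data.frame: term, seed_doc_count, background_doc_count, probability,
#'   weight; ascending probability, ties broken by term), `seed_authors`,
#'   `seed_scopes`, `seed_ids`, `k_limit`.
#' @export
extract_key_terms <- function(seed_ids, corpus, stats, k_limit = 75L,
                              tail = c("point", "upper")) {
  tail <- match.arg(tail)
  if (length(seed_ids) == 0L) stop("empty seed set", call. = FALSE)
  if (k_limit < 1L) stop("k_limit must be >= 1", call. = FALSE)
  seed_records <- corpus_get(corpus, unique(seed_ids))
  if (length(seed_ids) == 1L) seed_records <- list(seed_records)
  seed_size <- length(seed_records)
  bg_size <- stats$corpus_size
  max_n <- stats$ngrams$max_n

  seed_counts <- .seed_term_doc_counts(seed_records, max_n)
  bg_counts <- stats$ngrams$term_doc_count[names(seed_counts)]
  # terms unseen in the background (possible when stats come from a different
  # snapshot) are at least as frequent as in the seed
  bg_counts[is.na(bg_counts)] <- seed_counts[is.na(bg_counts)]

  expected <- seed_size * bg_counts / bg_size
  keep <- seed_counts > expected
  terms <- names(seed_counts)[keep]
  seed_hits <- unname(seed_counts[keep])
  bg_hits <- unname(bg_counts[keep])

  prob <- if (length(terms) == 0L) numeric(0) else if (tail == "point") {
    stats::dhyper(seed_hits, bg_hits, bg_size - bg_hits, seed_size)
  } else {
    stats::phyper(seed_hits - 1, bg_hits, bg_size - bg_hits, seed_size,
                  lower.tail = FALSE)
  }

  ord <- order(prob, terms)
  take <- ord[seq_len(min(k_limit, length(ord)))]
  key_terms <- data.frame(
    term = terms[take],
    seed_doc_count = seed_hits[take],
    background_doc_count = bg_hits[take],
    probability = prob[take],
    weight = -log(prob[take]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )

  structure(
    list(
      key_terms = key_terms,
      seed_authors = sort(unique(unlist(lapply(seed_records, `[[`, "authors"),
                                        use.names = FALSE))) %||% character(0),
      seed_scopes = sort(unique(unlist(lapply(seed_records, `[[`,
                                              "journal_subject_terms"),
                                       use.names = FALSE))) %||% character(0),
      seed_ids = vapply(seed_records, `[[`, character(1), "record_id"),
      k_limit = as.integer(k_limit)
    ),
    class = "seed_profile"
  )
}

#' @export
print.seed_profile <- function(x, ...) {
  cat("<seed_profile> ", nrow(x$key_terms), " key terms (k_limit=", x$k_limit,
      "), ", length(x$seed_authors), " authors, ", length(x$seed_scopes),
      " scopes\n", sep = "")
  if (nrow(x$key_terms) > 0L)
    print(utils::head(x$key_terms, 10L), row.names = FALSE)
  invisible(x)
}
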
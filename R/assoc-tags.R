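# Associative search within a personal library (IDF-weighted cosine over
# stemmed unigram vectors) and MeSH-enrichment tag suggestion with tag-name
# normalization.

#' Build a record's IDF-weighted term vector
#'
#' Sparse unigram vector over the record's title and abstract tokens:
#' `entries[t] = tf(t) * idf(t)` with raw term-frequency counts (sub-linear
#' damping available via `tf_log`). Terms with zero IDF (present in every
#' record) contribute nothing.
#'
#' @param record A `biblio_record`.
#' @param stats `background_stats` providing the IDF table.
#' @param tf_log If `TRUE`, use `1 + log(tf)` instead of raw counts.
#' @return An object of class `term_vector`: list with `entries` (named
#'   numeric, non-negative) and `norm` (cached Euclidean norm). A record
#'   with no tokens yields the zero vector.
#' @export
build_term_vector <- function(record, stats, tf_log = FALSE) {
  tokens <- c(tokenize(record$title), tokenize(record$abstract))
  if (length(tokens) == 0L) return(term_vector(numeric(0)))
  tf_tab <- table(tokens)
  tf <- as.numeric(tf_tab)
  if (tf_log) tf <- 1 + log(tf)
  w <- tf * idf_of(stats, names(tf_tab))
  names(w) <- names(tf_tab)
  term_vector(w[w > 0])
}

#' Construct a term vector from named weights
#'
#' @param entries Named numeric vector of non-negative term weights.
#' @return A `term_vector` with its Euclidean norm cached.
#' @export
term_vector <- function(entries) {
  if (any(entries < 0)) stop("term weights must be non-negative", call. = FALSE)
  structure(list(entries = entries, norm = sqrt(sum(entries^2))),
            class = "term_vector")
}

#' Cosine similarity of two term vectors
#'
#' Standard cosine in `[0, 1]` (weights are non-negative); 0 when either
#' vector is zero.
#'
#' @param a,b `term_vector` objects.
#' @return Similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (a$norm == 0 || b$norm == 0) return(0)
  shared <- intersect(names(a$entries), names(b$entries))
  if (length(shared) == 0L) return(0)
  sum(a$entries[shared] * b$entries[shared]) / (a$norm * b$norm)
}

#' Associative search within a library
#'
#' Ranks the non-seed records of a library by cosine similarity to the sum
#' of the seed records' term vectors (multiple seed papers are combined by
#' vector addition; ranking is invariant to positive scaling, so this equals
#' the centroid query). Ties broken by ascending record id.
#'
#' @param seed_ids Seed record ids; must all be in `library`.
#' @param library A `biblio_corpus` (the personal library).
#' @param stats `background_stats` providing IDF weights.
#' @param top_m Maximum hits returned; default all non-seed records.
#' @param tf_log Passed to [build_term_vector()].
#' @return data.frame (rank, record_id, similarity) sorted by descending
#'   similarity.
#' @export
associative_search <- function(seed_ids, library, stats, top_m = Inf,
                               tf_log = FALSE) {
  seed_records <- corpus_get(library, unique(seed_ids))
  if (length(unique(seed_ids)) == 1L) seed_records <- list(seed_records)
  seed_vecs <- lapply(seed_records, build_term_vector, stats = stats,
                      tf_log = tf_log)
  all_terms <- unique(unlist(lapply(seed_vecs, function(v) names(v$entries)),
                             use.names = FALSE))
  q <- stats::setNames(numeric(length(all_terms)), all_terms)
  for (v in seed_vecs) q[names(v$entries)] <- q[names(v$entries)] + v$entries
  query_vec <- term_vector(q)
  targets <- setdiff(corpus_ids(library), unique(seed_ids))
  sims <- vapply(targets, function(id)
    cosine_similarity(query_vec,
                      build_term_vector(library$records[[id]], stats,
                                        tf_log = tf_log)),
    numeric(1))
  ord <- order(-sims, targets)
  n <- min(top_m, length(targets))
  idx <- ord[seq_len(n)]
  data.frame(rank = seq_len(n), record_id = targets[idx],
             similarity = unname(sims[idx]), stringsAsFactors = FALSE)
}

#' Normalize a MeSH heading into a tag name
#'
#' Comma-inverted headings like `"Neoplasms, Experimental"` have their
#' comma-separated segments reversed and joined by spaces, then the whole
#' string is lowercased: `"experimental neoplasms"`. Headings without commas
#' are only lowercased. Idempotent.
#'
#' @param mesh_term Non-empty heading string (vectorized).
#' @return Normalized tag name(s).
#' @examples
#' normalize_mesh_tag("Neoplasms, Experimental")
#' @export
normalize_mesh_tag <- function(mesh_term) {
  vapply(mesh_term, function(h) {
    parts <- trimws(strsplit(h, ",", fixed = TRUE)[[1L]])
    tolower(paste(rev(parts[nzchar(parts)]), collapse = " "))
  }, character(1), USE.NAMES = FALSE)
}

#' Suggest tags for a set of papers by MeSH enrichment
#'
#' For every MeSH heading whose document frequency in the given set exceeds
#' the background expectation, computes the hypergeometric point probability
#' of the set count (population = corpus size, successes = background MeSH
#' document count, draws = set size), keeps headings with probability at or
#' below `prob_threshold`, sorts by ascending probability (ties by heading)
#' and truncates to `max_suggestions`.
#'
#' @param set_ids Record ids of the paper set; must all be in `library`.
#' @param library A `biblio_corpus`.
#' @param stats `background_stats` carrying `mesh_doc_count` and
#'   `corpus_size`.
#' @param max_suggestions Maximum suggestions returned; default 10.
#' @param prob_threshold Keep only suggestions with probability at or below
#'   this; default 0.01.
#' @return data.frame (mesh_term, tag_name, set_count, bg_count,
#'   probability), ascending probability.
#' @export
suggest_tags <- function(set_ids, library, stats, max_suggestions = 10L,
                         prob_threshold = 0.01) {
  if (max_suggestions < 1L || prob_threshold <= 0)
    stop("max_suggestions and prob_threshold must be positive", call. = FALSE)
  set_records <- corpus_get(library, unique(set_ids))
  if (length(unique(set_ids)) == 1L) set_records <- list(set_records)
  set_size <- length(set_records)
  tab <- table(unlist(lapply(set_records, function(r) unique(r$mesh_terms)),
                      use.names = FALSE))
  if (length(tab) == 0L) {
    return(data.frame(mesh_term = character(0), tag_name = character(0),
                      set_count = integer(0), bg_count = integer(0),
                      probability = numeric(0), stringsAsFactors = FALSE))
  }
  terms <- names(tab)
  set_count <- as.integer(tab)
  bg_count <- stats$mesh_doc_count[terms]
  bg_count[is.na(bg_count)] <- set_count[is.na(bg_count)]
  bg_count <- unname(bg_count)
  expected <- set_size * bg_count / stats$corpus_size
  keep <- set_count > expected
  terms <- terms[keep]; set_count <- set_count[keep]; bg_count <- bg_count[keep]
  prob <- if (length(terms) == 0L) numeric(0) else
    stats::dhyper(set_count, bg_count, stats$corpus_size - bg_count, set_size)
  sel <- prob <= prob_threshold
  terms <- terms[sel]; set_count <- set_count[sel]
  bg_count <- bg_count[sel]; prob <- prob[sel]
  ord <- order(prob, terms)
  ord <- ord[seq_len(min(max_suggestions, length(ord)))]
  data.frame(
    mesh_term = terms[ord],
    tag_name = normalize_mesh_tag(terms[ord]),
    set_count = set_count[ord],
    bg_count = bg_count[ord],
    probability = prob[ord],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
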
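# Corpus-wide background statistics: the N-gram dictionary with document and
# occurrence frequencies, the IDF table derived from it, and MeSH document
# counts. Everything statistical downstream (key-term enrichment, query
# scoring, term vectors, tag suggestion) consumes these.

# contiguous n-grams (joined by single spaces) of one token vector
.ngrams_of <- function(tokens, max_n) {
  L <- length(tokens)
  if (L == 0L) return(character(0))
  out <- vector("list", min(max_n, L))
  for (n in seq_len(min(max_n, L))) {
    if (n == 1L) {
      out[[n]] <- tokens
    } else {
      m <- L - n + 1L
      grams <- tokens[seq_len(m)]
      for (k in 2:n) grams <- paste(grams, tokens[k:(k + m - 1L)])
      out[[n]] <- grams
    }
  }
  unlist(out, use.names = FALSE)
}

# n-grams of a record: title and abstract streams, never crossing the boundary
.record_ngrams <- function(record, max_n) {
  c(.ngrams_of(tokenize(record$title), max_n),
    .ngrams_of(tokenize(record$abstract), max_n))
}

#' Build the corpus N-gram dictionary
#'
#' Enumerates contiguous runs of 1 to `max_n` tokens over each record's title
#' and abstract token streams (runs never span the title/abstract boundary)
#' and tallies, per term, the number of distinct records containing it and
#' its total occurrence count.
#'
#' @param corpus A non-empty `biblio_corpus`.
#' @param max_n Maximum N-gram token length; default 5.
#' @return An object of class `ngram_dictionary` with elements `max_n`,
#'   `corpus_size`, `term_doc_count` (named integer) and `term_total_count`
#'   (named integer).
#' @export
build_ngram_dictionary <- function(corpus, max_n = 5L) {
  if (corpus_size(corpus) == 0L)
    stop("cannot build an N-gram dictionary from an empty corpus", call. = FALSE)
  if (max_n < 1L) stop("max_n must be >= 1", call. = FALSE)
  per_record <- lapply(corpus$records, .record_ngrams, max_n = max_n)
  all_grams <- unlist(per_record, use.names = FALSE)
  total <- table(all_grams)
  doc <- table(unlist(lapply(per_record, unique), use.names = FALSE))
  term_total <- as.integer(total); names(term_total) <- names(total)
  term_doc <- as.integer(doc); names(term_doc) <- names(doc)
  # same key set by construction; align doc counts to total's order
  term_doc <- term_doc[names(term_total)]
  structure(
    list(max_n = as.integer(max_n), corpus_size = corpus_size(corpus),
         term_doc_count = term_doc, term_total_count = term_total),
    class = "ngram_dictionary"
  )
}

#' Build the full background statistics for a corpus
#'
#' Combines the N-gram dictionary with the IDF table
#' `idf[t] = log(corpus_size / doc_count[t])` (natural log, no smoothing)
#' and per-MeSH-heading document counts.
#'
#' @inheritParams build_ngram_dictionary
#' @return An object of class `background_stats` with elements `ngrams`
#'   (an `ngram_dictionary`), `idf` (named numeric), `mesh_doc_count`
#'   (named integer) and `corpus_size`.
#' @export
build_background_stats <- function(corpus, max_n = 5L) {
  ngrams <- build_ngram_dictionary(corpus, max_n)
  idf <- log(ngrams$corpus_size / ngrams$term_doc_count)
  mesh_all <- unlist(lapply(corpus$records, function(r) unique(r$mesh_terms)),
                     use.names = FALSE)
  mesh_tab <- table(mesh_all)
  mesh_doc <- as.integer(mesh_tab); names(mesh_doc) <- names(mesh_tab)
  structure(
    list(ngrams = ngrams, idf = idf, mesh_doc_count = mesh_doc,
         corpus_size = ngrams$corpus_size),
    class = "background_stats"
  )
}

#' @export
print.background_stats <- function(x, ...) {
  cat("<background_stats> corpus_size=", x$corpus_size,
      " terms=", length(x$idf),
      " mesh=", length(x$mesh_doc_count),
      " max_n=", x$ngrams$max_n, "\n", sep = "")
  invisible(x)
}

#' IDF of terms, with out-of-vocabulary fallback
#'
#' Terms absent from the background are scored as if they occurred in one
#' record, i.e. `log(corpus_size)`; needed for out-of-vocabulary seed terms.
#'
#' @param stats A `background_stats`.
#' @param terms Character vector of terms.
#' @return Numeric vector of IDF values.
#' @export
idf_of <- function(stats, terms) {
  v <- stats$idf[terms]
  v[is.na(v)] <- log(stats$corpus_size)
  unname(v)
}

# --- serialized index --------------------------------------------------------

.INDEX_FORMAT_VERSION <- 1L

#' Write a background-statistics index file
#'
#' Versioned JSON container holding corpus size, `max_n` and the term and
#' MeSH tables. The IDF table is derived, so only counts are stored.
#'
#' @param stats A `background_stats`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(stats, path) {
  obj <- list(
    format = jsonlite::unbox("litrec-index"),
    version = jsonlite::unbox(.INDEX_FORMAT_VERSION),
    corpus_size = jsonlite::unbox(stats$corpus_size),
    max_n = jsonlite::unbox(stats$ngrams$max_n),
    terms = names(stats$ngrams$term_doc_count),
    term_doc_count = unname(stats$ngrams$term_doc_count),
    term_total_count = unname(stats$ngrams$term_total_count),
    mesh_terms = names(stats$mesh_doc_count),
    mesh_doc_count = unname(stats$mesh_doc_count)
  )
  writeLines(jsonlite::toJSON(obj), path, useBytes = TRUE)
  invisible(path)
}

#' Read a background-statistics index file
#'
#' @param path Path written by [write_index()].
#' @return A `background_stats`.
#' @export
read_index <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "litrec-index") ||
      !identical(as.integer(obj$version), .INDEX_FORMAT_VERSION))
    stop("not a recognized index file: ", path, call. = FALSE)
  term_doc <- as.integer(obj$term_doc_count); names(term_doc) <- obj$terms
  term_total <- as.integer(obj$term_total_count); names(term_total) <- obj$terms
  mesh <- as.integer(obj$mesh_doc_count); names(mesh) <- obj$mesh_terms
  ngrams <- structure(
    list(max_n = as.integer(obj$max_n),
         corpus_size = as.integer(obj$corpus_size),
         term_doc_count = term_doc, term_total_count = term_total),
    class = "ngram_dictionary"
  )
  structure(
    list(ngrams = ngrams, idf = log(ngrams$corpus_size / term_doc),
         mesh_doc_count = mesh, corpus_size = ngrams$corpus_size),
    class = "background_stats"
  )
}
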
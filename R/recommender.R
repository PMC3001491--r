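# The recency recommendation engine: build a structured query from a seed
# profile, restrict candidates to a calendar window before the query date,
# and rank them by an additive score over key-term matches (title matches
# boosted), shared authors, and journal-scope overlap.

# calendar-month subtraction with day clamping: 2010-03-31 minus 1 month is
# 2010-02-28
add_months <- function(date, months) {
  lt <- as.POSIXlt(as.Date(date))
  y <- lt$year + 1900L
  m0 <- lt$mon + months            # zero-based month, possibly out of range
  y <- y + m0 %/% 12L
  m <- m0 %% 12L + 1L
  first <- as.Date(sprintf("%04d-%02d-01", y, m))
  next_first <- if (m == 12L) as.Date(sprintf("%04d-01-01", y + 1L)) else
    as.Date(sprintf("%04d-%02d-01", y, m + 1L))
  last_day <- as.integer(format(next_first - 1L, "%d"))
  first + min(lt$mday, last_day) - 1L
}

#' Build a structured recommendation query
#'
#' Concretizes the seed profile plus the scoring coefficients and the date
#' window into one query object. The additive score of a candidate is
#' `term_score + author_score + scope_score` where a key term matched in the
#' title counts `title_boost` times its weight, each shared author adds
#' `author_bonus`, and any journal-scope overlap adds `scope_bonus`. By
#' default `author_bonus` and `scope_bonus` are one median key-term weight,
#' so no single context signal can dominate the term evidence.
#'
#' @param profile A `seed_profile` from [extract_key_terms()].
#' @param title_boost Multiplier (>= 1) for key terms matched in the title;
#'   default 2.
#' @param author_bonus Score added per shared author; default the median
#'   key-term weight.
#' @param scope_bonus Score added when journal scopes overlap; default the
#'   median key-term weight.
#' @param window_months Length of the recency window in calendar months;
#'   default 3. `NULL` disables date filtering (associative-search-
#'   against-corpus mode).
#' @param as_of_date Query date; the window is `(as_of_date - window_months,
#'   as_of_date]`.
#' @param stop_terms Terms removed from the profile's key terms before
#'   scoring.
#' @param must_terms Terms a candidate must contain to be admitted.
#' @return An object of class `structured_query`.
#' @export
structured_query <- function(profile, title_boost = 2, author_bonus = NULL,
                             scope_bonus = NULL, window_months = 3L,
                             as_of_date = Sys.Date(),
                             stop_terms = character(0),
                             must_terms = character(0)) {
  if (title_boost < 1) stop("title_boost must be >= 1", call. = FALSE)
  if (!is.null(window_months) && window_months < 1L)
    stop("window_months must be >= 1 (or NULL to disable)", call. = FALSE)
  key_terms <- profile$key_terms
  if (length(stop_terms) > 0L)
    key_terms <- key_terms[!(key_terms$term %in% stop_terms), , drop = FALSE]
  med_w <- if (nrow(key_terms) > 0L) stats::median(key_terms$weight) else 0
  structure(
    list(
      key_terms = key_terms,
      seed_authors = profile$seed_authors,
      seed_scopes = profile$seed_scopes,
      seed_ids = profile$seed_ids,
      title_boost = title_boost,
      author_bonus = if (is.null(author_bonus)) med_w else author_bonus,
      scope_bonus = if (is.null(scope_bonus)) med_w else scope_bonus,
      window_months = if (is.null(window_months)) NULL else as.integer(window_months),
      as_of_date = as.Date(as_of_date),
      stop_terms = as.character(stop_terms),
      must_terms = as.character(must_terms)
    ),
    class = "structured_query"
  )
}

#' Restrict a corpus to the recency window
#'
#' Keeps records whose `registered_date` lies in the half-open calendar
#' window `(as_of_date - window_months, as_of_date]`, then removes
#' `exclude_ids` (a seed library is excluded from its own recommendations).
#'
#' @param corpus A `biblio_corpus`.
#' @param as_of_date Query date.
#' @param window_months Window length in calendar months; default 3.
#' @param exclude_ids Record ids to drop from the result.
#' @return Character vector of surviving record ids, in corpus order.
#' @export
filter_target_window <- function(corpus, as_of_date, window_months = 3L,
                                 exclude_ids = character(0)) {
  if (window_months < 1L) stop("window_months must be >= 1", call. = FALSE)
  as_of <- as.Date(as_of_date)
  lower <- add_months(as_of, -as.integer(window_months))
  dates <- as.Date(vapply(corpus$records, function(r)
    format(r$registered_date, "%Y-%m-%d"), character(1)))
  ids <- corpus_ids(corpus)
  keep <- dates > lower & dates <= as_of
  setdiff(ids[keep], exclude_ids)
}

# all distinct n-grams of one token stream up to max_n, for match lookups
.gram_set <- function(tokens, max_n) unique(.ngrams_of(tokens, max_n))

#' Score one candidate record against a structured query
#'
#' A record is admitted only if it matches at least one key term (after
#' stop-term filtering) and contains every `must_term`. Matching is
#' contiguous-token-subsequence containment under the corpus normalization.
#'
#' @param record A `biblio_record`.
#' @param query A `structured_query`.
#' @param max_n Maximum N-gram length used for matching (the index's
#'   `max_n`); default 5.
#' @return A one-row data.frame (record_id, term_score, author_score,
#'   scope_score, total, matched_terms as a comma-joined string), or `NULL`
#'   if the record is not admitted.
#' @export
score_candidate <- function(record, query, max_n = 5L) {
  title_grams <- .gram_set(tokenize(record$title), max_n)
  abstract_grams <- .gram_set(tokenize(record$abstract), max_n)
  any_grams <- c(title_grams, abstract_grams)
  if (length(query$must_terms) > 0L &&
      !all(query$must_terms %in% any_grams)) return(NULL)
  kt <- query$key_terms
  if (nrow(kt) == 0L) return(NULL)
  in_title <- kt$term %in% title_grams
  in_abstract <- kt$term %in% abstract_grams
  matched <- in_title | in_abstract
  if (!any(matched)) return(NULL)
  term_score <- sum(kt$weight[matched] * ifelse(in_title[matched],
                                                query$title_boost, 1))
  author_score <- query$author_bonus *
    length(intersect(record$authors, query$seed_authors))
  scope_score <- if (length(intersect(record$journal_subject_terms,
                                      query$seed_scopes)) > 0L)
    query$scope_bonus else 0
  data.frame(
    record_id = record$record_id,
    term_score = term_score,
    author_score = author_score,
    scope_score = scope_score,
    total = term_score + author_score + scope_score,
    matched_terms = paste(kt$term[matched], collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Recommend recent papers for a seed library
#'
#' The full pipeline: extract key terms from the seed set, apply stop/must
#' term tuning, restrict the corpus to the recency window (seed records
#' excluded), score every candidate and return the top hits sorted by
#' descending total score, ties broken by ascending record id. With
#' `window_months = NULL` the same machinery ranks the whole corpus, which
#' serves as associative search of arbitrary seed sets against the corpus.
#'
#' @param seed_ids Seed record ids.
#' @param corpus The background `biblio_corpus`.
#' @param stats `background_stats` for `corpus`.
#' @param top_m Maximum number of hits returned; default 20.
#' @param k_limit,title_boost,author_bonus,scope_bonus,window_months,as_of_date,stop_terms,must_terms
#'   Query configuration; see [extract_key_terms()] and [structured_query()].
#' @return A data.frame of ranked hits (rank, record_id, total, term_score,
#'   author_score, scope_score, matched_terms); zero rows if nothing is
#'   admitted.
#' @export
recommend <- function(seed_ids, corpus, stats, top_m = 20L, k_limit = 75L,
                      title_boost = 2, author_bonus = NULL, scope_bonus = NULL,
                      window_months = 3L, as_of_date = Sys.Date(),
                      stop_terms = character(0), must_terms = character(0)) {
  if (top_m < 1L) stop("top_m must be >= 1", call. = FALSE)
  profile <- extract_key_terms(seed_ids, corpus, stats, k_limit = k_limit)
  query <- structured_query(profile, title_boost = title_boost,
                            author_bonus = author_bonus,
                            scope_bonus = scope_bonus,
                            window_months = window_months,
                            as_of_date = as_of_date,
                            stop_terms = stop_terms, must_terms = must_terms)
  candidates <- if (is.null(query$window_months)) {
    setdiff(corpus_ids(corpus), query$seed_ids)
  } else {
    filter_target_window(corpus, query$as_of_date, query$window_months,
                         exclude_ids = query$seed_ids)
  }
  rows <- lapply(candidates, function(id)
    score_candidate(corpus$records[[id]], query, max_n = stats$ngrams$max_n))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(rank = integer(0), record_id = character(0),
                      total = numeric(0), term_score = numeric(0),
                      author_score = numeric(0), scope_score = numeric(0),
                      matched_terms = character(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  ord <- order(-hits$total, hits$record_id)
  hits <- hits[ord[seq_len(min(top_m, nrow(hits)))], , drop = FALSE]
  hits <- cbind(rank = seq_len(nrow(hits)), hits)
  rownames(hits) <- NULL
  hits[, c("rank", "record_id", "total", "term_score", "author_score",
           "scope_score", "matched_terms")]
}
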
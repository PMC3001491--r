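# Metadata utilities: DOI harvesting from free text, exact-title lookup
# against a corpus, and filename-pattern rendering for library files.

.DOI_REGEX <- "10\\.[0-9]{4,9}/[^[:space:]\"<>]+"

#' Extract DOIs from text
#'
#' Finds all substrings matching the DOI syntax `10.<registrant>/<suffix>`,
#' strips an optional `doi:` prefix, trims trailing sentence punctuation
#' that PDF text commonly glues onto identifiers, preserves order of first
#' appearance and removes duplicates.
#'
#' @param text Character scalar of arbitrary text.
#' @return Character vector of DOI strings (possibly empty).
#' @examples
#' extract_dois("see doi:10.1371/journal.pone.0000000 for details")
#' @export
extract_dois <- function(text) {
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character(0))
  m <- gregexpr(paste0("(?i)(doi:)?", .DOI_REGEX), text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(character(0))
  hits <- regmatches(text, list(m))[[1L]]
  hits <- sub("^(?i)doi:", "", hits, perl = TRUE)
  hits <- sub("[].,;:)]+$", "", hits)
  unique(hits[grepl(paste0("^", .DOI_REGEX, "$"), hits)])
}

#' Find corpus titles occurring in a text
#'
#' Returns the ids of records whose normalized title (at least
#' `min_title_tokens` tokens under the corpus tokenization) occurs as a
#' contiguous token subsequence of the normalized text. Results are ordered
#' longest-title-first (ties by record id). The token threshold guards
#' against generic short titles matching spuriously.
#'
#' @param text Character scalar (e.g. text extracted from a PDF).
#' @param corpus A `biblio_corpus`.
#' @param min_title_tokens Minimum normalized-title length considered;
#'   default 4.
#' @return Character vector of record ids.
#' @export
title_lookup <- function(text, corpus, min_title_tokens = 4L) {
  text_tokens <- tokenize(text)
  if (length(text_tokens) == 0L) return(character(0))
  padded <- paste0(" ", paste(text_tokens, collapse = " "), " ")
  cand <- Filter(Negate(is.null), lapply(corpus$records, function(r) {
    tt <- tokenize(r$title)
    if (length(tt) < min_title_tokens) return(NULL)
    if (grepl(paste0(" ", paste(tt, collapse = " "), " "), padded,
              fixed = TRUE))
      list(id = r$record_id, len = length(tt))
    else NULL
  }))
  if (length(cand) == 0L) return(character(0))
  ids <- unname(vapply(cand, `[[`, character(1), "id"))
  lens <- unname(vapply(cand, `[[`, integer(1), "len"))
  ids[order(-lens, ids)]
}

.WILDCARDS <- c("TITLE", "YEAR", "JOURNAL", "FIRSTAUTHOR", "PMID")
.UNSAFE_CHARS_REGEX <- "[/\\\\:*?\"<>|[:cntrl:]]"
.FIELD_MAX_CHARS <- 80L
.MISSING_PLACEHOLDER <- "unknown"

# split a template into literal text and $WILDCARD pieces; unknown wildcards
# are rejected before any rendering happens
.parse_pattern <- function(template) {
  m <- gregexpr("\\$[A-Za-z]+", template)[[1L]]
  if (m[1L] == -1L) return(list(literals = template, wildcards = character(0)))
  found <- regmatches(template, list(m))[[1L]]
  names_found <- sub("^\\$", "", found)
  bad <- setdiff(names_found, .WILDCARDS)
  if (length(bad) > 0L)
    stop("unknown wildcard(s) in pattern: ",
         paste0("$", bad, collapse = ", "),
         "; allowed: ", paste0("$", .WILDCARDS, collapse = ", "),
         call. = FALSE)
  list(template = template, wildcards = names_found)
}

.sanitize_field <- function(value) {
  if (length(value) == 0L || is.na(value) || !nzchar(value))
    return(.MISSING_PLACEHOLDER)
  v <- gsub(.UNSAFE_CHARS_REGEX, "_", value)
  v <- gsub("[[:space:]]+", " ", trimws(v))
  if (nchar(v) > .FIELD_MAX_CHARS) v <- substr(v, 1L, .FIELD_MAX_CHARS)
  if (!nzchar(v)) .MISSING_PLACEHOLDER else v
}

#' Render a filename from a pattern and a record
#'
#' Substitutes `$TITLE`, `$YEAR`, `$JOURNAL`, `$FIRSTAUTHOR` and `$PMID`
#' wildcards with sanitized field values: filesystem-unsafe characters
#' become `_`, fields are length-capped at 80 characters, and a missing
#' field renders as `unknown`. Literal text is preserved. Malformed
#' patterns (unknown wildcards) fail before any rendering.
#'
#' @param pattern Template string, e.g. `"$FIRSTAUTHOR-$YEAR.pdf"`.
#' @param record A `biblio_record`.
#' @return Rendered filename string.
#' @examples
#' r <- biblio_record("1", title = "On growth", authors = "Smith JD",
#'                    registered_date = "2009-05-01")
#' render_filename("$FIRSTAUTHOR-$YEAR.pdf", r)  # "Smith-2009.pdf"
#' @export
render_filename <- function(pattern, record) {
  parsed <- .parse_pattern(pattern)
  if (length(parsed$wildcards) == 0L) return(pattern)
  first_author <- if (length(record$authors) > 0L) {
    ln <- strsplit(record$authors[[1L]], " ", fixed = TRUE)[[1L]][1L]
    paste0(toupper(substr(ln, 1L, 1L)), substr(ln, 2L, nchar(ln)))
  } else ""
  values <- c(
    TITLE = .sanitize_field(record$title),
    YEAR = .sanitize_field(format(record$registered_date, "%Y")),
    JOURNAL = .sanitize_field(record$journal),
    FIRSTAUTHOR = .sanitize_field(first_author),
    PMID = .sanitize_field(record$record_id)
  )
  out <- pattern
  for (w in .WILDCARDS) {
    out <- gsub(paste0("$", w), values[[w]], out, fixed = TRUE)
  }
  out
}
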
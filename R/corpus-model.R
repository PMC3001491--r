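# Domain types and readers/writers for bibliographic corpora:
# biblio_record, biblio_corpus, tokenization, JSONL and MEDLINE-subset XML I/O.

#' Normalize author names
#'
#' Collapses "LastName Initials" strings to a canonical lowercase,
#' single-space form and removes duplicates while preserving order.
#'
#' @param authors Character vector of author name strings.
#' @return Character vector of normalized names.
#' @export
normalize_author <- function(authors) {
  x <- tolower(trimws(authors))
  x <- gsub("[[:space:]]+", " ", x)
  unique(x[nzchar(x)])
}

#' Construct a bibliographic record
#'
#' One record of a bibliographic corpus: a PMID-like identifier plus title,
#' abstract, authors, journal, NLM Journal Subject Terms, MeSH headings and
#' the date the record entered the index.
#'
#' @param record_id Non-empty identifier string, unique within a corpus.
#' @param title Title text.
#' @param abstract Abstract text (may be empty).
#' @param authors Character vector of author names; normalized with
#'   [normalize_author()], order preserved, duplicates dropped.
#' @param journal Journal name.
#' @param journal_subject_terms Character vector of Journal Subject Terms.
#' @param mesh_terms Character vector of MeSH headings (possibly
#'   comma-inverted, e.g. `"Neoplasms, Experimental"`).
#' @param registered_date A `Date` (or an ISO-8601 string coercible to one).
#' @return An object of class `biblio_record`.
#' @export
biblio_record <- function(record_id, title = "", abstract = "",
                          authors = character(0), journal = "",
                          journal_subject_terms = character(0),
                          mesh_terms = character(0),
                          registered_date = as.Date("1970-01-01")) {
  if (!is.character(record_id) || length(record_id) != 1L || !nzchar(record_id))
    stop("record_id must be a single non-empty string", call. = FALSE)
  d <- as.Date(registered_date)
  if (length(d) != 1L || is.na(d))
    stop("registered_date is not a valid calendar date for record ", record_id,
         call. = FALSE)
  structure(
    list(
      record_id = record_id,
      title = as.character(title)[1L],
      abstract = as.character(abstract)[1L],
      authors = normalize_author(authors),
      journal = as.character(journal)[1L],
      journal_subject_terms = sort(unique(as.character(journal_subject_terms))),
      mesh_terms = sort(unique(as.character(mesh_terms))),
      registered_date = d
    ),
    class = "biblio_record"
  )
}

#' Construct a corpus from bibliographic records
#'
#' @param records List of [biblio_record()] objects.
#' @return An object of class `biblio_corpus` whose `records` element is a
#'   list named by `record_id` (the id index), in input order.
#' @export
biblio_corpus <- function(records = list()) {
  ids <- vapply(records, function(r) r$record_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate record_id in corpus: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  names(records) <- ids
  structure(list(records = records), class = "biblio_corpus")
}

#' @export
print.biblio_corpus <- function(x, ...) {
  cat("<biblio_corpus> ", length(x$records), " records\n", sep = "")
  invisible(x)
}

#' Corpus record identifiers
#' @param corpus A `biblio_corpus`.
#' @return Character vector of record ids, in corpus order.
#' @export
corpus_ids <- function(corpus) names(corpus$records)

#' Number of records in a corpus
#' @param corpus A `biblio_corpus`.
#' @return Integer record count.
#' @export
corpus_size <- function(corpus) length(corpus$records)

#' Look up records by id
#'
#' @param corpus A `biblio_corpus`.
#' @param ids Character vector of record ids; every id must be present.
#' @return For one id, the record; for several, a list of records.
#' @export
corpus_get <- function(corpus, ids) {
  missing <- setdiff(ids, names(corpus$records))
  if (length(missing) > 0L)
    stop("unknown record id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(ids) == 1L) corpus$records[[ids]] else corpus$records[ids]
}

#' Tokenize text for indexing and search
#'
#' The single normalization used everywhere in the package: lowercase, split
#' on non-alphanumeric characters, drop single-digit number tokens, remove
#' stop words, then Porter-stem. Deterministic: equal input always yields
#' equal tokens.
#'
#' @param text Character scalar (may be empty or `NA`, both yield no tokens).
#' @return Character vector of tokens in source order (possibly empty).
#' @examples
#' tokenize("The hypergeometric distributions")  # "hypergeometr" "distribut"
#' @export
tokenize <- function(text) {
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!grepl("^[0-9]$", toks)]
  toks <- toks[!(toks %in% .STOP_WORDS)]
  porter_stem(toks)
}

# --- JSONL dialect -----------------------------------------------------------
# One UTF-8 JSON object per line with keys: record_id, title, abstract,
# authors (array), journal, journal_subject_terms (array), mesh_terms (array),
# registered_date ("YYYY-MM-DD"). abstract and the array fields are optional
# on input and default to empty.

.record_from_list <- function(obj, where) {
  if (is.null(obj$record_id))
    stop("missing record_id at ", where, call. = FALSE)
  biblio_record(
    record_id = obj$record_id,
    title = if (is.null(obj$title)) "" else obj$title,
    abstract = if (is.null(obj$abstract)) "" else obj$abstract,
    authors = unlist(obj$authors, use.names = FALSE) %||% character(0),
    journal = if (is.null(obj$journal)) "" else obj$journal,
    journal_subject_terms = unlist(obj$journal_subject_terms, use.names = FALSE) %||% character(0),
    mesh_terms = unlist(obj$mesh_terms, use.names = FALSE) %||% character(0),
    registered_date = if (is.null(obj$registered_date)) "1970-01-01" else obj$registered_date
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a corpus from JSONL
#'
#' Reads the one-record-per-line JSON dialect. Malformed lines and duplicate
#' ids are hard errors that name the offending line numbers.
#'
#' @param path File path (or connection) with one JSON object per line.
#' @return A `biblio_corpus`.
#' @export
read_corpus_jsonl <- function(path) {
  if (is.character(path) && !file.exists(path))
    stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  records <- vector("list", length(lines_keep))
  seen <- new.env(parent = emptyenv())
  for (j in seq_along(lines_keep)) {
    i <- lines_keep[j]
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) stop("undecodable JSON at line ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    rec <- .record_from_list(obj, paste0("line ", i))
    if (!is.null(seen[[rec$record_id]]))
      stop("duplicate record_id '", rec$record_id, "' at lines ",
           seen[[rec$record_id]], " and ", i, call. = FALSE)
    seen[[rec$record_id]] <- i
    records[[j]] <- rec
  }
  biblio_corpus(records)
}

#' Write a corpus to JSONL
#'
#' Writes the canonical form of the JSONL dialect: fixed key order, arrays
#' kept as arrays, dates as ISO-8601. Reading a canonically written file and
#' writing it again reproduces the bytes.
#'
#' @param corpus A `biblio_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus$records, function(r) {
    jsonlite::toJSON(list(
      record_id = jsonlite::unbox(r$record_id),
      title = jsonlite::unbox(r$title),
      abstract = jsonlite::unbox(r$abstract),
      authors = r$authors,
      journal = jsonlite::unbox(r$journal),
      journal_subject_terms = r$journal_subject_terms,
      mesh_terms = r$mesh_terms,
      registered_date = jsonlite::unbox(format(r$registered_date, "%Y-%m-%d"))
    ), auto_unbox = FALSE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# --- MEDLINE-subset XML ------------------------------------------------------

#' Read a corpus from MEDLINE-subset XML
#'
#' Parses the restricted MedlineCitation dialect: `PMID`, `DateCreated`
#' (Year/Month/Day), `Article/ArticleTitle`, `Article/Abstract/AbstractText`,
#' `Article/AuthorList/Author` (LastName + Initials), `MedlineTA`,
#' `MeshHeadingList/MeshHeading/DescriptorName`. Elements outside the subset
#' are ignored. The dialect has no Journal Subject Terms element, so those
#' are empty on XML-read records.
#'
#' @param path Path to a well-formed XML file.
#' @return A `biblio_corpus` with the same semantics as the JSONL reader.
#' @export
read_corpus_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  cits <- xml2::xml_find_all(doc, ".//MedlineCitation")
  records <- lapply(cits, function(cit) {
    pmid <- xml2::xml_text(xml2::xml_find_first(cit, "./PMID"))
    if (is.na(pmid) || !nzchar(pmid))
      stop("MedlineCitation without PMID", call. = FALSE)
    y <- xml2::xml_text(xml2::xml_find_first(cit, "./DateCreated/Year"))
    m <- xml2::xml_text(xml2::xml_find_first(cit, "./DateCreated/Month"))
    d <- xml2::xml_text(xml2::xml_find_first(cit, "./DateCreated/Day"))
    date <- if (is.na(y)) as.Date("1970-01-01") else
      as.Date(sprintf("%s-%s-%s", y, m, d))
    title <- xml2::xml_text(xml2::xml_find_first(cit, "./Article/ArticleTitle"))
    abstract <- xml2::xml_text(
      xml2::xml_find_first(cit, "./Article/Abstract/AbstractText"))
    authors <- vapply(
      xml2::xml_find_all(cit, "./Article/AuthorList/Author"),
      function(a) {
        ln <- xml2::xml_text(xml2::xml_find_first(a, "./LastName"))
        ini <- xml2::xml_text(xml2::xml_find_first(a, "./Initials"))
        trimws(paste(ln[!is.na(ln)], ini[!is.na(ini)]))
      }, character(1))
    journal <- xml2::xml_text(xml2::xml_find_first(cit, ".//MedlineTA"))
    mesh <- xml2::xml_text(
      xml2::xml_find_all(cit, "./MeshHeadingList/MeshHeading/DescriptorName"))
    biblio_record(
      record_id = pmid,
      title = if (is.na(title)) "" else title,
      abstract = if (is.na(abstract)) "" else abstract,
      authors = authors,
      journal = if (is.na(journal)) "" else journal,
      journal_subject_terms = character(0),
      mesh_terms = mesh,
      registered_date = date
    )
  })
  ids <- vapply(records, function(r) r$record_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate PMID in XML: ", paste(dup, collapse = ", "), call. = FALSE)
  biblio_corpus(records)
}
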
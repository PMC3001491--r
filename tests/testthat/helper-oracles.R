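# Independent oracles and small fixture builders. Everything here recomputes
# quantities by the most direct route available (loops, enumeration, dense
# algebra) and deliberately shares no code path with the package internals
# it checks, beyond the pinned tokenization.

# brute-force sliding-window n-gram enumeration over one token vector
oracle_ngrams <- function(tokens, max_n) {
  out <- character(0)
  L <- length(tokens)
  for (start in seq_len(L)) {
    for (n in seq_len(max_n)) {
      if (start + n - 1L > L) break
      out <- c(out, paste(tokens[start:(start + n - 1L)], collapse = " "))
    }
  }
  out
}

oracle_record_ngrams <- function(record, max_n) {
  c(oracle_ngrams(tokenize(record$title), max_n),
    oracle_ngrams(tokenize(record$abstract), max_n))
}

# direct tally of doc and total counts over a corpus
oracle_ngram_counts <- function(corpus, max_n) {
  doc <- list(); total <- list()
  for (r in corpus$records) {
    grams <- oracle_record_ngrams(r, max_n)
    for (g in unique(grams)) doc[[g]] <- (doc[[g]] %||% 0L) + 1L
    for (g in grams) total[[g]] <- (total[[g]] %||% 0L) + 1L
  }
  list(doc = unlist(doc), total = unlist(total))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hypergeometric pmf by exhaustive enumeration of all draws of seed_size
# papers from bg_size, counting draws containing exactly seed_hits of the
# bg_hits marked papers
oracle_hyper_pmf <- function(seed_hits, seed_size, bg_hits, bg_size) {
  if (seed_size == 0L) return(as.numeric(seed_hits == 0L))
  draws <- utils::combn(bg_size, seed_size)
  marked <- seq_len(bg_hits)
  hits_per_draw <- colSums(matrix(draws %in% marked, nrow = seed_size))
  mean(hits_per_draw == seed_hits)
}

# full key-term extraction recomputed with loops
oracle_key_terms <- function(seed_ids, corpus, max_n, corpus_counts, k_limit) {
  seed_size <- length(seed_ids)
  bg_size <- corpus_size(corpus)
  seed_doc <- list()
  for (id in seed_ids) {
    grams <- unique(oracle_record_ngrams(corpus$records[[id]], max_n))
    for (g in grams) seed_doc[[g]] <- (seed_doc[[g]] %||% 0L) + 1L
  }
  rows <- list()
  for (g in names(seed_doc)) {
    sh <- seed_doc[[g]]
    bh <- corpus_counts$doc[[g]]
    if (sh > seed_size * bh / bg_size) {
      p <- stats::dhyper(sh, bh, bg_size - bh, seed_size)
      rows[[g]] <- data.frame(term = g, seed_doc_count = sh,
                              background_doc_count = bh, probability = p,
                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(term = character(0), seed_doc_count = integer(0),
                      background_doc_count = integer(0),
                      probability = numeric(0)))
  df <- do.call(rbind, rows)
  df <- df[order(df$probability, df$term), , drop = FALSE]
  df <- utils::head(df, k_limit)
  df$weight <- -log(df$probability)
  rownames(df) <- NULL
  df
}

# naive end-to-end recommendation: loops only
oracle_recommend <- function(seed_ids, corpus, max_n, top_m, k_limit = 75L,
                             title_boost = 2, window_months = 3L,
                             as_of_date) {
  counts <- oracle_ngram_counts(corpus, max_n)
  kt <- oracle_key_terms(seed_ids, corpus, max_n, counts, k_limit)
  med_w <- if (nrow(kt) > 0L) stats::median(kt$weight) else 0
  seed_authors <- unique(unlist(lapply(seed_ids, function(id)
    corpus$records[[id]]$authors)))
  seed_scopes <- unique(unlist(lapply(seed_ids, function(id)
    corpus$records[[id]]$journal_subject_terms)))
  lower <- litrec:::add_months(as.Date(as_of_date), -window_months)
  rows <- list()
  for (r in corpus$records) {
    if (r$record_id %in% seed_ids) next
    if (!(r$registered_date > lower && r$registered_date <= as.Date(as_of_date)))
      next
    tg <- unique(oracle_ngrams(tokenize(r$title), max_n))
    ag <- unique(oracle_ngrams(tokenize(r$abstract), max_n))
    term_score <- 0; matched <- character(0)
    for (i in seq_len(nrow(kt))) {
      t <- kt$term[i]
      if (t %in% tg) {
        term_score <- term_score + kt$weight[i] * title_boost
        matched <- c(matched, t)
      } else if (t %in% ag) {
        term_score <- term_score + kt$weight[i]
        matched <- c(matched, t)
      }
    }
    if (length(matched) == 0L) next
    author_score <- med_w * length(intersect(r$authors, seed_authors))
    scope_score <- if (length(intersect(r$journal_subject_terms,
                                        seed_scopes)) > 0L) med_w else 0
    rows[[r$record_id]] <- data.frame(
      record_id = r$record_id, term_score = term_score,
      author_score = author_score, scope_score = scope_score,
      total = term_score + author_score + scope_score,
      matched_terms = paste(matched, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(record_id = character(0), term_score = numeric(0),
                      author_score = numeric(0), scope_score = numeric(0),
                      total = numeric(0), matched_terms = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(-df$total, df$record_id), , drop = FALSE]
  df <- utils::head(df, top_m)
  rownames(df) <- NULL
  df
}

# --- tiny hand-built fixtures ------------------------------------------------

tiny_record <- function(id, title = "", abstract = "", authors = character(0),
                        journal = "", scopes = character(0),
                        mesh = character(0), date = "2010-06-15") {
  biblio_record(record_id = id, title = title, abstract = abstract,
                authors = authors, journal = journal,
                journal_subject_terms = scopes, mesh_terms = mesh,
                registered_date = date)
}

tiny_corpus <- function(...) biblio_corpus(list(...))

# small corpus with interpretable content for reader and metadata tests
fixture_corpus <- function() {
  tiny_corpus(
    tiny_record("101",
                title = "Hypergeometric enrichment of gene annotations",
                abstract = "We test enrichment of annotations using the hypergeometric distribution across genomes.",
                authors = c("Smith JD", "Jones AB"),
                journal = "J Comput Biol",
                scopes = c("Computational Biology"),
                mesh = c("Genomics", "Models, Statistical"),
                date = "2010-03-05"),
    tiny_record("102",
                title = "Cosine similarity search for related articles",
                abstract = "Term vectors weighted by inverse document frequency support associative retrieval.",
                authors = c("Jones AB"),
                journal = "Bioinformatics",
                scopes = c("Computational Biology", "Information Science"),
                mesh = c("Information Storage and Retrieval", "Neoplasms, Experimental"),
                date = "2010-05-20"),
    tiny_record("103",
                title = "Microbial community profiling in soil samples",
                abstract = "Sequencing reveals microbial diversity patterns in agricultural soil.",
                authors = c("Garcia ML"),
                journal = "Appl Environ Microbiol",
                scopes = c("Microbiology"),
                mesh = c("Soil Microbiology"),
                date = "2010-06-01")
  )
}
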
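# Seeded generator of corpora with planted structure: topic-tilted term
# usage, author communities, journal scopes, MeSH assignments, and uniform
# registration dates. Every statistical module is testable against the
# planted labels without downloading anything.

#' Configuration for the synthetic corpus generator
#'
#' @param n_records Number of records to generate.
#' @param n_topics Number of planted topics.
#' @param vocab_size Size of the background vocabulary.
#' @param signature_terms_per_topic Signature (topic-marker) terms per topic.
#' @param signature_rate Per-token probability that a record draws one of
#'   its own topic's signature terms; must exceed `background_rate`.
#' @param background_rate Per-token probability that a record draws a
#'   signature term of some other topic (cross-topic leakage).
#' @param title_len,abstract_len Token counts of generated titles and
#'   abstracts.
#' @param n_authors Size of the global author pool.
#' @param authors_per_topic Authors in each topic's community (drawn from
#'   the global pool).
#' @param authors_per_record Authors listed on each record.
#' @param scopes Character vector of Journal Subject Terms; topics are
#'   assigned scopes round-robin.
#' @param mesh_per_topic Planted MeSH headings per topic.
#' @param date_range Length-2 `Date` vector; registration dates are drawn
#'   uniformly in `[start, end]`.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_records = 200L, n_topics = 4L,
                             vocab_size = 400L,
                             signature_terms_per_topic = 12L,
                             signature_rate = 0.30, background_rate = 0.02,
                             title_len = 8L, abstract_len = 60L,
                             n_authors = 60L, authors_per_topic = 8L,
                             authors_per_record = 3L,
                             scopes = c("Genetics", "Biochemistry",
                                        "Neurology", "Immunology",
                                        "Cell Biology", "Microbiology"),
                             mesh_per_topic = 4L,
                             date_range = as.Date(c("2010-01-01",
                                                    "2010-12-31")),
                             seed = 1L) {
  cfg <- list(n_records = as.integer(n_records), n_topics = as.integer(n_topics),
              vocab_size = as.integer(vocab_size),
              signature_terms_per_topic = as.integer(signature_terms_per_topic),
              signature_rate = signature_rate, background_rate = background_rate,
              title_len = as.integer(title_len),
              abstract_len = as.integer(abstract_len),
              n_authors = as.integer(n_authors),
              authors_per_topic = as.integer(authors_per_topic),
              authors_per_record = as.integer(authors_per_record),
              scopes = as.character(scopes),
              mesh_per_topic = as.integer(mesh_per_topic),
              date_range = as.Date(date_range), seed = as.integer(seed))
  counts <- c(cfg$n_records, cfg$n_topics, cfg$vocab_size,
              cfg$signature_terms_per_topic, cfg$title_len, cfg$abstract_len,
              cfg$n_authors, cfg$authors_per_topic, cfg$authors_per_record,
              cfg$mesh_per_topic)
  if (any(counts < 1L)) stop("all generator counts must be positive", call. = FALSE)
  if (!(cfg$signature_rate > cfg$background_rate))
    stop("signature_rate must exceed background_rate (the plant must be ",
         "detectable by construction)", call. = FALSE)
  if (cfg$signature_rate + cfg$background_rate >= 1)
    stop("signature_rate + background_rate must be < 1", call. = FALSE)
  if (length(cfg$date_range) != 2L || any(is.na(cfg$date_range)) ||
      cfg$date_range[1L] > cfg$date_range[2L])
    stop("date_range must be two ordered dates", call. = FALSE)
  if (cfg$authors_per_topic > cfg$n_authors)
    stop("authors_per_topic cannot exceed n_authors", call. = FALSE)
  structure(cfg, class = "generator_config")
}

# deterministic pseudo-word: letters only so stemming stays trivial to reason
# about; distinct prefixes keep signature and background vocabularies disjoint
.syn_word <- function(prefix, i) {
  letters5 <- c("ba", "de", "fi", "go", "hu", "ka", "lo", "mi", "nu", "po")
  digits <- integer(0)
  x <- i
  repeat {
    digits <- c(x %% 10L, digits)
    x <- x %/% 10L
    if (x == 0L) break
  }
  paste0(prefix, paste(letters5[digits + 1L], collapse = ""))
}

#' Generate a synthetic corpus with planted topics
#'
#' Each record draws a topic uniformly; its title and abstract tokens come
#' from a topic-tilted mixture (own-topic signature terms at
#' `signature_rate`, other topics' signature terms at `background_rate`,
#' background vocabulary otherwise). Authors are drawn preferentially from
#' the topic's author community, the journal scope and MeSH headings include
#' the topic's designated labels with high probability, and registration
#' dates are uniform over `date_range`. A single global random stream seeded
#' from `config$seed` drives all draws, so output is byte-reproducible.
#'
#' @param config A `generator_config`.
#' @return List with `corpus` (a `biblio_corpus`) and `labels` (named
#'   integer vector, record_id -> topic id).
#' @export
generate_corpus <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n_topics <- config$n_topics
  background_vocab <- vapply(seq_len(config$vocab_size),
                             function(i) .syn_word("w", i), character(1))
  signature <- lapply(seq_len(n_topics), function(t)
    vapply(seq_len(config$signature_terms_per_topic),
           function(i) .syn_word(paste0("sig", letters[t]), i), character(1)))
  authors <- vapply(seq_len(config$n_authors),
                    function(i) paste(.syn_word("auth", i), "jd"), character(1))
  topic_authors <- lapply(seq_len(n_topics), function(t)
    sample(authors, config$authors_per_topic))
  topic_scope <- config$scopes[((seq_len(n_topics) - 1L) %% length(config$scopes)) + 1L]
  topic_mesh <- lapply(seq_len(n_topics), function(t)
    vapply(seq_len(config$mesh_per_topic), function(i)
      paste0("Heading ", .syn_word("", i), ", Topic ", LETTERS[t]),
      character(1)))
  mesh_pool <- unlist(topic_mesh, use.names = FALSE)

  draw_tokens <- function(n, topic) {
    u <- stats::runif(n)
    own <- u < config$signature_rate
    other <- !own & u < config$signature_rate + config$background_rate
    out <- character(n)
    if (any(own))
      out[own] <- sample(signature[[topic]], sum(own), replace = TRUE)
    if (any(other)) {
      pool <- unlist(signature[-topic], use.names = FALSE)
      if (length(pool) == 0L) pool <- background_vocab
      out[other] <- sample(pool, sum(other), replace = TRUE)
    }
    bg <- !(own | other)
    if (any(bg)) out[bg] <- sample(background_vocab, sum(bg), replace = TRUE)
    out
  }

  n_days <- as.integer(config$date_range[2L] - config$date_range[1L]) + 1L
  records <- vector("list", config$n_records)
  labels <- integer(config$n_records)
  for (i in seq_len(config$n_records)) {
    topic <- sample.int(n_topics, 1L)
    labels[i] <- topic
    title <- paste(draw_tokens(config$title_len, topic), collapse = " ")
    abstract <- paste(draw_tokens(config$abstract_len, topic), collapse = " ")
    n_auth <- min(config$authors_per_record, config$n_authors)
    from_topic <- stats::runif(n_auth) < 0.8
    rec_authors <- character(n_auth)
    if (any(from_topic))
      rec_authors[from_topic] <- sample(topic_authors[[topic]],
                                        sum(from_topic), replace = TRUE)
    if (any(!from_topic))
      rec_authors[!from_topic] <- sample(authors, sum(!from_topic),
                                         replace = TRUE)
    scope <- if (stats::runif(1) < 0.9) topic_scope[topic] else
      sample(config$scopes, 1L)
    mesh <- topic_mesh[[topic]][stats::runif(config$mesh_per_topic) < 0.8]
    stray <- mesh_pool[stats::runif(length(mesh_pool)) < 0.02]
    date <- config$date_range[1L] +
      (sample.int(n_days, 1L) - 1L)
    records[[i]] <- biblio_record(
      record_id = sprintf("SYN%06d", i),
      title = title,
      abstract = abstract,
      authors = rec_authors,
      journal = paste("Journal of", topic_scope[topic]),
      journal_subject_terms = scope,
      mesh_terms = unique(c(mesh, stray)),
      registered_date = date
    )
  }
  corpus <- biblio_corpus(records)
  names(labels) <- corpus_ids(corpus)
  list(corpus = corpus, labels = labels,
       signature_terms = signature, topic_mesh = topic_mesh,
       topic_scope = topic_scope, topic_authors = topic_authors)
}
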
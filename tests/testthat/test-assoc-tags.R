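# IDF-weighted vectors and cosine against dense oracles, associative search
# ranking, MeSH tag suggestion, and tag-name normalization.

test_that("term vectors equal a direct tf x idf recomputation", {
  gen <- generate_corpus(generator_config(n_records = 20L, seed = 51L))
  st <- build_background_stats(gen$corpus)
  r <- gen$corpus$records[[5]]
  v <- build_term_vector(r, st)
  toks <- c(tokenize(r$title), tokenize(r$abstract))
  for (t in unique(toks)) {
    expect_equal(unname(v$entries[t]), sum(toks == t) * idf_of(st, t),
                 info = t)
  }
  expect_equal(v$norm, sqrt(sum(v$entries^2)))
  # empty record: zero vector
  v0 <- build_term_vector(tiny_record("E"), st)
  expect_identical(v0$norm, 0)
  expect_length(v0$entries, 0L)
})

test_that("a term present in every record contributes zero weight", {
  corp <- tiny_corpus(tiny_record("1", title = "kinase assay"),
                      tiny_record("2", title = "kinase protocol"))
  st <- build_background_stats(corp)
  v <- build_term_vector(corpus_get(corp, "1"), st)
  expect_false("kinas" %in% names(v$entries))  # idf 0 drops out
  expect_true("assai" %in% names(v$entries))
})

test_that("cosine matches a dense dot-product oracle and its bounds", {
  set.seed(7)
  vocab <- paste0("t", 1:40)
  for (i in 1:30) {
    a_terms <- sample(vocab, sample(1:15, 1))
    b_terms <- sample(vocab, sample(1:15, 1))
    a <- term_vector(stats::setNames(stats::runif(length(a_terms)), a_terms))
    b <- term_vector(stats::setNames(stats::runif(length(b_terms)), b_terms))
    dense_a <- stats::setNames(numeric(length(vocab)), vocab)
    dense_b <- dense_a
    dense_a[names(a$entries)] <- a$entries
    dense_b[names(b$entries)] <- b$entries
    want <- sum(dense_a * dense_b) /
      (sqrt(sum(dense_a^2)) * sqrt(sum(dense_b^2)))
    got <- cosine_similarity(a, b)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(got, cosine_similarity(b, a))       # symmetry
    expect_true(got >= 0 && got <= 1 + 1e-12)        # Cauchy-Schwarz
  }
  v <- term_vector(c(x = 1, y = 2))
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, term_vector(c(z = 3))), 0)
  expect_equal(cosine_similarity(v, term_vector(numeric(0))), 0)
})

test_that("a duplicated seed record ranks first with similarity 1", {
  gen <- generate_corpus(generator_config(n_records = 15L, seed = 53L))
  recs <- gen$corpus$records
  dup <- recs[[1]]
  dup$record_id <- "DUP"
  lib <- biblio_corpus(c(recs, list(dup)))
  st <- build_background_stats(lib)
  out <- associative_search(recs[[1]]$record_id, lib, st)
  expect_identical(out$record_id[1], "DUP")
  expect_equal(out$similarity[1], 1)
})

test_that("single-seed ordering equals a brute-force pairwise cosine sort", {
  gen <- generate_corpus(generator_config(n_records = 25L, seed = 55L))
  st <- build_background_stats(gen$corpus)
  ids <- corpus_ids(gen$corpus)
  seed_id <- ids[3]
  out <- associative_search(seed_id, gen$corpus, st)
  seed_vec <- build_term_vector(gen$corpus$records[[seed_id]], st)
  sims <- vapply(setdiff(ids, seed_id), function(id)
    cosine_similarity(seed_vec, build_term_vector(gen$corpus$records[[id]], st)),
    numeric(1))
  want <- names(sims)[order(-sims, names(sims))]
  expect_identical(out$record_id, want)
  expect_equal(out$similarity, unname(sims[want]))
  expect_error(associative_search("nope", gen$corpus, st), "nope")
})

test_that("scaling the query vector leaves the ranking unchanged", {
  # vector-sum vs centroid: ranking is invariant to positive scaling, so a
  # seed duplicated k times must rank targets identically to the single seed
  gen <- generate_corpus(generator_config(n_records = 20L, seed = 57L))
  st <- build_background_stats(gen$corpus)
  id <- corpus_ids(gen$corpus)[1]
  once <- associative_search(id, gen$corpus, st)
  thrice <- associative_search(rep(id, 3L), gen$corpus, st)
  expect_identical(once$record_id, thrice$record_id)
  expect_equal(once$similarity, thrice$similarity)
})

test_that("same-topic records outrank cross-topic ones in a planted library", {
  gen <- generate_corpus(generator_config(n_records = 60L, n_topics = 2L,
                                          seed = 59L))
  st <- build_background_stats(gen$corpus)
  seed_ids <- names(gen$labels)[gen$labels == 1L][1:3]
  out <- associative_search(seed_ids, gen$corpus, st)
  sims_by_topic <- split(out$similarity, gen$labels[out$record_id])
  expect_gt(mean(sims_by_topic[["1"]]), mean(sims_by_topic[["2"]]))
})

test_that("mesh tag normalization reverses comma segments and lowercases", {
  expect_identical(normalize_mesh_tag("Genomics"), "genomics")
  expect_identical(normalize_mesh_tag("Neoplasms, Experimental"),
                   "experimental neoplasms")
  expect_identical(normalize_mesh_tag("Receptors, Adrenergic, beta"),
                   "beta adrenergic receptors")
  # idempotent
  tags <- c("Genomics", "Neoplasms, Experimental", "Receptors, Adrenergic, beta")
  once <- normalize_mesh_tag(tags)
  expect_identical(normalize_mesh_tag(once), once)
})

test_that("tag suggestion finds the planted heading and obeys its bounds", {
  gen <- generate_corpus(generator_config(n_records = 80L, seed = 61L))
  st <- build_background_stats(gen$corpus)
  set_ids <- names(gen$labels)[gen$labels == 3L][1:8]
  tags <- suggest_tags(set_ids, gen$corpus, st)
  expect_true(nrow(tags) >= 1L)
  # top suggestion is one of topic 3's planted headings
  expect_true(grepl("Topic C$", tags$mesh_term[1]))
  expect_true(all(tags$probability <= 0.01))
  expect_false(is.unsorted(tags$probability))
  expect_identical(tags$tag_name, normalize_mesh_tag(tags$mesh_term))
  # suggested headings all occur in the paper set
  set_mesh <- unique(unlist(lapply(corpus_get(gen$corpus, set_ids),
                                   `[[`, "mesh_terms")))
  expect_true(all(tags$mesh_term %in% set_mesh))
  # probability equals a direct tally + pmf recomputation
  for (i in seq_len(nrow(tags))) {
    in_set <- sum(vapply(corpus_get(gen$corpus, set_ids), function(r)
      tags$mesh_term[i] %in% r$mesh_terms, logical(1)))
    in_bg <- sum(vapply(gen$corpus$records, function(r)
      tags$mesh_term[i] %in% r$mesh_terms, logical(1)))
    expect_identical(tags$set_count[i], in_set)
    expect_identical(tags$bg_count[i], in_bg)
    expect_equal(tags$probability[i],
                 stats::dhyper(in_set, in_bg,
                               corpus_size(gen$corpus) - in_bg,
                               length(set_ids)))
  }
})

test_that("a heading on every record is never suggested; whole-library set is empty", {
  corp <- tiny_corpus(
    tiny_record("1", mesh = c("Ubiquitous", "Rare A")),
    tiny_record("2", mesh = c("Ubiquitous", "Rare A")),
    tiny_record("3", mesh = "Ubiquitous"),
    tiny_record("4", mesh = "Ubiquitous")
  )
  st <- build_background_stats(corp)
  tags <- suggest_tags(c("1", "2"), corp, st, prob_threshold = 1)
  expect_false("Ubiquitous" %in% tags$mesh_term)
  expect_identical(tags$mesh_term, "Rare A")
  expect_identical(nrow(suggest_tags(corpus_ids(corp), corp, st,
                                     prob_threshold = 1)), 0L)
})
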
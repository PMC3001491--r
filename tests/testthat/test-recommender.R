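# Window filtering against a loop oracle, score decomposition, stop/must
# term semantics, and full-pipeline equivalence with a naive recomputation.

test_that("calendar month arithmetic clamps the day of month", {
  am <- litrec:::add_months
  expect_identical(am(as.Date("2010-06-15"), -3L), as.Date("2010-03-15"))
  expect_identical(am(as.Date("2010-03-31"), -1L), as.Date("2010-02-28"))
  expect_identical(am(as.Date("2012-03-30"), -1L), as.Date("2012-02-29"))
  expect_identical(am(as.Date("2010-01-10"), -3L), as.Date("2009-10-10"))
  expect_identical(am(as.Date("2010-12-31"), 2L), as.Date("2011-02-28"))
})

test_that("window default is three months with half-open boundaries", {
  expect_identical(eval(formals(filter_target_window)$window_months), 3L)
  corp <- tiny_corpus(
    tiny_record("on_query_day", date = "2010-06-15"),
    tiny_record("inside", date = "2010-04-01"),
    tiny_record("on_lower_bound", date = "2010-03-15"),
    tiny_record("one_day_before", date = "2010-03-14"),
    tiny_record("future", date = "2010-06-16")
  )
  kept <- filter_target_window(corp, as.Date("2010-06-15"))
  expect_setequal(kept, c("on_query_day", "inside"))
  expect_setequal(
    filter_target_window(corp, as.Date("2010-06-15"),
                         exclude_ids = "on_query_day"),
    "inside")
})

test_that("window survivors equal a direct date comparison loop", {
  gen <- generate_corpus(generator_config(n_records = 80L, seed = 17L))
  as_of <- as.Date("2010-09-30")
  for (w in c(1L, 3L, 6L)) {
    got <- filter_target_window(gen$corpus, as_of, w)
    lower <- litrec:::add_months(as_of, -w)
    want <- character(0)
    for (r in gen$corpus$records) {
      if (r$registered_date > lower && r$registered_date <= as_of)
        want <- c(want, r$record_id)
    }
    expect_identical(got, want)
  }
})

make_scored_query <- function() {
  profile <- structure(list(
    key_terms = data.frame(
      term = c("plant signatur", "enrich", "profil"),
      seed_doc_count = c(3L, 2L, 2L), background_doc_count = c(3L, 5L, 6L),
      probability = c(0.001, 0.01, 0.05),
      weight = -log(c(0.001, 0.01, 0.05)), stringsAsFactors = FALSE),
    seed_authors = c("smith jd", "lee k"),
    seed_scopes = "Genetics", seed_ids = c("S1", "S2", "S3"), k_limit = 75L
  ), class = "seed_profile")
  structured_query(profile, title_boost = 2, author_bonus = 0.5,
                   scope_bonus = 0.25, as_of_date = as.Date("2010-06-15"))
}

test_that("candidate scoring decomposes exactly and admits on key terms", {
  q <- make_scored_query()
  # no key-term match: not admitted even with author/scope overlap
  r0 <- tiny_record("X", title = "unrelated topic entirely",
                    authors = "Smith JD", scopes = "Genetics")
  expect_null(score_candidate(r0, q))
  # one abstract-only match, no context overlap: total equals the weight
  r1 <- tiny_record("Y", title = "different things",
                    abstract = "we report enrichment patterns")
  h1 <- score_candidate(r1, q)
  expect_equal(h1$total, -log(0.01))
  expect_identical(h1$matched_terms, "enrich")
  # bigram in title gets the boost; author and scope bonuses add up
  r2 <- tiny_record("Z", title = "a planted signature appears",
                    abstract = "with enrichment profiles",
                    authors = c("Smith JD", "Lee K"), scopes = "Genetics")
  h2 <- score_candidate(r2, q)
  expect_equal(h2$term_score,
               2 * -log(0.001) + -log(0.01) + -log(0.05))
  expect_equal(h2$author_score, 0.5 * 2)
  expect_equal(h2$scope_score, 0.25)
  expect_equal(h2$total, h2$term_score + h2$author_score + h2$scope_score)
})

test_that("must terms gate admission; stop terms only remove evidence", {
  gen <- generate_corpus(generator_config(n_records = 60L, seed = 19L))
  st <- build_background_stats(gen$corpus)
  seed_ids <- names(gen$labels)[gen$labels == 1L][1:5]
  as_of <- as.Date("2010-12-31")
  base <- recommend(seed_ids, gen$corpus, st, top_m = 100L, as_of_date = as_of)
  # removing a key term never increases a hit's term score
  prof <- extract_key_terms(seed_ids, gen$corpus, st)
  dropped <- prof$key_terms$term[1]
  tuned <- recommend(seed_ids, gen$corpus, st, top_m = 100L,
                     as_of_date = as_of, stop_terms = dropped)
  shared <- intersect(base$record_id, tuned$record_id)
  expect_true(length(shared) > 0L)
  expect_true(all(tuned$term_score[match(shared, tuned$record_id)] <=
                    base$term_score[match(shared, base$record_id)] + 1e-12))
  expect_false(any(vapply(strsplit(tuned$matched_terms, ",", fixed = TRUE),
                          function(ts) dropped %in% ts, logical(1))))
  # a must term can only shrink the hit set
  gated <- recommend(seed_ids, gen$corpus, st, top_m = 100L,
                     as_of_date = as_of, must_terms = dropped)
  expect_true(all(gated$record_id %in% base$record_id))
  expect_true(nrow(gated) <= nrow(base))
})

test_that("recommend equals the naive loop recomputation on random corpora", {
  for (s in c(31L, 32L, 33L)) {
    gen <- generate_corpus(generator_config(n_records = 30L, title_len = 5L,
                                            abstract_len = 12L, seed = s))
    st <- build_background_stats(gen$corpus, max_n = 3L)
    seed_ids <- names(gen$labels)[gen$labels == 1L][1:4]
    as_of <- as.Date("2010-12-31")
    got <- recommend(seed_ids, gen$corpus, st, top_m = 50L,
                     window_months = 6L, as_of_date = as_of)
    want <- oracle_recommend(seed_ids, gen$corpus, 3L, top_m = 50L,
                             window_months = 6L, as_of_date = as_of)
    expect_identical(got$record_id, want$record_id)
    expect_equal(got$total, want$total, tolerance = 1e-10)
    expect_equal(got$term_score, want$term_score, tolerance = 1e-10)
    expect_equal(got$author_score, want$author_score, tolerance = 1e-10)
    expect_equal(got$scope_score, want$scope_score, tolerance = 1e-10)
    expect_identical(got$matched_terms, want$matched_terms)
  }
})

test_that("ranking is invariant under corpus record permutation", {
  gen <- generate_corpus(generator_config(n_records = 40L, seed = 37L))
  st <- build_background_stats(gen$corpus)
  seed_ids <- names(gen$labels)[gen$labels == 2L][1:4]
  as_of <- as.Date("2010-12-31")
  base <- recommend(seed_ids, gen$corpus, st, top_m = 30L, as_of_date = as_of)
  set.seed(2)
  shuffled <- biblio_corpus(sample(gen$corpus$records))
  again <- recommend(seed_ids, shuffled, build_background_stats(shuffled),
                     top_m = 30L, as_of_date = as_of)
  expect_equal(base[, setdiff(names(base), "rank")],
               again[, setdiff(names(again), "rank")])
})

test_that("top_m larger than the hit count returns all hits, none invented", {
  gen <- generate_corpus(generator_config(n_records = 25L, seed = 41L))
  st <- build_background_stats(gen$corpus)
  seed_ids <- corpus_ids(gen$corpus)[1:3]
  hits <- recommend(seed_ids, gen$corpus, st, top_m = 10000L,
                    window_months = NULL)
  expect_lte(nrow(hits), corpus_size(gen$corpus) - 3L)
  expect_false(any(hits$record_id %in% seed_ids))
  expect_equal(hits$total, hits$term_score + hits$author_score +
                 hits$scope_score)
})
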
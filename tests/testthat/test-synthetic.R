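# Closed-form moments of per-report entity counts under the generator's
# sampling scheme. Each per-report count is (Bernoulli for finding 1) +
# (Poisson-thinned count for findings 2..N), since N - 1 ~ Poisson and
# binomial thinning of a Poisson is Poisson.
scheme_moments <- function(cfg, n_pos, n_all) {
  q <- cfg$negation_rate
  lam <- cfg$subtype_rate - 1
  p_g <- cfg$grade_rate / cfg$subtype_rate
  p_p <- cfg$position_rate / cfg$subtype_rate
  prev <- cfg$cancer_prevalence
  ppos <- n_pos / n_all
  mix <- function(b_t, l_t, b_f, l_f) {
    # Bern(b) + Pois(l) per cancer status, mixed over prevalence
    m_t <- b_t + l_t; v_t <- b_t * (1 - b_t) + l_t
    m_f <- b_f + l_f; v_f <- b_f * (1 - b_f) + l_f
    m <- prev * m_t + (1 - prev) * m_f
    v <- prev * (v_t + m_t^2) + (1 - prev) * (v_f + m_f^2) - m^2
    c(mean = m, var = v)
  }
  e2_t <- 1 - q; e2_f <- (1 - q)^2
  list(
    cancer_subtype = mix(1, lam * e2_t, 1 - q, lam * e2_f),
    cancer_grade = mix(p_g, lam * e2_t * ppos * p_g, 0, 0),
    lesion_position = mix(p_p, lam * e2_t * p_p, (1 - q) * p_p,
                          lam * e2_f * p_p))
}

test_that("the same seed reproduces a corpus bit for bit", {
  c1 <- tiny_corpus(25, seed = 111)
  c2 <- tiny_corpus(25, seed = 111)
  for (i in seq_along(c1)) {
    expect_identical(c1[[i]]$text, c2[[i]]$text)
    expect_identical(c1[[i]]$spans, c2[[i]]$spans)
    expect_identical(c1[[i]]$report_label, c2[[i]]$report_label)
  }
  c3 <- tiny_corpus(25, seed = 112)
  expect_false(identical(vapply(c1, `[[`, character(1), "text"),
                         vapply(c3, `[[`, character(1), "text")))
})

test_that("every generated report satisfies the annotation invariants", {
  corp <- tiny_corpus(60, seed = 113, misspelling_rate = 0.08,
                      abbreviation_rate = 0.4)
  for (r in corp) {
    expect_silent(validate_report(r))
    expect_identical(tokenize_words(r$text)$token, r$tokens$token)
  }
})

test_that("without corruption paths every subtype surface is a lexicon phrase", {
  g <- report_grammar()
  corp <- generate_corpus(clean_corpus(150, seed = 114), g)
  for (r in corp) {
    sub <- r$spans[r$spans$category == "cancer_subtype", ]
    for (i in seq_len(nrow(sub))) {
      surf <- paste(r$tokens$token[(sub$start[i] + 1):sub$end[i]],
                    collapse = " ")
      expect_true(surf %in% g$subtypes$phrase)
    }
  }
})

test_that("misspelling rate 0 leaves the grammar vocabulary intact", {
  g <- report_grammar()
  vocab <- unique(unlist(lapply(
    c(g$subtypes$phrase, g$grades, g$positions$internal, g$positions$external,
      g$templates$template, g$negation, g$filler, unlist(g$headers),
      g$subtypes$abbrev[!is.na(g$subtypes$abbrev)],
      "o'clock", "cm from the nipple", "/",
      paste(1:12, collapse = " ")),
    function(s) tokenize_words(s)$token)))
  corp <- tiny_corpus(80, seed = 115, misspelling_rate = 0)
  toks <- unique(unlist(lapply(corp, function(r) r$tokens$token)))
  expect_true(all(toks %in% c(vocab, as.character(0:9))))
})

test_that("corrupt_word stays in the 1-edit neighborhood", {
  rng <- make_rng(9)
  for (w in c("carcinoma", "features", "grade", "situ", "of")) {
    nb <- oracle_one_edit_neighborhood(w)
    for (i in 1:40) {
      out <- corrupt_word(w, rng)
      expect_true(out %in% nb)
    }
  }
  expect_identical(corrupt_word("a", rng), "a")
  # deterministic under seed
  expect_identical(corrupt_word("carcinoma", make_rng(5)),
                   corrupt_word("carcinoma", make_rng(5)))
})

test_that("realized entity counts and prevalence match the sampling scheme", {
  g <- report_grammar()
  cfg <- corpus_config(1000, seed = 116)
  corp <- generate_corpus(cfg, g)
  n_pos <- sum(g$subtypes$positive); n_all <- nrow(g$subtypes)
  mom <- scheme_moments(cfg, n_pos, n_all)
  counts <- table(factor(unlist(lapply(corp, function(r) r$spans$category)),
                         levels = entity_categories()))
  for (cat in entity_categories()) {
    mu <- 1000 * mom[[cat]]["mean"]
    sd3 <- 3 * sqrt(1000 * mom[[cat]]["var"])
    expect_lt(abs(counts[[cat]] - mu), sd3)
  }
  prev <- mean(vapply(corp, `[[`, logical(1), "report_label"))
  expect_lt(abs(prev - cfg$cancer_prevalence),
            3 * sqrt(cfg$cancer_prevalence * (1 - cfg$cancer_prevalence) / 1000))
})

test_that("every grammar phrase is realized in a large corpus", {
  g <- report_grammar()
  corp <- generate_corpus(
    corpus_config(5000, seed = 117, misspelling_rate = 0,
                  abbreviation_rate = 0, collision_rate = 0,
                  clock_rate = 0.2), g)
  surfaces <- unlist(lapply(corp, function(r) {
    vapply(seq_len(nrow(r$spans)), function(i)
      paste(r$tokens$token[(r$spans$start[i] + 1):r$spans$end[i]],
            collapse = " "), character(1))
  }))
  surfaces <- unique(surfaces)
  expect_true(all(g$grades %in% surfaces))
  expect_true(all(g$positions$internal %in% surfaces))
  # subtypes appear either as standalone findings or negated (no span);
  # coverage is over emitted spans
  expect_true(all(g$subtypes$phrase %in% surfaces))
})

test_that("the shift benchmark has the canonical sizes and disjoint ids", {
  for (seed in c(1, 7)) {
    bm <- make_shift_benchmark(n = c(train = 40, val = 12, test_internal = 10,
                                     test_external = 8), seed = seed)
    ids <- unlist(lapply(bm, function(cc)
      vapply(cc, `[[`, character(1), "report_id")))
    expect_equal(anyDuplicated(ids), 0L)
  }
  # default sizes mirror the emulated corpora
  fm <- formals(make_shift_benchmark)$n
  expect_equal(eval(fm),
               c(train = 968L, val = 276L, test_internal = 194L,
                 test_external = 55L))
})

test_that("the external test set is lexically shifted against the internal vocabulary", {
  bm <- make_shift_benchmark(n = c(train = 120, val = 20, test_internal = 60,
                                   test_external = 60), seed = 3)
  train_vocab <- unique(unlist(lapply(bm$train, function(r) r$tokens$token)))
  oov_rate <- function(corpus) {
    toks <- unlist(lapply(corpus, function(r) r$tokens$token))
    mean(!toks %in% train_vocab)
  }
  expect_gt(oov_rate(bm$test_external), oov_rate(bm$test_internal))
})
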
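mk_seq <- function() {
  token_label_sequence(
    c("-", "invasive", "ductal", "carcinoma", ",", "grade", "2", "."),
    c("O", rep("I-cancer_subtype", 3), "O", rep("I-cancer_grade", 2), "O"))
}

mk_index <- function(grade_mentions) {
  idx <- build_lexicon_index(list(mk_seq()))
  idx$mentions$cancer_grade <- grade_mentions
  idx
}

test_that("all four operators are the identity at probability 0", {
  s <- mk_seq()
  idx <- build_lexicon_index(list(s))
  sl <- default_synonym_lexicon()
  rng <- make_rng(1)
  expect_identical(mention_replacement(s, idx, rng, prob = 0)$tokens, s$tokens)
  expect_identical(synonym_replacement(s, sl, rng, prob = 0)$tokens, s$tokens)
  expect_identical(label_wise_token_replacement(s, idx, rng, prob = 0)$tokens,
                   s$tokens)
  expect_identical(shuffle_within_segments(s, rng, prob = 0)$tokens, s$tokens)
  pol <- augmentation_policy(p = 0)
  out <- apply_policy(s, pol, idx, sl, rng)
  expect_identical(out$tokens, s$tokens)
  expect_identical(out$labels, s$labels)
})

test_that("mention replacement swaps whole segments with same-category mentions", {
  s <- mk_seq()
  # single-outcome inventory forces the replacement
  idx <- mk_index(list(c("high", "nuclear", "grade")))
  out <- mention_replacement(s, idx, make_rng(5), prob = 1)
  expect_equal(out$tokens[6:8], c("high", "nuclear", "grade"))
  expect_equal(out$labels[6:8], rep("I-cancer_grade", 3))
  # O segments untouched
  expect_equal(out$tokens[c(1, 5)], c("-", ","))
  # segment count and categories preserved
  runs_in <- pathner:::label_runs(s$labels)
  runs_out <- pathner:::label_runs(out$labels)
  expect_equal(runs_in$label, runs_out$label)
})

test_that("mention replacement draws replay the rng stream", {
  s <- mk_seq()
  inv <- list(c("grade", "1"), c("grade", "3"), c("high", "grade"))
  idx <- mk_index(inv)
  outcomes <- vapply(1:50, function(seed) {
    out <- mention_replacement(s, idx, make_rng(seed), prob = 1)
    paste(out$tokens, collapse = " ")
  }, character(1))
  # the subtype inventory has one mention (itself), so the outcome set is
  # exactly the three grade-mention substitutions
  enumerated <- vapply(inv, function(m)
    paste(c("-", "invasive", "ductal", "carcinoma", ",", m, "."),
          collapse = " "), character(1))
  expect_true(all(outcomes %in% enumerated))
  expect_setequal(unique(outcomes), enumerated)  # 50 draws hit all 3
  # draw-by-draw replay: consuming the same stream by hand predicts the pick
  for (seed in 1:10) {
    out_a <- mention_replacement(s, idx, make_rng(seed), prob = 1)
    rng_b <- make_rng(seed)
    invisible(rng_bernoulli(rng_b, 1, 1))            # subtype gate
    invisible(rng_int(rng_b, 1, 1))                  # subtype pick (1 of 1)
    invisible(rng_bernoulli(rng_b, 1, 1))            # grade gate
    k <- rng_int(rng_b, 1, length(inv))              # grade pick
    expect_equal(out_a$tokens[6:(5 + length(inv[[k]]))], inv[[k]])
  }
})

test_that("synonym replacement changes tokens but never labels or length", {
  s <- mk_seq()
  empty <- synonym_lexicon(list())
  out <- synonym_replacement(s, empty, make_rng(2), prob = 1)
  expect_identical(out$tokens, s$tokens)   # no candidates -> identity
  sl <- default_synonym_lexicon()
  set.seed(71)
  for (i in 1:500) {
    x <- random_tls()
    y <- synonym_replacement(x, sl, make_rng(i), prob = 0.5)
    expect_identical(y$labels, x$labels)
    expect_length(y$tokens, length(x$tokens))
  }
})

test_that("label-wise token replacement respects the same-label constraint", {
  s <- mk_seq()
  idx <- build_lexicon_index(list(s))
  idx$token_pools$O <- "the"
  out <- label_wise_token_replacement(s, idx, make_rng(3), prob = 1)
  expect_equal(out$tokens[c(1, 5, 8)], rep("the", 3))
  expect_true(all(out$tokens[2:4] %in% idx$token_pools[["I-cancer_subtype"]]))
  expect_true(all(out$tokens[6:7] %in% idx$token_pools[["I-cancer_grade"]]))
  set.seed(72)
  for (i in 1:500) {
    x <- random_tls()
    ix <- build_lexicon_index(list(x))
    y <- label_wise_token_replacement(x, ix, make_rng(i), prob = 0.4)
    expect_identical(y$labels, x$labels)
  }
})

test_that("shuffle within segments permutes inside runs only", {
  # all runs length 1: identity at any probability
  s1 <- token_label_sequence(c("a", "b", "c"),
                             c("O", "I-cancer_grade", "O"))
  expect_identical(shuffle_within_segments(s1, make_rng(4), prob = 1)$tokens,
                   s1$tokens)
  set.seed(73)
  for (i in 1:200) {
    x <- random_tls()
    y <- shuffle_within_segments(x, make_rng(i), prob = 1)
    expect_identical(y$labels, x$labels)
    runs <- pathner:::label_runs(x$labels)
    for (j in seq_len(nrow(runs))) {
      idx <- (runs$start[j] + 1L):runs$end[j]
      expect_equal(sort(y$tokens[idx]), sort(x$tokens[idx]))
    }
  }
  # entity_only mode leaves O runs fixed
  x <- mk_seq()
  y <- shuffle_within_segments(x, make_rng(9), prob = 1, entity_only = TRUE)
  expect_identical(y$tokens[c(1, 5, 8)], x$tokens[c(1, 5, 8)])
})

test_that("policies validate operators, order and probabilities", {
  expect_error(augmentation_policy(steps = c("MR", "backtranslate")),
               "unknown augmentation operator")
  expect_error(augmentation_policy(steps = c("SR", "MR", "LwTR", "SiS")),
               "fixed order")
  expect_error(augmentation_policy(p = 1.4), "0, 1")
  sub <- augmentation_policy(p = 0.05, steps = c("MR", "LwTR"))
  expect_equal(sub$steps, c("MR", "LwTR"))
  expect_error(apply_policy(mk_seq(), augmentation_policy(), index = NULL,
                            synlex = NULL, rng = make_rng(1)),
               "lexicon index")
})

test_that("the full policy at p = 1 equals the manual operator composition", {
  sl <- default_synonym_lexicon()
  set.seed(74)
  for (i in 1:25) {
    x <- random_tls(15L)
    ix <- build_lexicon_index(list(x, mk_seq()))
    pol <- augmentation_policy(p = 1, inner = 1)
    got <- apply_policy(x, pol, ix, sl, make_rng(i))
    expect_setequal(attr(got, "applied"), c("MR", "SR", "LwTR", "SiS"))
    # replay: the same stream, composing by hand in the fixed order
    rng <- make_rng(i)
    y <- x
    invisible(rng_bernoulli(rng, 1, 1))   # MR gate
    y <- mention_replacement(y, ix, rng, prob = 1)
    invisible(rng_bernoulli(rng, 1, 1))   # SR gate
    y <- synonym_replacement(y, sl, rng, prob = 1)
    invisible(rng_bernoulli(rng, 1, 1))   # LwTR gate
    y <- label_wise_token_replacement(y, ix, rng, prob = 1)
    invisible(rng_bernoulli(rng, 1, 1))   # SiS gate
    y <- shuffle_within_segments(y, rng, prob = 1)
    expect_identical(got$tokens, y$tokens)
    expect_identical(got$labels, y$labels)
  }
})

test_that("corpus augmentation is reproducible and leaves the index alone", {
  corp <- lapply(tiny_corpus(15, seed = 81), spans_to_io_labels)
  idx <- build_lexicon_index(corp)
  before <- idx
  sl <- default_synonym_lexicon()
  pol <- augmentation_policy(p = 0.5)
  a1 <- augment_corpus(corp, pol, idx, sl, make_rng(11))
  a2 <- augment_corpus(corp, pol, idx, sl, make_rng(11))
  for (i in seq_along(a1))
    expect_identical(a1[[i]]$tokens, a2[[i]]$tokens)
  expect_identical(idx, before)
  expect_named(attr(a1, "op_counts"), c("MR", "SR", "LwTR", "SiS"))
})
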
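test_that("perfect predictions score 1.0 everywhere", {
  corp <- tiny_corpus(15, seed = 101)
  tls <- lapply(corp, spans_to_io_labels)
  w <- word_level_metrics(tls, tls)
  expect_true(all(w$per_class$f1[w$per_class$support > 0] == 1))
  expect_equal(w$weighted$f1, 1)
  spans <- lapply(corp, `[[`, "spans")
  e <- entity_level_metrics(spans, spans)
  expect_equal(e$weighted$f1, 1)
  lab <- vapply(corp, `[[`, logical(1), "report_label")
  expect_equal(unname(report_level_metrics(lab, lab)[c("f1", "accuracy")]),
               c(1, 1))
})

test_that("entity matching requires exact start, end and category", {
  tr <- list(entity_spans(0L, 3L, "cancer_subtype"))
  pr <- list(entity_spans(0L, 2L, "cancer_subtype"))
  e <- entity_level_metrics(tr, pr)
  sub <- e$per_class[e$per_class$category == "cancer_subtype", ]
  expect_equal(sub$precision, 0)
  expect_equal(sub$recall, 0)
  expect_equal(sub$f1, 0)
  pr2 <- list(entity_spans(0L, 3L, "cancer_grade"))
  e2 <- entity_level_metrics(tr, pr2)
  expect_equal(e2$per_class$f1, c(0, 0, 0))
})

test_that("absent classes report zero with support zero and leave weighting", {
  tr <- list(c("O", "I-cancer_grade", "I-cancer_grade"))
  pr <- list(c("O", "I-cancer_grade", "I-cancer_grade"))
  w <- word_level_metrics(tr, pr)
  sub <- w$per_class[w$per_class$category == "cancer_subtype", ]
  expect_equal(sub$support, 0)
  expect_equal(sub$f1, 0)
  expect_equal(w$weighted$f1, 1)   # only the grade class carries weight
  expect_error(word_level_metrics(tr, list(c("O", "O"))), "mismatch")
})

test_that("metrics agree with brute-force oracles on random pairs", {
  set.seed(401)
  n_pairs <- 250
  tr_lab <- list(); pr_lab <- list(); tr_sp <- list(); pr_sp <- list()
  for (i in seq_len(n_pairs)) {
    n <- sample(3:20, 1)
    mk <- function() {
      sp <- random_spanset(n)
      lab <- rep("O", n)
      for (j in seq_len(nrow(sp)))
        lab[(sp$start[j] + 1):sp$end[j]] <- paste0("I-", sp$category[j])
      list(sp = sp, lab = lab)
    }
    a <- mk(); b <- mk()
    tr_lab[[i]] <- a$lab; pr_lab[[i]] <- b$lab
    tr_sp[[i]] <- a$sp; pr_sp[[i]] <- b$sp
  }
  w <- word_level_metrics(tr_lab, pr_lab)
  ow <- oracle_word_metrics(tr_lab, pr_lab)
  expect_equal(w$weighted$precision, unname(ow$weighted["precision"]))
  expect_equal(w$weighted$recall, unname(ow$weighted["recall"]))
  expect_equal(w$weighted$f1, unname(ow$weighted["f1"]))
  e <- entity_level_metrics(tr_sp, pr_sp)
  oe <- oracle_entity_metrics(tr_sp, pr_sp)
  for (cat in entity_categories()) {
    row <- e$per_class[e$per_class$category == cat, ]
    expect_equal(row$precision, unname(oe$per_class[[cat]]["precision"]))
    expect_equal(row$recall, unname(oe$per_class[[cat]]["recall"]))
  }
  expect_equal(e$weighted$f1, unname(oe$weighted["f1"]))
})

test_that("weighted metrics are convex combinations of per-class metrics", {
  set.seed(402)
  for (i in 1:20) {
    tr <- replicate(10, random_spanset(sample(5:15, 1)), simplify = FALSE)
    pr <- replicate(10, random_spanset(sample(5:15, 1)), simplify = FALSE)
    e <- entity_level_metrics(tr, pr)
    pc <- e$per_class[e$per_class$support > 0, ]
    if (nrow(pc) == 0) next
    expect_gte(e$weighted$f1, min(pc$f1) - 1e-12)
    expect_lte(e$weighted$f1, max(pc$f1) + 1e-12)
  }
})

test_that("report labels derive from predicted subtype spans via the lexicon", {
  toks <- c("showing", "ductal", "carcinoma", "in", "situ", ",",
            "high", "grade")
  none <- entity_spans()
  expect_false(report_label_from_entities(none, toks))
  dcis <- entity_spans(1L, 5L, "cancer_subtype")
  expect_true(report_label_from_entities(dcis, toks))
  # LCIS is a high-risk benign finding, not cancer-positive
  toks2 <- c("lobular", "carcinoma", "in", "situ")
  lcis <- entity_spans(0L, 4L, "cancer_subtype")
  expect_false(report_label_from_entities(lcis, toks2))
  # grade spans never make a report positive
  grade <- entity_spans(6L, 8L, "cancer_grade")
  expect_false(report_label_from_entities(grade, toks))
})

test_that("evaluation is pure and serializes losslessly", {
  corp <- tiny_corpus(12, seed = 103)
  lex <- wildcard_lexicon()
  e1 <- evaluate_system(lex, corp)
  e2 <- evaluate_system(lex, corp)
  expect_identical(e1, e2)
  m <- train_tagger(corp[1:9], corp[10:12], fast_config(max_epochs = 3L))
  ev <- evaluate_system(m, corp)
  f <- withr::local_tempfile(fileext = ".json")
  eval_to_json(ev, f)
  back <- eval_from_json(f)
  expect_equal(back$entity$weighted$f1, ev$entity$weighted$f1)
  expect_equal(back$word$per_class$precision, ev$word$per_class$precision)
  expect_equal(unname(back$report["f1"]), unname(ev$report["f1"]))
})
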
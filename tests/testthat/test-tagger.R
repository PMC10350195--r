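test_that("a small tagger memorizes a tiny corpus", {
  corp <- tiny_corpus(10, seed = 91)
  cfg <- train_config(batch_size = 4L, learning_rate = 3e-3,
                      max_epochs = 30L, patience = 30L, d_model = 32L,
                      d_ff = 64L, seed = 2L)
  m <- train_tagger(corp, corp, cfg)
  h <- m$history
  # loss strictly decreases over the first epochs
  expect_true(all(diff(h$train_loss[1:5]) < 0))
  # capacity check: perfect entity F1 on the training set
  ev <- evaluate_system(m, corp)
  expect_equal(ev$entity$weighted$f1, 1.0)
  expect_equal(ev$word$weighted$f1, 1.0)
})

test_that("prediction contracts hold", {
  corp <- tiny_corpus(30, seed = 92)
  cfg <- fast_config(max_epochs = 5L, seed = 3L)
  m <- train_tagger(corp[1:24], corp[25:30], cfg)

  empty <- annotated_report("e", "")
  expect_length(predict_labels(m, empty)$labels, 0L)
  expect_equal(nrow(predict_entities(m, empty)), 0L)

  for (r in corp[c(1, 7, 19)]) {
    tls <- predict_labels(m, r)
    expect_length(tls$labels, nrow(r$tokens))
    expect_true(all(tls$labels %in% io_labels()))
    # emitted label is the row-wise argmax of the probability matrix
    P <- predict(m, r, type = "prob")
    expect_equal(tls$labels, io_labels()[apply(P, 1L, which.max)])
    # predict_entities is exactly decode(predict_labels)
    expect_identical(predict_entities(m, r), io_labels_to_spans(tls))
  }
})

test_that("prediction recombines windows for over-length reports", {
  corp <- tiny_corpus(20, seed = 93)
  cfg <- fast_config(max_epochs = 3L, max_len = 24L, overlap = 8L, seed = 4L)
  m <- train_tagger(corp[1:15], corp[16:20], cfg)
  long <- corp[[1]]
  wins <- encode_subwords(spans_to_io_labels(long), m$vocab, max_len = 24L,
                          overlap = 8L)
  expect_gt(length(wins), 1L)
  tls <- predict_labels(m, long)
  expect_length(tls$labels, nrow(long$tokens))
})

test_that("training is bit-reproducible given the seed", {
  corp <- tiny_corpus(16, seed = 94)
  cfg <- fast_config(max_epochs = 4L, seed = 11L,
                     policy = augmentation_policy(0.3))
  m1 <- train_tagger(corp[1:12], corp[13:16], cfg)
  m2 <- train_tagger(corp[1:12], corp[13:16], cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  cfg2 <- fast_config(max_epochs = 4L, seed = 12L,
                      policy = augmentation_policy(0.3))
  m3 <- train_tagger(corp[1:12], corp[13:16], cfg2)
  expect_false(identical(m1$history$train_loss, m3$history$train_loss))
})

test_that("the LSTM backend honors the same contract and reports both metric levels", {
  corp <- tiny_corpus(40, seed = 95)
  cfg <- fast_config(max_epochs = 6L, d_model = 24L, seed = 5L)
  m <- train_tagger(corp[1:30], corp[31:36], cfg, backend = "lstm")
  ev <- evaluate_system(m, corp[37:40])
  # both word- and entity-level numbers are produced; no ordering asserted
  expect_true(is.finite(ev$word$weighted$f1))
  expect_true(is.finite(ev$entity$weighted$f1))
  r <- corp[[37]]
  expect_length(predict_labels(m, r)$labels, nrow(r$tokens))
  m2 <- train_tagger(corp[1:30], corp[31:36], cfg, backend = "lstm")
  expect_identical(m$history, m2$history)
})

test_that("degenerate corpora are rejected", {
  corp <- tiny_corpus(4, seed = 96)
  expect_error(train_tagger(list(), corp, fast_config()), "non-empty")
  expect_error(train_tagger(corp, list(), fast_config()), "non-empty")
})
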
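#' Training configuration for the sequence tagger
#'
#' The grid explored on the original corpus covered batch sizes 8, 16 and 32
#' and learning rates 2e-4, 1e-4, 9e-5, 8e-5 and 6e-5 for the pre-trained
#' encoder; the selected configuration there was batch size 8 and learning
#' rate 6e-5 with all four augmentation operators gated at p = 0.1. The
#' bundled encoders train from random initialisation, for which a larger
#' default rate (1e-3) is appropriate.
#'
#' @param batch_size Sequences per optimisation step (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param max_epochs Maximum training epochs.
#' @param patience Early stopping: stop after this many epochs without a new
#'   validation-loss minimum; the best checkpoint is returned.
#' @param max_len Subword window length (the encoder's maximum sequence
#'   size).
#' @param overlap Word overlap between consecutive windows of an
#'   over-length report.
#' @param policy An [augmentation_policy()] applied to the training corpus,
#'   or `NULL` for plain supervised training. When set, every training
#'   instance is re-augmented with fresh draws each epoch; validation data
#'   are never augmented.
#' @param seed Seed governing initialisation, batch order and augmentation.
#' @param d_model Encoder hidden size H.
#' @param n_layers Transformer layers (transformer backend only).
#' @param d_ff Feed-forward width (transformer backend only).
#' @param bidirectional Run the LSTM in both directions (LSTM backend only).
#' @param n_hash Hash buckets for out-of-vocabulary subwords.
#' @param init_sd Standard deviation of random weight initialisation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, learning_rate = 1e-3,
                         max_epochs = 50L, patience = 5L, max_len = 128L,
                         overlap = 16L, policy = NULL, seed = 1L,
                         d_model = 48L, n_layers = 1L, d_ff = 96L,
                         bidirectional = TRUE, n_hash = 256L,
                         init_sd = 0.08) {
  stopifnot(batch_size >= 1L, learning_rate > 0, max_epochs >= 1L,
            is.null(policy) || inherits(policy, "augmentation_policy"))
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 max_len = as.integer(max_len),
                 overlap = as.integer(overlap), policy = policy,
                 seed = as.integer(seed), d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
                 bidirectional = isTRUE(bidirectional),
                 n_hash = as.integer(n_hash), init_sd = init_sd),
            class = "train_config")
}

.as_tls_corpus <- function(corpus, what = "corpus") {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop(what, " must be a non-empty list of reports or sequences")
  lapply(corpus, function(x) {
    if (inherits(x, "annotated_report")) spans_to_io_labels(x)
    else if (inherits(x, "token_label_sequence")) x
    else stop(what, " elements must be annotated_report or token_label_sequence")
  })
}

# token/label sequences -> trimmed training examples (one per window)
.make_examples <- function(seqs, vocab, max_len, overlap) {
  out <- list()
  for (s in seqs) {
    if (length(s$tokens) == 0L) next
    for (w in encode_subwords(s, vocab, max_len = max_len, overlap = overlap)) {
      n_real <- sum(w$attention_mask)
      out[[length(out) + 1L]] <- list(
        ids = w$subword_ids[seq_len(n_real)],
        heads = w$word_head_positions,
        y = w$label_ids[w$word_head_positions])
    }
  }
  out
}

.chunked_loss <- function(backend, params, examples, cfg, chunk = 32L) {
  tot <- 0; n <- 0L
  for (i in seq(1L, length(examples), by = chunk)) {
    b <- examples[i:min(i + chunk - 1L, length(examples))]
    r <- nn_apply(backend, params, b, cfg, need_grads = FALSE)
    tot <- tot + r$loss * r$n_sup
    n <- n + r$n_sup
  }
  tot / n
}

#' Train the NER sequence tagger
#'
#' Fits a token classifier over the IO label alphabet: an encoder backend
#' maps each subword to a hidden vector h, a linear head W produces class
#' scores z = W h, and softmax converts scores to per-class probabilities.
#' The loss is token-level cross-entropy in which only the first subword of
#' each word is supervised; continuation subwords and padding are ignored.
#' Optimisation is Adam with early stopping on validation loss: the returned
#' model is the checkpoint with the lowest validation loss. With an
#' augmentation policy configured, each training instance is re-augmented
#' with fresh draws every epoch; the validation corpus is never augmented.
#' Training is bit-reproducible given the config seed.
#'
#' @param train,val Disjoint lists of `annotated_report` or
#'   [token_label_sequence()] objects.
#' @param config A [train_config()].
#' @param backend `"transformer"` (small self-attention encoder, the
#'   default) or `"lstm"`.
#' @param synlex Synonym lexicon used by an SR policy step; defaults to the
#'   bundled lexicon.
#' @param quiet Suppress per-epoch progress output.
#' @return An object of class `ner_tagger` with `print()`, `summary()`,
#'   `predict()` and `plot()` methods.
#' @seealso [predict_labels()], [predict_entities()]
#' @export
train_tagger <- function(train, val, config = train_config(),
                         backend = c("transformer", "lstm"),
                         synlex = NULL, quiet = TRUE) {
  backend <- match.arg(backend)
  stopifnot(inherits(config, "train_config"))
  train_tls <- .as_tls_corpus(train, "train corpus")
  val_tls <- .as_tls_corpus(val, "validation corpus")

  rng <- make_rng(config$seed)
  vocab <- subword_vocab(train_tls, n_hash = config$n_hash)
  params <- nn_init(backend, vocab$size, config, rng)
  opt <- adam_init(params)

  index <- NULL
  if (!is.null(config$policy)) {
    index <- build_lexicon_index(train_tls)
    if ("SR" %in% config$policy$steps && is.null(synlex))
      synlex <- default_synonym_lexicon()
  }
  val_ex <- .make_examples(val_tls, vocab, config$max_len, config$overlap)
  if (length(val_ex) == 0L) stop("validation corpus has no tokens")

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  for (epoch in seq_len(config$max_epochs)) {
    seqs <- if (is.null(config$policy)) train_tls else
      augment_corpus(train_tls, config$policy, index, synlex, rng)
    ex <- .make_examples(seqs, vocab, config$max_len, config$overlap)
    ord <- rng_permute(rng, seq_along(ex))
    ep_loss <- 0; ep_n <- 0L
    for (i in seq(1L, length(ord), by = config$batch_size)) {
      b <- ex[ord[i:min(i + config$batch_size - 1L, length(ord))]]
      r <- nn_apply(backend, params, b, config, need_grads = TRUE)
      st <- adam_step(params, r$grads, opt, lr = config$learning_rate)
      params <- st$params; opt <- st$state
      ep_loss <- ep_loss + r$loss * r$n_sup; ep_n <- ep_n + r$n_sup
    }
    vl <- .chunked_loss(backend, params, val_ex, config)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / ep_n,
                                         val_loss = vl))
    if (!quiet)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / ep_n, vl))
    if (vl < best$loss) best <- list(loss = vl, params = params, epoch = epoch)
    if (epoch - best$epoch >= config$patience) break
  }

  structure(list(backend = backend, params = best$params, vocab = vocab,
                 label_map = io_labels(), config = config,
                 history = history, best_epoch = best$epoch,
                 best_val_loss = best$loss),
            class = "ner_tagger")
}

#' @export
print.ner_tagger <- function(x, ...) {
  cat("<ner_tagger> backend:", x$backend,
      sprintf("(H = %d)", x$config$d_model), "\n")
  cat("  labels:", paste(x$label_map, collapse = " "), "\n")
  cat(sprintf("  trained %d epochs; best validation loss %.4f at epoch %d\n",
              nrow(x$history), x$best_val_loss, x$best_epoch))
  if (!is.null(x$config$policy))
    cat("  augmentation:", paste(x$config$policy$steps, collapse = "-"),
        "at p =", paste(x$config$policy$p, collapse = "/"), "\n")
  invisible(x)
}

#' @export
summary.ner_tagger <- function(object, ...) {
  print(object)
  cat("  loss trace:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' @export
plot.ner_tagger <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

# per-word probability matrix (n_words x 4) for one sequence, windows
# recombined by centrality
.predict_word_probs <- function(model, tls) {
  m <- length(tls$tokens)
  if (m == 0L) return(matrix(numeric(), 0L, 4L))
  wins <- encode_subwords(tls, model$vocab, max_len = model$config$max_len,
                          overlap = model$config$overlap)
  exs <- lapply(wins, function(w) {
    n_real <- sum(w$attention_mask)
    list(ids = w$subword_ids[seq_len(n_real)],
         heads = w$word_head_positions, y = NULL)
  })
  owner <- window_owner(wins, m)
  P <- matrix(NA_real_, m, 4L)
  for (wi in unique(owner)) {
    probs <- nn_head_probs(model$backend, model$params, exs[[wi]],
                           model$config)
    words <- which(owner == wi)
    P[words, ] <- probs[words - wins[[wi]]$word_range[1], , drop = FALSE]
  }
  P
}

#' Predict IO labels or entity spans for a report
#'
#' `predict_labels()` assigns each word the class with the highest
#' probability (argmax over the first-subtoken probability row);
#' `predict_entities()` decodes those labels into maximal-run entity spans,
#' i.e. it equals `io_labels_to_spans(predict_labels(...))`. Both are
#' deterministic given a fixed model.
#'
#' @param model A fitted [train_tagger()] model.
#' @param report An `annotated_report` or [token_label_sequence()].
#' @return `predict_labels()`: a `token_label_sequence`;
#'   `predict_entities()`: a span data.frame.
#' @export
predict_labels <- function(model, report) {
  stopifnot(inherits(model, "ner_tagger"))
  tls <- if (inherits(report, "annotated_report")) {
    token_label_sequence(report$tokens$token,
                         rep("O", nrow(report$tokens)))
  } else if (inherits(report, "token_label_sequence")) report
  else stop("report must be an annotated_report or token_label_sequence")
  if (length(tls$tokens) == 0L)
    return(token_label_sequence(character(), character()))
  P <- .predict_word_probs(model, tls)
  token_label_sequence(tls$tokens, model$label_map[max.col(P, "first")])
}

#' @rdname predict_labels
#' @export
predict_entities <- function(model, report) {
  io_labels_to_spans(predict_labels(model, report))
}

#' @export
#' @param object A fitted `ner_tagger`.
#' @param newdata A report, sequence, or list of them.
#' @param type `"labels"`, `"entities"` or `"prob"` (per-word probability
#'   matrix).
#' @param ... Unused.
#' @rdname predict_labels
predict.ner_tagger <- function(object, newdata,
                               type = c("labels", "entities", "prob"), ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "annotated_report") ||
    inherits(newdata, "token_label_sequence")
  items <- if (single) list(newdata) else newdata
  out <- lapply(items, function(r) {
    switch(type,
           labels = predict_labels(object, r),
           entities = predict_entities(object, r),
           prob = {
             tls <- if (inherits(r, "annotated_report"))
               token_label_sequence(r$tokens$token, rep("O", nrow(r$tokens)))
             else r
             p <- .predict_word_probs(object, tls)
             colnames(p) <- object$label_map
             p
           })
  })
  if (single) out[[1]] else out
}
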
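#' Wildcard lexicon for the rule-based report classifier
#'
#' For every word of every malignant-finding phrase the matcher accepts the
#' exact word plus all single-position wildcard variants (e.g. `.eft`,
#' `l.ft`, `le.t`, `lef.` for "left", where `.` matches any single
#' non-newline character), so a term of length n yields exactly n wildcard
#' patterns plus the exact term. This tolerates any one-character
#' substitution but nothing more — the brittleness the approach is known
#' for.
#'
#' @param terms Character vector of lowercase phrases denoting malignant
#'   findings. Defaults to the bundled cancer-positive findings list.
#' @return An object of class `wildcard_lexicon` with the per-word pattern
#'   sets materialised in `generated_patterns`.
#' @export
wildcard_lexicon <- function(terms = positive_findings()) {
  terms <- tolower(as.character(terms))
  if (length(terms) == 0L) stop("lexicon must contain at least one term")
  term_words <- lapply(terms, function(t) tokenize_words(t)$token)
  patterns <- lapply(term_words, function(ws) {
    lapply(ws, function(w) {
      n <- nchar(w)
      wild <- vapply(seq_len(n), function(i) {
        p <- w; substr(p, i, i) <- "."; p
      }, character(1))
      c(w, wild)
    })
  })
  structure(list(terms = terms, term_words = term_words,
                 generated_patterns = patterns),
            class = "wildcard_lexicon")
}

#' @export
print.wildcard_lexicon <- function(x, ...) {
  cat("<wildcard_lexicon>", length(x$terms), "terms,",
      sum(lengths(unlist(x$generated_patterns, recursive = FALSE))),
      "patterns\n")
  invisible(x)
}

# word matches a term word iff equal length and at most one differing char
.word_matches <- function(word, target) {
  if (identical(word, target)) return(TRUE)
  n <- nchar(target)
  if (nchar(word) != n) return(FALSE)
  sum(strsplit(word, "")[[1]] != strsplit(target, "")[[1]]) <= 1L
}

#' Rule-based cancer-presence classifier
#'
#' Scans the lowercased, word-tokenized text for any lexicon phrase, where
#' each phrase word may match with at most one character substituted
#' (wildcard patterns). Punctuation tokens are skipped, so "carcinoma ,
#' invasive" still matches phrase-internally. The output is presence/absence
#' only — this baseline cannot delimit findings.
#'
#' @param text A report string.
#' @param lexicon A [wildcard_lexicon()].
#' @return Logical cancer-positive flag.
#' @export
rule_based_classify <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "wildcard_lexicon"))
  toks <- tokenize_words(text)$token
  toks <- toks[grepl("[a-z0-9]", toks)]
  n <- length(toks)
  if (n == 0L) return(FALSE)
  for (ws in lexicon$term_words) {
    k <- length(ws)
    if (k > n) next
    for (i in seq_len(n - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!.word_matches(toks[i + j - 1L], ws[j])) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
  }
  FALSE
}

# ---- TF-IDF + gradient boosting -------------------------------------------

.doc_tokens <- function(x) {
  toks <- if (inherits(x, "annotated_report")) x$tokens$token
  else tokenize_words(x)$token
  toks[grepl("[a-z0-9]", toks)]
}

.tfidf_matrix <- function(doc_tokens, vocab = NULL, idf = NULL, ngram = 1L) {
  if (ngram >= 2L) {
    doc_tokens <- lapply(doc_tokens, function(t) {
      if (length(t) < 2L) return(t)
      c(t, paste(t[-length(t)], t[-1L], sep = "_"))
    })
  }
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(doc_tokens, use.names = FALSE)))
    df <- numeric(length(vocab)); names(df) <- vocab
    for (t in doc_tokens) {
      u <- unique(t)
      df[u] <- df[u] + 1
    }
    idf <- log((1 + length(doc_tokens)) / (1 + df)) + 1
  }
  X <- matrix(0, length(doc_tokens), length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(doc_tokens)) {
    t <- doc_tokens[[i]][doc_tokens[[i]] %in% vocab]
    if (length(t) == 0L) next
    tf <- table(t)
    X[i, names(tf)] <- as.numeric(tf)
  }
  X <- .colscale(X, idf)
  nrm <- sqrt(rowSums(X * X))
  X <- .rowscale(X, ifelse(nrm > 0, 1 / nrm, 0))
  list(X = X, vocab = vocab, idf = idf)
}

#' TF-IDF + gradient-boosted-trees report classifier
#'
#' Converts each report to a term-frequency x inverse-document-frequency
#' vector (vocabulary and document frequencies fixed on the training set;
#' unseen test words are ignored) and fits a binary gradient-boosted tree
#' classifier. The representation is a bag of words: predictions depend only
#' on the multiset of tokens, not their order.
#'
#' @param texts Character vector of report texts, or a list of
#'   `annotated_report`s (whose `report_label` supplies `labels`).
#' @param labels Logical/0-1 vector of cancer-positive flags; both classes
#'   must be present.
#' @param ngram 1 for unigrams (default), 2 to add adjacent-word bigrams.
#' @param nrounds Boosting rounds.
#' @param seed Seed for the tree learner.
#' @return An object of class `tfidf_xgb` with a `predict()` method.
#' @export
fit_tfidf_report_classifier <- function(texts, labels = NULL, ngram = 1L,
                                        nrounds = 50L, seed = 1L) {
  if (is.list(texts) && length(texts) > 0L &&
      inherits(texts[[1]], "annotated_report")) {
    if (is.null(labels))
      labels <- vapply(texts, function(r) r$report_label, logical(1))
  }
  labels <- as.integer(as.logical(labels))
  if (length(texts) < 2L) stop("need at least two reports")
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  doc_tokens <- lapply(texts, .doc_tokens)
  tf <- .tfidf_matrix(doc_tokens, ngram = as.integer(ngram))
  dtrain <- xgboost::xgb.DMatrix(tf$X, label = labels, nthread = 1L)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", nthread = 1L,
                  seed = as.integer(seed)),
    data = dtrain, nrounds = as.integer(nrounds), verbose = 0)
  structure(list(booster = booster, vocab = tf$vocab, idf = tf$idf,
                 nrounds = as.integer(nrounds), ngram = as.integer(ngram)),
            class = "tfidf_xgb")
}

#' @export
print.tfidf_xgb <- function(x, ...) {
  cat("<tfidf_xgb>", length(x$vocab), "terms,",
      x$nrounds, "boosting rounds\n")
  invisible(x)
}

#' @export
#' @param object A fitted `tfidf_xgb` model.
#' @param newdata Character vector of texts or list of `annotated_report`s.
#' @param type `"class"` for logical flags, `"prob"` for probabilities.
#' @param ... Unused.
#' @rdname fit_tfidf_report_classifier
predict.tfidf_xgb <- function(object, newdata,
                              type = c("class", "prob"), ...) {
  type <- match.arg(type)
  doc_tokens <- lapply(newdata, .doc_tokens)
  X <- .tfidf_matrix(doc_tokens, vocab = object$vocab, idf = object$idf,
                     ngram = object$ngram)$X
  p <- stats::predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1L))
  if (type == "prob") p else p >= 0.5
}
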
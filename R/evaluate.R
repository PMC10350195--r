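#' Cancer-positive findings lexicon
#'
#' The findings that make a report cancer-positive: the primary breast
#' cancers (invasive ductal carcinoma, invasive lobular carcinoma,
#' special-type invasive carcinomas including tubular, mucinous and
#' cribriform carcinoma, intraductal papillary carcinoma, microinvasive
#' carcinoma, ductal carcinoma in situ) and, as a non-primary cancer,
#' lymphoma. Lobular carcinoma in situ is a high-risk *benign* finding and
#' is deliberately absent. The list is configuration, not code: pass your
#' own phrases to extend it.
#'
#' @return Lowercase character vector of phrases.
#' @export
positive_findings <- function() {
  c("invasive ductal carcinoma",
    "invasive lobular carcinoma",
    "invasive mammary carcinoma",
    "tubular carcinoma",
    "mucinous carcinoma",
    "cribriform carcinoma",
    "intraductal papillary carcinoma",
    "papillary carcinoma",
    "microinvasive carcinoma",
    "microinvasive ductal carcinoma",
    "ductal carcinoma in situ",
    "lymphoma")
}

.zero_safe <- function(num, den) if (den == 0) 0 else num / den

.prf <- function(tp, fp, fn) {
  p <- .zero_safe(tp, tp + fp)
  r <- .zero_safe(tp, tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

.metric_table <- function(counts) {
  # counts: data.frame(category, tp, fp, fn, support)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    m <- .prf(counts$tp[i], counts$fp[i], counts$fn[i])
    data.frame(category = counts$category[i], precision = m[1],
               recall = m[2], f1 = m[3], support = counts$support[i])
  })
  per_class <- do.call(rbind, rows)
  rownames(per_class) <- NULL
  w <- per_class$support
  weighted <- if (sum(w) == 0) c(precision = 0, recall = 0, f1 = 0) else
    c(precision = sum(per_class$precision * w) / sum(w),
      recall = sum(per_class$recall * w) / sum(w),
      f1 = sum(per_class$f1 * w) / sum(w))
  list(per_class = per_class,
       weighted = data.frame(category = "weighted_avg",
                             precision = weighted[1], recall = weighted[2],
                             f1 = weighted[3], support = sum(w),
                             row.names = NULL))
}

#' Word-level classification metrics
#'
#' Pools tokens across reports and computes precision, recall and F1 per
#' entity class (`"other"` is excluded from the averages), plus the
#' support-weighted average with supports equal to true token counts.
#' Classes absent from both truth and prediction are reported with metrics 0
#' and support 0 and excluded from the weighting.
#'
#' @param true_labels,pred_labels Lists of IO label vectors (or
#'   [token_label_sequence()]s), aligned per report and of equal lengths.
#' @return A list with `per_class` and `weighted` metric data.frames.
#' @export
word_level_metrics <- function(true_labels, pred_labels) {
  get_lab <- function(x) if (inherits(x, "token_label_sequence")) x$labels else x
  true_labels <- lapply(true_labels, get_lab)
  pred_labels <- lapply(pred_labels, get_lab)
  if (length(true_labels) != length(pred_labels))
    stop("true and predicted corpora differ in length")
  if (any(lengths(true_labels) != lengths(pred_labels)))
    stop("label sequence length mismatch between truth and prediction")
  tr <- unlist(true_labels, use.names = FALSE)
  pr <- unlist(pred_labels, use.names = FALSE)
  counts <- do.call(rbind, lapply(entity_categories(), function(cat) {
    l <- paste0("I-", cat)
    data.frame(category = cat,
               tp = sum(tr == l & pr == l),
               fp = sum(tr != l & pr == l),
               fn = sum(tr == l & pr != l),
               support = sum(tr == l))
  }))
  .metric_table(counts)
}

#' Entity-level (exact-match) metrics
#'
#' A predicted entity counts as correct only if a true span with identical
#' start, end and category exists in the same report. Precision is computed
#' over predicted spans, recall over true spans, and the weighted average
#' uses true-span supports.
#'
#' @param true_spans,pred_spans Lists of span data.frames (one per report,
#'   aligned).
#' @return A list with `per_class` and `weighted` metric data.frames.
#' @export
entity_level_metrics <- function(true_spans, pred_spans) {
  if (length(true_spans) != length(pred_spans))
    stop("true and predicted corpora differ in length")
  cats <- entity_categories()
  tp <- fp <- fn <- stats::setNames(numeric(length(cats)), cats)
  for (i in seq_along(true_spans)) {
    ts <- true_spans[[i]]; ps <- pred_spans[[i]]
    validate_spans(ts); validate_spans(ps)
    tkey <- sprintf("%d:%d:%s", ts$start, ts$end, ts$category)
    pkey <- sprintf("%d:%d:%s", ps$start, ps$end, ps$category)
    hit <- pkey %in% tkey
    for (cat in cats) {
      pc <- ps$category == cat
      tc <- ts$category == cat
      tp[cat] <- tp[cat] + sum(hit & pc)
      fp[cat] <- fp[cat] + sum(!hit & pc)
      fn[cat] <- fn[cat] + sum(!(tkey[tc] %in% pkey))
    }
  }
  counts <- data.frame(category = cats, tp = tp, fp = fp, fn = fn,
                       support = tp + fn)
  .metric_table(counts)
}

#' Derive a binary report label from predicted entities
#'
#' A report is cancer-positive iff any predicted cancer-subtype span's
#' surface tokens contain all the (normalized) tokens of some
#' positive-findings phrase. Normalization keeps alphanumeric lowercase
#' tokens only, so punctuation and hyphenation differences are ignored.
#' This derivation — NER output to report label — is a documented
#' interpretation; the lexicon is configurable.
#'
#' @param spans Predicted span data.frame.
#' @param tokens Character vector of the report's word tokens.
#' @param lexicon Character vector of positive phrases
#'   (default [positive_findings()]).
#' @return Logical cancer-positive flag.
#' @export
report_label_from_entities <- function(spans, tokens,
                                       lexicon = positive_findings()) {
  sub <- spans[spans$category == "cancer_subtype", , drop = FALSE]
  if (nrow(sub) == 0L) return(FALSE)
  norm <- function(ws) ws[grepl("[a-z0-9]", ws)]
  phrases <- lapply(lexicon, function(p) norm(tokenize_words(p)$token))
  for (i in seq_len(nrow(sub))) {
    stoks <- norm(tolower(tokens[(sub$start[i] + 1L):sub$end[i]]))
    for (ph in phrases)
      if (all(ph %in% stoks)) return(TRUE)
  }
  FALSE
}

#' Binary report-classification metrics
#'
#' @param true,pred Logical vectors of cancer-positive flags.
#' @return Named vector with precision, recall, F1 and accuracy over the
#'   positive class.
#' @export
report_level_metrics <- function(true, pred) {
  true <- as.logical(true); pred <- as.logical(pred)
  stopifnot(length(true) == length(pred), !anyNA(true), !anyNA(pred))
  m <- .prf(sum(true & pred), sum(!true & pred), sum(true & !pred))
  c(m, accuracy = mean(true == pred))
}

#' Evaluate a system on an annotated test corpus
#'
#' Runs the evaluation protocols a system supports: for a tagger, word-level
#' and exact-match entity-level precision/recall/F1 (per class and
#' support-weighted) plus report-level binary classification with the label
#' derived from predicted entities; for a report classifier (rule-based or
#' TF-IDF model), report-level metrics only. The test corpus is used as-is
#' and must never be augmented. Evaluation is pure: repeated calls on fixed
#' inputs return identical results.
#'
#' @param system A `ner_tagger`, `tfidf_xgb` or `wildcard_lexicon` object.
#' @param corpus List of `annotated_report`s with gold spans (and report
#'   labels where report-level metrics are wanted).
#' @param positive_lexicon Phrases defining cancer-positive findings.
#' @return An object of class `ner_eval`; see [print.ner_eval()],
#'   [eval_to_json()].
#' @export
evaluate_system <- function(system, corpus,
                            positive_lexicon = positive_findings()) {
  stopifnot(is.list(corpus), length(corpus) > 0L)
  true_lab <- vapply(corpus, function(r) r$report_label, logical(1))
  res <- list(n_reports = length(corpus))

  if (inherits(system, "ner_tagger")) {
    gold_tls <- lapply(corpus, spans_to_io_labels)
    pred_tls <- lapply(corpus, function(r) predict_labels(system, r))
    res$word <- word_level_metrics(gold_tls, pred_tls)
    res$entity <- entity_level_metrics(
      lapply(corpus, `[[`, "spans"),
      lapply(pred_tls, io_labels_to_spans))
    if (!anyNA(true_lab)) {
      pred_lab <- mapply(function(tls, r)
        report_label_from_entities(io_labels_to_spans(tls), tls$tokens,
                                   positive_lexicon),
        pred_tls, corpus)
      res$report <- report_level_metrics(true_lab, pred_lab)
    }
  } else if (inherits(system, "wildcard_lexicon")) {
    pred_lab <- vapply(corpus, function(r)
      rule_based_classify(r$text, system), logical(1))
    res$report <- report_level_metrics(true_lab, pred_lab)
  } else if (inherits(system, "tfidf_xgb")) {
    pred_lab <- predict(system, corpus)
    res$report <- report_level_metrics(true_lab, pred_lab)
  } else stop("unsupported system class")
  structure(res, class = "ner_eval")
}

#' @export
#' @param x A `ner_eval` object.
#' @param ... Unused.
#' @rdname evaluate_system
print.ner_eval <- function(x, ...) {
  cat("<ner_eval> on", x$n_reports, "reports\n")
  fmt <- function(tab) {
    df <- rbind(tab$per_class, tab$weighted)
    df$precision <- sprintf("%.3f", df$precision)
    df$recall <- sprintf("%.3f", df$recall)
    df$f1 <- sprintf("%.3f", df$f1)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$word)) { cat("\nWord classification:\n"); fmt(x$word) }
  if (!is.null(x$entity)) { cat("\nEntity recognition (exact match):\n"); fmt(x$entity) }
  if (!is.null(x$report)) {
    cat("\nReport classification:\n")
    print(round(x$report, 3))
  }
  invisible(x)
}

#' Serialize / deserialize an evaluation report
#'
#' @param eval A `ner_eval` object.
#' @param path Optional file path to write to / read from.
#' @return `eval_to_json()` returns the JSON string (invisibly when writing
#'   to a file); `eval_from_json()` returns a `ner_eval`.
#' @export
eval_to_json <- function(eval, path = NULL) {
  stopifnot(inherits(eval, "ner_eval"))
  obj <- unclass(eval)
  if (!is.null(obj$report)) obj$report <- as.list(obj$report)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}

#' @rdname eval_to_json
#' @param json JSON string (alternative to `path`).
#' @export
eval_from_json <- function(path = NULL, json = NULL) {
  obj <- jsonlite::fromJSON(if (!is.null(path)) path else json,
                            simplifyDataFrame = TRUE)
  for (lvl in c("word", "entity")) {
    if (!is.null(obj[[lvl]])) {
      obj[[lvl]]$per_class <- as.data.frame(obj[[lvl]]$per_class)
      obj[[lvl]]$weighted <- as.data.frame(obj[[lvl]]$weighted)
    }
  }
  if (!is.null(obj$report)) obj$report <- unlist(obj$report)
  structure(obj, class = "ner_eval")
}
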
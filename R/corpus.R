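#' Entity categories and IO label alphabet
#'
#' The tagger distinguishes three clinically relevant entity categories in
#' breast pathology reports — cancer subtype, cancer grade and lesion
#' position — plus the non-entity class `"other"`. Under the IO scheme every
#' word token is labelled either `"O"` or `"I-<category>"`; `"other"` is a
#' token label only, never a span category.
#'
#' @return `entity_categories()` returns the three span categories;
#'   `io_labels()` returns the 4-value token label alphabet.
#' @export
entity_categories <- function() {
  c("cancer_subtype", "cancer_grade", "lesion_position")
}

#' @rdname entity_categories
#' @export
io_labels <- function() {
  c("O", paste0("I-", entity_categories()))
}

# ---- spans -----------------------------------------------------------------

#' Construct an entity span table
#'
#' @param start,end 0-based half-open word-index bounds (`start < end`).
#' @param category Entity category, one of [entity_categories()].
#' @return A data.frame with columns `start`, `end`, `category`.
#' @export
entity_spans <- function(start = integer(), end = integer(),
                         category = character()) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   category = as.character(category), stringsAsFactors = FALSE)
  validate_spans(df)
  df
}

validate_spans <- function(spans, n_tokens = NULL) {
  stopifnot(is.data.frame(spans),
            all(c("start", "end", "category") %in% names(spans)))
  if (nrow(spans) == 0L) return(invisible(spans))
  if (any(!spans$category %in% entity_categories()))
    stop("unknown span category: ",
         paste(setdiff(spans$category, entity_categories()), collapse = ", "))
  if (any(spans$start < 0L) || any(spans$start >= spans$end))
    stop("spans must satisfy 0 <= start < end")
  if (!is.null(n_tokens) && any(spans$end > n_tokens))
    stop("span end exceeds token count")
  o <- order(spans$start)
  s <- spans[o, , drop = FALSE]
  if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
    stop("overlapping spans are not a valid annotation")
  invisible(spans)
}

# ---- annotated reports -----------------------------------------------------

#' Construct an annotated pathology report
#'
#' An annotated report couples the raw text, its word tokenization (with
#' character offsets back into the text) and a set of non-overlapping
#' category-labelled entity spans over word indices. All word coordinates are
#' 0-based half-open.
#'
#' @param report_id Opaque identifier string.
#' @param text Raw report text.
#' @param spans A data.frame as returned by [entity_spans()].
#' @param report_label Optional logical cancer-positive flag (`NA` if unknown).
#' @param tokens Optional pre-computed tokenization; defaults to
#'   `tokenize_words(text)`.
#' @return An object of class `annotated_report`.
#' @export
annotated_report <- function(report_id, text, spans = entity_spans(),
                             report_label = NA, tokens = NULL) {
  if (is.null(tokens)) tokens <- tokenize_words(text)
  rep <- structure(
    list(report_id = as.character(report_id), text = text, tokens = tokens,
         spans = spans, report_label = as.logical(report_label)),
    class = "annotated_report")
  validate_report(rep)
  rep
}

#' Validate an annotated report's invariants
#'
#' Checks that token offsets are ordered, non-overlapping and reproduce each
#' token verbatim (modulo lowercasing), and that spans lie within the token
#' range without overlapping.
#'
#' @param report An `annotated_report`.
#' @return The report, invisibly; signals an error on violation.
#' @export
validate_report <- function(report) {
  stopifnot(inherits(report, "annotated_report"))
  tk <- report$tokens
  if (nrow(tk) > 0L) {
    if (any(tk$start >= tk$end)) stop("empty token range")
    if (any(tk$start[-1L] < tk$end[-nrow(tk)]))
      stop("token offsets overlap or are unordered")
    surf <- tolower(substring(report$text, tk$start + 1L, tk$end))
    if (!identical(surf, tk$token))
      stop("token text does not match its character offsets")
  }
  validate_spans(report$spans, n_tokens = nrow(tk))
  invisible(report)
}

#' @export
print.annotated_report <- function(x, ...) {
  cat("<annotated_report ", x$report_id, ">: ", nrow(x$tokens), " tokens, ",
      nrow(x$spans), " spans", sep = "")
  if (!is.na(x$report_label))
    cat(", report_label =", x$report_label)
  cat("\n")
  invisible(x)
}

# Surface text (original casing) of a word-index range of a report.
span_surface <- function(report, start, end) {
  tk <- report$tokens
  substring(report$text, tk$start[start + 1L] + 1L, tk$end[end])
}

# ---- token/label sequences -------------------------------------------------

#' Construct a token/label sequence
#'
#' The parallel (tokens, IO labels) representation all augmentation operators
#' and the tagger operate on.
#'
#' @param tokens Character vector of word tokens.
#' @param labels Character vector of IO labels, one per token.
#' @return An object of class `token_label_sequence`.
#' @export
token_label_sequence <- function(tokens, labels) {
  tokens <- as.character(tokens)
  labels <- as.character(labels)
  if (length(tokens) != length(labels))
    stop("labels must be the same length as tokens")
  bad <- setdiff(unique(labels), io_labels())
  if (length(bad) > 0L)
    stop("unknown IO label: ", paste(bad, collapse = ", "))
  structure(list(tokens = tokens, labels = labels),
            class = "token_label_sequence")
}

#' @export
print.token_label_sequence <- function(x, ...) {
  cat("<token_label_sequence>", length(x$tokens), "tokens\n")
  if (length(x$tokens) > 0L)
    print(data.frame(token = x$tokens, label = x$labels))
  invisible(x)
}

#' @export
length.token_label_sequence <- function(x) length(x$tokens)

# ---- IO codec --------------------------------------------------------------

#' Encode entity spans as word-level IO labels
#'
#' Words inside any span receive `"I-<category>"`; all other words `"O"`.
#' Adjacent same-category spans cannot be distinguished once encoded — the
#' documented lossiness of the IO scheme — so they are merged with a warning.
#'
#' @param report An `annotated_report`.
#' @return A [token_label_sequence()].
#' @export
spans_to_io_labels <- function(report) {
  validate_report(report)
  n <- nrow(report$tokens)
  labels <- rep("O", n)
  sp <- report$spans
  if (nrow(sp) > 0L) {
    sp <- sp[order(sp$start), , drop = FALSE]
    if (nrow(sp) > 1L &&
        any(sp$start[-1L] == sp$end[-nrow(sp)] &
            sp$category[-1L] == sp$category[-nrow(sp)]))
      warning("adjacent same-category spans merge under the IO scheme")
    for (i in seq_len(nrow(sp)))
      labels[(sp$start[i] + 1L):sp$end[i]] <- paste0("I-", sp$category[i])
  }
  token_label_sequence(report$tokens$token, labels)
}

#' Decode IO labels into entity spans
#'
#' Maximal runs of an identical `"I-"` label become one span; spans are
#' returned in start order.
#'
#' @param x A [token_label_sequence()] or a character vector of IO labels.
#' @return A span data.frame as from [entity_spans()].
#' @export
io_labels_to_spans <- function(x) {
  labels <- if (inherits(x, "token_label_sequence")) x$labels else as.character(x)
  bad <- setdiff(unique(labels), io_labels())
  if (length(bad) > 0L)
    stop("unknown IO label: ", paste(bad, collapse = ", "))
  n <- length(labels)
  if (n == 0L) return(entity_spans())
  run_id <- cumsum(c(1L, as.integer(labels[-1L] != labels[-n])))
  starts <- which(!duplicated(run_id))
  ends <- c(starts[-1L], n + 1L)
  keep <- labels[starts] != "O"
  entity_spans(start = starts[keep] - 1L, end = ends[keep] - 1L,
               category = sub("^I-", "", labels[starts[keep]]))
}

# Maximal same-label runs of a label vector: data.frame(start, end, label),
# 0-based half-open. Shared by augmentation operators.
label_runs <- function(labels) {
  n <- length(labels)
  if (n == 0L)
    return(data.frame(start = integer(), end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  run_id <- cumsum(c(1L, as.integer(labels[-1L] != labels[-n])))
  starts <- which(!duplicated(run_id))
  ends <- c(starts[-1L], n + 1L)
  data.frame(start = starts - 1L, end = ends - 1L, label = labels[starts],
             stringsAsFactors = FALSE)
}
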
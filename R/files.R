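#' Read and write standoff annotation files
#'
#' A report is stored as a plain-text `.txt` file plus a brat-like `.ann`
#' file holding one span per line:
#' `id TAB category TAB char-begin TAB char-end TAB surface-text`,
#' with 0-based half-open character offsets into the text. On reading, every
#' span is validated: offsets must lie inside the text, the quoted surface
#' text must equal `text[begin:end)`, and the character range must align with
#' word-token boundaries.
#'
#' @param report An `annotated_report`.
#' @param txt_path,ann_path File paths for the text and annotation parts.
#' @param report_id Identifier for the report being read (defaults to the
#'   text file's base name).
#' @param report_label Optional logical cancer-positive flag to attach.
#' @return `read_standoff()` returns an `annotated_report`;
#'   `write_standoff()` returns the report invisibly.
#' @export
write_standoff <- function(report, txt_path, ann_path) {
  validate_report(report)
  writeLines(report$text, txt_path, useBytes = TRUE, sep = "")
  sp <- report$spans
  lines <- character(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    cb <- report$tokens$start[sp$start[i] + 1L]
    ce <- report$tokens$end[sp$end[i]]
    lines[i] <- paste(paste0("T", i), sp$category[i], cb, ce,
                      substring(report$text, cb + 1L, ce), sep = "\t")
  }
  writeLines(lines, ann_path, useBytes = TRUE)
  invisible(report)
}

#' @rdname write_standoff
#' @export
read_standoff <- function(txt_path, ann_path,
                          report_id = sub("\\.txt$", "", basename(txt_path)),
                          report_label = NA) {
  text <- readChar(txt_path, file.size(txt_path), useBytes = TRUE)
  Encoding(text) <- "UTF-8"
  tokens <- tokenize_words(text)
  lines <- readLines(ann_path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  start <- end <- integer(length(lines))
  category <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L)
      stop(sprintf("%s:%d: expected 5 tab-separated fields", ann_path, i))
    if (!f[2] %in% entity_categories())
      stop(sprintf("%s:%d: unknown category '%s'", ann_path, i, f[2]))
    cb <- suppressWarnings(as.integer(f[3]))
    ce <- suppressWarnings(as.integer(f[4]))
    if (is.na(cb) || is.na(ce) || cb < 0L || ce > nchar(text) || cb >= ce)
      stop(sprintf("%s:%d: character offsets outside the text", ann_path, i))
    surface <- paste(f[-(1:4)], collapse = "\t")
    if (!identical(substring(text, cb + 1L, ce), surface))
      stop(sprintf("%s:%d: surface text does not match text[%d:%d)",
                   ann_path, i, cb, ce))
    ws <- which(tokens$start == cb)
    we <- which(tokens$end == ce)
    if (length(ws) != 1L || length(we) != 1L)
      stop(sprintf("%s:%d: span is not aligned to token boundaries",
                   ann_path, i))
    start[i] <- ws - 1L
    end[i] <- we
    category[i] <- f[2]
  }
  annotated_report(report_id, text,
                   spans = entity_spans(start, end, category),
                   report_label = report_label, tokens = tokens)
}

#' Read and write CoNLL-style token/label files
#'
#' Two tab-separated columns (`token TAB label`), one token per line, with a
#' blank line separating sequences.
#'
#' @param seqs A list of [token_label_sequence()] objects.
#' @param path File path.
#' @return `read_conll()` returns a list of `token_label_sequence` objects;
#'   `write_conll()` returns `seqs` invisibly.
#' @export
write_conll <- function(seqs, path) {
  if (inherits(seqs, "token_label_sequence")) seqs <- list(seqs)
  blocks <- vapply(seqs, function(s) {
    paste(paste(s$tokens, s$labels, sep = "\t"), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(seqs)
}

#' @rdname write_conll
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  seqs <- list()
  tok <- lab <- character()
  flush <- function() {
    if (length(tok) > 0L)
      seqs[[length(seqs) + 1L]] <<- token_label_sequence(tok, lab)
    tok <<- character(); lab <<- character()
  }
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) { flush(); next }
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L)
      stop(sprintf("%s:%d: expected 'token TAB label'", path, i))
    if (!f[2] %in% io_labels())
      stop(sprintf("%s:%d: unknown IO label '%s'", path, i, f[2]))
    tok <- c(tok, f[1]); lab <- c(lab, f[2])
  }
  flush()
  seqs
}

#' Read and write JSONL corpus dumps
#'
#' One JSON object per line with fields `report_id`, `text`, `report_label`
#' and `spans` (word-index coordinates). Tokenization is recomputed
#' deterministically on read.
#'
#' @param corpus A list of `annotated_report` objects.
#' @param path File path.
#' @return `read_corpus_jsonl()` returns a list of `annotated_report`s.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(r) {
    validate_report(r)
    jsonlite::toJSON(list(
      report_id = r$report_id, text = r$text,
      report_label = r$report_label,
      spans = r$spans), auto_unbox = TRUE, na = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(corpus)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    obj <- jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE)
    spans <- if (length(obj$spans) == 0L) entity_spans() else
      entity_spans(obj$spans$start, obj$spans$end, obj$spans$category)
    lab <- if (is.null(obj$report_label)) NA else obj$report_label
    annotated_report(obj$report_id, obj$text, spans = spans,
                     report_label = lab)
  })
}
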
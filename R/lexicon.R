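#' Harvest a lexicon index from a training corpus
#'
#' The lexicon index is the raw material for mention replacement and
#' label-wise token replacement: the full inventory of annotated entity
#' mentions per category (with multiplicity, so frequent mentions are drawn
#' more often) and the multiset of word tokens per IO label. Build it from
#' the designated training split only — augmentation must never see
#' validation or test material.
#'
#' @param corpus Non-empty list of `annotated_report` or
#'   `token_label_sequence` objects.
#' @return An object of class `lexicon_index` with elements `mentions`
#'   (per-category list of token vectors) and `token_pools` (per-IO-label
#'   character vector with multiplicity).
#' @export
build_lexicon_index <- function(corpus) {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop("corpus must be a non-empty list")
  seqs <- lapply(corpus, function(x) {
    if (inherits(x, "annotated_report")) spans_to_io_labels(x)
    else if (inherits(x, "token_label_sequence")) x
    else stop("corpus elements must be annotated_report or token_label_sequence")
  })
  mentions <- stats::setNames(vector("list", length(entity_categories())),
                              entity_categories())
  for (cat in entity_categories()) mentions[[cat]] <- list()
  pools <- stats::setNames(vector("list", length(io_labels())), io_labels())
  for (l in io_labels()) pools[[l]] <- character()

  for (s in seqs) {
    runs <- label_runs(s$labels)
    ent <- runs[runs$label != "O", , drop = FALSE]
    for (i in seq_len(nrow(ent))) {
      cat <- sub("^I-", "", ent$label[i])
      mentions[[cat]][[length(mentions[[cat]]) + 1L]] <-
        s$tokens[(ent$start[i] + 1L):ent$end[i]]
    }
    for (l in unique(s$labels))
      pools[[l]] <- c(pools[[l]], s$tokens[s$labels == l])
  }
  structure(list(mentions = mentions, token_pools = pools),
            class = "lexicon_index")
}

#' @export
print.lexicon_index <- function(x, ...) {
  cat("<lexicon_index>\n")
  for (cat in names(x$mentions))
    cat("  mentions[", cat, "]: ", length(x$mentions[[cat]]), "\n", sep = "")
  for (l in names(x$token_pools))
    cat("  token_pool[", l, "]: ", length(x$token_pools[[l]]), "\n", sep = "")
  invisible(x)
}

#' Synonym lexicons
#'
#' `synonym_lexicon()` builds a word-to-synonym-set mapping from synonym
#' groups; `default_synonym_lexicon()` loads the bundled pathology-domain
#' lexicon (a few hundred report-domain word groups), so synonym replacement
#' needs no external lexical database. Lookup of an unknown word returns an
#' empty set, and a word is never a member of its own synonym set.
#'
#' @param groups A list of character vectors; the words of each vector are
#'   mutual synonyms.
#' @return An object of class `synonym_lexicon`.
#' @export
synonym_lexicon <- function(groups) {
  mapping <- list()
  for (g in groups) {
    g <- unique(tolower(as.character(g)))
    if (length(g) < 2L) next
    for (w in g) {
      syn <- setdiff(g, w)
      mapping[[w]] <- unique(c(mapping[[w]], syn))
    }
  }
  structure(list(mapping = mapping), class = "synonym_lexicon")
}

#' @rdname synonym_lexicon
#' @export
default_synonym_lexicon <- function() {
  path <- system.file("extdata", "synonyms.tsv", package = "pathner")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  synonym_lexicon(strsplit(lines, "\t", fixed = TRUE))
}

#' @rdname synonym_lexicon
#' @param synlex A `synonym_lexicon`.
#' @param word A word to look up.
#' @export
synonyms_of <- function(synlex, word) {
  s <- synlex$mapping[[word]]
  if (is.null(s)) character() else s
}

#' @export
print.synonym_lexicon <- function(x, ...) {
  cat("<synonym_lexicon>", length(x$mapping), "words\n")
  invisible(x)
}
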
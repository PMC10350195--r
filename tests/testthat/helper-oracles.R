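# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation: the tokenizer
# oracle is a character-by-character scanner, the metric oracles are
# brute-force tallies, the span merger is quadratic.

# regex-free hand scanner: split on whitespace; every punctuation char is
# its own token
oracle_tokenize <- function(text) {
  chars <- strsplit(text, "")[[1]]
  is_word <- function(c) grepl("[A-Za-z0-9]", c)
  is_space <- function(c) grepl("[[:space:]]", c)
  toks <- list(); cur <- ""; cur_start <- NA_integer_
  flush <- function(i) {
    if (nzchar(cur))
      toks[[length(toks) + 1L]] <<- list(token = tolower(cur),
                                         start = cur_start, end = i - 1L)
    cur <<- ""; cur_start <<- NA_integer_
  }
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (is_space(c)) { flush(i) }
    else if (is_word(c)) {
      if (!nzchar(cur)) cur_start <- i - 1L
      cur <- paste0(cur, c)
    } else {
      flush(i)
      toks[[length(toks) + 1L]] <- list(token = tolower(c), start = i - 1L,
                                        end = i)
    }
  }
  flush(length(chars) + 1L)
  if (length(toks) == 0L)
    return(data.frame(token = character(), start = integer(),
                      end = integer()))
  data.frame(token = vapply(toks, `[[`, character(1), "token"),
             start = vapply(toks, `[[`, integer(1), "start"),
             end = vapply(toks, `[[`, integer(1), "end"),
             stringsAsFactors = FALSE)
}

# brute-force merger of adjacent same-category spans
oracle_merge_spans <- function(spans) {
  if (nrow(spans) == 0L) return(spans)
  spans <- spans[order(spans$start), , drop = FALSE]
  out <- spans[1, , drop = FALSE]
  for (i in seq_len(nrow(spans))[-1]) {
    last <- nrow(out)
    if (spans$start[i] == out$end[last] &&
        spans$category[i] == out$category[last]) {
      out$end[last] <- spans$end[i]
    } else {
      out <- rbind(out, spans[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

# random non-overlapping span set over n tokens (uses the ambient RNG)
random_spanset <- function(n_tokens, max_spans = 5L) {
  cats <- c("cancer_subtype", "cancer_grade", "lesion_position")
  k <- sample(0:max_spans, 1L)
  starts <- integer(); ends <- integer(); cat <- character()
  cur <- 0L
  for (i in seq_len(k)) {
    if (cur >= n_tokens) break
    s <- cur + sample(0:min(3L, n_tokens - cur - 1L), 1L)
    if (s >= n_tokens) break
    e <- s + sample.int(min(4L, n_tokens - s), 1L)
    starts <- c(starts, s); ends <- c(ends, e)
    cat <- c(cat, sample(cats, 1L))
    cur <- e
  }
  data.frame(start = starts, end = ends, category = cat,
             stringsAsFactors = FALSE)
}

# brute-force pooled confusion-matrix word metrics
oracle_word_metrics <- function(true_labels, pred_labels) {
  tr <- unlist(true_labels); pr <- unlist(pred_labels)
  cats <- c("cancer_subtype", "cancer_grade", "lesion_position")
  res <- lapply(cats, function(cat) {
    l <- paste0("I-", cat)
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(tr)) {
      if (tr[i] == l && pr[i] == l) tp <- tp + 1
      if (tr[i] != l && pr[i] == l) fp <- fp + 1
      if (tr[i] == l && pr[i] != l) fn <- fn + 1
    }
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f, support = sum(tr == l))
  })
  names(res) <- cats
  sup <- vapply(res, `[[`, numeric(1), "support")
  wsum <- function(field) {
    if (sum(sup) == 0) return(0)
    sum(vapply(res, `[[`, numeric(1), field) * sup) / sum(sup)
  }
  list(per_class = res,
       weighted = c(precision = wsum("precision"), recall = wsum("recall"),
                    f1 = wsum("f1")))
}

# brute-force set-intersection entity metrics
oracle_entity_metrics <- function(true_spans, pred_spans) {
  cats <- c("cancer_subtype", "cancer_grade", "lesion_position")
  tp <- fp <- fn <- stats::setNames(numeric(3), cats)
  for (i in seq_along(true_spans)) {
    ts <- true_spans[[i]]; ps <- pred_spans[[i]]
    for (j in seq_len(nrow(ps))) {
      found <- FALSE
      for (k in seq_len(nrow(ts))) {
        if (ps$start[j] == ts$start[k] && ps$end[j] == ts$end[k] &&
            ps$category[j] == ts$category[k]) { found <- TRUE; break }
      }
      if (found) tp[ps$category[j]] <- tp[ps$category[j]] + 1
      else fp[ps$category[j]] <- fp[ps$category[j]] + 1
    }
    for (k in seq_len(nrow(ts))) {
      found <- FALSE
      for (j in seq_len(nrow(ps))) {
        if (ps$start[j] == ts$start[k] && ps$end[j] == ts$end[k] &&
            ps$category[j] == ts$category[k]) { found <- TRUE; break }
      }
      if (!found) fn[ts$category[k]] <- fn[ts$category[k]] + 1
    }
  }
  res <- lapply(cats, function(cat) {
    p <- if (tp[[cat]] + fp[[cat]] == 0) 0 else tp[[cat]] / (tp[[cat]] + fp[[cat]])
    r <- if (tp[[cat]] + fn[[cat]] == 0) 0 else tp[[cat]] / (tp[[cat]] + fn[[cat]])
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f, support = tp[[cat]] + fn[[cat]])
  })
  names(res) <- cats
  sup <- vapply(res, `[[`, numeric(1), "support")
  wsum <- function(field) {
    if (sum(sup) == 0) return(0)
    sum(vapply(res, `[[`, numeric(1), field) * sup) / sum(sup)
  }
  list(per_class = res,
       weighted = c(precision = wsum("precision"), recall = wsum("recall"),
                    f1 = wsum("f1")))
}

# full 1-edit (Damerau) neighborhood of a word: substitutions, deletions,
# adjacent transpositions
oracle_one_edit_neighborhood <- function(word) {
  ch <- strsplit(word, "")[[1]]
  n <- length(ch)
  out <- character()
  for (i in seq_len(n)) for (l in letters) {
    x <- ch; x[i] <- l
    out <- c(out, paste(x, collapse = ""))
  }
  for (i in seq_len(n)) out <- c(out, paste(ch[-i], collapse = ""))
  if (n >= 2L) for (i in seq_len(n - 1L)) {
    x <- ch; x[c(i, i + 1L)] <- x[c(i + 1L, i)]
    out <- c(out, paste(x, collapse = ""))
  }
  setdiff(unique(out), word)
}

# random token/label sequence (ambient RNG)
random_tls <- function(n_tokens = NULL) {
  if (is.null(n_tokens)) n_tokens <- sample(3:20, 1L)
  words <- c("invasive", "ductal", "carcinoma", "grade", "situ", "margins",
             "upper", "outer", "quadrant", "the", "of", "breast", "biopsy",
             "high", "nuclear", "2", ",", ".")
  tokens <- sample(words, n_tokens, replace = TRUE)
  spans <- random_spanset(n_tokens)
  labels <- rep("O", n_tokens)
  for (i in seq_len(nrow(spans)))
    labels[(spans$start[i] + 1L):spans$end[i]] <- paste0("I-", spans$category[i])
  token_label_sequence(tokens, labels)
}
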
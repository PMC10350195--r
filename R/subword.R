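#' Build a deterministic subword vocabulary
#'
#' Words seen at build time map to a single subword id of their own; any other
#' word decomposes into character bigrams hashed into a fixed bucket range, so
#' unseen surface forms (misspellings, dialect short forms) still receive a
#' deterministic encoding without any external tokenizer download. Id 1 is
#' reserved for padding.
#'
#' @param words Character vector of word tokens (typically every token of the
#'   training corpus), or a list of `annotated_report` /
#'   `token_label_sequence` objects to harvest tokens from.
#' @param n_hash Number of hash buckets for out-of-vocabulary bigrams.
#' @return An object of class `subword_vocab`.
#' @export
subword_vocab <- function(words, n_hash = 256L) {
  if (is.list(words)) {
    words <- unlist(lapply(words, function(x) {
      if (inherits(x, "annotated_report")) x$tokens$token
      else if (inherits(x, "token_label_sequence")) x$tokens
      else as.character(x)
    }), use.names = FALSE)
  }
  uw <- sort(unique(as.character(words)))
  ids <- seq_along(uw) + 1L + as.integer(n_hash)
  names(ids) <- uw
  env <- new.env(hash = TRUE, parent = emptyenv(), size = length(uw) + 1L)
  for (i in seq_along(uw)) assign(uw[i], ids[[i]], envir = env)
  structure(list(word_id = ids, env = env, n_hash = as.integer(n_hash),
                 pad_id = 1L, size = 1L + as.integer(n_hash) + length(uw)),
            class = "subword_vocab")
}

#' @export
print.subword_vocab <- function(x, ...) {
  cat("<subword_vocab>", length(x$word_id), "words +", x$n_hash,
      "hash buckets (", x$size, "ids )\n")
  invisible(x)
}

# Deterministic polynomial string hash into 1..n.
.hash_string <- function(s, n) {
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% n
  as.integer(h) + 1L
}

# Subword ids for one word: its own id if known, else hashed character
# bigrams (a single hashed unigram for one-character words).
subword_ids_for_word <- function(vocab, word) {
  id <- get0(word, envir = vocab$env, inherits = FALSE)
  if (!is.null(id)) return(id)
  n <- nchar(word)
  pieces <- if (n <= 1L) word else
    substring(word, seq_len(n - 1L), seq_len(n - 1L) + 1L)
  vapply(pieces, .hash_string, integer(1), n = vocab$n_hash) + 1L
}

#' Encode a token/label sequence as fixed-length subword windows
#'
#' Each word contributes one or more subword ids; only the first subword of a
#' word (its head) carries the word's label id, while continuation subwords
#' and padding carry the ignore marker (`NA`), so exactly one position per
#' word is supervised. Sequences whose subword count exceeds `max_len` are
#' split into word-aligned windows that overlap by `overlap` words; at
#' prediction time each word's label is taken from the window in which the
#' word is most central (see [window_owner()]).
#'
#' @param seq A [token_label_sequence()].
#' @param vocab A [subword_vocab()].
#' @param max_len Window length in subword positions.
#' @param overlap Number of words shared by consecutive windows.
#' @return A list of windows, each a list with `subword_ids` (length
#'   `max_len`, padded), `word_head_positions` (1-based positions of each
#'   word's first subword), `label_ids` (per-position integer label id or
#'   `NA` for ignored positions), `attention_mask` (1 for real subwords, 0
#'   for padding) and `word_range` (0-based half-open word-index range
#'   covered).
#' @export
encode_subwords <- function(seq, vocab, max_len = 128L, overlap = 16L) {
  stopifnot(inherits(seq, "token_label_sequence"),
            inherits(vocab, "subword_vocab"), max_len >= 2L)
  m <- length(seq$tokens)
  if (m == 0L) return(list())
  per_word <- lapply(seq$tokens, subword_ids_for_word, vocab = vocab)
  # a pathological word longer than the window is truncated to fit
  per_word <- lapply(per_word, function(x) x[seq_len(min(length(x), max_len))])
  counts <- lengths(per_word)
  label_id <- match(seq$labels, io_labels())

  windows <- list()
  w_start <- 1L
  repeat {
    cum <- cumsum(counts[w_start:m])
    n_fit <- max(1L, sum(cum <= max_len))
    w_end <- w_start + n_fit - 1L
    idx <- w_start:w_end
    ids <- unlist(per_word[idx], use.names = FALSE)
    heads <- cumsum(c(1L, counts[idx][-length(idx)]))
    n_real <- length(ids)
    subword_ids <- c(ids, rep(vocab$pad_id, max_len - n_real))
    lab <- rep(NA_integer_, max_len)
    lab[heads] <- label_id[idx]
    windows[[length(windows) + 1L]] <- list(
      subword_ids = subword_ids,
      word_head_positions = heads,
      label_ids = lab,
      attention_mask = c(rep(1L, n_real), rep(0L, max_len - n_real)),
      word_range = c(w_start - 1L, w_end))
    if (w_end >= m) break
    w_start <- max(w_start + 1L, w_end - as.integer(overlap) + 1L)
  }
  windows
}

#' Assign each word to its most central window
#'
#' For overlapping windows, a word's prediction is taken from the window
#' whose covered word range centres closest to the word; ties go to the
#' earlier window.
#'
#' @param windows A window list from [encode_subwords()].
#' @param n_words Total word count of the encoded sequence.
#' @return Integer vector of length `n_words`: the owning window index of
#'   each word.
#' @export
window_owner <- function(windows, n_words) {
  if (n_words == 0L) return(integer())
  centers <- vapply(windows, function(w) mean(w$word_range), numeric(1))
  owner <- integer(n_words)
  for (wd in seq_len(n_words)) {
    pos <- wd - 0.5  # centre of word interval [wd-1, wd)
    covering <- which(vapply(windows, function(w)
      wd - 1L >= w$word_range[1] && wd <= w$word_range[2], logical(1)))
    owner[wd] <- covering[which.min(abs(centers[covering] - pos))]
  }
  owner
}
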
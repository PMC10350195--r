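#' Tokenize report text into word tokens with character offsets
#'
#' Splits on whitespace and treats every punctuation character as a token of
#' its own, so `"situ,"` yields `"situ"` and `","`. Token text is lowercased;
#' the character offsets always index the original (unmodified) string, using
#' 0-based half-open `[start, end)` coordinates.
#'
#' @param text A single report string.
#' @return A data.frame with columns `token` (lowercased surface form),
#'   `start`, `end` (0-based half-open character offsets into `text`).
#' @examples
#' tokenize_words("Invasive ductal carcinoma, grade 2")
#' @export
tokenize_words <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[A-Za-z0-9]+|[^[:space:]A-Za-z0-9]", text)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tok <- tolower(regmatches(text, list(m))[[1]])
  data.frame(token = tok, start = start, end = start + as.integer(len),
             stringsAsFactors = FALSE)
}
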
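# Sentiment: lexicon-based polarity and subjectivity in the style of the
# pattern/TextBlob analyzer family. Each lexicon entry carries a polarity in
# [-1, 1], a subjectivity in [0, 1], and an intensity multiplier (> or < 1
# for intensifying/attenuating adverbs such as "very" or "slightly"). The
# document score is the mean over all matched words, with two local rules:
# an intensifier immediately before a scored word multiplies that word's
# polarity and subjectivity instead of being scored itself, and a negator
# ("not", "never", "no", "cannot", or any n't contraction) within the two
# preceding tokens flips and damps polarity by a factor of -0.5.

.webiq_env <- new.env(parent = emptyenv())

sentiment_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.webiq_env$lexicon)) return(.webiq_env$lexicon)
    path <- system.file("extdata", "sentiment_lexicon.csv", package = "webiq")
  }
  lex <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("word", "polarity", "subjectivity", "intensity") %in% names(lex)))
  rownames(lex) <- tolower(lex$word)
  .webiq_env$lexicon <- lex
  lex
}

.negators <- c("not", "no", "never", "cannot")

is_negator <- function(tok) {
  tok %in% .negators | grepl("n't$", tok)
}

#' Score text sentiment with the weighted lexicon
#'
#' @param content A `webiq_content`, or a character vector of text.
#' @param lexicon Optional lexicon data frame (see
#'   `inst/extdata/sentiment_lexicon.csv` for the shipped one).
#' @return Tibble with `polarity` (in \[-1, 1\]), `subjectivity` (in
#'   \[0, 1\]), `objectivity` (exactly `1 - subjectivity`), and
#'   `n_assessments` (matched words). Text with no lexicon match — including
#'   empty content — scores polarity 0, subjectivity 0 by convention.
#' @export
#' @examples
#' sentiment("They have the best available doctors.")
sentiment <- function(content, lexicon = NULL) {
  text <- if (inherits(content, "webiq_content")) content_text(content) else content
  lex <- if (is.null(lexicon)) sentiment_lexicon() else lexicon
  tokens <- tolower(word_tokens(text))
  pols <- numeric(0)
  subs <- numeric(0)
  n <- length(tokens)
  i <- 1L
  while (i <= n) {
    tok <- tokens[i]
    row <- match(tok, rownames(lex))
    if (!is.na(row)) {
      start <- i
      pol <- lex$polarity[row]
      sub <- lex$subjectivity[row]
      nxt <- if (i < n) match(tokens[i + 1L], rownames(lex)) else NA_integer_
      if (!is.na(nxt) && lex$intensity[row] != 1) {
        # intensifier modifying the following scored word
        pol <- lex$polarity[nxt] * lex$intensity[row]
        sub <- lex$subjectivity[nxt] * lex$intensity[row]
        i <- i + 1L
      }
      before <- tokens[seq.int(max(1L, start - 2L), length.out = min(2L, start - 1L))]
      if (any(is_negator(before))) pol <- pol * -0.5
      pols <- c(pols, max(-1, min(1, pol)))
      subs <- c(subs, max(0, min(1, sub)))
    }
    i <- i + 1L
  }
  if (length(pols) == 0) {
    polarity <- 0
    subjectivity <- 0
  } else {
    polarity <- mean(pols)
    subjectivity <- mean(subs)
  }
  tibble::tibble(polarity = polarity, subjectivity = subjectivity,
                 objectivity = 1 - subjectivity, n_assessments = length(pols))
}
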
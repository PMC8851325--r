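# Readability: Flesch Reading Ease (FRE) and Flesch-Kincaid Grade Level
# (FKGL) over the consolidated content. Both need word, sentence, and
# syllable counts; sentences are the consolidated sentence records, words
# are letter/digit tokens (internal apostrophes and hyphens kept), and
# syllables come from the heuristic counter below.

# Syllable counting: count vowel groups ([aeiouy]+), then correct the common
# silent endings.
#   - terminal silent "e": "care", "device" (consonant before the final e,
#     and not a consonant+"le" ending, where the e is sounded: "table");
#   - a trailing plural "s" is dropped first so "makes" behaves like "make"
#     while "classes" keeps its sounded "-es";
#   - "-ed" is silent after any consonant except t/d ("used" = 1,
#     "needed" = 2, "located" = 3).
# Floor of one syllable for any word containing a letter.

#' Count syllables in a word
#'
#' Deterministic heuristic counter (vowel groups with silent-ending
#' corrections); at least 1 for any word containing a vowel. Validated
#' against a 50-word dictionary fixture in the test suite.
#'
#' @param word Character vector of tokens.
#' @return Integer vector of syllable counts (0 for tokens with no letters).
#' @export
#' @examples
#' count_syllables(c("a", "doctor", "university"))
count_syllables <- function(word) {
  vapply(word, function(w) {
    w <- tolower(gsub("[^a-z]", "", tolower(w)))
    if (!nzchar(w)) return(0L)
    groups <- gregexpr("[aeiouy]+", w, perl = TRUE)[[1]]
    n <- if (groups[1] == -1L) 0L else length(groups)
    if (n == 0L) return(1L)  # letters but no vowel (e.g. "Dr"): one beat
    if (n > 1L) {
      if (grepl("[^aeiouyscxzgl]es$", w, perl = TRUE)) {
        n <- n - 1L                        # makes, times (but: classes, pages)
      } else if (grepl("[^aeiouytd]ed$", w, perl = TRUE)) {
        n <- n - 1L                        # used, helped (but: needed, located)
      } else if (grepl("[^aeiouy]e$", w, perl = TRUE) &&
                 !grepl("[^aeiouy]le$", w, perl = TRUE)) {
        n <- n - 1L                        # care, device (but: table)
      }
    }
    max(1L, n)
  }, integer(1), USE.NAMES = FALSE)
}

# Word tokens for readability/similarity counting: runs of letters/digits
# with internal apostrophes or hyphens ("5-year" and "don't" are one word).
word_tokens <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+(?:['-][A-Za-z0-9]+)*", paste(text, collapse = " "),
                perl = TRUE)
  unlist(regmatches(paste(text, collapse = " "), m), use.names = FALSE)
}

#' Flesch-Kincaid readability of consolidated content
#'
#' Computes the two standard Flesch-Kincaid scores from syllable, word, and
#' sentence counts:
#' \deqn{FRE = 206.835 - 1.015 \frac{words}{sentences} - 84.6 \frac{syllables}{words}}
#' \deqn{FKGL = 0.39 \frac{words}{sentences} + 11.8 \frac{syllables}{words} - 15.59}
#' Higher FRE means easier text; FKGL is a US school grade level.
#'
#' @param content A `webiq_content` (see [consolidate()]) or a character
#'   vector of sentences.
#' @return Tibble with `fre`, `fkgl`, `n_sentences`, `n_words`,
#'   `n_syllables`. On empty content the scores are `NA` (metric undefined,
#'   not zero).
#' @export
#' @examples
#' readability(c("The cat sat.", "The dog ran."))
readability <- function(content) {
  sentences <- if (inherits(content, "webiq_content")) content_text(content) else content
  n_sentences <- length(sentences)
  words <- word_tokens(sentences)
  n_words <- length(words)
  n_syllables <- sum(count_syllables(words))
  if (n_sentences == 0 || n_words == 0) {
    return(tibble::tibble(fre = NA_real_, fkgl = NA_real_,
                          n_sentences = n_sentences, n_words = n_words,
                          n_syllables = n_syllables))
  }
  wps <- n_words / n_sentences
  spw <- n_syllables / n_words
  tibble::tibble(
    fre  = 206.835 - 1.015 * wps - 84.6 * spw,
    fkgl = 0.39 * wps + 11.8 * spw - 15.59,
    n_sentences = n_sentences, n_words = n_words, n_syllables = n_syllables)
}
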
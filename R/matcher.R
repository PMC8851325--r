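# Shared keyword matcher.
#
# Every keyword-sensitive operation in the package (site search, anchor
# detection, prevalence, coverage) goes through these three functions, so a
# keyword matches in one place iff it matches everywhere. Matching is
# case-insensitive and whole-token: "IUD" must not match inside "liudmila".
# Multi-word keywords match as contiguous token phrases; whitespace and
# hyphens between the tokens are interchangeable, so "Depo Provera" also
# matches "Depo-Provera".

keyword_regex <- function(keyword) {
  tokens <- strsplit(trimws(keyword), "[\\s-]+", perl = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) stop_webiq("keyword is empty", "webiq_invalid_input")
  escaped <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tokens)
  body <- paste(escaped, collapse = "[\\s-]+")
  paste0("(?i)(?<![A-Za-z0-9])", body, "(?![A-Za-z0-9])")
}

#' Count keyword occurrences in text
#'
#' Whole-token, case-insensitive matching; multi-word keywords are matched
#' as contiguous phrases (whitespace/hyphen insensitive). Each keyword is
#' counted independently, so overlapping keywords (e.g. "IUD" and
#' "hormonal IUD") each contribute their own occurrences.
#'
#' @param text Character vector of text to scan (concatenated before
#'   counting).
#' @param keywords Character vector of keyword phrases.
#' @return Named integer vector, one count per keyword.
#' @export
#' @examples
#' count_keywords("An IUD is a device. The IUD is safe.", c("IUD", "implant"))
count_keywords <- function(text, keywords) {
  joined <- paste(text, collapse = "\n")
  counts <- vapply(keywords, function(kw) {
    m <- gregexpr(keyword_regex(kw), joined, perl = TRUE)[[1]]
    if (length(m) == 1 && m[1] == -1L) 0L else length(m)
  }, integer(1))
  names(counts) <- keywords
  counts
}

#' @rdname count_keywords
#' @return `keywords_present()`: named logical vector.
#' @export
keywords_present <- function(text, keywords) {
  count_keywords(text, keywords) > 0L
}

# For each element of `texts`, TRUE when any keyword matches it.
text_has_any_keyword <- function(texts, keywords) {
  if (length(texts) == 0) return(logical(0))
  patterns <- vapply(keywords, keyword_regex, character(1))
  out <- rep(FALSE, length(texts))
  for (p in patterns) {
    out <- out | grepl(p, texts, perl = TRUE)
  }
  out
}
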
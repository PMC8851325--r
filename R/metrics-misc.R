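# Prevalence, coverage, timeliness, and cosine similarity.

#' Cumulative keyword frequency (prevalence)
#'
#' Sum over keywords of their occurrence counts in the consolidated text
#' (shared matcher; overlapping keywords each counted independently). A raw
#' count, deliberately not normalized by text length.
#'
#' @param content A `webiq_content` or character vector.
#' @param topic A [topic_spec()].
#' @return Non-negative integer count.
#' @export
prevalence <- function(content, topic) {
  stopifnot(inherits(topic, "webiq_topic"))
  text <- if (inherits(content, "webiq_content")) content_text(content) else content
  sum(count_keywords(text, topic$keywords))
}

#' Percentage of distinct keywords found (coverage)
#'
#' `100 * (distinct keywords with at least one occurrence) / (total
#' keywords)`; 0 means no keyword was found, 100 means all were.
#'
#' @inheritParams prevalence
#' @return Percentage in \[0, 100\].
#' @export
coverage <- function(content, topic) {
  stopifnot(inherits(topic, "webiq_topic"))
  text <- if (inherits(content, "webiq_content")) content_text(content) else content
  100 * sum(keywords_present(text, topic$keywords)) / length(topic$keywords)
}

#' Per-page Last-Modified timeliness
#'
#' For each fetched page, the parsed `Last-Modified` timestamp; pages
#' served without the header (or with an unparseable value) carry the
#' sentinel `-1`, meaning the recency of their content cannot be
#' determined.
#'
#' @param pages List of `webiq_page` objects (see [fetch_page()]).
#' @return Tibble with `url`, `last_modified` (POSIXct, `NA` when absent),
#'   and `timeliness` (epoch seconds, or `-1` sentinel).
#' @export
timeliness <- function(pages) {
  if (inherits(pages, "webiq_page")) pages <- list(pages)
  urls <- vapply(pages, function(p) p$final_url, character(1))
  raw <- vapply(pages, function(p) p$last_modified %||% NA_character_, character(1))
  parsed <- parse_http_date(raw)
  tibble::tibble(
    url = urls,
    last_modified = parsed,
    timeliness = ifelse(is.na(parsed), -1, as.numeric(parsed)))
}

# Case-folded term-frequency vector over word tokens.
term_freq <- function(text) {
  tokens <- tolower(word_tokens(text))
  if (length(tokens) == 0) return(integer(0))
  table(tokens)
}

#' Cosine similarity against an ideal reference document
#'
#' Raw term-frequency vectors over case-folded word tokens (no stop-word
#' removal, no weighting), compared by the cosine of the angle between them
#' over the union vocabulary: 1 for identical direction, 0 for disjoint
#' vocabularies. Symmetric, and invariant under whole-document duplication.
#'
#' @param content A `webiq_content` or character vector (the gathered text).
#' @param reference Plain text of the expert-written reference document.
#' @return Similarity in \[0, 1\]; 0 when either side has no tokens.
#' @export
#' @examples
#' similarity("iud iud condom", "iud condom condom")
similarity <- function(content, reference) {
  text <- if (inherits(content, "webiq_content")) content_text(content) else content
  a <- term_freq(text)
  b <- term_freq(reference)
  if (length(a) == 0 || length(b) == 0) return(0)
  vocab <- union(names(a), names(b))
  va <- as.numeric(a[vocab]); va[is.na(va)] <- 0
  vb <- as.numeric(b[vocab]); vb[is.na(vb)] <- 0
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}
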
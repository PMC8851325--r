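# Phase 2: retrieve topic-relevant pages from the SHC site and extract the
# keyword-anchored text. A site-restricted disjunctive search finds candidate
# pages; each page's visible text is segmented into sentences; every sentence
# containing a keyword (anchor) is kept together with a window of context
# sentences around it; per-page extracts are consolidated with exact-duplicate
# removal.

#' Build a site-restricted disjunctive topic query
#'
#' The query pairs the topic's keyword set (one disjunct per distinct
#' keyword) with the host the search must be restricted to. Serializing the
#' query into a concrete engine syntax is the search backend's job.
#'
#' @param topic A [topic_spec()].
#' @param site_host Host of the SHC site, e.g. `"health.sfsu.edu"`.
#' @return A `webiq_query` object (list with `keywords`, `restrict_host`).
#' @export
#' @examples
#' build_topic_query(topic_spec("COVID", c("Corona", "coronavirus", "COVID")),
#'                   "health.sfsu.edu")
build_topic_query <- function(topic, site_host) {
  stopifnot(inherits(topic, "webiq_topic"))
  if (!is.character(site_host) || length(site_host) != 1 || !nzchar(site_host)) {
    stop_webiq("site_host must be a non-empty host name", "webiq_invalid_input")
  }
  structure(list(keywords = topic$keywords, restrict_host = tolower(site_host)),
            class = "webiq_query")
}

#' Run a site-restricted search through a backend
#'
#' The backend maps a `webiq_query` to an ordered vector of result URLs.
#' URLs whose host is not the restriction host (or a subdomain of it) are
#' dropped; backend order is preserved otherwise.
#'
#' @param query A [build_topic_query()] object.
#' @param backend Function `function(query) -> character vector of URLs`.
#' @return Character vector of within-site result URLs, backend order.
#' @export
site_search <- function(query, backend) {
  stopifnot(inherits(query, "webiq_query"))
  urls <- tryCatch(backend(query), error = function(e) {
    stop_webiq(paste0("search backend failed: ", conditionMessage(e)),
               "webiq_search_backend")
  })
  urls <- as.character(urls)
  if (length(urls) == 0) return(character(0))
  keep <- host_within(vapply(urls, url_host, character(1)), query$restrict_host)
  urls[keep]
}

#' Fetch one page through a pluggable fetcher
#'
#' Failures never raise: the outcome is encoded in `status`
#' (`ok`/`timeout`/`http_error`) so one dead page cannot abort a batch run.
#' A timed-out request is retried up to `retries` times.
#'
#' @param url Absolute URL to fetch.
#' @param fetcher Function `function(url, timeout_seconds) -> list` with
#'   elements `status`, `final_url`, `html`, `last_modified` (raw header
#'   value or `NA`).
#' @param timeout_seconds Per-request timeout (default 30 s).
#' @param retries Extra attempts after a timeout (default 1).
#' @return A `webiq_page`: list with `requested_url`, `final_url`, `status`,
#'   `html` (`NA` unless ok), `last_modified`, `fetched_at`.
#' @export
fetch_page <- function(url, fetcher, timeout_seconds = 30, retries = 1L) {
  stopifnot(timeout_seconds > 0)
  attempt <- 0L
  repeat {
    res <- tryCatch(fetcher(url, timeout_seconds),
                    error = function(e) list(status = "http_error"))
    attempt <- attempt + 1L
    if (!identical(res$status, "timeout") || attempt > retries) break
  }
  structure(list(
    requested_url = url,
    final_url     = res$final_url %||% url,
    status        = res$status %||% "http_error",
    html          = if (identical(res$status, "ok")) res$html else NA_character_,
    last_modified = res$last_modified %||% NA_character_,
    fetched_at    = Sys.time()
  ), class = "webiq_page")
}

# Sentence segmentation: split on terminal punctuation followed by
# whitespace and an upper-case/digit sentence opener, protecting a list of
# common abbreviations so "Dr. Smith" stays one sentence. Fixture manifests
# bypass segmentation ambiguity in tests; this splitter is for real pages.
.abbreviations <- c("dr", "mr", "mrs", "ms", "prof", "st", "no", "fig",
                    "vs", "etc", "e.g", "i.e", "approx", "dept", "univ")

split_sentences <- function(text) {
  text <- gsub("[\r\n\t]+", " ", text)
  text <- gsub(" {2,}", " ", trimws(text))
  if (!nzchar(text)) return(character(0))
  # shield abbreviation periods with a placeholder, split, then restore
  ph <- intToUtf8(1L)
  shielded <- text
  for (ab in .abbreviations) {
    ab_re <- gsub(".", "\\\\.", ab, fixed = TRUE)
    shielded <- gsub(paste0("(?i)(?<![A-Za-z])(", ab_re, ")\\."),
                     paste0("\\1", ph), shielded, perl = TRUE)
  }
  parts <- strsplit(shielded, "(?<=[.!?])\\s+(?=[\"'(]?[A-Z0-9])", perl = TRUE)[[1]]
  parts <- gsub(ph, ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Extract visible sentences from HTML markup
#'
#' Parses the markup, removes script/style and structural boilerplate
#' (`<nav>`, `<header>`, `<footer>`), and segments the remaining visible
#' text into sentences in document order. Unparseable markup yields an
#' empty vector rather than an error.
#'
#' @param html Raw markup text.
#' @return Character vector of sentences in document order.
#' @export
#' @examples
#' html_to_sentences("<p>A red dog. A blue cat.</p>")
html_to_sentences <- function(html) {
  if (is.null(html) || length(html) != 1 || is.na(html) || !nzchar(html)) {
    return(character(0))
  }
  doc <- tryCatch(xml2::read_html(html), error = function(e) NULL)
  if (is.null(doc)) return(character(0))
  for (xp in c("//script", "//style", "//nav", "//header", "//footer")) {
    xml2::xml_remove(xml2::xml_find_all(doc, xp))
  }
  blocks <- xml2::xml_find_all(
    doc, "//p | //li | //h1 | //h2 | //h3 | //h4 | //h5 | //h6 | //td | //blockquote")
  texts <- if (length(blocks) > 0) {
    xml2::xml_text(blocks)
  } else {
    body <- xml2::xml_find_first(doc, "//body")
    if (inherits(body, "xml_missing")) character(0) else xml2::xml_text(body)
  }
  unlist(lapply(texts, split_sentences), use.names = FALSE)
}

#' Keep anchor sentences plus surrounding context
#'
#' An anchor sentence contains at least one topic keyword (shared matcher).
#' The extract is, in document order, every sentence whose 0-based index
#' lies within `window` of an anchor index; overlapping windows contribute
#' each sentence once, and windows truncate at the page boundary. With
#' `window = 0` the extract is exactly the anchor sentences.
#'
#' @param sentences Ordered character vector: one page's sentences.
#' @param topic A [topic_spec()].
#' @param window Context radius in sentences (default 5).
#' @param source_url URL the sentences came from (recorded per row).
#' @return Tibble with `text`, `source_url`, `index` (0-based position in
#'   the page), `is_anchor`.
#' @export
extract_keyword_context <- function(sentences, topic, window = 5L,
                                    source_url = NA_character_) {
  stopifnot(inherits(topic, "webiq_topic"), window >= 0)
  n <- length(sentences)
  empty <- tibble::tibble(text = character(0), source_url = character(0),
                          index = integer(0), is_anchor = logical(0))
  if (n == 0) return(empty)
  anchor <- text_has_any_keyword(sentences, topic$keywords)
  if (!any(anchor)) return(empty)
  keep <- rep(FALSE, n)
  for (i in which(anchor)) {
    lo <- max(1L, i - window)
    hi <- min(n, i + window)
    keep[lo:hi] <- TRUE
  }
  idx <- which(keep)
  tibble::tibble(text = unname(sentences[idx]),
                 source_url = rep(source_url, length(idx)),
                 index = idx - 1L,
                 is_anchor = anchor[idx])
}

# Dedup key: case-fold, collapse internal whitespace, strip terminal
# punctuation. Exact match thereafter.
normalize_sentence <- function(text) {
  x <- tolower(trimws(text))
  x <- gsub("\\s+", " ", x)
  sub("[[:punct:]]+$", "", x)
}

#' Consolidate per-page extracts into one content set
#'
#' Concatenates extracts in page order (then sentence order within a page)
#' and removes duplicate sentences — same normalized text — keeping the
#' first occurrence. Consolidation is idempotent.
#'
#' @param extracts A list of per-page extract tibbles (from
#'   [extract_keyword_context()]), a single such tibble, or a
#'   `webiq_content`.
#' @param source_urls URLs of the result pages the extracts came from
#'   (defaults to the distinct `source_url` values present).
#' @return A `webiq_content`: list with `sentences` (tibble) and
#'   `source_urls`.
#' @export
consolidate <- function(extracts, source_urls = NULL) {
  if (inherits(extracts, "webiq_content")) {
    source_urls <- source_urls %||% extracts$source_urls
    extracts <- extracts$sentences
  }
  if (is.data.frame(extracts)) extracts <- list(extracts)
  all <- dplyr::bind_rows(extracts)
  if (nrow(all) == 0) {
    all <- tibble::tibble(text = character(0), source_url = character(0),
                          index = integer(0), is_anchor = logical(0))
  }
  all <- all[!duplicated(normalize_sentence(all$text)), , drop = FALSE]
  urls <- source_urls %||% unique(all$source_url[!is.na(all$source_url)])
  structure(list(sentences = tibble::as_tibble(all), source_urls = urls),
            class = "webiq_content")
}

#' @export
print.webiq_content <- function(x, ...) {
  cat("<webiq_content> ", nrow(x$sentences), " sentences from ",
      length(x$source_urls), " page(s)\n", sep = "")
  invisible(x)
}

content_text <- function(content) {
  stopifnot(inherits(content, "webiq_content"))
  content$sentences$text
}

#' Gather topic content from an SHC site
#'
#' End-to-end phase 2: site-restricted search, page download, per-page
#' anchor/context extraction, consolidation. Pages that time out or error
#' are recorded and skipped; they never abort the run.
#'
#' @param home_url Sanitized SHC home URL (host restriction comes from it).
#' @param topic A [topic_spec()].
#' @param search_backend See [site_search()].
#' @param fetcher See [fetch_page()].
#' @param window Context radius (default 5).
#' @param timeout_seconds,retries Fetch policy (defaults 30 s, 1 retry).
#' @return List with `content` (`webiq_content`), `pages` (list of
#'   `webiq_page`, one per search result), `result_urls`.
#' @export
gather_content <- function(home_url, topic, search_backend, fetcher,
                           window = 5L, timeout_seconds = 30, retries = 1L) {
  query <- build_topic_query(topic, url_host(home_url))
  result_urls <- site_search(query, search_backend)
  pages <- lapply(result_urls, fetch_page, fetcher = fetcher,
                  timeout_seconds = timeout_seconds, retries = retries)
  extracts <- lapply(pages, function(pg) {
    if (!identical(pg$status, "ok")) return(NULL)
    sentences <- html_to_sentences(pg$html)
    extract_keyword_context(sentences, topic, window = window,
                            source_url = pg$final_url)
  })
  ok_urls <- vapply(pages, function(pg) pg$final_url, character(1))[
    vapply(pages, function(pg) identical(pg$status, "ok"), logical(1))]
  list(content = consolidate(purrr::compact(extracts), source_urls = ok_urls),
       pages = pages,
       result_urls = result_urls)
}
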
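# Phase 1: resolve a university name to the canonical URL of its student
# health center (SHC) home page. There is no naming convention for SHC sites
# (health.sfsu.edu, www.csub.edu/healthcenter, www.cpp.edu/~health, ...), so
# location goes through a web search: query the name plus "student health
# center", keep the first .edu hit among the top three results, then
# canonicalize the URL.

#' Build the SHC locator search query
#'
#' Joins the trimmed university name with the phrase
#' `"student health center"`.
#'
#' @param university_name Official institution name (non-empty).
#' @return Query text, e.g. `"San Francisco State University student health
#'   center"`.
#' @export
build_locator_query <- function(university_name) {
  if (!is.character(university_name) || length(university_name) != 1 ||
      is.na(university_name) || !nzchar(trimws(university_name))) {
    stop_webiq("university name must be non-empty text", "webiq_invalid_input")
  }
  paste(trimws(university_name), "student health center")
}

#' Pick the SHC URL from ranked search results
#'
#' Scans the top 3 results in rank order and returns the first whose host
#' ends in `.edu` (case-insensitive). Results beyond rank 3 are never
#' consulted; if no `.edu` host appears among ranks 1-3 the SHC website is
#' declared not found. The raw result URL is judged as returned by the
#' search backend — redirects are not resolved before the `.edu` test.
#'
#' @param results Tibble/data frame with `rank` (unique integers from 1) and
#'   `url` columns, or a character vector of URLs taken to be in rank order.
#' @return A list with `status` (`"found"` or `"not_found"`) and `home_url`
#'   (`NA` unless found).
#' @export
#' @examples
#' select_shc_url(c("https://clinic.example.com/", "https://www.csub.edu/healthcenter"))
select_shc_url <- function(results) {
  if (is.character(results)) {
    results <- tibble::tibble(rank = seq_along(results), url = results)
  }
  not_found <- list(status = "not_found", home_url = NA_character_)
  if (is.null(results) || nrow(results) == 0) return(not_found)
  if (anyDuplicated(results$rank)) {
    stop_webiq("search result ranks must be unique", "webiq_invalid_input")
  }
  results <- results[order(results$rank), , drop = FALSE]
  top <- utils::head(results, 3L)
  edu <- host_is_edu(vapply(top$url, url_host, character(1)))
  if (!any(edu)) return(not_found)
  list(status = "found", home_url = top$url[which(edu)[1]])
}

#' Canonicalize a candidate SHC home URL
#'
#' Three steps: (a) follow redirects to the final URL using the supplied
#' resolver; (b) drop any query string and fragment; (c) remove one trailing
#' path segment when it is in `strip_segments` (by default the
#' appointment/contact/location leaf pages that search engines often rank
#' above the SHC home itself). The result is the URL used as the navigation
#' start point and the site-search restriction host.
#'
#' @param url Absolute URL of the selected search result.
#' @param resolver `NULL` (no redirect following) or a function
#'   `function(url) -> target URL or NULL` returning the immediate redirect
#'   target of `url`, `NULL` when the URL does not redirect.
#' @param strip_segments Trailing path segments to strip (exact segment
#'   match, at most one removed per call).
#' @param max_hops Redirect chain cap; a longer chain raises a
#'   `webiq_redirect_loop` error.
#' @return The canonical home URL.
#' @export
#' @examples
#' sanitize_home_url("https://health.sfsu.edu/contacts")
sanitize_home_url <- function(url, resolver = NULL,
                              strip_segments = c("contacts", "appointments", "location"),
                              max_hops = 10L) {
  if (!is_absolute_url(url)) {
    stop_webiq(paste0("not an absolute URL: ", url), "webiq_invalid_input")
  }
  if (!is.null(resolver)) {
    hops <- 0L
    repeat {
      nxt <- resolver(url)
      if (is.null(nxt) || identical(nxt, url)) break
      hops <- hops + 1L
      if (hops > max_hops) {
        stop_webiq(paste0("redirect chain exceeded ", max_hops, " hops at ", url),
                   "webiq_redirect_loop", url = url)
      }
      url <- nxt
    }
  }
  url <- sub("[?#].*$", "", url)
  scheme <- url_scheme(url)
  host <- url_host(url)
  path <- url_path(url)
  segments <- strsplit(path, "/", fixed = TRUE)[[1]]
  segments <- segments[nzchar(segments)]
  if (length(segments) > 0 &&
      tolower(segments[length(segments)]) %in% tolower(strip_segments)) {
    segments <- segments[-length(segments)]
  }
  path <- if (length(segments) == 0) "/" else paste0("/", paste(segments, collapse = "/"))
  paste0(scheme, "://", host, path)
}

#' Locate SHC websites for a batch of universities
#'
#' Runs the locator (query, search, top-3 `.edu` selection, sanitization)
#' for each university and returns one row per university.
#'
#' @param universities Tibble with a `university_name` column (see
#'   [read_universities()]), or a character vector of names.
#' @param search_backend Function `function(query_text) -> ranked results`
#'   (tibble with `rank`/`url` or a character vector in rank order).
#' @param resolver Redirect resolver passed to [sanitize_home_url()].
#' @inheritParams sanitize_home_url
#' @return Tibble with columns `university_name`, `status`
#'   (`found`/`not_found`), `home_url`.
#' @export
locate_shc <- function(universities, search_backend, resolver = NULL,
                       strip_segments = c("contacts", "appointments", "location")) {
  if (is.character(universities)) {
    universities <- tibble::tibble(university_name = universities)
  }
  purrr::map_dfr(universities$university_name, function(nm) {
    query <- build_locator_query(nm)
    loc <- select_shc_url(search_backend(query))
    home <- NA_character_
    if (loc$status == "found") {
      home <- sanitize_home_url(loc$home_url, resolver = resolver,
                                strip_segments = strip_segments)
    }
    tibble::tibble(university_name = nm, status = loc$status, home_url = home)
  })
}
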
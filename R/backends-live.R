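# Live-web backend pieces. The search backend against a commercial engine
# needs credentials and an engine-specific serialization of the disjunctive
# query, so it is injected by the user; the fetcher and redirect resolver
# below cover the HTTP side through the curl package when it is installed.

#' HTTP fetcher for live runs
#'
#' Returns a fetcher with the [fetch_page()] contract backed by libcurl:
#' redirects followed, `Last-Modified` captured, timeouts and HTTP errors
#' mapped to the `timeout`/`http_error` statuses.
#'
#' @return A `function(url, timeout_seconds)` suitable for [fetch_page()]
#'   and [navigation()].
#' @export
live_fetcher <- function() {
  if (!requireNamespace("curl", quietly = TRUE)) {
    stop_webiq("the curl package is required for live fetching", "webiq_invalid_input")
  }
  function(url, timeout_seconds) {
    h <- curl::new_handle(timeout = timeout_seconds, followlocation = TRUE,
                          maxredirs = 10)
    res <- tryCatch(curl::curl_fetch_memory(url, handle = h), error = function(e) e)
    if (inherits(res, "error")) {
      timed_out <- grepl("timed out|timeout", conditionMessage(res), ignore.case = TRUE)
      return(list(status = if (timed_out) "timeout" else "http_error",
                  final_url = url))
    }
    if (res$status_code >= 400) {
      return(list(status = "http_error", final_url = res$url))
    }
    headers <- curl::parse_headers_list(res$headers)
    list(status = "ok", final_url = res$url,
         html = rawToChar(res$content),
         last_modified = headers[["last-modified"]] %||% NA_character_)
  }
}

#' Redirect resolver for live runs
#'
#' Issues a non-following request and reports the `Location` header, or
#' `NULL` when the URL does not redirect.
#'
#' @return A `function(url)` suitable for [sanitize_home_url()].
#' @export
live_resolver <- function() {
  if (!requireNamespace("curl", quietly = TRUE)) {
    stop_webiq("the curl package is required for live fetching", "webiq_invalid_input")
  }
  function(url) {
    h <- curl::new_handle(followlocation = FALSE, nobody = TRUE)
    res <- tryCatch(curl::curl_fetch_memory(url, handle = h), error = function(e) NULL)
    if (is.null(res) || res$status_code < 300 || res$status_code >= 400) return(NULL)
    loc <- curl::parse_headers_list(res$headers)[["location"]]
    if (is.null(loc)) NULL else resolve_href(loc, url)
  }
}
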
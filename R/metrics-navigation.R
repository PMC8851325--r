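# Navigation metric: minimum number of hyperlink clicks from the SHC home
# page to the nearest page carrying topic content, found by breadth-first
# search over the site's own hyperlinks. A FIFO queue holds (URL, level,
# trace) nodes; links are enqueued in document order; off-domain links are
# filtered out. The search stops with -1 and an empty trace when a popped
# node's level exceeds the cap (nodes at the cap level are still examined)
# or when the queue empties. A visited set keyed on the normalized URL
# prevents re-enqueueing on cyclic sites; because the first BFS visit is a
# shortest one, it cannot change the reported minimum.

extract_links <- function(html, base_url) {
  if (is.na(html) || !nzchar(html)) return(character(0))
  doc <- tryCatch(xml2::read_html(html), error = function(e) NULL)
  if (is.null(doc)) return(character(0))
  hrefs <- xml2::xml_attr(xml2::xml_find_all(doc, "//a[@href]"), "href")
  hrefs <- hrefs[!is.na(hrefs) & nzchar(hrefs) & !grepl("^(#|mailto:|javascript:|tel:)", hrefs)]
  vapply(hrefs, resolve_href, character(1), base = base_url, USE.NAMES = FALSE)
}

#' Minimum-click navigation distance by breadth-first search
#'
#' Walks the live link structure (through `fetcher`, not a site map) from
#' the home page and returns the level of the first page whose normalized
#' URL matches a target, together with the click trace from home to it.
#'
#' @param home_url Sanitized SHC home URL (level-0 start node).
#' @param target_urls URLs of the keyword-bearing pages (from
#'   [site_search()]).
#' @param fetcher Page fetcher (see [fetch_page()]).
#' @param level_cap Deepest level still examined (default 10). A popped node
#'   beyond it ends the search with clicks `-1`.
#' @param timeout_seconds,retries Fetch policy.
#' @return List with `clicks` (`-1` or `0..level_cap`), `trace` (URL vector;
#'   empty iff clicks is `-1`), and `status` (`"ok"`, `"not_reached"`, or
#'   `"home_unfetchable"`).
#' @export
navigation <- function(home_url, target_urls, fetcher, level_cap = 10L,
                       timeout_seconds = 30, retries = 1L) {
  not_reached <- list(clicks = -1L, trace = character(0), status = "not_reached")
  if (length(target_urls) == 0) return(not_reached)
  targets <- unique(normalize_url(target_urls))
  home_host <- url_host(home_url)

  queue <- list(list(url = home_url, level = 0L, trace = home_url))
  visited <- normalize_url(home_url)
  first_pop <- TRUE
  while (length(queue) > 0) {
    node <- queue[[1]]
    queue <- queue[-1]
    if (node$level > level_cap) return(not_reached)
    if (normalize_url(node$url) %in% targets) {
      return(list(clicks = node$level, trace = node$trace, status = "ok"))
    }
    page <- fetch_page(node$url, fetcher, timeout_seconds = timeout_seconds,
                       retries = retries)
    if (!identical(page$status, "ok")) {
      if (first_pop) {
        return(list(clicks = -1L, trace = character(0),
                    status = "home_unfetchable"))
      }
      first_pop <- FALSE
      next
    }
    first_pop <- FALSE
    links <- extract_links(page$html, page$final_url)
    links <- links[host_within(vapply(links, url_host, character(1)), home_host)]
    for (h in links) {
      key <- normalize_url(h)
      if (key %in% visited) next
      visited <- c(visited, key)
      queue[[length(queue) + 1L]] <- list(url = h, level = node$level + 1L,
                                          trace = c(node$trace, h))
    }
  }
  not_reached
}
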
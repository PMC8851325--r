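#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @import tibble
NULL

# URL helpers. The pipeline deals only in absolute http(s) URLs; these
# regex-based accessors avoid pulling a full URL grammar for the handful of
# components we need (scheme, host, path).

url_scheme <- function(url) {
  m <- regmatches(url, regexpr("^[A-Za-z][A-Za-z0-9+.-]*(?=://)", url, perl = TRUE))
  if (length(m) == 0) NA_character_ else tolower(m)
}

url_host <- function(url) {
  rest <- sub("^[A-Za-z][A-Za-z0-9+.-]*://", "", url)
  host <- sub("[/?#].*$", "", rest)
  host <- sub(":[0-9]+$", "", host)   # port
  host <- sub("^[^@]*@", "", host)    # userinfo
  if (!nzchar(host)) NA_character_ else tolower(host)
}

url_path <- function(url) {
  rest <- sub("^[A-Za-z][A-Za-z0-9+.-]*://[^/?#]*", "", url)
  path <- sub("[?#].*$", "", rest)
  if (!nzchar(path)) "/" else path
}

is_absolute_url <- function(url) {
  is.character(url) && length(url) == 1 && !is.na(url) &&
    grepl("^[A-Za-z][A-Za-z0-9+.-]*://[^/?#]+", url)
}

#' Normalize a URL for identity comparison
#'
#' Lower-cases the scheme and host, drops the fragment and query string, and
#' normalizes a bare trailing slash (`/foo/` and `/foo` compare equal; the
#' root path is always `/`). This is the single normalization used for the
#' breadth-first-search visited set, for target matching in the navigation
#' metric, and for deduplicating fetched pages, so all three agree on when
#' two URLs name the same page.
#'
#' @param url Character vector of absolute URLs.
#' @return Character vector of normalized URLs.
#' @export
#' @examples
#' normalize_url("HTTPS://Health.SFSU.edu/services/#top")
normalize_url <- function(url) {
  vapply(url, function(u) {
    if (is.na(u)) return(NA_character_)
    u <- sub("#.*$", "", u)
    u <- sub("\\?.*$", "", u)
    scheme <- url_scheme(u)
    if (is.na(scheme)) return(u)
    host <- url_host(u)
    path <- url_path(u)
    if (path != "/") path <- sub("/+$", "", path)
    if (!nzchar(path)) path <- "/"
    paste0(scheme, "://", host, path)
  }, character(1), USE.NAMES = FALSE)
}

# TRUE when host is exactly `domain` or a subdomain of it.
host_within <- function(host, domain) {
  host <- tolower(host)
  domain <- tolower(domain)
  !is.na(host) & (host == domain | endsWith(host, paste0(".", domain)))
}

host_is_edu <- function(host) {
  !is.na(host) & grepl("\\.edu$", tolower(host))
}

# Resolve a possibly relative href against a base URL (delegates to xml2,
# which implements the RFC 3986 merge rules).
resolve_href <- function(href, base) {
  xml2::url_absolute(href, base)
}

#' Parse an HTTP-date header value
#'
#' Accepts the three date formats HTTP/1.1 allows (RFC 1123, RFC 850, and
#' asctime). Parsing is done under the C time locale so month and weekday
#' names match regardless of the session locale.
#'
#' @param x Character vector of `Last-Modified` header values.
#' @return `POSIXct` (UTC) vector; `NA` where the value is missing or does
#'   not parse.
#' @export
#' @examples
#' parse_http_date("Wed, 21 Oct 2015 07:28:00 GMT")
parse_http_date <- function(x) {
  old <- Sys.getlocale("LC_TIME")
  on.exit(suppressWarnings(Sys.setlocale("LC_TIME", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_TIME", "C"))
  formats <- c(
    "%a, %d %b %Y %H:%M:%S",  # RFC 1123: Wed, 21 Oct 2015 07:28:00 GMT
    "%A, %d-%b-%y %H:%M:%S",  # RFC 850:  Wednesday, 21-Oct-15 07:28:00 GMT
    "%a %b %e %H:%M:%S %Y"    # asctime:  Wed Oct 21 07:28:00 2015
  )
  out <- rep(as.POSIXct(NA), length(x))
  for (fmt in formats) {
    todo <- is.na(out) & !is.na(x)
    if (!any(todo)) break
    parsed <- as.POSIXct(strptime(x[todo], fmt, tz = "GMT"))
    out[todo] <- parsed
  }
  attr(out, "tzone") <- "UTC"
  out
}

stop_webiq <- function(message, class, ...) {
  abort(message, class = c(class, "webiq_error"), ...)
}
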
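# Synthetic SHC-like websites: deterministic multi-page sites with a known
# hyperlink graph, chosen keyword placements, per-page Last-Modified headers,
# redirect chains, and unresponsive (stall) pages. The site manifest is the
# single source of ground truth for oracle tests, and the fixture backends
# implement the same fetcher/search/resolver contracts as a live deployment,
# so the whole pipeline runs offline.

#' Describe one fixture page
#'
#' @param path Site-relative URL path (must start with `/`, unique within a
#'   site).
#' @param body_sentences Ordered character vector of body sentences (one
#'   paragraph each in the emitted HTML).
#' @param link_paths Site-relative paths this page links to, in document
#'   order.
#' @param external_links Absolute off-domain URLs emitted after the internal
#'   links.
#' @param last_modified HTTP-date string for the `Last-Modified` header, or
#'   `NA` for a page served without one.
#' @param behavior `"ok"`, `"stall"` (unresponsive), `"http_error"`, or
#'   `"redirect:<path>"`.
#' @param stall_seconds How long a `"stall"` page hangs before the server
#'   would answer (compared against the fetch timeout).
#' @return A `webiq_pagespec` list.
#' @export
page_spec <- function(path, body_sentences = character(0),
                      link_paths = character(0), external_links = character(0),
                      last_modified = NA_character_, behavior = "ok",
                      stall_seconds = 60) {
  if (!is.character(path) || length(path) != 1 || !startsWith(path, "/")) {
    stop_webiq("page path must start with '/'", "webiq_invalid_spec")
  }
  if (!identical(behavior, "ok") && !identical(behavior, "stall") &&
      !identical(behavior, "http_error") && !startsWith(behavior, "redirect:")) {
    stop_webiq(paste0("unknown page behavior: ", behavior), "webiq_invalid_spec")
  }
  structure(list(path = path,
                 body_sentences = as.character(body_sentences),
                 link_paths = as.character(link_paths),
                 external_links = as.character(external_links),
                 last_modified = last_modified,
                 behavior = behavior,
                 stall_seconds = stall_seconds),
            class = "webiq_pagespec")
}

#' Describe a fixture site
#'
#' @param domain Host name the fixture pretends to be served from (give it
#'   a `.edu` suffix when the locator is part of the test).
#' @param pages List of [page_spec()] objects.
#' @param home_path Path of the home page (must exist in `pages`).
#' @param seed Seed recorded when the site was generated by [random_site()].
#' @return A `webiq_sitespec` list; link paths that resolve to no page are
#'   recorded in `dangling`.
#' @export
site_spec <- function(domain, pages, home_path = "/", seed = NULL) {
  paths <- vapply(pages, `[[`, character(1), "path")
  if (anyDuplicated(paths)) {
    stop_webiq("duplicate page paths in site spec", "webiq_invalid_spec")
  }
  if (!home_path %in% paths) {
    stop_webiq("home_path has no page in the spec", "webiq_invalid_spec")
  }
  linked <- unique(unlist(lapply(pages, `[[`, "link_paths")))
  redirected <- unlist(lapply(pages, function(p) {
    if (startsWith(p$behavior, "redirect:")) sub("^redirect:", "", p$behavior) else NULL
  }))
  dangling <- setdiff(unique(c(linked, redirected)), paths)
  names(pages) <- paths
  structure(list(domain = tolower(domain), home_path = home_path,
                 pages = pages, dangling = dangling, seed = seed),
            class = "webiq_sitespec")
}

#' @export
print.webiq_sitespec <- function(x, ...) {
  cat("<webiq_sitespec> ", x$domain, ": ", length(x$pages), " page(s), home ",
      x$home_path, "\n", sep = "")
  invisible(x)
}

#' Absolute URL of a fixture page
#' @param site A `webiq_sitespec`.
#' @param path Site-relative path.
#' @export
page_url <- function(site, path) {
  paste0("https://", site$domain, path)
}

#' Home URL of a fixture site
#' @param site A `webiq_sitespec`.
#' @export
site_home_url <- function(site) page_url(site, site$home_path)

# Hyperlink adjacency (internal links only) as a two-column tibble of paths;
# the ground truth the shortest-path oracle runs on.
#' Internal link graph of a fixture site
#' @param site A `webiq_sitespec`.
#' @return Tibble with `from`/`to` path columns, one row per hyperlink, in
#'   document order within each page.
#' @export
site_graph <- function(site) {
  edges <- purrr::map_dfr(site$pages, function(p) {
    if (length(p$link_paths) == 0) return(NULL)
    tibble::tibble(from = p$path, to = p$link_paths)
  })
  if (nrow(edges) == 0) tibble::tibble(from = character(0), to = character(0)) else edges
}

render_page_html <- function(page, domain) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  paras <- sprintf("    <p>%s</p>", esc(page$body_sentences))
  internal <- sprintf('    <a href="%s">%s</a>', esc(page$link_paths),
                      esc(page$link_paths))
  external <- sprintf('    <a href="%s">%s</a>', esc(page$external_links),
                      esc(page$external_links))
  paste(c("<!DOCTYPE html>",
          "<html>",
          sprintf("  <head><title>%s</title></head>", esc(page$path)),
          "  <body>",
          paras,
          if (length(page$link_paths) > 0) internal,
          if (length(page$external_links) > 0) external,
          "  </body>",
          "</html>"),
        collapse = "\n")
}

page_file_name <- function(path) {
  if (path == "/") "index.html" else paste0(gsub("/", "__", sub("^/", "", path)), ".html")
}

#' Materialize a fixture site to disk
#'
#' Writes one HTML file per page (body sentences as paragraphs, hyperlinks
#' in declared order) plus a `manifest.json` carrying the full spec and the
#' path-to-file mapping. Output is byte-identical across runs for the same
#' spec.
#'
#' @param site A `webiq_sitespec`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
generate_site <- function(site, out_dir) {
  stopifnot(inherits(site, "webiq_sitespec"))
  files <- vapply(site$pages, function(p) page_file_name(p$path), character(1))
  if (anyDuplicated(files)) {
    stop_webiq("page paths collide after file-name mapping", "webiq_invalid_spec")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in site$pages) {
    writeLines(render_page_html(p, site$domain),
               file.path(out_dir, page_file_name(p$path)), useBytes = TRUE)
  }
  manifest <- list(
    domain = site$domain, home_path = site$home_path,
    seed = site$seed,
    pages = lapply(unname(site$pages), function(p) {
      list(path = p$path, file = page_file_name(p$path),
           body_sentences = as.list(p$body_sentences),
           link_paths = as.list(p$link_paths),
           external_links = as.list(p$external_links),
           last_modified = if (is.na(p$last_modified)) NULL else p$last_modified,
           behavior = p$behavior, stall_seconds = p$stall_seconds)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' Read a materialized fixture site back from its manifest
#'
#' @param dir Directory written by [generate_site()] (or a path to the
#'   manifest file itself).
#' @return A `webiq_sitespec`.
#' @export
read_site <- function(dir) {
  manifest_path <- if (grepl("\\.json$", dir)) dir else file.path(dir, "manifest.json")
  m <- jsonlite::read_json(manifest_path)
  pages <- lapply(m$pages, function(p) {
    page_spec(path = p$path,
              body_sentences = unlist(p$body_sentences) %||% character(0),
              link_paths = unlist(p$link_paths) %||% character(0),
              external_links = unlist(p$external_links) %||% character(0),
              last_modified = p$last_modified %||% NA_character_,
              behavior = p$behavior,
              stall_seconds = p$stall_seconds %||% 60)
  })
  site_spec(m$domain, pages, home_path = m$home_path, seed = m$seed)
}

# Bank of neutral health-information sentences used as filler in random
# sites, plus keyword-bearing templates. Worded to avoid the sentiment
# lexicon so fixture sentiment is deterministic (polarity 0).
.sentence_bank <- c(
  "The student health center is on the second floor of the campus services building.",
  "Appointments can be scheduled through the online student portal.",
  "The clinic accepts most student insurance plans.",
  "Walk-in hours run from nine in the morning until noon on weekdays.",
  "Students should bring their campus identification card to each visit.",
  "The pharmacy fills prescriptions written by campus providers.",
  "Medical records are maintained according to state and federal regulations.",
  "The nursing staff reviews immunization records during the first semester.",
  "Laboratory testing is performed on site during clinic hours.",
  "Referrals to community providers are coordinated by the case manager.",
  "Health education workshops are held each month in the student union.",
  "The center follows the guidance issued by the county health department.",
  "Students may complete intake forms before their first appointment.",
  "Telehealth visits are offered for follow-up consultations.",
  "After-hours advice is handled by the campus nurse line.",
  "Flu shots are given each autumn at the campus clinic.")

.keyword_templates <- c(
  "Information about %s is published by the student health center.",
  "Students can ask the clinic staff about %s during any visit.",
  "The health center maintains a resource page on %s.")

#' Generate a seeded random fixture site
#'
#' Same seed, same arguments: identical spec. The home page is always
#' present; each ordered page pair is linked with probability `link_prob`
#' (links in path order); keywords from `topic` are injected into
#' `ceiling(keyword_page_fraction * n_pages)` pages chosen by the seeded
#' generator; roughly 70% of pages carry a `Last-Modified` header.
#'
#' @param seed Integer seed.
#' @param n_pages Number of pages including the home page (>= 1).
#' @param link_prob Probability of a hyperlink for each ordered page pair.
#' @param topic A [topic_spec()] supplying the keywords to place.
#' @param keyword_page_fraction Fraction of pages that receive a keyword
#'   sentence (0 gives a site where coverage must evaluate to 0).
#' @param domain Fixture host name.
#' @return A `webiq_sitespec`.
#' @export
random_site <- function(seed, n_pages, link_prob = 0.2, topic = NULL,
                        keyword_page_fraction = 0.3,
                        domain = sprintf("shc%d.example.edu", seed)) {
  stopifnot(n_pages >= 1, link_prob >= 0, link_prob <= 1,
            keyword_page_fraction >= 0, keyword_page_fraction <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  paths <- c("/", if (n_pages > 1) sprintf("/page%d", seq_len(n_pages - 1)))
  n_kw <- ceiling(keyword_page_fraction * n_pages)
  kw_paths <- if (n_kw > 0 && !is.null(topic)) {
    sample(paths, min(n_kw, n_pages))
  } else character(0)

  pages <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    body <- sample(.sentence_bank, size = sample(3:6, 1), replace = TRUE)
    if (p %in% kw_paths) {
      kw <- sample(topic$keywords, 1)
      kw_sentence <- sprintf(sample(.keyword_templates, 1), kw)
      pos <- sample(seq_len(length(body) + 1), 1)
      body <- append(body, kw_sentence, after = pos - 1)
    }
    links <- paths[paths != p & stats::runif(length(paths)) < link_prob]
    lm <- if (stats::runif(1) < 0.7) {
      format_http_date(as.POSIXct("2015-01-01", tz = "UTC") +
                         round(stats::runif(1, 0, 5 * 365 * 86400)))
    } else NA_character_
    page_spec(p, body_sentences = body, link_paths = links, last_modified = lm)
  })
  site_spec(domain, pages, home_path = "/", seed = seed)
}

# RFC 1123 formatter, locale-independent.
format_http_date <- function(time) {
  t <- as.POSIXlt(time, tz = "GMT")
  days <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")
  months <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
              "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
  sprintf("%s, %02d %s %04d %02d:%02d:%02d GMT",
          days[t$wday + 1], t$mday, months[t$mon + 1], t$year + 1900,
          t$hour, t$min, floor(t$sec))
}

#' Rename fixture paths while preserving content and link graph
#'
#' Emulates a site restructuring (directory renames, URL changes): every
#' path in `rename` is replaced in page paths, link targets, redirect
#' targets, and the home path. Content, link structure, and headers are
#' otherwise untouched, so the restructured site is graph-isomorphic to the
#' original.
#'
#' @param site A `webiq_sitespec`.
#' @param rename Named character vector, `old path = new path`. Must be
#'   injective and must not collide with untouched paths.
#' @return The renamed `webiq_sitespec`.
#' @export
restructure_site <- function(site, rename) {
  stopifnot(inherits(site, "webiq_sitespec"))
  old <- names(rename)
  paths <- vapply(site$pages, `[[`, character(1), "path")
  if (is.null(old) || anyDuplicated(old) || anyDuplicated(rename) ||
      !all(old %in% paths)) {
    stop_webiq("rename must be an injective map over existing site paths",
               "webiq_invalid_spec")
  }
  final <- ifelse(paths %in% old, rename[paths], paths)
  if (anyDuplicated(final)) {
    stop_webiq("rename collides with untouched paths", "webiq_invalid_spec")
  }
  map_path <- function(p) if (p %in% old) unname(rename[p]) else p
  pages <- lapply(unname(site$pages), function(pg) {
    behavior <- pg$behavior
    if (startsWith(behavior, "redirect:")) {
      behavior <- paste0("redirect:", map_path(sub("^redirect:", "", behavior)))
    }
    page_spec(map_path(pg$path),
              body_sentences = pg$body_sentences,
              link_paths = vapply(pg$link_paths, map_path, character(1),
                                  USE.NAMES = FALSE),
              external_links = pg$external_links,
              last_modified = pg$last_modified,
              behavior = behavior,
              stall_seconds = pg$stall_seconds)
  })
  site_spec(site$domain, pages, home_path = map_path(site$home_path),
            seed = site$seed)
}

#' Offline backends serving a fixture site
#'
#' Returns the three pluggable interfaces the pipeline needs, all answering
#' from the site spec (or a materialized site directory):
#' \describe{
#'   \item{fetcher}{Serves pages per their declared behavior: `ok` pages
#'     return rendered HTML and any `Last-Modified` header; `stall` pages
#'     time out whenever their stall time exceeds the fetch timeout;
#'     `redirect:` pages follow the declared chain (capped at 10 hops) and
#'     report the final URL; unknown paths and `http_error` pages return an
#'     HTTP error, as a real server would.}
#'   \item{search_backend}{Answers site-restricted queries by brute-force
#'     keyword scan over the manifest sentences (shared matcher), returning
#'     matching page URLs in path order.}
#'   \item{redirect_resolver}{Immediate redirect target of a URL, or `NULL`.}
#'   \item{locator_backend}{Single-result search backend whose rank-1 hit is
#'     the site's home URL (for end-to-end locator runs).}
#' }
#'
#' @param site A `webiq_sitespec` or a directory written by
#'   [generate_site()].
#' @return Named list of functions plus `home_url` and `site`.
#' @export
fixture_backends <- function(site) {
  if (is.character(site)) site <- read_site(site)
  stopifnot(inherits(site, "webiq_sitespec"))
  by_norm <- vapply(site$pages, function(p) normalize_url(page_url(site, p$path)),
                    character(1))

  find_page <- function(url) {
    hit <- match(normalize_url(url), by_norm)
    if (is.na(hit)) NULL else site$pages[[hit]]
  }

  fetcher <- function(url, timeout_seconds) {
    if (!host_within(url_host(url), site$domain)) {
      return(list(status = "http_error", final_url = url))
    }
    pg <- find_page(url)
    hops <- 0L
    while (!is.null(pg) && startsWith(pg$behavior, "redirect:")) {
      hops <- hops + 1L
      if (hops > 10L) return(list(status = "http_error", final_url = url))
      target <- sub("^redirect:", "", pg$behavior)
      url <- page_url(site, target)
      pg <- find_page(url)
    }
    if (is.null(pg) || identical(pg$behavior, "http_error")) {
      return(list(status = "http_error", final_url = url))
    }
    if (identical(pg$behavior, "stall") && pg$stall_seconds > timeout_seconds) {
      return(list(status = "timeout", final_url = url))
    }
    list(status = "ok", final_url = page_url(site, pg$path),
         html = render_page_html(pg, site$domain),
         last_modified = pg$last_modified)
  }

  search_backend <- function(query) {
    hits <- vapply(site$pages, function(p) {
      length(p$body_sentences) > 0 &&
        any(text_has_any_keyword(p$body_sentences, query$keywords))
    }, logical(1))
    paths <- sort(vapply(site$pages[hits], `[[`, character(1), "path"))
    vapply(paths, function(p) page_url(site, p), character(1), USE.NAMES = FALSE)
  }

  redirect_resolver <- function(url) {
    pg <- find_page(url)
    if (is.null(pg) || !startsWith(pg$behavior, "redirect:")) return(NULL)
    page_url(site, sub("^redirect:", "", pg$behavior))
  }

  locator_backend <- function(query_text) {
    tibble::tibble(rank = 1L, url = site_home_url(site))
  }

  list(fetcher = fetcher, search_backend = search_backend,
       redirect_resolver = redirect_resolver, locator_backend = locator_backend,
       home_url = site_home_url(site), site = site)
}
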
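# End-to-end orchestration: for each (university, topic) pair, locate the
# SHC site, gather keyword-anchored content, compute the eight quality
# metrics, and emit one report row. Per-university failures (SHC not found,
# dead pages) become status rows; they never abort the batch. Wall time is
# logged per phase and classed as network (locate, fetch) or compute
# (metric computation) so the runtime breakdown of any run is recomputable
# from its log.

#' Assemble a run configuration
#'
#' @param universities Tibble with `university_name`, a character vector of
#'   names, or a path to a CSV with that column.
#' @param topics A [topic_spec()], a list of them, or a path to a JSON/YAML
#'   topic config (see [read_topics()]).
#' @param backend_provider Function `function(university_name) -> backends`
#'   returning a list with `locator_backend`, `redirect_resolver`,
#'   `search_backend`, `fetcher` (see [fixture_backends()]), or `NULL` when
#'   the university has no reachable site. For fixture runs, see
#'   [fixture_provider()].
#' @param reference_docs Optional named list/character vector mapping topic
#'   name to reference-document text (or a file path to read).
#' @param timeout_seconds,retries Fetch policy (defaults 30 s, 1 retry).
#' @param level_cap Navigation BFS level cap (default 10).
#' @param window Context window radius in sentences (default 5).
#' @param output_csv,log_path Optional output locations (report CSV, JSON
#'   lines timing log).
#' @return A validated `webiq_config` list.
#' @export
run_config <- function(universities, topics, backend_provider,
                       reference_docs = NULL, timeout_seconds = 30,
                       retries = 1L, level_cap = 10L, window = 5L,
                       output_csv = NULL, log_path = NULL) {
  if (is.character(universities) && length(universities) == 1 &&
      file.exists(universities)) {
    universities <- read_universities(universities)
  } else if (is.character(universities)) {
    universities <- tibble::tibble(university_name = universities)
  }
  if (is.character(topics)) topics <- read_topics(topics)
  if (inherits(topics, "webiq_topic")) topics <- list(topics)
  if (length(topics) == 0) {
    stop_webiq("at least one topic is required", "webiq_invalid_input")
  }
  stopifnot(is.function(backend_provider), timeout_seconds > 0, level_cap >= 0)
  reference_docs <- lapply(reference_docs, function(r) {
    if (is.character(r) && length(r) == 1 && file.exists(r)) {
      paste(readLines(r, warn = FALSE), collapse = "\n")
    } else r
  })
  structure(list(universities = universities, topics = topics,
                 backend_provider = backend_provider,
                 reference_docs = reference_docs,
                 timeout_seconds = timeout_seconds, retries = retries,
                 level_cap = level_cap, window = window,
                 output_csv = output_csv, log_path = log_path),
            class = "webiq_config")
}

#' Backend provider over a set of fixture sites
#'
#' Maps each university name to the [fixture_backends()] of its fixture
#' site. Universities without an entry get `NULL` (their SHC will not be
#' found).
#'
#' @param sites Named list: university name to `webiq_sitespec` or
#'   materialized site directory.
#' @return A backend provider function for [run_config()].
#' @export
fixture_provider <- function(sites) {
  cache <- lapply(sites, function(s) if (is.null(s)) NULL else fixture_backends(s))
  function(university_name) {
    if (!university_name %in% names(cache)) return(NULL)
    cache[[university_name]]
  }
}

empty_metrics <- function() {
  tibble::tibble(fre = NA_real_, fkgl = NA_real_, prevalence = 0L,
                 coverage_pct = 0, objectivity = NA_real_, polarity = NA_real_,
                 nav_clicks = -1L, nav_trace = "", n_pages = 0L,
                 timeliness = "", similarity = NA_real_)
}

serialize_timeliness <- function(tl) {
  if (nrow(tl) == 0) return("")
  val <- ifelse(tl$timeliness < 0, "-1",
                format(tl$last_modified, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  paste(paste0(tl$url, "=", val), collapse = ";")
}

#' Run the full quality pipeline
#'
#' @param config A [run_config()].
#' @return A `webiq_report` tibble, one row per (university, topic) with the
#'   report schema: `university_name`, `topic`, `status` (`ok`,
#'   `shc_not_found`, `no_content`), `fre`, `fkgl`, `prevalence`,
#'   `coverage_pct`, `objectivity`, `polarity`, `nav_clicks`, `nav_trace`
#'   (`|`-joined URLs), `n_pages`, `timeliness` (`URL=timestamp;...` with
#'   `-1` sentinels written literally), `similarity`. The timing log is
#'   attached as attribute `"log"`. Side effects: the report CSV and JSON
#'   lines log when configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "webiq_config"))
  log_rows <- list()
  add_log <- function(university, topic, phase, class, status, elapsed_ms) {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      university = university, topic = topic, phase = phase,
      class = class, status = status, elapsed_ms = elapsed_ms)
  }
  timed <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- expr
    list(value = value, ms = (proc.time()[["elapsed"]] - t0) * 1000)
  }

  rows <- list()
  for (uni in config$universities$university_name) {
    backends <- config$backend_provider(uni)

    loc <- timed({
      if (is.null(backends)) {
        list(status = "not_found", home_url = NA_character_)
      } else {
        res <- select_shc_url(backends$locator_backend(build_locator_query(uni)))
        if (res$status == "found") {
          res$home_url <- sanitize_home_url(res$home_url,
                                            resolver = backends$redirect_resolver)
        }
        res
      }
    })
    add_log(uni, NA_character_, "locate", "network", loc$value$status, loc$ms)

    for (topic in config$topics) {
      if (loc$value$status != "found") {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(university_name = uni, topic = topic$name,
                         status = "shc_not_found"),
          empty_metrics())
        next
      }
      home <- loc$value$home_url
      gath <- timed(gather_content(home, topic, backends$search_backend,
                                   backends$fetcher, window = config$window,
                                   timeout_seconds = config$timeout_seconds,
                                   retries = config$retries))
      add_log(uni, topic$name, "gather", "network", "ok", gath$ms)

      nav <- timed(navigation(home, gath$value$result_urls, backends$fetcher,
                              level_cap = config$level_cap,
                              timeout_seconds = config$timeout_seconds,
                              retries = config$retries))
      add_log(uni, topic$name, "navigation", "network", nav$value$status, nav$ms)

      met <- timed({
        content <- gath$value$content
        pages_ok <- Filter(function(p) identical(p$status, "ok"), gath$value$pages)
        reference <- config$reference_docs[[topic$name]]
        if (nrow(content$sentences) == 0) {
          m <- empty_metrics()
          m$nav_clicks <- nav$value$clicks
          m$nav_trace <- paste(nav$value$trace, collapse = "|")
          m$n_pages <- length(gath$value$pages)
          tibble::add_column(m, status = "no_content", .before = 1)
        } else {
          rd <- readability(content)
          sen <- sentiment(content)
          tl <- timeliness(pages_ok)
          tibble::tibble(
            status = "ok",
            fre = rd$fre, fkgl = rd$fkgl,
            prevalence = prevalence(content, topic),
            coverage_pct = coverage(content, topic),
            objectivity = sen$objectivity, polarity = sen$polarity,
            nav_clicks = nav$value$clicks,
            nav_trace = paste(nav$value$trace, collapse = "|"),
            n_pages = length(gath$value$pages),
            timeliness = serialize_timeliness(tl),
            similarity = if (is.null(reference)) NA_real_ else {
              similarity(content, reference)
            })
        }
      })
      add_log(uni, topic$name, "metrics", "compute", met$value$status, met$ms)

      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(university_name = uni, topic = topic$name),
        met$value)
    }
  }

  report <- dplyr::bind_rows(rows)
  if (nrow(report) == 0) {
    report <- dplyr::bind_cols(
      tibble::tibble(university_name = character(0), topic = character(0),
                     status = character(0)),
      empty_metrics()[0, ])
  }
  report <- dplyr::relocate(report, "status", .after = "topic")
  class(report) <- c("webiq_report", class(report))
  log <- dplyr::bind_rows(log_rows)
  attr(report, "log") <- log

  if (!is.null(config$output_csv)) write_report(report, config$output_csv)
  if (!is.null(config$log_path)) {
    writeLines(vapply(seq_len(nrow(log)), function(i) {
      jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)
    }, character(1)), config$log_path)
  }
  report
}

#' Write the report CSV
#'
#' @param report A `webiq_report` tibble.
#' @param path Output CSV path.
#' @export
write_report <- function(report, path) {
  readr::write_csv(report, path, na = "", progress = FALSE)
  invisible(path)
}

#' Network-versus-compute runtime breakdown
#'
#' Sums the per-phase timers of a run log by university: phases that touch
#' the network (locate, gather, navigation) against pure metric computation.
#' The two fractions sum to 1 for every university with any recorded time.
#'
#' @param log The tibble attached to a report as attribute `"log"`, a
#'   JSON-lines log file path, or any tibble with `university`, `class`,
#'   `elapsed_ms` columns (injected timers welcome).
#' @return Tibble with `university`, `network_ms`, `compute_ms`, `total_ms`,
#'   `network_frac`, `compute_frac`.
#' @export
timing_report <- function(log) {
  if (is.character(log)) {
    log <- dplyr::bind_rows(lapply(readLines(log), function(l) {
      tibble::as_tibble(jsonlite::fromJSON(l))
    }))
  }
  if (inherits(log, "webiq_report")) log <- attr(log, "log")
  log |>
    dplyr::group_by(.data$university) |>
    dplyr::summarise(
      network_ms = sum(.data$elapsed_ms[.data$class == "network"]),
      compute_ms = sum(.data$elapsed_ms[.data$class == "compute"]),
      .groups = "drop") |>
    dplyr::mutate(
      total_ms = .data$network_ms + .data$compute_ms,
      network_frac = ifelse(.data$total_ms > 0, .data$network_ms / .data$total_ms, NA_real_),
      compute_frac = ifelse(.data$total_ms > 0, .data$compute_ms / .data$total_ms, NA_real_))
}

#' Plot a quality report
#'
#' One panel per metric, one bar per (university, topic) pair. Rows whose
#' status is not `ok` are dropped (their metrics are markers, not values).
#'
#' @param object A `webiq_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.webiq_report <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$status == "ok")
  long <- tidyr::pivot_longer(
    df, c("fre", "fkgl", "prevalence", "coverage_pct", "objectivity",
          "polarity", "nav_clicks", "similarity"),
    names_to = "metric", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(
    x = interaction(.data$university_name, .data$topic, sep = " / "),
    y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Web health-information quality metrics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.webiq_report
#' @param report A `webiq_report`.
#' @export
plot_report <- function(report, ...) autoplot.webiq_report(report, ...)
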
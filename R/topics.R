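#' Define a health topic as a named keyword set
#'
#' A topic is the user-facing query vocabulary: a label plus one or more
#' keyword phrases. Keywords that duplicate an earlier one after case-folding
#' are collapsed (set semantics), keeping the first spelling.
#'
#' @param name Topic label (non-empty text).
#' @param keywords Character vector of keyword phrases, each non-empty.
#' @return A `webiq_topic` object (list with `name` and `keywords`).
#' @export
#' @examples
#' topic_spec("LARC", c("IUD", "intrauterine device", "contraceptive implant"))
topic_spec <- function(name, keywords) {
  if (!is.character(name) || length(name) != 1 || !nzchar(trimws(name))) {
    stop_webiq("topic name must be non-empty text", "webiq_invalid_input")
  }
  keywords <- as.character(keywords)
  keywords <- trimws(keywords)
  if (length(keywords) == 0 || any(!nzchar(keywords))) {
    stop_webiq("topic needs at least one non-empty keyword", "webiq_invalid_input")
  }
  keywords <- keywords[!duplicated(tolower(keywords))]
  structure(list(name = trimws(name), keywords = keywords), class = "webiq_topic")
}

#' @export
print.webiq_topic <- function(x, ...) {
  cat("<webiq_topic> ", x$name, ": ",
      paste(x$keywords, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read topic definitions from a config file
#'
#' The config maps topic name to keyword list, either as JSON
#' (`{"LARC": ["IUD", ...], ...}`) or YAML with the same shape (by file
#' extension `.yml`/`.yaml`).
#'
#' @param path Path to the JSON or YAML topic config.
#' @return Named list of [topic_spec()] objects.
#' @export
read_topics <- function(path) {
  if (!file.exists(path)) {
    stop_webiq(paste0("topic config not found: ", path), "webiq_invalid_input")
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_webiq("the yaml package is required to read YAML topic configs",
                 "webiq_invalid_input")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(raw) || is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop_webiq("topic config must map topic names to keyword lists",
               "webiq_invalid_input")
  }
  topics <- lapply(names(raw), function(nm) topic_spec(nm, unlist(raw[[nm]])))
  names(topics) <- vapply(topics, `[[`, character(1), "name")
  topics
}

#' Read the university list
#'
#' @param path CSV file with a header row and a `university_name` column.
#' @return Tibble with a `university_name` character column (possibly zero
#'   rows).
#' @export
read_universities <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!"university_name" %in% names(df)) {
    stop_webiq("universities CSV must have a 'university_name' column",
               "webiq_invalid_input")
  }
  tibble::tibble(university_name = trimws(df$university_name))
}
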
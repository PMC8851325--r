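# Independent oracles the tests check the implementation against. These are
# deliberately written with different primitives than the package code
# (fixed-string scanning instead of regex, igraph instead of the hand-rolled
# breadth-first search).

# Brute-force keyword occurrence count: fixed-substring scan over the
# case-folded, hyphen/whitespace-normalized text with manual boundary checks.
oracle_count_keyword <- function(text, keyword) {
  norm <- function(x) gsub("[\\s-]+", " ", tolower(x), perl = TRUE)
  t <- norm(paste(text, collapse = " \n "))
  k <- norm(trimws(keyword))
  hits <- gregexpr(k, t, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(0L)
  ok <- vapply(hits, function(s) {
    before <- if (s > 1) substr(t, s - 1, s - 1) else ""
    after_pos <- s + nchar(k)
    after <- if (after_pos <= nchar(t)) substr(t, after_pos, after_pos) else ""
    !grepl("[a-z0-9]", before) && !grepl("[a-z0-9]", after)
  }, logical(1))
  sum(ok)
}

oracle_prevalence <- function(text, topic) {
  sum(vapply(topic$keywords, function(k) oracle_count_keyword(text, k), integer(1)))
}

oracle_coverage <- function(text, topic) {
  found <- vapply(topic$keywords, function(k) oracle_count_keyword(text, k) > 0,
                  logical(1))
  100 * sum(found) / length(topic$keywords)
}

# Pages whose manifest sentences contain any topic keyword, by the
# brute-force scanner.
oracle_keyword_paths <- function(site, topic) {
  hits <- vapply(site$pages, function(p) {
    length(p$body_sentences) > 0 && oracle_prevalence(p$body_sentences, topic) > 0
  }, logical(1))
  vapply(site$pages[hits], `[[`, character(1), "path", USE.NAMES = FALSE)
}

# Shortest-path navigation oracle on the manifest link graph via igraph.
oracle_navigation <- function(site, topic, level_cap = 10) {
  targets <- oracle_keyword_paths(site, topic)
  if (length(targets) == 0) return(-1L)
  paths <- vapply(site$pages, `[[`, character(1), "path", USE.NAMES = FALSE)
  edges <- site_graph(site)
  edges <- edges[edges$to %in% paths, , drop = FALSE]  # drop dangling links
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = paths))
  d <- igraph::distances(g, v = site$home_path, to = targets, mode = "out")
  dmin <- suppressWarnings(min(d))
  if (!is.finite(dmin) || dmin > level_cap) -1L else as.integer(dmin)
}
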
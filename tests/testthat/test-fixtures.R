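# Synthetic-site generator: determinism, materialization round-trip,
# restructuring, backend contracts.

test_that("site specs reject duplicate paths and missing home", {
  expect_error(site_spec("x.edu", list(page_spec("/a"), page_spec("/a")),
                         home_path = "/a"),
               class = "webiq_invalid_spec")
  expect_error(site_spec("x.edu", list(page_spec("/a")), home_path = "/"),
               class = "webiq_invalid_spec")
  expect_error(page_spec("no-slash"), class = "webiq_invalid_spec")
  expect_error(page_spec("/x", behavior = "explode"), class = "webiq_invalid_spec")
})

test_that("random sites are reproducible and leave the session RNG alone", {
  topic <- larc_topic()
  s1 <- random_site(1, n_pages = 5, topic = topic)
  s2 <- random_site(1, n_pages = 5, topic = topic)
  expect_identical(s1, s2)
  s3 <- random_site(2, n_pages = 5, topic = topic)
  expect_false(identical(s1, s3))

  set.seed(99)
  before <- .Random.seed
  invisible(random_site(7, n_pages = 10, topic = topic))
  expect_identical(.Random.seed, before)
})

test_that("keyword_page_fraction zero yields a site with zero coverage", {
  topic <- larc_topic()
  site <- random_site(5, n_pages = 8, topic = topic, keyword_page_fraction = 0)
  b <- fixture_backends(site)
  g <- gather_content(site_home_url(site), topic, b$search_backend, b$fetcher)
  expect_equal(coverage(g$content, topic), 0)
  expect_equal(prevalence(g$content, topic), 0)
})

test_that("materialization is byte-identical and round-trips the link graph", {
  site <- demo_site()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_site(site, d1)
  generate_site(site, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }

  # manifest round-trip recovers the spec
  back <- read_site(d1)
  expect_equal(vapply(back$pages, `[[`, character(1), "path"),
               vapply(site$pages, `[[`, character(1), "path"))
  expect_identical(site_graph(back), site_graph(site))

  # re-parsing the emitted HTML recovers the declared adjacency, in order
  for (p in site$pages) {
    if (!identical(p$behavior, "ok")) next
    html <- paste(readLines(file.path(d1,
      if (p$path == "/") "index.html" else paste0(gsub("/", "__", sub("^/", "", p$path)), ".html")),
      warn = FALSE), collapse = "\n")
    doc <- xml2::read_html(html)
    hrefs <- xml2::xml_attr(xml2::xml_find_all(doc, "//a[@href]"), "href")
    internal <- hrefs[startsWith(hrefs, "/")]
    expect_equal(internal, p$link_paths, info = p$path)
  }

  # backends can serve straight from the materialized directory
  b <- fixture_backends(d1)
  pg <- fetch_page("https://health.demo.edu/services", b$fetcher)
  expect_equal(pg$status, "ok")
})

test_that("restructuring renames paths but preserves content and graph shape", {
  site <- demo_site()
  paths <- vapply(site$pages, `[[`, character(1), "path")
  rename <- stats::setNames(paste0("/r", seq_along(paths)), paths)
  moved <- restructure_site(site, rename)

  expect_setequal(vapply(moved$pages, `[[`, character(1), "path"), unname(rename))
  # same number of edges, isomorphic under the rename map
  g0 <- site_graph(site); g1 <- site_graph(moved)
  expect_equal(nrow(g0), nrow(g1))
  expect_equal(unname(rename[g0$from]), g1$from)
  expect_equal(unname(rename[g0$to]), g1$to)
  # content and headers untouched
  expect_equal(lapply(moved$pages, `[[`, "body_sentences") |> unname(),
               lapply(site$pages, `[[`, "body_sentences") |> unname())
  expect_equal(vapply(moved$pages, `[[`, character(1), "last_modified") |> unname(),
               vapply(site$pages, `[[`, character(1), "last_modified") |> unname())

  # identity rename returns an equal spec
  ident <- restructure_site(site, stats::setNames(paths, paths))
  expect_equal(ident, site)

  expect_error(restructure_site(site, c("/" = "/x", "/services" = "/x")),
               class = "webiq_invalid_spec")
  expect_error(restructure_site(site, c("/nonexistent" = "/x")),
               class = "webiq_invalid_spec")
})

test_that("the fixture search backend finds exactly the keyword-bearing pages", {
  topic <- larc_topic()
  for (seed in 1:15) {
    site <- random_case(seed)
    b <- fixture_backends(site)
    hits <- site_search(build_topic_query(topic, site$domain), b$search_backend)
    hit_paths <- sub("^https://[^/]+", "", hits)
    hit_paths[hit_paths == ""] <- "/"
    expect_setequal(hit_paths, oracle_keyword_paths(site, topic))
  }
})

test_that("fixture fetcher honors behaviors: redirects, stalls, errors, headers", {
  site <- demo_site()
  b <- fixture_backends(site)
  # redirect chain reported through final_url and the resolver
  expect_equal(b$redirect_resolver("https://health.demo.edu/old"),
               "https://health.demo.edu/new/home")
  expect_null(b$redirect_resolver("https://health.demo.edu/services"))
  # stall vs generous timeout
  ok <- b$fetcher("https://health.demo.edu/slow", 300)
  expect_equal(ok$status, "ok")
  to <- b$fetcher("https://health.demo.edu/slow", 1)
  expect_equal(to$status, "timeout")
  # Last-Modified surfaced only when declared
  home <- b$fetcher("https://health.demo.edu/", 30)
  expect_equal(home$last_modified, "Wed, 21 Oct 2015 07:28:00 GMT")
  svc <- b$fetcher("https://health.demo.edu/services", 30)
  expect_true(is.na(svc$last_modified))
})
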
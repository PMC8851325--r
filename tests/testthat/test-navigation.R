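# Navigation metric: breadth-first minimum-click distance over live links.

test_that("a home page that is itself a target scores zero clicks", {
  site <- chain_site(3)
  b <- fixture_backends(site)
  home <- site_home_url(site)
  nav <- navigation(home, target_urls = home, fetcher = b$fetcher)
  expect_equal(nav$clicks, 0L)
  expect_equal(nav$trace, home)
  expect_equal(nav$status, "ok")
})

test_that("a target just beyond the level cap returns -1 with an empty trace", {
  site <- chain_site(11)   # home + 11 pages; target at depth 11
  b <- fixture_backends(site)
  q <- build_topic_query(larc_topic(), site$domain)
  targets <- site_search(q, b$search_backend)
  expect_equal(targets, "https://chain.example.edu/p11")
  nav <- navigation(site_home_url(site), targets, b$fetcher, level_cap = 10)
  expect_equal(nav$clicks, -1L)
  expect_length(nav$trace, 0)
})

test_that("a target exactly at the level cap is still found", {
  site <- chain_site(10)
  b <- fixture_backends(site)
  nav <- navigation(site_home_url(site), "https://chain.example.edu/p10",
                    b$fetcher, level_cap = 10)
  expect_equal(nav$clicks, 10L)
  expect_length(nav$trace, 11)
  expect_equal(nav$trace[1], site_home_url(site))
  expect_equal(nav$trace[11], "https://chain.example.edu/p10")
})

test_that("the trace is a hyperlink path from home to the first target", {
  site <- demo_site()
  b <- fixture_backends(site)
  nav <- navigation(site_home_url(site), "https://health.demo.edu/services",
                    b$fetcher)
  expect_equal(nav$clicks, 1L)
  expect_equal(nav$trace, c("https://health.demo.edu/",
                            "https://health.demo.edu/services"))
  # consecutive trace URLs are linked on the earlier page
  for (i in seq_len(length(nav$trace) - 1)) {
    pg <- fetch_page(nav$trace[i], b$fetcher)
    links <- html_to_links <- xml2::xml_attr(
      xml2::xml_find_all(xml2::read_html(pg$html), "//a[@href]"), "href")
    abs <- vapply(links, function(h) xml2::url_absolute(h, pg$final_url),
                  character(1), USE.NAMES = FALSE)
    expect_true(normalize_url(nav$trace[i + 1]) %in% normalize_url(abs))
  }
})

test_that("cyclic sites terminate and off-domain links are never followed", {
  site <- site_spec("cyc.example.edu", list(
    page_spec("/", body_sentences = "Home.", link_paths = c("/a", "/b"),
              external_links = "https://outside.example.org/trap"),
    page_spec("/a", body_sentences = "Page a.", link_paths = c("/", "/b")),
    page_spec("/b", body_sentences = "Page b about the IUD.", link_paths = "/")))
  b <- fixture_backends(site)
  nav <- navigation(site_home_url(site), "https://cyc.example.edu/b", b$fetcher)
  expect_equal(nav$clicks, 1L)
  expect_false(any(grepl("outside", nav$trace)))
  # unreachable target on a cyclic site ends with -1, not an infinite loop
  lonely <- site_spec("cyc2.example.edu", list(
    page_spec("/", body_sentences = "Home.", link_paths = "/a"),
    page_spec("/a", body_sentences = "Page a.", link_paths = "/"),
    page_spec("/island", body_sentences = "Unlinked island with an IUD note.")))
  lb <- fixture_backends(lonely)
  nav2 <- navigation(site_home_url(lonely), "https://cyc2.example.edu/island",
                     lb$fetcher)
  expect_equal(nav2$clicks, -1L)
  expect_length(nav2$trace, 0)
})

test_that("an unfetchable home page is flagged distinctly", {
  site <- site_spec("down.example.edu", list(
    page_spec("/", behavior = "http_error"),
    page_spec("/a", body_sentences = "Page a about the IUD.")))
  b <- fixture_backends(site)
  nav <- navigation(site_home_url(site), "https://down.example.edu/a", b$fetcher)
  expect_equal(nav$clicks, -1L)
  expect_equal(nav$status, "home_unfetchable")
})

test_that("BFS clicks equal the shortest-path oracle on seeded random sites", {
  skip_if_not_installed("igraph")
  topic <- larc_topic()
  for (seed in 1:30) {
    site <- random_case(seed)
    b <- fixture_backends(site)
    q <- build_topic_query(topic, site$domain)
    targets <- site_search(q, b$search_backend)
    nav <- navigation(site_home_url(site), targets, b$fetcher, level_cap = 10)
    expect_equal(nav$clicks, oracle_navigation(site, topic, level_cap = 10),
                 info = paste("seed", seed))
    if (nav$clicks >= 0) {
      expect_length(nav$trace, nav$clicks + 1)
      expect_equal(nav$trace[1], site_home_url(site))
      expect_true(normalize_url(nav$trace[length(nav$trace)]) %in%
                    normalize_url(targets))
    } else {
      expect_length(nav$trace, 0)
    }
  }
})
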
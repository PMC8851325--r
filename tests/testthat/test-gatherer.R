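# Phase-2 gathering: queries, site search, fetching, sentence extraction,
# consolidation.

test_that("topic queries collapse case-fold duplicate keywords to one disjunct", {
  q <- build_topic_query(topic_spec("COVID", c("Corona", "coronavirus", "COVID")),
                         "health.sfsu.edu")
  expect_s3_class(q, "webiq_query")
  expect_length(q$keywords, 3)
  expect_equal(q$restrict_host, "health.sfsu.edu")

  dup <- topic_spec("t", c("IUD", "iud", "Implant"))
  expect_equal(dup$keywords, c("IUD", "Implant"))
  expect_length(build_topic_query(topic_spec("one", "condom"), "x.edu")$keywords, 1)
})

test_that("fixture site search returns exactly the keyword-bearing pages", {
  site <- demo_site()
  b <- fixture_backends(site)
  q <- build_topic_query(larc_topic(), site$domain)
  hits <- site_search(q, b$search_backend)
  expect_setequal(hits, c("https://health.demo.edu/",
                          "https://health.demo.edu/services",
                          "https://health.demo.edu/slow"))
  # no page carries these keywords
  none <- build_topic_query(topic_spec("none", "zymurgy"), site$domain)
  expect_length(site_search(none, b$search_backend), 0)
})

test_that("site search drops URLs outside the restriction host", {
  q <- build_topic_query(larc_topic(), "health.demo.edu")
  backend <- function(query) c("https://health.demo.edu/a",
                               "https://sub.health.demo.edu/b",
                               "https://evil.example.com/c")
  expect_equal(site_search(q, backend),
               c("https://health.demo.edu/a", "https://sub.health.demo.edu/b"))
})

test_that("fetch_page encodes outcomes in status instead of raising", {
  b <- fixture_backends(demo_site())
  ok <- fetch_page("https://health.demo.edu/services", b$fetcher)
  expect_equal(ok$status, "ok")
  expect_true(grepl("contraceptive implant", ok$html))

  stalled <- fetch_page("https://health.demo.edu/slow", b$fetcher,
                        timeout_seconds = 1)
  expect_equal(stalled$status, "timeout")
  expect_true(is.na(stalled$html))

  dead <- fetch_page("https://health.demo.edu/dead", b$fetcher)
  expect_equal(dead$status, "http_error")
  missing <- fetch_page("https://health.demo.edu/nope", b$fetcher)
  expect_equal(missing$status, "http_error")

  redirected <- fetch_page("https://health.demo.edu/old", b$fetcher)
  expect_equal(redirected$status, "ok")
  expect_equal(redirected$final_url, "https://health.demo.edu/new/home")
})

test_that("html_to_sentences keeps visible prose and drops boilerplate", {
  expect_equal(html_to_sentences("<p>A red dog. A blue cat.</p>"),
               c("A red dog.", "A blue cat."))
  html <- "<html><head><script>var x = 'Secret script text.';</script></head>
           <body><nav><a href='/x'>Menu item.</a></nav>
           <p>Visible sentence one.</p><p>Visible sentence two.</p></body></html>"
  out <- html_to_sentences(html)
  expect_equal(out, c("Visible sentence one.", "Visible sentence two."))
  expect_false(any(grepl("Secret", out)))
  expect_length(html_to_sentences(""), 0)
})

test_that("a rendered fixture page parses back to its manifest sentences", {
  site <- demo_site()
  b <- fixture_backends(site)
  pg <- fetch_page("https://health.demo.edu/services", b$fetcher)
  expect_equal(html_to_sentences(pg$html), site$pages[["/services"]]$body_sentences)
})

test_that("the sentence splitter respects abbreviations", {
  out <- split_sentences("Dr. Smith sees students daily. Visits are free.")
  expect_equal(out, c("Dr. Smith sees students daily.", "Visits are free."))
})

test_that("context extraction returns the window union around anchors", {
  topic <- topic_spec("t", "IUD")
  sentences <- sprintf("Filler sentence number %d.", 1:12)
  sentences[7] <- "The IUD is discussed here."   # 0-based index 6
  out <- extract_keyword_context(sentences, topic, window = 5)
  expect_equal(out$index, 1:11)
  expect_equal(sum(out$is_anchor), 1)

  # no anchors -> empty
  expect_equal(nrow(extract_keyword_context(sprintf("Filler %d.", 1:4), topic)), 0)

  # overlapping windows contribute each sentence once
  s10 <- sprintf("Filler sentence number %d.", 1:10)
  s10[3] <- "An IUD mention."   # index 2
  s10[5] <- "Another IUD mention."  # index 4
  out2 <- extract_keyword_context(s10, topic, window = 5)
  expect_equal(out2$index, 0:9)
  expect_equal(anyDuplicated(out2$index), 0)
})

test_that("window zero yields exactly the anchor sentences", {
  topic <- topic_spec("t", "IUD")
  for (seed in 1:10) {
    site <- random_case(seed)
    sentences <- unlist(lapply(site$pages, `[[`, "body_sentences"))
    out <- extract_keyword_context(sentences, topic, window = 0)
    expect_equal(out$text,
                 unname(sentences[text_has_any_keyword(sentences, "IUD")]))
    expect_true(all(out$is_anchor))
  }
})

test_that("context extraction output is an order-preserving subset containing all anchors", {
  topic <- larc_topic()
  for (seed in 1:15) {
    site <- random_case(seed)
    sentences <- unlist(lapply(site$pages, `[[`, "body_sentences"))
    for (w in c(0, 2, 5)) {
      out <- extract_keyword_context(sentences, topic, window = w)
      expect_true(all(out$text %in% sentences))
      expect_false(is.unsorted(out$index))
      anchors <- which(text_has_any_keyword(sentences, topic$keywords)) - 1L
      expect_true(all(anchors %in% out$index))
      # brute-force union of index windows
      expected_idx <- sort(unique(unlist(lapply(anchors, function(a) {
        seq(max(0, a - w), min(length(sentences) - 1, a + w))
      }))))
      expect_equal(out$index, as.integer(expected_idx))
    }
  }
})

test_that("consolidation removes duplicate sentences and is idempotent", {
  topic <- topic_spec("t", "IUD")
  shared <- "This disclaimer mentions the IUD policy."
  p1 <- extract_keyword_context(c(shared, "Unique line one about care."), topic,
                                window = 5, source_url = "https://x.edu/a")
  p2 <- extract_keyword_context(c(shared, "Unique line two about visits."), topic,
                                window = 5, source_url = "https://x.edu/b")
  cc <- consolidate(list(p1, p2), c("https://x.edu/a", "https://x.edu/b"))
  expect_equal(sum(cc$sentences$text == shared), 1)
  expect_equal(nrow(cc$sentences), 3)
  expect_true(all(cc$sentences$source_url %in% cc$source_urls))

  again <- consolidate(cc)
  expect_equal(again$sentences, cc$sentences)

  empty <- consolidate(list())
  expect_equal(nrow(empty$sentences), 0)
})

test_that("dedup normalization folds case, whitespace, and terminal punctuation", {
  topic <- topic_spec("t", "IUD")
  a <- extract_keyword_context("The IUD  is Safe to use.", topic, window = 0,
                               source_url = "u1")
  b <- extract_keyword_context("the iud is safe to use", topic, window = 0,
                               source_url = "u2")
  cc <- consolidate(list(a, b))
  expect_equal(nrow(cc$sentences), 1)
  expect_equal(cc$sentences$source_url, "u1")  # first occurrence wins
})
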
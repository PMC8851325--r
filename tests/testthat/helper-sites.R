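# Fixture-site builders shared across test files.

larc_topic <- function() {
  topic_spec("LARC", c("IUD", "intrauterine device", "contraceptive implant",
                       "contraceptive shot", "Depo Provera"))
}

# A linear chain home -> /p1 -> ... -> /p<depth>, with a keyword sentence
# only on the deepest page.
chain_site <- function(depth, keyword = "IUD", domain = "chain.example.edu") {
  pages <- list(page_spec("/", body_sentences = "Welcome to the health center.",
                          link_paths = "/p1"))
  for (i in seq_len(depth)) {
    body <- if (i == depth) {
      sprintf("Ask the clinic staff about the %s at your next visit.", keyword)
    } else {
      sprintf("This is hallway page number %d of the site.", i)
    }
    links <- if (i < depth) sprintf("/p%d", i + 1) else character(0)
    pages[[length(pages) + 1]] <- page_spec(sprintf("/p%d", i),
                                            body_sentences = body,
                                            link_paths = links)
  }
  site_spec(domain, pages)
}

# A compact hand-built site exercising most behaviors: keyword pages,
# redirects, a stalling page, a 404, headers present and absent.
demo_site <- function(domain = "health.demo.edu") {
  site_spec(domain, list(
    page_spec("/",
              body_sentences = c("Welcome to the student health center.",
                                 "We can tell you about the IUD and other methods."),
              link_paths = c("/services", "/old", "/dead"),
              external_links = "https://www.example.org/outside",
              last_modified = "Wed, 21 Oct 2015 07:28:00 GMT"),
    page_spec("/services",
              body_sentences = c("The clinic offers many services.",
                                 "A contraceptive implant can be placed here.",
                                 "Walk-in hours run on weekday mornings."),
              link_paths = c("/", "/slow")),
    page_spec("/old", behavior = "redirect:/new/home"),
    page_spec("/new/home",
              body_sentences = "This is the relocated page about the campus pharmacy.",
              link_paths = "/"),
    page_spec("/slow",
              body_sentences = "Ask about Depo Provera at the front desk.",
              behavior = "stall", stall_seconds = 120),
    page_spec("/dead", behavior = "http_error")))
}

# Report rows with the timing-log attribute and rownames stripped, for
# value-only comparisons.
strip_report <- function(report) {
  df <- as.data.frame(report)
  attr(df, "log") <- NULL
  rownames(df) <- NULL
  df
}

# Seeded random site parameterization used by the oracle-equivalence suites.
random_case <- function(seed) {
  n_pages <- 5 + (seed * 7) %% 46             # 5..50
  link_prob <- 0.05 + ((seed * 13) %% 36) / 100  # 0.05..0.40
  frac <- ((seed * 3) %% 6) / 10              # 0, 0.1, ..., 0.5
  random_site(seed, n_pages = n_pages, link_prob = link_prob,
              topic = larc_topic(), keyword_page_fraction = frac)
}
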
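# webiq

Quantitative quality metrics for web-based health information, aimed at
university **student health center (SHC) websites**.

SHC websites are the first point of contact between students and campus
health services, yet no governing body reviews the health information they
publish. `webiq` lets public-health researchers and college health
administrators audit that information at scale: given a list of
universities and one or more health topics (each a set of keywords), it
locates each SHC website, gathers the keyword-anchored text from it, and
scores that text with eight information-quality metrics. Everything is
pluggable and fully runnable offline against synthetic fixture websites,
which also makes longitudinal monitoring reproducible and testable.

## The pipeline

1. **Locate** — the query *"\<university name\> student health center"* is
   sent to a search backend; the first `.edu` host among the top 3 results
   is accepted (otherwise the SHC is declared not found), redirects are
   resolved, and leaf paths such as `/contacts`, `/appointments`,
   `/location` are stripped to get the canonical home URL.
2. **Gather** — a site-restricted disjunctive keyword query selects
   candidate pages; each page's visible text is segmented into sentences;
   every *anchor* sentence (one containing a keyword) is kept with 5
   sentences of context on each side; per-page extracts are consolidated
   with duplicate sentences removed.
3. **Score** — eight metrics over the consolidated content:

| Metric | Definition |
|---|---|
| FRE | `206.835 − 1.015·(W/S) − 84.6·(Y/W)` (words W, sentences S, syllables Y); higher = easier |
| FKGL | `0.39·(W/S) + 11.8·(Y/W) − 15.59`, a US grade level |
| Prevalence | cumulative keyword frequency in the gathered text |
| Coverage | % of distinct keywords found at least once (0–100) |
| Objectivity | `1 − subjectivity` from a weighted-lexicon sentiment analyzer |
| Polarity | signed sentiment in [−1, 1] from the same analyzer |
| Navigation | minimum clicks from the SHC home page to a keyword page, by breadth-first search over the site's own links (−1 if unreachable within 10 levels) |
| Timeliness | per-page `Last-Modified` timestamp, `−1` when the header is absent |

An optional ninth value, **similarity**, is the cosine of term-frequency
vectors between the gathered text and an expert-written "ideal" reference
document.

## Worked example

Fixture sites stand in for live universities, so this runs with no network:

```r
library(webiq)

topic <- topic_spec("LARC", c("IUD", "intrauterine device", "contraceptive implant"))
site <- site_spec("health.alpha.edu", list(
  page_spec("/",
            body_sentences = c("Welcome to the student health center.",
                               "Our clinic is open on weekdays."),
            link_paths = c("/services", "/hours"),
            last_modified = "Wed, 21 Oct 2015 07:28:00 GMT"),
  page_spec("/services",
            body_sentences = c("A contraceptive implant can be placed by appointment.",
                               "We can tell you about the IUD and other methods.",
                               "Bring your campus identification card."),
            link_paths = "/"),
  page_spec("/hours",
            body_sentences = "Walk-in hours run from nine until noon.",
            link_paths = "/")))

cfg <- run_config(
  universities = "Alpha University",
  topics = topic,
  backend_provider = fixture_provider(list("Alpha University" = site)),
  reference_docs = list(
    LARC = "The IUD and the contraceptive implant are long acting reversible contraceptive methods."))
report <- run_pipeline(cfg)
dplyr::glimpse(report)
#> $ university_name <chr> "Alpha University"
#> $ topic           <chr> "LARC"
#> $ status          <chr> "ok"
#> $ fre             <dbl> 59.27942
#> $ fkgl            <dbl> 6.895652
#> $ prevalence      <int> 2
#> $ coverage_pct    <dbl> 66.66667
#> $ objectivity     <dbl> 1
#> $ polarity        <dbl> 0
#> $ nav_clicks      <int> 1
#> $ nav_trace       <chr> "https://health.alpha.edu/|https://health.alpha.edu/se…
#> $ n_pages         <int> 1
#> $ timeliness      <chr> "https://health.alpha.edu/services=-1"
#> $ similarity      <dbl> 0.4
```

Reading the row: only `/services` matched the keywords (`n_pages = 1`); it
mentions 2 of the 3 keywords (`coverage_pct = 66.7`) twice in total
(`prevalence = 2`); the text reads at roughly a 7th-grade level
(`fkgl = 6.9`), is neutral and fully objective (`polarity = 0`,
`objectivity = 1`); the page is one click from the home page
(`nav_clicks = 1`, with the click trace in `nav_trace`); it is served
without a `Last-Modified` header (`-1` sentinel); and its term-frequency
direction has cosine 0.4 to the reference sentence. `timing_report(report)`
breaks the run's wall time into network versus compute phases, and
`ggplot2::autoplot(report)` charts the metrics.

A shell entry point with the same behavior lives at `inst/cli/webiq.R`
(`--universities`, `--topics`, `--backend fixture`, `--fixture-manifest`,
`--out`, ...), and `generate_site()` materializes any fixture to disk as
HTML plus a `manifest.json` that oracle tests treat as ground truth.

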
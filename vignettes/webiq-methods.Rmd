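---
title: "Methods: quantifying web health-information quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying web health-information quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(webiq)
```

## The problem

University student health center (SHC) websites are an authoritative health
information source for young adults, but the information they publish is
not reviewed by any central body. `webiq` turns "how good is the health
information on this site?" into a reproducible computation: locate the SHC
site, gather the text that concerns a stated health topic, and score that
text on readability, topical coverage, sentiment, navigability, freshness,
and relevance. This vignette explains the models behind each step, the
tunable parameters and their defaults, and the design decisions taken where
more than one reasonable choice existed.

## Locating the SHC site

SHC web addresses follow no convention (`hcs.calpoly.edu`,
`www.csub.edu/healthcenter`, `www.cpp.edu/~health`, ...), so location goes
through a web search for *"\<university name\> student health center"*.
Only the top 3 ranked results are examined, in order, and the first whose
host ends in `.edu` wins; otherwise the SHC is recorded as not found.
Two readings deserve note:

* *`.edu` is a host-suffix test*, not a substring test anywhere in the URL.
  This matches the intent (US institutional domains) and is directly
  testable; `edu.example.com` does not qualify.
* *The raw result URL is judged.* A non-`.edu` result that would redirect
  to a `.edu` host does not qualify; resolving redirects before the test
  would make the outcome depend on fetch-time state, which hurts
  reproducibility.

The accepted URL is then canonicalized: redirects are followed (hop cap 10,
a longer chain is reported as a loop error), query strings and fragments
are dropped, and one trailing path segment from the configurable strip list
`{contacts, appointments, location}` is removed — search engines often rank
those leaf pages above the SHC home itself. Stripping at most one exact
segment per call keeps the operation conservative and idempotent.

## Gathering topical text

A topic is a keyword set. One matching rule is shared by every
keyword-sensitive operation (site search, anchor detection, prevalence,
coverage): case-insensitive, whole-token, with multi-word keywords matched
as contiguous phrases and whitespace/hyphen treated as interchangeable.
Whole-token matching is essential with medical abbreviations — `IUD` must
not match inside `Liudmila`, and `IUDs` is deliberately not a match for
`IUD` (stemming is out of scope and would have to be justified per topic
vocabulary).

Candidate pages come from a site-restricted disjunctive query answered by a
pluggable search backend. Each page's visible text (scripts, styles, and
`nav`/`header`/`footer` boilerplate removed) is segmented into sentences by
a punctuation-based splitter with a small abbreviation list; fixture
manifests carry their sentence lists explicitly, so tests are not hostage
to segmentation ambiguity. Every sentence containing a keyword is an
*anchor*; the extract is the union of ±`window` sentences around each
anchor (default 5, truncated at page boundaries — context windows do not
leak across pages). Per-page extracts are concatenated in page order and
deduplicated on normalized text (case-folded, internal whitespace
collapsed, terminal punctuation stripped), keeping the first occurrence;
consolidation is idempotent.

Fetching never throws: a page's outcome is encoded in its status
(`ok` / `timeout` / `http_error`) so one dead page cannot abort a batch.
Defaults are a 30 s timeout with 1 retry; unresponsive sites are the
dominant cause of outlier runtimes in live batches, which is why the
timeout is a first-class, per-run parameter.

## The metrics

**Readability.** Flesch Reading Ease and Flesch–Kincaid Grade Level with
the standard coefficients,
`FRE = 206.835 − 1.015 (W/S) − 84.6 (Y/W)` and
`FKGL = 0.39 (W/S) + 11.8 (Y/W) − 15.59`.
Words are letter/digit runs (internal apostrophes/hyphens kept), sentences
are the consolidated records, and syllables come from a deterministic
heuristic: count vowel groups (`[aeiouy]+`), then correct silent endings —
a trailing silent *e* after a consonant (`care`, `device`) but not in
consonant-*le* (`table`); silent *-es* after most consonants (`makes`) but
not after sibilants/velars where the vowel is sounded (`classes`,
`services`); silent *-ed* except after *t*/*d* (`used` vs `needed`). The
counter is validated against a 50-word dictionary fixture and must agree on
at least 48; miscounts on rare words (e.g. `diabetes`) are an
accepted cost of determinism and zero dependencies.

**Prevalence and coverage.** Prevalence is the cumulative keyword frequency
in the gathered text — a raw count, deliberately not normalized by text
length, since the quantity of relevant material is itself the signal.
Coverage is the percentage (0–100) of distinct keywords found at least
once. Overlapping keywords (`IUD`, `hormonal IUD`) each count
independently.

**Sentiment.** A weighted-lexicon analyzer in the pattern/TextBlob family:
each lexicon entry carries polarity in [−1, 1], subjectivity in [0, 1], and
an intensity multiplier. The document score is the mean over matched words,
with an intensifier immediately before a scored word multiplying that
word's scores instead of being scored itself, and a negator within the two
preceding tokens flipping and damping polarity by −0.5. Objectivity is
exactly `1 − subjectivity`. The shipped lexicon
(`inst/extdata/sentiment_lexicon.csv`, swappable via the `lexicon`
argument) is a compact curation of about a hundred common evaluative words
with conventional pattern-family weights; its conformance anchor is the
three published reference sentences that score 0.7, 0, and −0.39 (asserted
in the test suite and the acceptance script). Text with no lexicon match —
including empty text — scores polarity 0, subjectivity 0 by convention. A
compact lexicon reads neutral-but-evaluative rare words as neutral; for
institutional health prose, which is overwhelmingly neutral, this
under-coverage biases polarity toward 0 rather than flipping signs.

**Navigation.** Minimum clicks from the home page to the nearest
keyword-bearing page, by breadth-first search over hyperlinks the crawler
actually fetches (not a site map). Choices that matter:

* *Level cap semantics*: nodes at level 10 are still examined; −1 is
  returned when a level-11 node is popped, so reported clicks lie in
  {−1, 0..10}.
* *Visited set*: keyed on the normalized URL (scheme and host lower-cased,
  fragment and query dropped, trailing slash normalized). The first BFS
  visit to a node is a shortest one, so the set cannot change the reported
  minimum, but it prevents exponential re-enqueueing on cyclic sites.
* *Domain scope*: a link is followed only when its host equals (or is a
  subdomain of) the home host — the strictest testable reading of "within
  the SHC web domain".
* *Tie-breaks*: links are enqueued in document order, so among equally
  near targets the one reached through earlier links wins; the clicks
  value is unaffected.
* An unfetchable home page is reported as −1 with a distinct
  `home_unfetchable` status, so "site down" is distinguishable from
  "content absent".

**Timeliness.** The parsed `Last-Modified` header per keyword-bearing page
(all three HTTP date formats accepted, parsed under the C locale), with a
literal `−1` sentinel when the header is missing or malformed — absence of
evidence about freshness is reported as such, never as an epoch.

**Similarity.** Cosine between raw term-frequency vectors of the gathered
text and an expert reference document, over case-folded word tokens with no
stop-word removal or weighting — the minimal deterministic vectorization,
documented as swappable. It is symmetric and invariant under duplication of
a whole document (direction-preserving scaling), which the tests assert.

Empty gathered content yields explicit markers (`status = "no_content"`,
`NA` scores) rather than zeros for readability and sentiment, so "nothing
found" is never confused with "neutral, easy text".

## Synthetic fixture sites

`site_spec()`/`page_spec()` describe a site as data: domain, pages with
ordered body sentences, hyperlinks in document order, optional
`Last-Modified` headers, and per-page behavior (`ok`, `stall`,
`http_error`, `redirect:<path>`). `generate_site()` materializes HTML plus
a `manifest.json` byte-identically; `random_site(seed, ...)` generates
reproducible sites (same seed, same spec) with keyword sentences injected
into a chosen fraction of pages and filler drawn from a bank of neutral
health-services sentences worded to avoid the sentiment lexicon, so fixture
sentiment is deterministic. `restructure_site()` renames paths bijectively
while preserving content and graph shape, emulating the directory
reorganizations real SHC sites undergo; the pipeline's metric values must
be identical before and after, except for URL strings in traces and
timeliness keys — the invariance the test suite asserts.

The fixture *backends* answer the same contracts as live ones: the fetcher
serves pages per their declared behavior directly from the manifest — a
`stall` page times out whenever its declared stall time exceeds the fetch
timeout, redirect chains are followed with the same 10-hop cap, and
headers are emitted as declared. Serving from the manifest rather than
through a local socket keeps the fixtures deterministic and free of
event-loop coupling in a single-threaded session; the contract surface
exercised (statuses, final URLs, headers, timeouts) is identical, which is
what the pipeline sees. What fixtures do *not* emulate: JavaScript-rendered
content, cookies and authentication, real network jitter, and the
adversarial messiness of production HTML. Passing fixture tests therefore
demonstrates the correctness of the algorithms on well-formed inputs, not
robustness to every real-world page.

## Problem sizes and numerical conventions

The oracle-equivalence suites run 100 seeded random sites of 5–50 pages
with link densities 0.05–0.4 and keyword fractions 0–0.5 — large enough to
hit empty, sparse, cyclic, and unreachable-target regimes while keeping the
whole suite comfortably fast. Navigation is checked against an independent
igraph shortest-path computation on the manifest graph; prevalence and
coverage against a fixed-substring scanning oracle written with different
primitives than the package matcher. Readability expectations are
hand-evaluated from hand-counted words/sentences/syllables and asserted to
4 decimals. End-to-end determinism is asserted as bit-identical report
CSVs across reruns, the precondition for longitudinal monitoring.

## Limitations

* Metrics are only as good as the keyword list; a biased or incomplete
  vocabulary biases every downstream number.
* Text embedded in images and PDFs is invisible to the gatherer.
* US-English assumptions throughout (`.edu` rule, Flesch–Kincaid,
  the sentiment lexicon).
* The syllable counter and sentence splitter are deterministic heuristics;
  both are validated on fixtures but will err on unusual words and
  unconventional punctuation.
* Live search backends (commercial APIs) are injected by the user; the
  package ships only the contract and the offline fixture implementation,
  plus a libcurl-based live fetcher.
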
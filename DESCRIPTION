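Package: dreamgraphs
Title: Speech Graph Analysis of Dream Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts free-text dream reports into directed lemma multigraphs
    and computes their structural attributes (nodes, edges, parallel edges,
    loop counts, largest strongly connected component, degree, density,
    diameter, clustering, average shortest path, betweenness centrality and
    average neighbor degree). Per-dreamer "average graphs" are formed for each
    dream condition, screened with a median-absolute-deviation outlier rule,
    and compared across conditions with weighted linear models (log dream-count
    weights, type II F tests, pairwise contrasts and per-condition interaction
    slopes). Also builds sentence-adjacency word co-occurrence networks and
    ships a seeded synthetic dream-corpus generator with controllable narrative
    recurrence for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    car,
    emmeans,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
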
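Package: fctopo
Title: Graph-Theoretic Topology Analysis of Functional Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted functional-connectivity graphs from regional BOLD
    time series and characterizes their topology across dementia syndromes:
    motion scrubbing with a minimum-duration inclusion rule, cost-based
    thresholding with small-worldness and connectedness validity criteria,
    cost-integrated degree centrality and nodal efficiency, two-stage Louvain
    consensus community detection (subject co-classification and group
    allegiance matrices), within-module degree and participation coefficient
    against group-level partitions, adjusted-Rand-index partition similarity
    with subgroup resampling, and covariate-adjusted group contrasts and
    brain-behavior correlations. Includes a synthetic-cohort generator with
    planted community structure and group-specific network lesions so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    pracma,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
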
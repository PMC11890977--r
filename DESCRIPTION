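Package: sfconn
Title: Structure-Function Coupling Analysis of Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary structural and functional brain networks from
    streamline-count matrices and regional BOLD time series, computes a
    graph-topology battery (global and nodal efficiency, clustering,
    characteristic path length, small-worldness against degree-preserving
    null models) across a sparsity grid with area-under-curve summaries,
    quantifies per-node structure-function coupling as the Spearman rank
    correlation of non-zero connectivity profiles, and performs
    covariate-adjusted two-group inference with permutation-based
    family-wise error control plus partial correlations between coupling
    and cognitive scores. Includes a seeded generator of coupled synthetic
    structural/functional cohorts with planted group effects for
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
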
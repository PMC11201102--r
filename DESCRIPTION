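Package: mmagc
Title: Meta-Analytic Multi-Omics Gene Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene clustering that integrates multi-omics measurements from
    multiple independent studies. Per-study gene-to-gene similarity is
    quantified by the first canonical correlation (CC), the maximum omics
    correlation (MOC) or the maximum same-omics correlation (MSOC) between
    two genes' sample-by-omics profiles. Study-level correlation vectors are
    pooled with a fixed-effects generalized least squares estimator using
    the Olkin-Siotani covariance of sample correlations (full or diagonal
    error covariance), and the pooled matrix is clustered with a modified
    weighted correlation network analysis: soft-threshold power selection
    (traditional scale-free criterion or a connectivity-inflection rule),
    topological overlap, average-linkage hierarchical clustering and
    minimum-cluster-size pruning. Includes a block-correlation multivariate
    normal simulator and an adjusted-Rand-index benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), cluster, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
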
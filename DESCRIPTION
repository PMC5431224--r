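Package: toxflow
Title: Gene Set Discovery, Clustering and Compound Ranking for
    Toxicogenomics Expression Data
Version: 0.1.0
Authors@R:
    person("toxflow", "maintainers", email = "toxflow@example.org",
           role = c("aut", "cre"))
Description: A headless analysis environment for dose- and time-course
    toxicogenomics microarray data. Builds group-wise log2 fold-change
    tables against matched vehicle controls (mean-then-log2 convention),
    discovers gene sets through column filters and statistical test
    columns (Welch's t, Mann-Whitney U), performs agglomerative
    hierarchical clustering with dendrogram-cutoff partitioning,
    hypergeometric gene-set enrichment against GMT collections, compound
    ranking by consistent up- or down-regulation of a query gene set, and
    cross-species ortholog aggregation (median of per-group averages).
    Includes a synthetic data generator that emulates compound x dose x
    time designs with matched controls and planted truth, plus file
    readers/writers and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
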
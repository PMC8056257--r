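Package: pleiocfdr
Title: Pleiotropy-Informed Conditional FDR Analysis of Paired GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for leveraging pleiotropy between two correlated traits to
    boost discovery in genome-wide association studies from summary statistics
    alone. Implements harmonization of two summary-statistic tables on common
    SNPs, MAF-aware linkage-disequilibrium pruning, pleiotropic-enrichment
    stratified Q-Q curves, the per-SNP empirical conditional false discovery
    rate (cFDR) in both conditioning directions, the conjunction ccFDR,
    LD-block novelty classification against a known-association catalog,
    interval-based gene mapping, and rank-based expression validation
    statistics. A fully seeded synthetic-data generator produces paired
    summary statistics with known null/specific/pleiotropic structure, LD
    panels, catalogs and expression matrices so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
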
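Package: seldrift
Title: Monitoring Selection and Drift in Pedigreed Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for monitoring the footprint of selection in closed,
    pedigreed livestock populations with overlapping generations. Estimates
    effective population size from the rate of pedigree inbreeding, builds a
    pure-drift null distribution for allele-frequency change by gene dropping
    founder alleles through the observed pedigree, runs single-SNP mixed-model
    association scans against a VanRaden genomic relationship matrix with
    variance components fixed from a REML null fit, and relates observed
    allele-frequency trajectories to association results. Includes a
    quantitative-genetics breeding-population simulator (index truncation
    selection over pleiotropic QTL, overlapping generations) so the whole
    chain can be exercised and calibrated without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
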
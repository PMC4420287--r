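Package: panet
Title: Active-Subnetwork Pathway Analysis for Differential Proteomics
Version: 0.1.0
Authors@R:
    person("CSF Proteomics", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Group-wise differential-abundance statistics for spot or protein
    intensity tables (fold changes, Welch t-tests, coefficient-of-variation
    quality control, pairwise ANOVA with Bonferroni correction) feeding an
    active-subnetwork search over a protein-protein interaction network
    (p-value to z-score aggregation with Monte-Carlo size calibration and a
    simulated-annealing module search), followed by two-sided hypergeometric
    pathway enrichment with Bonferroni correction, overlap-limited
    multi-module reporting, and a label-shuffling randomization control.
    Includes a synthetic-study generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
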
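Package: fuccitrace
Title: Cell-Cycle Phase Quantification from PIP/FUCCI Reporter Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("fuccitrace", "developers", email = "fuccitrace@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of dual-colour cell-cycle reporter
    (PIP-degron mVenus with either a constitutive H2A-mScarlet or a
    geminin-mCherry partner) time-lapse movies of epithelial monolayers:
    synthetic movie and trace simulation with lineage ground truth,
    nucleus segmentation with a pluggable detector, gap-free
    linear-assignment tracking, full-cycle track selection by duration
    and mitotic-spike rules, G1/S and S/G2 transition calling from
    fluorescence traces, snapshot phase classification, and the
    downstream statistics (normality-gated two-group tests, phase
    regressions, effect size and a-priori sample size).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
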
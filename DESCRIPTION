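Package: corddecon
Title: Reference-Based Cell-Type Deconvolution of Cord Blood DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reference-based deconvolution of umbilical cord blood
    DNA methylation profiles. Implements constrained-projection (CP/QP)
    estimation of cell-type proportions from beta values, projection-based
    quality control of sorted reference samples with a purity cutoff and
    reclassification rule, combination of reference datasets by probe
    intersection, two leukocyte-DMR library selection strategies (automatic
    top-N differential methylation and an IDOL-style iterative optimizer
    scored against known mixture proportions), and a validation panel
    (per-cell-type R-squared, RMSE, absolute errors, Bland-Altman agreement,
    leave-one-out reference comparison). A synthetic-methylome generator with
    planted cell-type-specific differentially methylated probes, contaminated
    sorted samples and Dirichlet mixtures provides ground truth for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
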
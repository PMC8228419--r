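Package: mrwald
Title: Two-Sample Summary-Level Mendelian Randomization with Wald Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample summary-level Mendelian randomization from GWAS
    summary statistics: allele harmonization onto a shared effect-allele
    orientation, genome-wide-significance instrument selection with
    per-locus pruning, per-variant Wald ratio estimates with delta-method
    standard errors, fixed-effects inverse-variance-weighted pooling with
    Cochran's Q heterogeneity, standard-deviation rescaling of the exposure,
    odds-ratio conversion for binary outcomes, and a confounder screen
    against a local trait-association table. Includes a generator of
    synthetic two-sample GWAS summary statistics with known causal effect,
    configurable instrument strength, allele frequencies, sample sizes and
    pleiotropy, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    yaml,
    optparse
Config/testthat/edition: 3
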
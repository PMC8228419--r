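# In-code fixtures shared across the suite.

# minimal valid summary-stats data.frame builder
make_stats <- function(rsid, ea, oa, beta, se,
                       eaf = NA_real_, pvalue = NULL, n = NA_real_) {
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
             trait = "trait", unit = "unit", stringsAsFactors = FALSE)
}

write_stats_file <- function(df, path = tempfile(fileext = ".tsv"), sep = "\t") {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, na = "NA")
  path
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "mrwald")
  stopifnot(nzchar(path))
  path
}

# random harmonized instrument sets for property-style tests
random_instruments <- function(j) {
  data.frame(
    rsid = sprintf("rs%03d", seq_len(j)),
    beta_exposure = runif(j, 0.02, 0.2) * sample(c(-1, 1), j, replace = TRUE),
    se_exposure = runif(j, 0.001, 0.02),
    beta_outcome = rnorm(j, 0, 0.05),
    se_outcome = runif(j, 0.001, 0.05),
    stringsAsFactors = FALSE
  )
}
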
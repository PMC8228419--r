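# Synthetic two-sample GWAS summary statistics with known ground truth.
#
# Summary statistics are simulated directly: per-variant standard errors
# are computed analytically from allele frequency, sample size and trait
# variance, and the observed betas are drawn normally around their true
# values. This matches the two-sample summary-level scope exactly (and is
# orders of magnitude faster than simulating genotypes), at the price of
# only partially representing weak-instrument and winner's-curse phenomena,
# which arise from selection on the observed exposure scan.

#' Configuration for the two-sample summary-statistics generator
#'
#' Defaults emulate the study conditions of a three-variant instrument for
#' a log-transformed serum metabolite (exposure GWAS n = 7781, log-scale
#' SD 0.25, per-allele effects 0.04-0.08) tested against a heel-ultrasound
#' bone-density outcome in a large biobank (n = 426,824, variance 0.0132
#' g^2/cm^4, i.e. SD ~0.115 g/cm^2) or, for the binary case, a fracture
#' outcome with 53,184 cases and 373,611 controls.
#'
#' @param n_snps number of instruments J.
#' @param theta true causal effect, outcome units per exposure unit.
#' @param gamma_range interval for per-variant exposure effects, drawn
#'   uniformly (uniform rather than normal so the instrument-strength
#'   bounds are explicit).
#' @param eaf_range interval for allele frequencies, strictly inside (0, 1).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param exposure_variance,outcome_variance phenotypic variances; the
#'   outcome variance is used only for a continuous outcome.
#' @param binary_outcome simulate a case-control outcome on the log-odds
#'   scale; standard errors then use the standard approximation
#'   `1 / sqrt(2 p (1-p) n phi (1-phi))` with case fraction `phi`.
#' @param n_cases,n_controls case-control split (binary outcome only;
#'   overrides `n_outcome` with their sum).
#' @param pleiotropy_mean,pleiotropy_sd distribution of per-variant direct
#'   effects on the outcome (0, 0 = exclusion restriction holds).
#' @param palindromic_fraction expected fraction of variants assigned an
#'   A/T or C/G allele pair.
#' @param allele_swap_fraction expected fraction of outcome records emitted
#'   with effect/other alleles swapped (beta negated, frequency flipped) to
#'   exercise harmonization.
#' @param seed integer RNG seed; fixed seed implies bit-identical output.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 3,
                              theta = 0.28,
                              gamma_range = c(0.04, 0.08),
                              eaf_range = c(0.1, 0.9),
                              n_exposure = 7781,
                              n_outcome = 426824,
                              exposure_variance = 0.0625,
                              outcome_variance = 0.0132,
                              binary_outcome = FALSE,
                              n_cases = 53184,
                              n_controls = 373611,
                              pleiotropy_mean = 0,
                              pleiotropy_sd = 0,
                              palindromic_fraction = 1 / 3,
                              allele_swap_fraction = 0,
                              seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps), theta = theta,
              gamma_range = gamma_range, eaf_range = eaf_range,
              n_exposure = n_exposure, n_outcome = n_outcome,
              exposure_variance = exposure_variance,
              outcome_variance = outcome_variance,
              binary_outcome = isTRUE(binary_outcome),
              n_cases = n_cases, n_controls = n_controls,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              palindromic_fraction = palindromic_fraction,
              allele_swap_fraction = allele_swap_fraction,
              seed = as.integer(seed))
  if (cfg$binary_outcome) cfg$n_outcome <- cfg$n_cases + cfg$n_controls

  with(cfg, {
    if (n_snps < 1L) mr_input_error("n_snps must be >= 1")
    if (length(gamma_range) != 2L || diff(gamma_range) < 0) {
      mr_input_error("gamma_range must be an ordered interval")
    }
    if (length(eaf_range) != 2L || eaf_range[1] <= 0 || eaf_range[2] >= 1 ||
        diff(eaf_range) < 0) {
      mr_input_error("eaf_range must be an ordered interval strictly inside (0, 1)")
    }
    if (n_exposure <= 1 || n_outcome <= 1) mr_input_error("sample sizes must exceed 1")
    if (exposure_variance <= 0 || outcome_variance <= 0) {
      mr_input_error("trait variances must be positive")
    }
    if (pleiotropy_sd < 0) mr_input_error("pleiotropy_sd must be >= 0")
    for (f in c(palindromic_fraction, allele_swap_fraction)) {
      if (f < 0 || f > 1) mr_input_error("fractions must lie in [0, 1]")
    }
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate two-sample GWAS summary statistics with known causal effect
#'
#' Linear structural model: variant j with allele frequency `p_j` has true
#' exposure effect `gamma_j` (uniform on `gamma_range`) and true outcome
#' effect `theta * gamma_j + alpha_j`, where the direct (pleiotropic)
#' effect `alpha_j` is normal with the configured mean and SD. Observed
#' betas are drawn normally around the true effects with the analytic
#' standard errors `se = sqrt(trait_variance / (2 p (1-p) n))` (for a
#' binary outcome, the log-odds approximation
#' `1 / sqrt(2 p (1-p) n phi (1-phi))`). P-values are two-sided normal.
#'
#' The RNG stream is seeded once from `config$seed`; sub-draws occur in a
#' fixed documented order (frequencies, gamma, alpha, beta_exposure,
#' beta_outcome, allele assignment, allele swaps), so output is
#' bit-reproducible for a fixed config.
#'
#' @param config a [simulation_config()].
#' @return a list with `exposure` and `outcome` (summary-statistics
#'   data.frames as consumed by [harmonize()]) and `truth` (list carrying
#'   `theta`, `gamma`, `alpha`, `eaf`, `swapped`, `seed`, and the config).
#' @examples
#' sim <- simulate_two_sample(simulation_config(n_snps = 3, seed = 7))
#' h <- harmonize(sim$exposure, sim$outcome)
#' ivw_pool(wald_ratio(h))
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  J <- config$n_snps

  # documented draw order
  p <- stats::runif(J, config$eaf_range[1], config$eaf_range[2])
  gamma <- stats::runif(J, config$gamma_range[1], config$gamma_range[2])
  alpha <- if (config$pleiotropy_sd > 0) {
    stats::rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd)
  } else rep(config$pleiotropy_mean, J)

  se_x <- sqrt(config$exposure_variance / (2 * p * (1 - p) * config$n_exposure))
  beta_x <- stats::rnorm(J, gamma, se_x)

  if (config$binary_outcome) {
    phi <- config$n_cases / config$n_outcome
    se_y <- 1 / sqrt(2 * p * (1 - p) * config$n_outcome * phi * (1 - phi))
  } else {
    se_y <- sqrt(config$outcome_variance / (2 * p * (1 - p) * config$n_outcome))
  }
  beta_y <- stats::rnorm(J, config$theta * gamma + alpha, se_y)

  # allele assignment: palindromic pairs A/T or C/G, others a transversion-
  # free mix, then optional swaps on the outcome emission
  pal <- stats::runif(J) < config$palindromic_fraction
  pal_pairs <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)
  oth_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                      ncol = 2, byrow = TRUE)
  pick_pal <- sample.int(2L, J, replace = TRUE)
  pick_oth <- sample.int(4L, J, replace = TRUE)
  ea <- ifelse(pal, pal_pairs[pick_pal, 1], oth_pairs[pick_oth, 1])
  oa <- ifelse(pal, pal_pairs[pick_pal, 2], oth_pairs[pick_oth, 2])
  swapped <- stats::runif(J) < config$allele_swap_fraction

  rsid <- sprintf("rs_sim_%04d", seq_len(J))
  pval <- function(b, s) 2 * stats::pnorm(-abs(b / s))

  exposure <- data.frame(
    rsid = rsid, effect_allele = ea, other_allele = oa, eaf = p,
    beta = beta_x, se = se_x, pvalue = pval(beta_x, se_x),
    n = config$n_exposure, trait = "exposure", unit = "exposure units",
    stringsAsFactors = FALSE
  )
  outcome <- data.frame(
    rsid = rsid,
    effect_allele = ifelse(swapped, oa, ea),
    other_allele = ifelse(swapped, ea, oa),
    eaf = ifelse(swapped, 1 - p, p),
    beta = ifelse(swapped, -beta_y, beta_y),
    se = se_y, pvalue = pval(beta_y, se_y),
    n = config$n_outcome,
    trait = "outcome",
    unit = if (config$binary_outcome) "log-odds" else "outcome units",
    stringsAsFactors = FALSE
  )
  class(exposure) <- class(outcome) <- c("summary_stats", "data.frame")

  list(exposure = exposure, outcome = outcome,
       truth = list(theta = config$theta, gamma = gamma, alpha = alpha,
                    eaf = p, se_exposure = se_x, se_outcome = se_y,
                    swapped = swapped, seed = config$seed, config = config))
}

#' Write a simulation truth record
#'
#' Key-value plain text alongside the emitted summary-statistics tables:
#' the causal effect, per-variant exposure and direct effects, and the seed.
#'
#' @param truth the `truth` element returned by [simulate_two_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = ",")
  lines <- c(
    sprintf("theta=%s", num(truth$theta)),
    sprintf("gamma=%s", num(truth$gamma)),
    sprintf("alpha=%s", num(truth$alpha)),
    sprintf("eaf=%s", num(truth$eaf)),
    sprintf("swapped=%s", paste(truth$swapped, collapse = ",")),
    sprintf("seed=%d", truth$seed)
  )
  writeLines(lines, path)
  invisible(path)
}
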
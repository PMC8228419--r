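# Statistical core: per-variant Wald ratios, fixed-effects inverse-variance
# weighted pooling with Cochran's Q, SD rescaling and odds-ratio conversion.

# conventional 95% normal multiplier used throughout summary-level MR
Z95 <- 1.96

#' Per-variant Wald ratio estimates
#'
#' For each harmonized instrument the causal effect of the exposure on the
#' outcome is estimated as the ratio of the variant-outcome to the
#' variant-exposure association, `beta_outcome / beta_exposure`, with a
#' delta-method standard error:
#'
#' * first order (default): `se_outcome / |beta_exposure|` — the convention
#'   under which inverse-variance-weighted pooling equals weighted
#'   through-origin regression of outcome betas on exposure betas;
#' * second order: adds the uncertainty of the exposure beta,
#'   `sqrt(se_outcome^2 / beta_exposure^2 +
#'         beta_outcome^2 * se_exposure^2 / beta_exposure^4)`.
#'
#' 95% confidence bounds use the 1.96 normal quantile; p-values are
#' two-sided from the standard normal.
#'
#' @param instruments a `harmonized_data` data.frame (see [harmonize()]), or
#'   any data.frame with columns `rsid`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`.
#' @param se_order `"first"` or `"second"` order delta-method standard error.
#' @return a `data.frame` of class `wald_estimates` with columns `rsid`,
#'   `ratio`, `se`, `ci_low`, `ci_high`, `pvalue`.
#' @examples
#' h <- data.frame(rsid = "rs1", beta_exposure = 0.1, se_exposure = 0.01,
#'                 beta_outcome = 0.02, se_outcome = 0.005)
#' wald_ratio(h)                       # ratio 0.2, se 0.05
#' wald_ratio(h, se_order = "second")  # se ~0.05385
#' @export
wald_ratio <- function(instruments, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  req <- c("rsid", "beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing_cols <- setdiff(req, names(instruments))
  if (length(missing_cols) > 0L) {
    mr_input_error(sprintf("instruments lack column(s): %s",
                           paste(missing_cols, collapse = ", ")))
  }
  if (nrow(instruments) == 0L) mr_input_error("no instruments supplied")
  zero <- instruments$beta_exposure == 0
  if (any(zero)) {
    mr_input_error(sprintf("undefined Wald ratio: beta_exposure is 0 for %s",
                           paste(instruments$rsid[zero], collapse = ", ")))
  }
  if (any(instruments$se_exposure <= 0) || any(instruments$se_outcome <= 0)) {
    mr_input_error("standard errors must be > 0")
  }

  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome

  ratio <- by / bx
  se <- switch(se_order,
    first = sy / abs(bx),
    second = sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  )
  out <- data.frame(
    rsid = instruments$rsid,
    ratio = ratio,
    se = se,
    ci_low = ratio - Z95 * se,
    ci_high = ratio + Z95 * se,
    pvalue = 2 * stats::pnorm(-abs(ratio / se)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("wald_estimates", "data.frame")
  attr(out, "se_order") <- se_order
  attr(out, "per_sd") <- FALSE
  out
}

#' Inverse-variance-weighted pooling of Wald ratios
#'
#' Pools per-variant causal estimates with weights `w_j = 1 / se_j^2`:
#' the pooled estimate is `sum(w * ratio) / sum(w)` with standard error
#' `1 / sqrt(sum(w))` (fixed effects, assuming one common causal effect).
#' Heterogeneity is measured by Cochran's
#' `Q = sum(w * (ratio - pooled)^2)`, chi-square with `n_snps - 1` degrees
#' of freedom under homogeneity (undefined for a single variant).
#'
#' `model = "multiplicative"` additionally inflates the standard error by
#' `sqrt(Q / df)` when `Q/df > 1` (a multiplicative random-effects
#' sensitivity option; the default fixed-effects model is the primary
#' analysis).
#'
#' @param estimates a `wald_estimates` data.frame from [wald_ratio()], or
#'   any data.frame with columns `rsid`, `ratio`, `se`.
#' @param model `"fixed"` (default) or `"multiplicative"`.
#' @param scale `"linear"` for continuous outcomes, `"log_odds"` when the
#'   outcome betas were log odds ratios; recorded in the result and enforced
#'   by [to_odds_ratio()] and [relative_effect()].
#' @return an object of class `mr_result`: a list with `estimate`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`, `n_snps`, `q_stat`, `q_df`, `q_pvalue`
#'   (`NA` when `n_snps == 1`), `scale`, `per_sd`, `sd_used`, `model`,
#'   `snps`, and the per-variant weights (`weights`, normalized to sum 1).
#' @examples
#' est <- data.frame(rsid = c("a", "b"), ratio = c(0.2, 0.1), se = c(0.05, 0.1))
#' ivw_pool(est)  # estimate 0.18, se 1/sqrt(500), Q = 0.8
#' @export
ivw_pool <- function(estimates, model = c("fixed", "multiplicative"),
                     scale = c("linear", "log_odds")) {
  model <- match.arg(model)
  scale <- match.arg(scale)
  if (is.null(estimates) || nrow(estimates) == 0L) {
    mr_input_error("cannot pool an empty set of estimates")
  }
  if (any(estimates$se <= 0)) mr_input_error("all standard errors must be > 0")

  w <- 1 / estimates$se^2
  k <- nrow(estimates)
  estimate <- sum(w * estimates$ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  q_stat <- sum(w * (estimates$ratio - estimate)^2)
  q_df <- k - 1L
  q_pvalue <- if (q_df >= 1L) {
    stats::pchisq(q_stat, df = q_df, lower.tail = FALSE)
  } else NA_real_

  if (model == "multiplicative" && q_df >= 1L && q_stat / q_df > 1) {
    se <- se * sqrt(q_stat / q_df)
  }

  structure(list(
    estimate = estimate,
    se = se,
    ci_low = estimate - Z95 * se,
    ci_high = estimate + Z95 * se,
    pvalue = 2 * stats::pnorm(-abs(estimate / se)),
    n_snps = k,
    q_stat = q_stat,
    q_df = q_df,
    q_pvalue = q_pvalue,
    scale = scale,
    per_sd = FALSE,
    sd_used = NA_real_,
    model = model,
    snps = estimates$rsid,
    weights = w / sum(w)
  ), class = "mr_result")
}

#' Rescale an estimate per one SD of the exposure
#'
#' Multiplies the estimate, standard error and confidence bounds by the
#' exposure standard deviation, converting an effect per exposure unit
#' (e.g. per log-unit of a serum concentration) into an effect per
#' one-standard-deviation increment. The z-score, and hence the p-value,
#' is unchanged. Double application is an error.
#'
#' @param x an `mr_result` or `wald_estimates` object.
#' @param sd exposure standard deviation, on the same scale as the exposure
#'   betas (strictly positive).
#' @return the same type of object, rescaled, with the SD recorded.
#' @export
rescale_per_sd <- function(x, sd) UseMethod("rescale_per_sd")

#' @export
rescale_per_sd.mr_result <- function(x, sd) {
  check_sd(sd, x$per_sd)
  x$estimate <- x$estimate * sd
  x$se <- x$se * sd
  x$ci_low <- x$ci_low * sd
  x$ci_high <- x$ci_high * sd
  x$per_sd <- TRUE
  x$sd_used <- sd
  x
}

#' @export
rescale_per_sd.wald_estimates <- function(x, sd) {
  check_sd(sd, isTRUE(attr(x, "per_sd")))
  for (col in c("ratio", "se", "ci_low", "ci_high")) x[[col]] <- x[[col]] * sd
  attr(x, "per_sd") <- TRUE
  attr(x, "sd_used") <- sd
  x
}

check_sd <- function(sd, already) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd <= 0) {
    mr_input_error("sd must be a single positive number")
  }
  if (already) mr_state_error("per-SD rescaling already applied")
  invisible(TRUE)
}

#' Convert a log-odds MR result to an odds-ratio summary
#'
#' Exponentiates the pooled estimate and its additive confidence bounds.
#' Refuses to exponentiate a linear-scale estimate.
#'
#' @param result an `mr_result` with `scale == "log_odds"`.
#' @return a list of class `or_result`: `or`, `ci_low`, `ci_high`, `pvalue`.
#' @export
to_odds_ratio <- function(result) {
  stopifnot(inherits(result, "mr_result"))
  if (!identical(result$scale, "log_odds")) {
    mr_state_error("odds-ratio conversion requires a log-odds scale estimate")
  }
  structure(list(
    or = exp(result$estimate),
    ci_low = exp(result$ci_low),
    ci_high = exp(result$ci_high),
    pvalue = result$pvalue
  ), class = "or_result")
}

#' Effect size relative to a reference mean
#'
#' Expresses a linear-scale estimate as a percentage of a reference outcome
#' mean (e.g. a per-SD change in bone density relative to the population
#' mean density).
#'
#' @param result an `mr_result` with `scale == "linear"`.
#' @param reference_mean positive reference value in outcome units.
#' @return the relative effect in percent, `100 * estimate / reference_mean`.
#' @export
relative_effect <- function(result, reference_mean) {
  stopifnot(inherits(result, "mr_result"))
  if (!identical(result$scale, "linear")) {
    mr_state_error("relative effect is defined for linear-scale estimates only")
  }
  if (!is.numeric(reference_mean) || length(reference_mean) != 1L ||
      is.na(reference_mean) || reference_mean <= 0) {
    mr_input_error("reference_mean must be a single positive number")
  }
  100 * result$estimate / reference_mean
}

#' @export
print.mr_result <- function(x, digits = 3, ...) {
  cat(sprintf("Inverse-variance weighted MR (%s effects), %d variant(s)\n",
              x$model, x$n_snps))
  unit <- if (x$per_sd) sprintf(" per SD (sd = %g)", x$sd_used) else ""
  cat(sprintf("  estimate: %s (95%% CI %s, %s)%s, p = %s\n",
              format(x$estimate, digits = digits),
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits),
              unit,
              format.pval(x$pvalue, digits = digits)))
  if (!is.na(x$q_pvalue)) {
    cat(sprintf("  heterogeneity: Q = %s on %d df, p = %s\n",
                format(x$q_stat, digits = digits), x$q_df,
                format.pval(x$q_pvalue, digits = digits)))
  }
  if (identical(x$scale, "log_odds")) {
    cat(sprintf("  scale: log-odds (OR %s, 95%% CI %s, %s)\n",
                format(exp(x$estimate), digits = digits),
                format(exp(x$ci_low), digits = digits),
                format(exp(x$ci_high), digits = digits)))
  }
  invisible(x)
}

#' @export
print.or_result <- function(x, digits = 3, ...) {
  cat(sprintf("OR %s (95%% CI %s, %s), p = %s\n",
              format(x$or, digits = digits),
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits),
              format.pval(x$pvalue, digits = digits)))
  invisible(x)
}
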
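# Hand-derived oracle values are frozen in comments next to each assertion.

test_that("Wald ratio matches the hand-evaluated delta-method formulas", {
  h <- data.frame(rsid = "rs1", beta_exposure = 0.1, se_exposure = 0.01,
                  beta_outcome = 0.02, se_outcome = 0.005)
  w1 <- wald_ratio(h, se_order = "first")
  expect_equal(w1$ratio, 0.2, tolerance = 1e-12)
  expect_equal(w1$se, 0.05, tolerance = 1e-12)     # 0.005 / |0.1|
  expect_equal(w1$ci_low, 0.2 - 1.96 * 0.05, tolerance = 1e-12)
  expect_equal(w1$pvalue, 2 * pnorm(-4), tolerance = 1e-12)

  w2 <- wald_ratio(h, se_order = "second")
  # sqrt(0.005^2/0.1^2 + 0.02^2 * 0.01^2 / 0.1^4) = sqrt(0.0025 + 0.0004)
  expect_equal(w2$se, sqrt(0.0029), tolerance = 1e-12)
  expect_equal(sqrt(0.0029), 0.05385, tolerance = 1e-4)
  expect_gt(w2$se, w1$se)
})

test_that("null outcome beta gives ratio 0 with p = 1; zero exposure beta errors", {
  h <- data.frame(rsid = "rs1", beta_exposure = -0.07, se_exposure = 0.01,
                  beta_outcome = 0, se_outcome = 0.004)
  w <- wald_ratio(h)
  expect_equal(w$ratio, 0)
  expect_equal(w$pvalue, 1)
  h$beta_exposure <- 0
  expect_error(wald_ratio(h), "rs1", class = "mrwald_input_error")
})

test_that("fixed-effects IVW matches the hand-computed two-estimate pooling", {
  est <- data.frame(rsid = c("a", "b"), ratio = c(0.2, 0.1), se = c(0.05, 0.1))
  res <- ivw_pool(est)
  # weights 400 and 100: estimate (400*0.2 + 100*0.1)/500 = 0.18
  expect_equal(res$estimate, 0.18, tolerance = 1e-12)
  expect_equal(res$se, 1 / sqrt(500), tolerance = 1e-12)
  # Q = 400*(0.2-0.18)^2 + 100*(0.1-0.18)^2 = 0.16 + 0.64 = 0.8
  expect_equal(res$q_stat, 0.8, tolerance = 1e-12)
  expect_equal(res$q_df, 1L)
  expect_equal(res$q_pvalue, pchisq(0.8, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$ci_low, 0.18 - 1.96 / sqrt(500), tolerance = 1e-12)
  expect_equal(res$weights, c(0.8, 0.2), tolerance = 1e-12)
})

test_that("pooling a single estimate is the identity with undefined Q p-value", {
  est <- data.frame(rsid = "a", ratio = 0.3, se = 0.02)
  res <- ivw_pool(est)
  expect_equal(res$estimate, 0.3)
  expect_equal(res$se, 0.02)
  expect_equal(res$q_df, 0L)
  expect_true(is.na(res$q_pvalue))
  expect_error(ivw_pool(est[0, ]), class = "mrwald_input_error")
})

test_that("IVW pooling properties hold on random instrument sets", {
  set.seed(11)
  for (rep in 1:25) {
    inst <- random_instruments(sample(2:12, 1))
    w <- wald_ratio(inst)
    res <- ivw_pool(w)
    # pooled estimate within the per-SNP range; pooled se below the smallest
    expect_gte(res$estimate, min(w$ratio) - 1e-12)
    expect_lte(res$estimate, max(w$ratio) + 1e-12)
    expect_lte(res$se, min(w$se))
    # permutation invariance
    perm <- w[sample(nrow(w)), ]
    res_p <- ivw_pool(perm)
    expect_equal(res_p$estimate, res$estimate, tolerance = 1e-14)
    expect_equal(res_p$q_stat, res$q_stat, tolerance = 1e-12)
  }
})

test_that("IVW agrees with independent meta-analysis and regression oracles", {
  skip_if_not_installed("metafor")
  set.seed(7)
  inst <- random_instruments(8)
  w <- wald_ratio(inst)
  res <- ivw_pool(w)
  # oracle 1: fixed-effects meta-analysis
  m <- metafor::rma(yi = w$ratio, sei = w$se, method = "FE")
  expect_equal(res$estimate, as.numeric(m$beta), tolerance = 1e-10)
  expect_equal(res$se, m$se, tolerance = 1e-10)
  expect_equal(res$q_stat, m$QE, tolerance = 1e-10)
  # oracle 2: weighted through-origin regression of outcome on exposure betas
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = inst,
            weights = 1 / inst$se_outcome^2)
  expect_equal(res$estimate, unname(coef(fit)), tolerance = 1e-10)
})

test_that("multiplicative random-effects option only ever widens the interval", {
  set.seed(3)
  inst <- random_instruments(10)
  w <- wald_ratio(inst)
  fe <- ivw_pool(w, model = "fixed")
  re <- ivw_pool(w, model = "multiplicative")
  expect_equal(re$estimate, fe$estimate)
  expect_gte(re$se, fe$se)
})

test_that("per-SD rescaling scales location and spread but not evidence", {
  est <- data.frame(rsid = c("a", "b"), ratio = c(0.3, 0.26), se = c(0.05, 0.04))
  res <- ivw_pool(est)
  sc <- rescale_per_sd(res, 0.25)
  expect_equal(sc$estimate, res$estimate * 0.25, tolerance = 1e-12)
  expect_equal(sc$se, res$se * 0.25, tolerance = 1e-12)
  expect_equal(sc$ci_low, res$ci_low * 0.25, tolerance = 1e-12)
  expect_equal(sc$pvalue, res$pvalue, tolerance = 1e-15)  # z unchanged
  expect_true(sc$per_sd)
  expect_equal(sc$sd_used, 0.25)
  # 0.28 per log-unit at SD 0.25 is 0.07 per SD
  expect_equal(0.28 * 0.25, 0.07, tolerance = 1e-12)

  id <- rescale_per_sd(res, 1)
  expect_equal(id$estimate, res$estimate)
  expect_true(id$per_sd)

  expect_error(rescale_per_sd(sc, 0.25), class = "mrwald_state_error")
  expect_error(rescale_per_sd(res, -1), class = "mrwald_input_error")

  w <- wald_ratio(data.frame(rsid = "a", beta_exposure = 0.1, se_exposure = 0.01,
                             beta_outcome = 0.02, se_outcome = 0.005))
  ws <- rescale_per_sd(w, 0.25)
  expect_equal(ws$ratio, w$ratio * 0.25)
  expect_error(rescale_per_sd(ws, 0.25), class = "mrwald_state_error")
})

test_that("odds-ratio conversion exponentiates log-odds results and refuses linear", {
  est <- data.frame(rsid = "a", ratio = 0, se = 0.1)
  null <- to_odds_ratio(ivw_pool(est, scale = "log_odds"))
  expect_equal(null$or, 1.0)

  est2 <- data.frame(rsid = c("a", "b"), ratio = c(-0.04, -0.02), se = c(0.05, 0.07))
  res2 <- ivw_pool(est2, scale = "log_odds")
  or2 <- to_odds_ratio(res2)
  expect_equal(or2$or, exp(res2$estimate), tolerance = 1e-12)
  expect_equal(or2$ci_low, exp(res2$estimate - 1.96 * res2$se), tolerance = 1e-12)
  expect_equal(or2$pvalue, res2$pvalue)
  # fixture-style magnitudes: estimate -0.0305 (se 0.0366) maps to OR ~0.970
  hand <- ivw_pool(data.frame(rsid = "a", ratio = -0.0305, se = 0.0366),
                   scale = "log_odds")
  expect_equal(to_odds_ratio(hand)$or, exp(-0.0305), tolerance = 1e-12)
  expect_equal(round(to_odds_ratio(hand)$or, 3), 0.970)
  expect_equal(round(to_odds_ratio(hand)$ci_low, 3), round(exp(-0.0305 - 1.96 * 0.0366), 3))

  expect_error(to_odds_ratio(ivw_pool(est, scale = "linear")),
               class = "mrwald_state_error")
})

test_that("relative effect divides the estimate by a positive reference mean", {
  res <- ivw_pool(data.frame(rsid = "a", ratio = 0.07, se = 0.01))
  expect_equal(relative_effect(res, 0.51), 100 * 0.07 / 0.51, tolerance = 1e-12)
  expect_equal(relative_effect(res, 0.56), 12.5, tolerance = 1e-12)
  null <- ivw_pool(data.frame(rsid = "a", ratio = 0, se = 0.01))
  expect_equal(relative_effect(null, 0.51), 0)
  expect_error(relative_effect(res, 0), class = "mrwald_input_error")
  lo <- ivw_pool(data.frame(rsid = "a", ratio = 0.1, se = 0.01), scale = "log_odds")
  expect_error(relative_effect(lo, 0.5), class = "mrwald_state_error")
})

test_that("Cochran's Q is calibrated under homogeneity", {
  set.seed(101)
  n_rep <- 2000
  j <- 5
  rejected <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    se <- runif(j, 0.02, 0.1)
    ratios <- rnorm(j, mean = 0.2, sd = se)
    res <- ivw_pool(data.frame(rsid = as.character(seq_len(j)),
                               ratio = ratios, se = se))
    rejected[r] <- res$q_pvalue < 0.05
  }
  rate <- mean(rejected)
  # binomial 99.9% band around 0.05 at 2000 replicates: +/- 3.3 * 0.0049
  expect_gt(rate, 0.05 - 0.017)
  expect_lt(rate, 0.05 + 0.017)
})
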
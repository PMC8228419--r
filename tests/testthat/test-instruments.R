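test_that("selection applies a strict genome-wide significance cut", {
  cand <- make_stats(c("rs964184", "rs2108622", "rs11057830", "rsX"),
                     "A", "G",
                     beta = c(0.072, 0.048, 0.042, 0.01),
                     se = c(0.0105, 0.0075, 0.0073, 0.01),
                     pvalue = c(7.8e-12, 1.4e-10, 8.2e-9, 5e-8))
  sel <- select_instruments(cand, pvalue_threshold = 5e-8)
  expect_s3_class(sel, "instrument_set")
  expect_setequal(sel$members, c("rs964184", "rs2108622", "rs11057830"))
  expect_false("rsX" %in% sel$members)  # p exactly at the threshold is excluded
})

test_that("one-per-locus keeps the strongest candidate with deterministic ties", {
  cand <- make_stats(c("rs1", "rs2", "rs3", "rs4"), "A", "G",
                     beta = 0.05, se = c(0.01, 0.01, 0.02, 0.01),
                     pvalue = c(1e-9, 1e-10, 1e-11, 1e-11))
  sel <- select_instruments(cand, one_per_locus = TRUE,
                            locus = c("L1", "L1", "L2", "L2"))
  expect_setequal(sel$members, c("rs2", "rs4"))  # argmin p, then smaller se
  # lexicographic rsid breaks full ties
  cand2 <- make_stats(c("rsB", "rsA"), "A", "G", beta = 0.05,
                      se = 0.01, pvalue = 1e-9)
  sel2 <- select_instruments(cand2, one_per_locus = TRUE, locus = c("L", "L"))
  expect_equal(sel2$members, "rsA")
})

test_that("selection is a subset of input and monotone in the threshold", {
  set.seed(5)
  cand <- make_stats(sprintf("rs%02d", 1:30), "A", "G",
                     beta = rnorm(30, 0, 0.05), se = runif(30, 0.005, 0.02))
  for (thr in c(1e-10, 5e-8, 1e-4)) {
    sel <- select_instruments(cand, pvalue_threshold = thr)
    expect_true(all(sel$members %in% cand$rsid))
    expect_true(all(cand$pvalue[match(sel$members, cand$rsid)] < thr))
  }
  small <- select_instruments(cand, pvalue_threshold = 1e-8)$members
  large <- select_instruments(cand, pvalue_threshold = 1e-3)$members
  expect_true(all(small %in% large))
  expect_message(select_instruments(cand, pvalue_threshold = 1e-300), "empty")
})

test_that("variance explained matches 2p(1-p)b^2/V and its symmetries", {
  # eaf 0.5, beta 0.1, variance 0.0625: 2*0.25*0.01/0.0625 = 0.08
  expect_equal(variance_explained(0.1, 0.0625, eaf = 0.5), 0.08, tolerance = 1e-12)
  expect_equal(variance_explained(0, 0.0625, eaf = 0.3), 0)
  expect_equal(variance_explained(0.1, 1, eaf = 0.2),
               variance_explained(0.1, 1, eaf = 0.8), tolerance = 1e-15)
  expect_equal(variance_explained(0.1, 1, eaf = 0.2),
               variance_explained(-0.1, 1, eaf = 0.2), tolerance = 1e-15)
  df <- make_stats("rs1", "A", "G", beta = 0.1, se = 0.01, eaf = 0.5)
  expect_equal(variance_explained(df, 0.0625), 0.08)
  df$eaf <- NA
  expect_warning(r2 <- variance_explained(df, 0.0625), "frequency missing")
  expect_true(is.na(r2))
  expect_error(variance_explained(0.1, -1, eaf = 0.5), class = "mrwald_input_error")
})

test_that("F-statistic follows r2(n-k-1)/((1-r2)k) with validated domain", {
  # r2 1.7%, n = 7781, k = 3
  expect_equal(f_statistic(0.017, 7781, 3),
               0.017 * 7777 / (0.983 * 3), tolerance = 1e-12)
  expect_equal(f_statistic(0.017, 7781, 3), 44.8, tolerance = 0.01)
  expect_lt(f_statistic(1e-9, 1000, 2), 1e-5)  # vanishes with r2
  # linear in n - k - 1
  f1 <- f_statistic(0.02, 1005, 3)          # n - k - 1 = 1001
  f2 <- f_statistic(0.02, 2006, 3)          # n - k - 1 = 2002
  expect_equal(f2 / f1, 2, tolerance = 1e-12)
  expect_error(f_statistic(0, 100, 3), class = "mrwald_input_error")
  expect_error(f_statistic(0.5, 4, 3), class = "mrwald_input_error")
})

test_that("confounder screen flags only listed traits below the threshold", {
  snps <- c("rs964184", "rs2108622", "rs11057830")
  expect_message(none <- confounder_screen(snps, data.frame()), "empty")
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "caveat"), "empty lookup table")

  tab <- data.frame(
    rsid = c("rs964184", "rs2108622", "rs964184", "rs_other"),
    trait = c("Body Mass Index", "height", "triglycerides", "smoking"),
    pvalue = c(0.005, 0.02, 1e-20, 1e-5))
  flags <- confounder_screen(snps, tab)
  # case-insensitive match below 0.01; height at 0.02 not flagged;
  # unlisted trait ignored; non-instrument rsid ignored
  expect_equal(nrow(flags), 1L)
  expect_equal(flags$rsid, "rs964184")
  expect_equal(tolower(flags$trait), "body mass index")

  # flags monotone in the threshold
  lo <- confounder_screen(snps, tab, pvalue_threshold = 1e-4)
  hi <- confounder_screen(snps, tab, pvalue_threshold = 0.05)
  expect_true(all(paste(lo$rsid, lo$trait) %in% paste(hi$rsid, hi$trait)))
  expect_equal(nrow(hi), 2L)  # height now flagged too
})

test_that("trait tables read from disk feed the screen", {
  flags <- confounder_screen(c("rs964184", "rs2108622", "rs11057830"),
                             read_trait_table(extdata("synthetic_trait_associations.tsv")))
  expect_equal(nrow(flags), 0L)  # no listed confounder below 0.01
})
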
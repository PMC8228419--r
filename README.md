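# mrwald

Two-sample summary-level Mendelian randomization (MR) in R: Wald ratio
estimates per genetic variant, pooled by fixed-effects inverse-variance
weighting, with everything the analysis needs around the estimator —
allele harmonization, instrument selection and strength diagnostics,
per-SD rescaling, odds-ratio conversion, Cochran's Q heterogeneity, a
confounder screen, and a synthetic two-sample GWAS summary-statistics
generator with known ground truth.

## Who this is for

Genetic epidemiologists asking whether a circulating biomarker causally
affects a disease outcome when only *published GWAS summary statistics*
are available: per-variant effect sizes for the exposure from one study
and for the outcome from another, non-overlapping study. The motivating
use case is an analysis of a serum antioxidant (vitamin E's α-tocopherol
isoform) against heel-ultrasound bone mineral density (eBMD) and
fracture risk, instrumented by three genome-wide-significant variants.

## The statistic

For variant *j* with exposure association β̂ₓⱼ (SE σₓⱼ) and outcome
association β̂ᵧⱼ (SE σᵧⱼ), the Wald ratio and its delta-method SE are

    θ̂ⱼ = β̂ᵧⱼ / β̂ₓⱼ,   σⱼ = σᵧⱼ / |β̂ₓⱼ|          (first order)
                        σⱼ = √(σᵧⱼ²/β̂ₓⱼ² + β̂ᵧⱼ²σₓⱼ²/β̂ₓⱼ⁴)   (second order)

and the fixed-effects IVW pool, with wⱼ = 1/σⱼ²,

    θ̂ = Σ wⱼθ̂ⱼ / Σ wⱼ,   SE(θ̂) = (Σ wⱼ)^(-1/2),
    Q  = Σ wⱼ(θ̂ⱼ − θ̂)²  ~  χ²(J−1) under homogeneity.

With first-order SEs, θ̂ equals the slope of the weighted through-origin
regression of outcome betas on exposure betas — a property the test
suite verifies against `lm()` and `metafor` to 1e-10.

## Worked example

The package ships a **synthetic** three-variant instrument set
(`inst/extdata/synthetic_*.tsv`): per-SNP association tables constructed
to be consistent with the published summary results of the motivating
study, since the study's own appendix table is not redistributed here.
The exposure is the log-transformed serum concentration (SD 0.25
log-units); outcomes are eBMD (g/cm², n = 426,824) and any fracture
(53,184 cases / 373,611 controls, log-odds).

```r
library(mrwald)
extfile <- function(f) system.file("extdata", f, package = "mrwald")
ana <- run_mr_analysis(analysis_config(
  exposure_path = extfile("synthetic_alpha_tocopherol_exposure.tsv"),
  outcomes = list(
    list(name = "eBMD", path = extfile("synthetic_ebmd_outcome.tsv"),
         scale = "linear", reference_mean = 0.51),
    list(name = "fracture", path = extfile("synthetic_fracture_outcome.tsv"),
         scale = "log_odds")),
  sd = 0.25,
  confounder_table_path = extfile("synthetic_trait_associations.tsv")))
ana
```

prints

```
Two-sample summary-level MR analysis
instruments: 3 variant(s) at p < 5e-08

eBMD: 0.07 (0.05, 0.09) per SD increase in the exposure
eBMD: relative effect 13.7% of reference mean 0.51
eBMD: heterogeneity Q = 2.24 on 2 df (p = 0.33)
fracture: OR 0.97 (0.91, 1.05) per SD increase in the exposure
fracture: heterogeneity Q = 0.09 on 2 df (p = 0.96)

confounder screen: no instrument associated with a listed confounder
```

Read: a genetically predicted one-SD increase in the exposure raises
eBMD by 0.07 g/cm² (95% CI 0.05–0.09) — about 13.7% of the mean female
eBMD of 0.51 g/cm² — while the fracture odds ratio 0.97 (0.91–1.05) is
compatible with no effect. `ana$results$eBMD$forest` gives the
forest-plot-ready per-variant table:

```
        rsid   estimate      ci_low    ci_high weight_pct
1 rs11057830 0.03737679 -0.01045655 0.08521012   18.58572
2  rs2108622 0.08000000  0.04733333 0.11266667   39.85024
3   rs964184 0.07500000  0.04301389 0.10698611   41.56404
4        IVW 0.06999997  0.04937847 0.09062147         NA
```

Setting `output_dir` additionally writes `forest_<outcome>.tsv`,
`report.txt`, full-precision `results.json` and the confounder-screen
table. The same pipeline is scriptable via `exec/mrwald`
(`run`, `simulate`, `screen`, `forest` subcommands), and
`simulate_two_sample()` generates ground-truth datasets for method
checks — see the vignette (`vignettes/two-sample-mr.Rmd`) for the model,
the harmonization rules, the generator design, and the calibration
experiments.

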
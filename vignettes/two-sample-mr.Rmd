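---
title: "Two-sample summary-level Mendelian randomization with mrwald"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample summary-level Mendelian randomization with mrwald}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrwald)
```

## The model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for an exposure. Because alleles are assorted at random at
conception, a variant that raises the exposure is (under the instrumental
assumptions) independent of the confounders that plague observational
epidemiology, and any association it shows with the outcome must flow
through the exposure. In the *two-sample summary-level* design nothing
individual-level is needed: for each variant $j$ we take the published
per-allele association with the exposure, $\hat\beta_{Xj}$ (SE
$\sigma_{Xj}$), from one GWAS, and with the outcome, $\hat\beta_{Yj}$ (SE
$\sigma_{Yj}$), from a second, non-overlapping GWAS.

The per-variant causal estimate is the **Wald ratio**

$$\hat\theta_j = \frac{\hat\beta_{Yj}}{\hat\beta_{Xj}},$$

with a delta-method standard error of either first order,
$\sigma_j = \sigma_{Yj}/|\hat\beta_{Xj}|$, or second order,
$\sigma_j = \sqrt{\sigma_{Yj}^2/\hat\beta_{Xj}^2 +
\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4}$.
Ratios are pooled by **fixed-effects inverse-variance weighting** (IVW):
with $w_j = 1/\sigma_j^2$,

$$\hat\theta = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},
\qquad \mathrm{SE}(\hat\theta) = \Big(\sum_j w_j\Big)^{-1/2},$$

and heterogeneity between variants is measured by Cochran's
$Q = \sum_j w_j (\hat\theta_j - \hat\theta)^2$, chi-square with $J-1$
degrees of freedom when all variants estimate one common effect.

The instrumental assumptions matter more than the arithmetic: each
variant must be robustly associated with the exposure (relevance),
unconfounded with the outcome (independence), and affect the outcome only
through the exposure (exclusion restriction / no pleiotropy). The package
addresses relevance through the selection threshold and the
$r^2$/F-statistic diagnostics, and probes exclusion with the confounder
screen and Q; with very few instruments, pleiotropy-robust estimators
(MR-Egger, weighted median) are not identified and are deliberately not
provided.

## Harmonization

Exposure and outcome GWAS rarely report the same effect allele. Before
any ratio is computed, `harmonize()` re-expresses every outcome record on
the exposure's effect-allele orientation:

* identical allele pair: copy;
* swapped pair: negate the outcome beta, flip its allele frequency;
* palindromic pair (A/T or C/G): the letters are strand-ambiguous, so
  orientation is inferred from allele frequencies — and only when both
  frequencies fall outside the window
  (`eaf_ambiguity_threshold`, `1 - eaf_ambiguity_threshold`). The default
  threshold of 0.42 drops any palindromic variant whose frequency on
  either side sits within 0.08 of 0.5, where frequency comparison cannot
  distinguish strands reliably. Missing frequencies also drop the
  variant: strand is never guessed.

Every drop and flip is recorded (`harmonization_log()`), and the whole
operation is idempotent. Duplicated rsids are an error rather than a
first-wins, because IVW weights are per-variant.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `pvalue_threshold` | 5e-8 | — | genome-wide significance, strict `<` |
| `eaf_ambiguity_threshold` | 0.42 | allele frequency | palindromic disambiguation unreliable near 0.5 |
| `se_order` | `"first"` | — | matches the IVW/weighted-regression equivalence and the dominant convention; `"second"` adds exposure-side uncertainty |
| `sd` | — | exposure units | rescales the estimate to a per-SD effect; for a log-transformed serum metabolite with SD 0.25 log-units, an effect of 0.28 per log-unit becomes 0.07 per SD |
| `report_rounding` | 2 | decimals | presentation only; rounding is half-away-from-zero, computations are never rounded |
| `model` | `"fixed"` | — | fixed-effects IVW is the primary analysis; `"multiplicative"` inflates the SE by $\sqrt{Q/\mathrm{df}}$ when $Q/\mathrm{df}>1$ as a sensitivity option |

95% intervals use the conventional 1.96 normal multiplier (not a t
quantile), and p-values are two-sided normal, as is standard for
summary-level MR. A Wald ratio with `beta_exposure == 0` is an error, not
an epsilon-fudge. "Uncorrelated instruments" is operationalized as
one-per-locus-label pruning (smallest p per label, ties broken by smaller
SE then lexicographic rsid): the available annotation for published
instrument sets is a cytoband or gene-region label, not an LD matrix, and
no LD reference panel is consulted.

## A worked pipeline

The package ships a synthetic three-variant instrument set for a
log-transformed serum antioxidant (a vitamin E isoform) with two outcome
tables from a large biobank: heel-ultrasound estimated bone mineral
density (eBMD, g/cm², n = 426,824) and any-fracture case-control status
(53,184 cases / 373,611 controls, log-odds scale). The per-variant
association values are *synthetic*: they were constructed to be
consistent with the published summary results of the corresponding study
(the published appendix table is not redistributed here), so the pipeline
output below is a consistency demonstration, not an independent
re-derivation.

```{r pipeline}
extfile <- function(f) system.file("extdata", f, package = "mrwald")
ana <- run_mr_analysis(analysis_config(
  exposure_path = extfile("synthetic_alpha_tocopherol_exposure.tsv"),
  outcomes = list(
    list(name = "eBMD", path = extfile("synthetic_ebmd_outcome.tsv"),
         scale = "linear", reference_mean = 0.51),
    list(name = "fracture", path = extfile("synthetic_fracture_outcome.tsv"),
         scale = "log_odds")),
  sd = 0.25,  # SD of the exposure on the log scale
  confounder_table_path = extfile("synthetic_trait_associations.tsv")))
ana
ana$results$eBMD$forest
```

A genetically predicted one-SD increase in the exposure is associated
with 0.07 (0.05, 0.09) g/cm² higher eBMD — over 10% of the mean density
in either sex (0.51 women / 0.56 men) — while the fracture odds ratio of
0.97 (0.91, 1.05) is compatible with no effect. The instrument explains
about 1.7% of the exposure variance in a GWAS of 7,781, giving
`f_statistic(0.017, 7781, 3)` ≈ 44.8, comfortably above the conventional
weak-instrument rule of thumb of 10.

## The synthetic-data generator

`simulate_two_sample()` emulates the two-sample design under a linear
structural model with known causal effect $\theta$: variant $j$ has
frequency $p_j$, exposure effect $\gamma_j$ (uniform on `gamma_range`, so
instrument-strength bounds are explicit), and outcome effect
$\theta\gamma_j + \alpha_j$ with a pleiotropic direct effect $\alpha_j$.
Observed betas are drawn normally around the true effects with analytic
standard errors $\sigma = \sqrt{V/(2p(1-p)n)}$ (for a binary outcome the
log-odds approximation $1/\sqrt{2p(1-p)\,n\,\varphi(1-\varphi)}$ with
case fraction $\varphi$). Defaults mirror the worked example's study
conditions: 3 instruments, exposure GWAS n = 7,781 with log-scale
variance 0.0625, outcome n = 426,824 with variance 0.0132 (SD 0.115
g/cm², the midpoint of the sex-specific SDs 0.11 and 0.12), per-allele
effects 0.04–0.08, one in three variants palindromic.

Simulating summary statistics directly — rather than genotypes — matches
the summary-level scope, makes standard errors exact by construction, and
runs orders of magnitude faster; the price is that weak-instrument
selection effects (winner's curse: instruments chosen *because* their
observed betas are extreme) are only partially representable, because
`gamma_range` is specified rather than selected from a scan. The RNG is
seeded once and sub-draws occur in a fixed order (frequencies, $\gamma$,
$\alpha$, $\beta_X$, $\beta_Y$, alleles, swaps), so output is
bit-reproducible.

```{r simulate}
sim <- simulate_two_sample(simulation_config(n_snps = 10, theta = 0.28,
                                             seed = 42))
res <- ivw_pool(wald_ratio(harmonize(sim$exposure, sim$outcome)))
c(truth = sim$truth$theta, estimate = res$estimate)
```

## Calibration experiments, and what they do and do not show

The test suite runs two Monte-Carlo experiments (problem sizes chosen so
the whole suite completes in well under a minute per experiment):

* **Interval calibration and recovery** — 1,000 simulated datasets with
  J = 10 instruments, no pleiotropy, and $\theta = 0$: the mean IVW
  estimate is within Monte-Carlo error of the truth and the empirical
  95% CI coverage lands in [0.93, 0.97]. The null is the right place to
  test calibration in this design: conditional on the exposure betas,
  the first-order Wald interval is *exact* under $\theta = 0$. With a
  nonzero $\theta$ and an outcome GWAS ~55× larger than the exposure GWAS
  (the worked example's regime), the exposure-side noise dominates the
  ratio, the no-measurement-error assumption behind both delta SEs
  fails, and fixed-effects IVW visibly undercovers — a documented
  limitation of the estimator itself, not of the implementation, and the
  reason real analyses in this regime should read the F-statistic before
  the confidence interval. A separate consistency check confirms the
  estimate converges to a nonzero $\theta$ as sample sizes grow.
* **Heterogeneity calibration** — 2,000 homogeneous ratio sets: Cochran's
  Q rejects at the 0.05 chi-square cut at the nominal rate within
  binomial tolerance.

With directional pleiotropy (`pleiotropy_mean != 0`) the same seed grid
shows the expected bias of the expected sign, of magnitude roughly
$\bar\alpha/\bar\gamma$.

Because the generator draws independent variants with exact SEs and no
sample overlap, passing these experiments says nothing about LD between
instruments, overlapping GWAS samples, population stratification, or
misreported units in real summary files — all of which remain the
analyst's responsibility.

## Numerical and degenerate-input choices

* Reports round half-away-from-zero (so 0.065 prints as 0.07); the
  machine-readable `results.json` is always full precision, and rounded
  report lines are pure presentation of those numbers.
* Delimiters are auto-detected from the header line (tab beats comma);
  output is always tab-separated at 17 significant digits so write/read
  round-trips exactly.
* An empty instrument selection is a logged outcome, not an error; an
  empty confounder table yields an all-clear with an explicit caveat.
* Stage failures in the pipeline carry the stage name and variant
  context, and no output file is written unless the whole analysis
  succeeded; re-running an identical configuration reproduces
  byte-identical outputs.
* Indels and multi-character alleles are rejected on read (the design
  targets SNV instruments).

## Known limitations

No LD modelling, no live database queries (the confounder screen runs
against a local table the analyst supplies), no MR-Egger or
median/mode-based estimators (not identified with very few instruments),
and no correction for weak-instrument bias beyond reporting F. The
assumption that published outcome tables are already oriented to the
exposure-increasing allele is *not* made: everything passes through
`harmonize()`, but a table whose frequencies are wrong will silently
mis-resolve palindromic variants — frequency sanity checks upstream are
advised.
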
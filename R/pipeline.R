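# End-to-end orchestration: read exposure and outcome tables, select and
# harmonize instruments, estimate per-variant Wald ratios, pool by IVW,
# rescale per SD, convert to odds ratios for binary outcomes, screen
# confounders, and emit forest-ready tables plus a run report.

#' Analysis configuration
#'
#' Bundles and validates everything [run_mr_analysis()] needs. Each outcome
#' is a list with `name`, `path` and `scale` (`"linear"` or `"log_odds"`);
#' `reference_mean` per outcome is optional and enables the relative-effect
#' line in the report.
#'
#' @param exposure_path path to the exposure summary-statistics table.
#' @param outcomes list of outcome descriptors, each
#'   `list(name =, path =, scale =, reference_mean = NULL)`.
#' @param sd exposure standard deviation used for per-SD rescaling, on the
#'   scale of the exposure betas; strictly positive.
#' @param pvalue_threshold instrument significance cut (default 5e-8).
#' @param eaf_ambiguity_threshold palindromic ambiguity window bound passed
#'   to [harmonize()] (default 0.42).
#' @param se_order Wald-ratio standard-error order, `"first"` or `"second"`.
#' @param one_per_locus prune to one instrument per locus label when labels
#'   are present.
#' @param confounder_table_path optional path to a variant-trait table for
#'   [confounder_screen()].
#' @param confounder_traits confounder trait names; defaults to
#'   [default_confounders()].
#' @param output_dir optional directory for emitted files; when `NULL`,
#'   results are only returned.
#' @param report_rounding decimal places for the plain-text report
#'   (half-away-from-zero; default 2). Full-precision results are always
#'   emitted unrounded in the machine-readable file.
#' @param column_map optional column mapping applied to every input table.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(exposure_path,
                            outcomes,
                            sd = 1,
                            pvalue_threshold = 5e-8,
                            eaf_ambiguity_threshold = 0.42,
                            se_order = c("first", "second"),
                            one_per_locus = FALSE,
                            confounder_table_path = NULL,
                            confounder_traits = default_confounders(),
                            output_dir = NULL,
                            report_rounding = 2,
                            column_map = NULL) {
  se_order <- match.arg(se_order)
  if (!is.numeric(sd) || sd <= 0) mr_config_error("sd must be positive")
  if (!is.list(outcomes) || length(outcomes) == 0L) {
    mr_config_error("at least one outcome descriptor is required")
  }
  if (!is.null(names(outcomes)) && all(c("name", "path") %in% names(outcomes))) {
    outcomes <- list(outcomes)  # single descriptor passed bare
  }
  for (o in outcomes) {
    if (is.null(o$name) || is.null(o$path)) {
      mr_config_error("each outcome needs a name and a path")
    }
    if (!identical(o$scale %||% "linear", "linear") &&
        !identical(o$scale, "log_odds")) {
      mr_config_error(sprintf("outcome '%s': scale must be linear or log_odds", o$name))
    }
  }
  paths <- c(exposure_path, vapply(outcomes, `[[`, "", "path"))
  if (anyDuplicated(paths)) mr_config_error("input paths must be distinct")

  structure(list(
    exposure_path = exposure_path, outcomes = outcomes, sd = sd,
    pvalue_threshold = pvalue_threshold,
    eaf_ambiguity_threshold = eaf_ambiguity_threshold,
    se_order = se_order, one_per_locus = one_per_locus,
    confounder_table_path = confounder_table_path,
    confounder_traits = confounder_traits,
    output_dir = output_dir, report_rounding = report_rounding,
    column_map = column_map
  ), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; all paths are resolved
#' relative to the config file's directory.
#'
#' @param path path to a YAML config file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    mr_config_error("reading YAML configs requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  raw$exposure_path <- rel(raw$exposure_path)
  raw$outcomes <- lapply(raw$outcomes, function(o) { o$path <- rel(o$path); o })
  raw$confounder_table_path <- rel(raw$confounder_table_path)
  raw$output_dir <- rel(raw$output_dir)
  do.call(analysis_config, raw)
}

wrap_stage <- function(stage, context, expr) {
  tryCatch(expr, error = function(e) {
    mr_abort(sprintf("[%s%s] %s", stage,
                     if (nzchar(context)) paste0(": ", context) else "",
                     conditionMessage(e)),
             class = class(e)[1])
  })
}

#' Run the full two-sample MR analysis
#'
#' For each outcome: select instruments at the significance threshold,
#' harmonize onto the exposure's effect-allele orientation, compute Wald
#' ratios, pool them in a fixed-effects inverse-variance-weighted model,
#' rescale per one SD of the exposure, and — for log-odds outcomes —
#' convert to an odds ratio. When a confounder table is supplied, each
#' instrument is screened against the configured confounder traits. Every
#' dropped SNP and every harmonization decision is logged on the result.
#'
#' When `output_dir` is set, the function emits (only after the whole
#' analysis has succeeded, so no partial outputs are written):
#' forest-ready per-variant + pooled tables (`forest_<outcome>.tsv`), a
#' plain-text report with rounded headline lines (`report.txt`), a
#' machine-readable full-precision results file (`results.json`), and the
#' confounder-screen flags (`confounder_screen.tsv`) when a table was
#' supplied.
#'
#' @param config an [analysis_config()].
#' @return a list of class `mr_analysis`: `results` (per outcome: the
#'   per-SD `mr_result`, per-variant `wald_estimates`, forest table,
#'   odds-ratio summary for log-odds outcomes, harmonization log),
#'   `instruments` (the selected `instrument_set`), `screen` (confounder
#'   flags or `NULL`), `report` (character lines), and `config`.
#' @export
run_mr_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))

  exposure <- wrap_stage("read_exposure", config$exposure_path,
                         read_summary_stats(config$exposure_path,
                                            column_map = config$column_map))
  instruments <- wrap_stage("select_instruments", "",
    select_instruments(exposure, pvalue_threshold = config$pvalue_threshold,
                       one_per_locus = config$one_per_locus))
  if (length(instruments$members) == 0L) {
    mr_input_error("no instruments pass the significance threshold; nothing to analyse")
  }
  exposure_sel <- exposure[exposure$rsid %in% instruments$members, , drop = FALSE]

  results <- list()
  for (o in config$outcomes) {
    scale <- o$scale %||% "linear"
    outcome <- wrap_stage("read_outcome", o$path,
                          read_summary_stats(o$path, column_map = config$column_map))
    harm <- wrap_stage("harmonize", o$name,
      harmonize(exposure_sel, outcome,
                eaf_ambiguity_threshold = config$eaf_ambiguity_threshold))
    if (nrow(harm) == 0L) {
      mr_input_error(sprintf("[harmonize: %s] no instruments survive harmonization",
                             o$name))
    }
    per_snp <- wrap_stage("wald_ratio", o$name,
                          wald_ratio(harm, se_order = config$se_order))
    pooled <- wrap_stage("ivw_pool", o$name, ivw_pool(per_snp, scale = scale))
    per_snp_sd <- rescale_per_sd(per_snp, config$sd)
    pooled_sd <- rescale_per_sd(pooled, config$sd)
    orr <- if (identical(scale, "log_odds")) to_odds_ratio(pooled_sd) else NULL

    results[[o$name]] <- list(
      name = o$name, scale = scale,
      harmonized = harm,
      log = harmonization_log(harm),
      per_snp = per_snp_sd,
      pooled = pooled_sd,
      odds_ratio = orr,
      forest = forest_table(per_snp_sd, pooled_sd),
      reference_mean = o$reference_mean
    )
  }

  screen <- NULL
  if (!is.null(config$confounder_table_path)) {
    tab <- wrap_stage("read_confounder_table", config$confounder_table_path,
                      read_trait_table(config$confounder_table_path))
    screen <- confounder_screen(instruments$members, tab,
                                confounder_traits = config$confounder_traits)
  }

  report <- build_report(results, screen, config)
  analysis <- structure(list(results = results, instruments = instruments,
                             screen = screen, report = report, config = config),
                        class = "mr_analysis")
  if (!is.null(config$output_dir)) write_analysis(analysis, config$output_dir)
  analysis
}

#' Forest-ready table of per-variant and pooled estimates
#'
#' Per-variant rows ordered by rsid, followed by a final pooled `IVW` row;
#' each variant row carries its inverse-variance weight as a percentage
#' (weights sum to 100).
#'
#' @param per_snp a `wald_estimates` data.frame.
#' @param pooled the `mr_result` pooled from exactly those estimates.
#' @return data.frame with columns `rsid`, `estimate`, `ci_low`, `ci_high`,
#'   `weight_pct` (`NA` for the IVW row).
#' @export
forest_table <- function(per_snp, pooled) {
  stopifnot(inherits(pooled, "mr_result"))
  if (pooled$n_snps != nrow(per_snp) || !setequal(pooled$snps, per_snp$rsid)) {
    mr_state_error("pooled result does not match the per-variant estimate list")
  }
  w <- 1 / per_snp$se^2
  ord <- order(per_snp$rsid)
  out <- data.frame(
    rsid = c(per_snp$rsid[ord], "IVW"),
    estimate = c(per_snp$ratio[ord], pooled$estimate),
    ci_low = c(per_snp$ci_low[ord], pooled$ci_low),
    ci_high = c(per_snp$ci_high[ord], pooled$ci_high),
    weight_pct = c(100 * w[ord] / sum(w), NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

headline <- function(res, rounding) {
  p <- res$pooled
  if (identical(res$scale, "log_odds")) {
    o <- res$odds_ratio
    sprintf("%s: OR %s (%s, %s) per SD increase in the exposure",
            res$name, fmt_round(o$or, rounding),
            fmt_round(o$ci_low, rounding), fmt_round(o$ci_high, rounding))
  } else {
    sprintf("%s: %s (%s, %s) per SD increase in the exposure",
            res$name, fmt_round(p$estimate, rounding),
            fmt_round(p$ci_low, rounding), fmt_round(p$ci_high, rounding))
  }
}

build_report <- function(results, screen, config) {
  lines <- c("Two-sample summary-level MR analysis",
             sprintf("instruments: %d variant(s) at p < %g",
                     length(results[[1]]$per_snp$rsid), config$pvalue_threshold),
             "")
  for (res in results) {
    lines <- c(lines, headline(res, config$report_rounding))
    if (!is.null(res$reference_mean) && identical(res$scale, "linear")) {
      rel <- relative_effect(res$pooled, res$reference_mean)
      lines <- c(lines, sprintf(
        "%s: relative effect %s%% of reference mean %g",
        res$name, fmt_round(rel, 1), res$reference_mean))
    }
    if (!is.na(res$pooled$q_pvalue)) {
      lines <- c(lines, sprintf(
        "%s: heterogeneity Q = %s on %d df (p = %s)",
        res$name, fmt_round(res$pooled$q_stat, config$report_rounding),
        res$pooled$q_df, format.pval(res$pooled$q_pvalue, digits = 2)))
    }
    dropped <- res$log[res$log$action == "drop", , drop = FALSE]
    if (nrow(dropped) > 0L) {
      lines <- c(lines, sprintf("%s: dropped %s (%s)", res$name,
                                dropped$rsid, dropped$reason))
    }
  }
  if (!is.null(screen)) {
    lines <- c(lines, "",
               if (nrow(screen) == 0L) {
                 "confounder screen: no instrument associated with a listed confounder"
               } else {
                 sprintf("confounder screen: %s associated with %s (p = %g)",
                         screen$rsid, screen$trait, screen$pvalue)
               })
  }
  lines
}

result_record <- function(res) {
  p <- res$pooled
  rec <- list(scale = res$scale, estimate = p$estimate, se = p$se,
              ci_low = p$ci_low, ci_high = p$ci_high, pvalue = p$pvalue,
              n_snps = p$n_snps, q_stat = p$q_stat, q_df = p$q_df,
              q_pvalue = p$q_pvalue, per_sd = p$per_sd, sd_used = p$sd_used,
              per_snp = res$per_snp[c("rsid", "ratio", "se",
                                      "ci_low", "ci_high", "pvalue")])
  if (!is.null(res$odds_ratio)) {
    rec$odds_ratio <- res$odds_ratio[c("or", "ci_low", "ci_high", "pvalue")]
  }
  rec
}

write_analysis <- function(analysis, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (res in analysis$results) {
    utils::write.table(res$forest,
                       file.path(output_dir, sprintf("forest_%s.tsv", res$name)),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }
  writeLines(analysis$report, file.path(output_dir, "report.txt"))
  jsonlite::write_json(lapply(analysis$results, result_record),
                       file.path(output_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null", pretty = TRUE)
  if (!is.null(analysis$screen)) {
    utils::write.table(analysis$screen,
                       file.path(output_dir, "confounder_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(output_dir)
}

#' @export
print.mr_analysis <- function(x, ...) {
  writeLines(x$report)
  invisible(x)
}
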
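# Instrument selection, strength diagnostics (variance explained, F), and
# the confounder screen against a local trait-association table.

#' Select genetic instruments by significance and locus
#'
#' Retains candidates with `pvalue` strictly below the threshold
#' (genome-wide significance, 5e-8, by default). When `one_per_locus` is
#' set and locus labels are available, only the strongest candidate per
#' locus label is kept (smallest p; ties broken by smaller standard error,
#' then lexicographic rsid) — a stand-in for LD-based pruning when the
#' available annotation is a cytoband or gene-region label rather than a
#' reference panel.
#'
#' @param candidates a summary-statistics data.frame carrying `pvalue`
#'   (and `se`, `rsid`); may carry a `locus` column.
#' @param pvalue_threshold significance cut, strict inequality. Default 5e-8.
#' @param one_per_locus keep only the smallest-p candidate per locus label.
#' @param locus optional character vector of locus labels (overrides any
#'   `locus` column), recycled against `candidates` rows.
#' @return an object of class `instrument_set`: list with `members` (rsids),
#'   `pvalue_threshold`, `loci` (named by rsid, possibly `NA`), and `table`
#'   (the retained candidate rows). An empty selection is valid and is
#'   reported via a message, not an error.
#' @export
select_instruments <- function(candidates, pvalue_threshold = 5e-8,
                               one_per_locus = FALSE, locus = NULL) {
  if (!is.numeric(pvalue_threshold) || pvalue_threshold <= 0) {
    mr_config_error("pvalue_threshold must be positive")
  }
  tab <- as.data.frame(candidates)
  if (!is.null(locus)) tab$locus <- rep_len(as.character(locus), nrow(tab))
  if (!"locus" %in% names(tab)) tab$locus <- NA_character_

  tab <- tab[!is.na(tab$pvalue) & tab$pvalue < pvalue_threshold, , drop = FALSE]

  if (one_per_locus && nrow(tab) > 0L && any(!is.na(tab$locus))) {
    # per locus: argmin p, ties by smaller se then lexicographic rsid;
    # unlabelled rows are all kept
    orig <- seq_len(nrow(tab))
    ord <- order(tab$pvalue, tab$se, tab$rsid)
    tab <- tab[ord, , drop = FALSE]
    orig <- orig[ord]
    labelled <- !is.na(tab$locus)
    drop_dup <- duplicated(tab$locus) & labelled
    tab <- tab[!drop_dup, , drop = FALSE]
    tab <- tab[order(orig[!drop_dup]), , drop = FALSE]  # restore input order
  }
  rownames(tab) <- NULL

  if (nrow(tab) == 0L) {
    message(sprintf("no candidate passed p < %g; instrument set is empty",
                    pvalue_threshold))
  }
  structure(list(
    members = tab$rsid,
    pvalue_threshold = pvalue_threshold,
    loci = stats::setNames(tab$locus, tab$rsid),
    table = tab
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d variant(s) at p < %g\n",
              length(x$members), x$pvalue_threshold))
  if (length(x$members)) {
    cat(paste(sprintf("  %s (%s)", x$members,
                      ifelse(is.na(x$loci), "locus n/a", x$loci)),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Variance in the exposure explained by a variant
#'
#' For an additively coded biallelic variant with effect-allele frequency
#' `p` and per-allele effect `beta`,
#' `r^2 = 2 p (1 - p) beta^2 / trait_variance`. Summing over an instrument
#' set gives the total variance explained. Symmetric in `p` vs `1 - p` and
#' in the sign of `beta`.
#'
#' @param assoc a data.frame with columns `beta` and `eaf` (e.g. a
#'   summary-statistics table), or a numeric vector of betas.
#' @param trait_variance phenotypic variance of the exposure, strictly
#'   positive, on the scale of the betas.
#' @param eaf effect-allele frequencies, required when `assoc` is numeric.
#' @return numeric vector of per-variant r-squared values; `NA` (with a
#'   warning, not an error) where the allele frequency is missing.
#' @export
variance_explained <- function(assoc, trait_variance, eaf = NULL) {
  if (!is.numeric(trait_variance) || length(trait_variance) != 1L ||
      is.na(trait_variance) || trait_variance <= 0) {
    mr_input_error("trait_variance must be a single positive number")
  }
  if (is.data.frame(assoc)) {
    beta <- assoc$beta
    eaf <- assoc$eaf
  } else {
    beta <- assoc
    if (is.null(eaf)) mr_input_error("eaf is required when assoc is a numeric vector")
  }
  if (any(is.na(eaf))) {
    warning("allele frequency missing for some variants; r^2 unavailable (NA)",
            call. = FALSE)
  }
  2 * eaf * (1 - eaf) * beta^2 / trait_variance
}

#' F-statistic for instrument strength
#'
#' The standard first-stage strength diagnostic from the total variance
#' explained: `F = r2 * (n - k - 1) / ((1 - r2) * k)` for `k` instruments
#' in a sample of `n`. Values above ~10 are conventionally taken to
#' indicate that weak-instrument bias is limited.
#'
#' @param r2_total total variance explained by the instruments, in (0, 1).
#' @param n exposure GWAS sample size, `n > k + 1`.
#' @param k number of instruments, `k >= 1`.
#' @return the F-statistic (scalar).
#' @export
f_statistic <- function(r2_total, n, k) {
  if (!is.numeric(r2_total) || length(r2_total) != 1L || is.na(r2_total) ||
      r2_total <= 0 || r2_total >= 1) {
    mr_input_error("r2_total must lie strictly between 0 and 1")
  }
  if (!is.numeric(k) || k < 1) mr_input_error("k must be a positive integer")
  if (!is.numeric(n) || n <= k + 1) mr_input_error("n must exceed k + 1")
  r2_total * (n - k - 1) / ((1 - r2_total) * k)
}

#' Default confounder trait list for bone outcomes
#'
#' Known risk factors for low bone density and fracture used by the
#' default confounder screen: anthropometry, type 2 diabetes, smoking,
#' alcohol, and steroid hormones.
#'
#' @return character vector of trait names (matched case-insensitively).
#' @export
default_confounders <- function() {
  c("body mass index", "fat-free soft tissue body mass", "height",
    "type 2 diabetes", "smoking", "alcohol consumption",
    "estrogens", "testosterone", "cortisol")
}

#' Screen instruments against a confounder trait table
#'
#' Looks up each instrument in a local table of variant-trait associations
#' (columns `rsid`, `trait`, `pvalue`) and flags any association with a
#' listed confounder trait at `pvalue < pvalue_threshold`. Trait matching
#' is case-insensitive exact match. An empty table yields an all-clear
#' with a logged caveat (absence of evidence, not evidence of absence).
#'
#' @param instruments character vector of rsids, or an `instrument_set`.
#' @param table data.frame with columns `rsid`, `trait`, `pvalue`.
#' @param confounder_traits trait names to screen; defaults to
#'   [default_confounders()].
#' @param pvalue_threshold flag associations with `pvalue` strictly below
#'   this cut (default 0.01).
#' @return data.frame of flags (`rsid`, `trait`, `pvalue`), zero rows when
#'   no instrument is associated with any listed confounder; attribute
#'   `"caveat"` set when the lookup table was empty.
#' @export
confounder_screen <- function(instruments, table,
                              confounder_traits = default_confounders(),
                              pvalue_threshold = 0.01) {
  if (inherits(instruments, "instrument_set")) instruments <- instruments$members
  empty <- data.frame(rsid = character(), trait = character(),
                      pvalue = numeric(), stringsAsFactors = FALSE)
  if (is.null(table) || nrow(table) == 0L) {
    message("confounder table is empty: screen is all-clear by absence of records")
    attr(empty, "caveat") <- "empty lookup table"
    return(empty)
  }
  req <- c("rsid", "trait", "pvalue")
  if (!all(req %in% names(table))) {
    mr_config_error("confounder table needs columns rsid, trait, pvalue")
  }
  hit <- table$rsid %in% instruments &
    tolower(table$trait) %in% tolower(confounder_traits) &
    !is.na(table$pvalue) & table$pvalue < pvalue_threshold
  out <- table[hit, req, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a variant-trait association table
#'
#' Delimited text (tab or comma, auto-detected) with columns `rsid`,
#' `trait`, `pvalue`, as consumed by [confounder_screen()].
#'
#' @param path path to the table.
#' @return data.frame with `rsid`, `trait`, `pvalue`.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) mr_input_error(sprintf("file '%s' does not exist", path))
  sep <- detect_delimiter(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"")
  req <- c("rsid", "trait", "pvalue")
  if (!all(req %in% names(tab))) {
    mr_config_error("trait table needs columns rsid, trait, pvalue")
  }
  tab$pvalue <- as.numeric(tab$pvalue)
  tab
}
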
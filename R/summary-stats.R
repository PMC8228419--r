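# GWAS summary statistics: reading, validation, writing, harmonization.
#
# A summary-statistics table is a plain data.frame with canonical columns
#   rsid, effect_allele, other_allele, eaf, beta, se, pvalue, n, trait, unit
# of which rsid, effect_allele, other_allele, beta, se, pvalue are mandatory.
# beta is the per-effect-allele effect (trait units, or log-odds for binary
# traits); eaf is the effect-allele frequency.

CANONICAL_COLUMNS <- c("rsid", "effect_allele", "other_allele", "eaf",
                       "beta", "se", "pvalue", "n", "trait", "unit")
MANDATORY_COLUMNS <- c("rsid", "effect_allele", "other_allele",
                       "beta", "se", "pvalue")

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab or comma, auto-detected from the header
#' line) into a validated summary-statistics data.frame. Column names can be
#' remapped via `column_map`. Alleles are uppercased. Rows violating the type
#' invariants (non-SNV alleles, identical alleles, `se <= 0`, p-value outside
#' (0, 1], allele frequency outside [0, 1]) are rejected with a per-row
#' report attached as the `"rejected"` attribute and surfaced as a warning —
#' never silently dropped.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map optional named character vector mapping canonical names
#'   to file column names, e.g. `c(rsid = "SNP", beta = "Effect")`.
#' @param trait,unit optional labels stored in the `trait`/`unit` columns
#'   when the file does not carry them.
#' @return a `data.frame` of class `summary_stats` with canonical columns;
#'   attribute `"rejected"` holds a data.frame (`row`, `rsid`, `reason`) of
#'   rejected rows.
#' @seealso [write_summary_stats()], [harmonize()]
#' @export
read_summary_stats <- function(path, column_map = NULL, trait = NULL, unit = NULL) {
  if (!file.exists(path)) mr_input_error(sprintf("file '%s' does not exist", path))
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"",
                           colClasses = NA)

  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == "")) {
      mr_config_error("column_map must be a named vector: canonical = file column")
    }
    for (canon in names(column_map)) {
      fcol <- column_map[[canon]]
      if (!fcol %in% names(raw)) {
        mr_config_error(sprintf(
          "column_map names file column '%s' (for '%s') which is absent", fcol, canon))
      }
      names(raw)[names(raw) == fcol] <- canon
    }
  }

  missing_cols <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    mr_config_error(sprintf("missing mandatory column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(CANONICAL_COLUMNS, names(raw))) {
    raw[[col]] <- rep(NA, nrow(raw))
  }
  raw <- raw[CANONICAL_COLUMNS]

  raw$rsid <- as.character(raw$rsid)
  raw$effect_allele <- toupper(as.character(raw$effect_allele))
  raw$other_allele <- toupper(as.character(raw$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  if (!is.null(trait)) raw$trait <- trait
  if (!is.null(unit)) raw$unit <- unit

  out <- validate_summary_stats(raw)
  if (nrow(out) == 0L) {
    mr_input_error(sprintf("zero valid rows in '%s'", path))
  }
  rej <- attr(out, "rejected")
  if (nrow(rej) > 0L) {
    warning(sprintf("%d row(s) rejected while reading '%s':\n%s",
                    nrow(rej), path,
                    paste(sprintf("  row %d (%s): %s", rej$row, rej$rsid, rej$reason),
                          collapse = "\n")),
            call. = FALSE)
  }
  out
}

# Apply the per-row type invariants; returns the valid rows (class
# summary_stats) with the rejected rows and reasons in attr "rejected".
validate_summary_stats <- function(df) {
  nucleotides <- c("A", "C", "G", "T")
  reasons <- character(nrow(df))
  bad <- function(cond, why) {
    cond <- cond & reasons == ""
    reasons[cond] <<- why
  }
  bad(is.na(df$rsid) | df$rsid == "", "missing rsid")
  bad(!(df$effect_allele %in% nucleotides), "effect_allele not a single A/C/G/T")
  bad(!(df$other_allele %in% nucleotides), "other_allele not a single A/C/G/T")
  bad(df$effect_allele == df$other_allele, "effect_allele equals other_allele")
  bad(is.na(df$beta) | !is.finite(df$beta), "beta missing or non-finite")
  bad(is.na(df$se) | df$se <= 0, "se missing or not > 0")
  bad(is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1, "pvalue outside (0, 1]")
  bad(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf outside [0, 1]")
  bad(!is.na(df$n) & df$n <= 0, "n not positive")

  keep <- reasons == ""
  rejected <- data.frame(row = which(!keep),
                         rsid = df$rsid[!keep],
                         reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "rejected") <- rejected
  out
}

#' Write a summary-statistics table
#'
#' Tab-separated, full precision (17 significant digits, so write-then-read
#' round-trips every field exactly).
#'
#' @param x a summary-statistics data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  out <- as.data.frame(x)[intersect(CANONICAL_COLUMNS, names(x))]
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA, sprintf("%.17g", out[[col]]))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A variant is palindromic when its two alleles are Watson-Crick
#' complements ({A,T} or {C,G}), so strand orientation cannot be resolved
#' from the allele letters alone.
#'
#' @param a1,a2 character vectors of single-nucleotide alleles.
#' @return logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  p <- paste(pmin(toupper(a1), toupper(a2)), pmax(toupper(a1), toupper(a2)))
  p %in% c("A T", "C G")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations onto the exposure's effect-allele
#' orientation, SNP by SNP:
#'
#' * same allele orientation: outcome beta copied unchanged;
#' * swapped alleles (outcome effect allele equals exposure other allele and
#'   vice versa): outcome beta negated, outcome allele frequency flipped to
#'   `1 - eaf`, `flipped` set;
#' * palindromic pair (A/T or C/G): allele letters cannot resolve strand, so
#'   alignment uses the allele frequencies — only when both are present and
#'   both fall outside the ambiguous window
#'   (`eaf_ambiguity_threshold`, `1 - eaf_ambiguity_threshold`); frequencies
#'   on the same side of 0.5 mean same orientation, opposite sides mean
#'   flip; otherwise the SNP is dropped with a logged reason (strand is
#'   never guessed);
#' * incompatible allele pairs, and SNPs absent from either table, are
#'   dropped with a logged reason.
#'
#' Harmonization is idempotent: re-harmonizing an already-aligned pair
#' changes nothing.
#'
#' @param exposure,outcome summary-statistics data.frames (see
#'   [read_summary_stats()]); rsids must be unique within each table.
#' @param eaf_ambiguity_threshold frequency in \[0, 0.5\]; palindromic SNPs
#'   with either allele frequency inside
#'   (`threshold`, `1 - threshold`) are considered strand-ambiguous and
#'   dropped. Default 0.42: frequency-based disambiguation is unreliable
#'   near 0.5.
#' @return a `data.frame` of class `harmonized_data` with columns `rsid`,
#'   `effect_allele`, `other_allele` (exposure orientation),
#'   `beta_exposure`, `se_exposure`, `eaf_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_outcome`, `palindromic`, `flipped`; attribute
#'   `"log"` records every dropped SNP and its reason.
#' @examples
#' exp <- data.frame(rsid = "rs1", effect_allele = "T", other_allele = "C",
#'                   eaf = 0.3, beta = 0.02, se = 0.005, pvalue = 1e-8, n = 1000)
#' out <- data.frame(rsid = "rs1", effect_allele = "C", other_allele = "T",
#'                   eaf = 0.7, beta = 0.005, se = 0.002, pvalue = 0.01, n = 5000)
#' harmonize(exp, out)  # outcome beta becomes -0.005, flipped = TRUE
#' @export
harmonize <- function(exposure, outcome, eaf_ambiguity_threshold = 0.42) {
  if (eaf_ambiguity_threshold < 0 || eaf_ambiguity_threshold > 0.5) {
    mr_config_error("eaf_ambiguity_threshold must lie in [0, 0.5]")
  }
  for (side in list(exposure = exposure, outcome = outcome)) {
    dup <- unique(side$rsid[duplicated(side$rsid)])
    if (length(dup) > 0L) {
      mr_input_error(sprintf("duplicated rsid(s): %s (MR weights are per-variant)",
                             paste(dup, collapse = ", ")))
    }
  }

  log <- list()
  note <- function(rsid, action, reason) {
    log[[length(log) + 1L]] <<- data.frame(rsid = rsid, action = action,
                                           reason = reason, stringsAsFactors = FALSE)
  }

  shared <- intersect(exposure$rsid, outcome$rsid)
  for (id in setdiff(exposure$rsid, shared)) note(id, "drop", "absent from outcome")
  for (id in setdiff(outcome$rsid, shared)) note(id, "drop", "absent from exposure")
  if (length(shared) == 0L) {
    warning("exposure and outcome share no rsids; harmonized set is empty",
            call. = FALSE)
  }

  rows <- vector("list", length(shared))
  ambiguous <- function(f) is.na(f) |
    (f > eaf_ambiguity_threshold & f < 1 - eaf_ambiguity_threshold)

  for (i in seq_along(shared)) {
    id <- shared[i]
    ex <- exposure[exposure$rsid == id, ]
    ou <- outcome[outcome$rsid == id, ]
    pal <- is_palindromic(ex$effect_allele, ex$other_allele)
    same_letters <- setequal(c(ex$effect_allele, ex$other_allele),
                             c(ou$effect_allele, ou$other_allele))

    if (!same_letters) {
      note(id, "drop", sprintf("incompatible alleles (%s/%s vs %s/%s)",
                               ex$effect_allele, ex$other_allele,
                               ou$effect_allele, ou$other_allele))
      next
    }

    if (pal) {
      # allele letters are uninformative for strand; use frequencies
      if (ambiguous(ex$eaf) || ambiguous(ou$eaf)) {
        note(id, "drop",
             "palindromic with missing or near-0.5 allele frequency; strand not guessed")
        next
      }
      flip <- sign(ex$eaf - 0.5) != sign(ou$eaf - 0.5)
      if (flip) note(id, "flip", "palindromic aligned by allele frequency")
      else note(id, "keep", "palindromic retained; frequencies concordant")
    } else if (ou$effect_allele == ex$effect_allele &&
               ou$other_allele == ex$other_allele) {
      flip <- FALSE
    } else {
      # swapped orientation
      flip <- TRUE
      note(id, "flip", "outcome alleles swapped relative to exposure")
    }

    rows[[i]] <- data.frame(
      rsid = id,
      effect_allele = ex$effect_allele,
      other_allele = ex$other_allele,
      beta_exposure = ex$beta,
      se_exposure = ex$se,
      eaf_exposure = ex$eaf,
      beta_outcome = if (flip) -ou$beta else ou$beta,
      se_outcome = ou$se,
      eaf_outcome = if (flip) 1 - ou$eaf else ou$eaf,
      palindromic = pal,
      flipped = flip,
      stringsAsFactors = FALSE
    )
  }

  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(rsid = character(), effect_allele = character(),
                      other_allele = character(), beta_exposure = numeric(),
                      se_exposure = numeric(), eaf_exposure = numeric(),
                      beta_outcome = numeric(), se_outcome = numeric(),
                      eaf_outcome = numeric(), palindromic = logical(),
                      flipped = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("harmonized_data", "data.frame")
  attr(out, "log") <- if (length(log)) do.call(rbind, log) else
    data.frame(rsid = character(), action = character(), reason = character())
  out
}

#' Harmonization audit log
#'
#' @param x a `harmonized_data` object from [harmonize()].
#' @return a data.frame (`rsid`, `action`, `reason`) listing every drop,
#'   flip and palindromic retention decision.
#' @export
harmonization_log <- function(x) attr(x, "log")
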
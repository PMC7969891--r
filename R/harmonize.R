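COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_snv <- function(a) a %in% names(COMPLEMENT)

complement_allele <- function(a) unname(COMPLEMENT[a])

is_palindromic_pair <- function(ea, oa) {
  is_snv(ea) & is_snv(oa) & complement_allele(ea) == oa
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Joins exposure and outcome association records by rsID and reorients each
#' outcome record onto the exposure's effect allele: identical alleles are
#' kept as-is; swapped alleles flip the outcome beta and complement its
#' frequency; strand-complemented alleles are complemented first. Palindromic
#' SNPs (A/T or C/G), whose strand cannot be resolved from allele labels, are
#' resolved by allele-frequency concordance: if both frequencies lie outside
#' `0.5 +/- eaf_window` they are kept (same side) or flipped (opposite
#' sides); if either lies inside the window the SNP is dropped as ambiguous.
#' Indels, multi-allelic records and irreconcilable allele pairs are dropped
#' with a reason.
#'
#' @param exposure,outcome Data frames of association records sharing an
#'   `rsid` column (e.g. a [liberal_set()] and [als_associations()]).
#' @param eaf_window Half-width of the palindrome ambiguity window around
#'   0.5; default 0.08 (drop when either frequency is in \[0.42, 0.58\]).
#' @param eaf_warn Warn when aligned exposure/outcome frequencies differ by
#'   more than this (default 0.2); small cross-study differences pass
#'   silently.
#' @return A tibble of harmonized instruments: `rsid`, `effect_allele`,
#'   `other_allele`, `bx`, `se_x`, `eaf_x`, `pval_x`, `by`, `se_y`, `eaf_y`,
#'   `pval_y`, `palindromic`, `flipped`. Attributes: `log` (tibble of
#'   per-SNP actions and reasons, including drops) and `missing` (exposure
#'   rsIDs absent from the outcome). The `exposure` attribute carries the
#'   exposure trait label when unique.
#' @export
#' @examples
#' harmonize(liberal_set(iron_associations(), "iron"), als_associations())
harmonize <- function(exposure, outcome, eaf_window = 0.08, eaf_warn = 0.2) {
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)
  missing <- setdiff(exposure$rsid, outcome$rsid)
  shared <- exposure[exposure$rsid %in% outcome$rsid, , drop = FALSE]
  if (nrow(shared) == 0) {
    abort("no exposure SNP found in the outcome records")
  }
  oc <- outcome[match(shared$rsid, outcome$rsid), , drop = FALSE]

  rows <- vector("list", nrow(shared))
  log_rows <- vector("list", nrow(shared))
  for (i in seq_len(nrow(shared))) {
    ex <- shared[i, ]
    ou <- oc[i, ]
    h <- harmonize_pair(ex, ou, eaf_window = eaf_window)
    log_rows[[i]] <- tibble::tibble(
      rsid = ex$rsid, action = h$action, reason = h$reason
    )
    rows[[i]] <- h$row
  }
  out <- dplyr::bind_rows(rows)
  log <- dplyr::bind_rows(log_rows)
  if (length(missing) > 0) {
    log <- dplyr::bind_rows(
      log,
      tibble::tibble(
        rsid = missing, action = "missing",
        reason = "absent from outcome records (no proxy search)"
      )
    )
  }
  if (nrow(out) > 0) {
    gap <- abs(out$eaf_x - out$eaf_y)
    big <- !is.na(gap) & gap > eaf_warn
    if (any(big)) {
      warn(paste0(
        "allele-frequency gap > ", eaf_warn, " after alignment for: ",
        paste(out$rsid[big], collapse = ", ")
      ))
    }
  }
  traits <- unique(shared$trait)
  attr(out, "exposure") <- if (length(traits) == 1) traits else NA_character_
  attr(out, "log") <- log
  attr(out, "missing") <- missing
  out
}

# Align one exposure/outcome record pair; returns list(row?, action, reason)
harmonize_pair <- function(ex, ou, eaf_window = 0.08) {
  if (ex$rsid != ou$rsid) abort("rsid mismatch between exposure and outcome")
  drop <- function(reason) list(row = NULL, action = "drop", reason = reason)
  keep <- function(flipped, strand_flipped = FALSE, palindromic = FALSE) {
    by <- ou$beta
    eaf_y <- ou$eaf
    if (flipped) {
      by <- -by
      eaf_y <- if (is.na(eaf_y)) NA_real_ else 1 - eaf_y
    }
    action <- if (flipped) "flip" else "keep"
    reason <- if (palindromic) {
      "palindromic SNP resolved by allele-frequency concordance"
    } else if (strand_flipped) {
      "alleles matched after strand complement"
    } else if (flipped) {
      "outcome alleles swapped relative to exposure"
    } else {
      "alleles already aligned"
    }
    row <- tibble::tibble(
      rsid = ex$rsid,
      effect_allele = ex$effect_allele,
      other_allele = ex$other_allele,
      bx = ex$beta, se_x = ex$se, eaf_x = ex$eaf,
      pval_x = ex$pvalue,
      by = by, se_y = ou$se, eaf_y = eaf_y,
      pval_y = ou$pvalue,
      palindromic = palindromic, flipped = flipped
    )
    list(row = row, action = action, reason = reason)
  }

  ea_x <- ex$effect_allele
  oa_x <- ex$other_allele
  ea_y <- ou$effect_allele
  oa_y <- ou$other_allele
  if (!all(is_snv(c(ea_x, oa_x, ea_y, oa_y)))) {
    return(drop("indel or non-ACGT allele (biallelic SNVs only)"))
  }

  if (is_palindromic_pair(ea_x, oa_x)) {
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
      return(drop("irreconcilable alleles"))
    }
    fx <- ex$eaf
    fy <- ou$eaf
    if (is.na(fx) || is.na(fy)) {
      return(drop("palindromic SNP without both allele frequencies"))
    }
    lo <- 0.5 - eaf_window
    hi <- 0.5 + eaf_window
    if ((fx >= lo && fx <= hi) || (fy >= lo && fy <= hi)) {
      return(drop("palindromic SNP with ambiguous allele frequency"))
    }
    same_side <- (fx - 0.5) * (fy - 0.5) > 0
    return(keep(flipped = !same_side, palindromic = TRUE))
  }

  if (ea_y == ea_x && oa_y == oa_x) return(keep(flipped = FALSE))
  if (ea_y == oa_x && oa_y == ea_x) return(keep(flipped = TRUE))
  cea <- complement_allele(ea_y)
  coa <- complement_allele(oa_y)
  if (cea == ea_x && coa == oa_x) {
    return(keep(flipped = FALSE, strand_flipped = TRUE))
  }
  if (cea == oa_x && coa == ea_x) {
    return(keep(flipped = TRUE, strand_flipped = TRUE))
  }
  drop("irreconcilable alleles")
}

# shared input check for the estimators
check_harmonized <- function(dat, min_snp = 1, caller = "estimator") {
  dat <- tibble::as_tibble(dat)
  need <- c("rsid", "bx", "se_x", "by", "se_y")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols) > 0) {
    abort(paste0(
      caller, " needs harmonized instruments with columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(dat) < min_snp) {
    abort(paste0(caller, " requires at least ", min_snp, " instrument(s)"))
  }
  if (any(dat$se_y <= 0) || any(dat$se_x <= 0, na.rm = TRUE)) {
    abort("standard errors must be strictly positive")
  }
  dat
}
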
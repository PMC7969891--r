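#' Filter association records at a p-value threshold
#'
#' Keeps records with p strictly below `threshold`. Records without a stored
#' p-value (the packaged exposure table prints none; a row's presence encodes
#' genome-wide significance) count as passing the conventional 5e-8
#' threshold, and only that threshold.
#'
#' @param records A data frame of association records.
#' @param threshold P-value threshold in (0, 1); default genome-wide
#'   significance, 5e-8.
#' @return The passing records as a tibble, input order preserved.
#' @export
#' @examples
#' iron_associations("iron") |> significance_filter()  # all 5 pass
significance_filter <- function(records, threshold = 5e-8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must lie strictly inside (0, 1)")
  }
  records <- tibble::as_tibble(records)
  # NA p = presence flag for genome-wide significance; passes only if the
  # requested threshold is at least as lenient as 5e-8
  pass <- ifelse(
    is.na(records$pvalue), threshold >= 5e-8, records$pvalue < threshold
  )
  records[pass, , drop = FALSE]
}

#' Greedy LD pruning of association records
#'
#' Iterates records by ascending p-value (missing p sorts first, i.e. most
#' significant; ties broken by input order) and drops any later record with
#' pairwise r-squared strictly above `threshold` against an already kept
#' record.
#'
#' @param records A data frame of association records.
#' @param ld Pairwise LD, either a symmetric matrix with rsIDs as dimnames or
#'   a three-column data frame (`rsid_a`, `rsid_b`, `r2`).
#' @param threshold r-squared cutoff; pairs at exactly the threshold are both
#'   kept. Default 0.01 (linkage equilibrium).
#' @param assume_unlinked If `TRUE`, pairs absent from `ld` are taken as
#'   r2 = 0 instead of raising an error.
#' @return The kept records, in input order.
#' @export
ld_prune <- function(records, ld, threshold = 0.01, assume_unlinked = FALSE) {
  records <- tibble::as_tibble(records)
  J <- nrow(records)
  if (J <= 1) return(records)
  lookup <- ld_lookup(ld)
  pair_r2 <- function(a, b) {
    v <- lookup(a, b)
    if (is.na(v)) {
      if (assume_unlinked) 0 else {
        abort(paste0("no LD value for pair ", a, " / ", b))
      }
    } else v
  }
  p <- records$pvalue
  p[is.na(p)] <- -Inf
  ord <- order(p)  # stable: ties keep input order
  kept_idx <- integer(0)
  for (i in ord) {
    clash <- any(vapply(
      kept_idx,
      function(k) pair_r2(records$rsid[i], records$rsid[k]) > threshold,
      logical(1)
    ))
    if (!clash) kept_idx <- c(kept_idx, i)
  }
  records[sort(kept_idx), , drop = FALSE]
}

ld_lookup <- function(ld) {
  if (is.null(ld)) return(function(a, b) NA_real_)
  if (is.matrix(ld)) {
    if (is.null(dimnames(ld))) abort("LD matrix needs rsID dimnames")
    if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8))) {
      abort("LD matrix must be symmetric")
    }
    if (any(ld < 0 | ld > 1, na.rm = TRUE)) abort("LD r2 must lie in [0, 1]")
    function(a, b) {
      if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b] else NA_real_
    }
  } else {
    ld <- tibble::as_tibble(ld)
    stopifnot(all(c("rsid_a", "rsid_b", "r2") %in% names(ld)))
    if (any(ld$r2 < 0 | ld$r2 > 1, na.rm = TRUE)) {
      abort("LD r2 must lie in [0, 1]")
    }
    key <- c(
      paste(ld$rsid_a, ld$rsid_b, sep = "\r"),
      paste(ld$rsid_b, ld$rsid_a, sep = "\r")
    )
    val <- c(ld$r2, ld$r2)
    function(a, b) {
      hit <- match(paste(a, b, sep = "\r"), key)
      if (is.na(hit)) NA_real_ else val[hit]
    }
  }
}

#' Conservative instrument set: four-biomarker concordance
#'
#' Selects SNPs that are genome-wide significant for all four iron-status
#' biomarkers with a sign pattern consistent with a single systemic
#' iron-status axis: iron, ferritin and transferrin saturation move together
#' and transferrin moves opposite (higher iron status lowers transferrin).
#' The rule is direction-symmetric, so relabelling a SNP's effect allele
#' (flipping all four betas) does not change membership.
#'
#' @param records Long-format exposure records covering the four biomarkers
#'   (as returned by [iron_associations()]).
#' @return A tibble with one row per concordant SNP: `rsid`, the four signed
#'   betas (`beta_iron`, `beta_ferritin`, `beta_transferrin_saturation`,
#'   `beta_transferrin`) and a `provenance` note; attribute `mode` is
#'   `"conservative"`.
#' @export
#' @examples
#' conservative_set(iron_associations())  # rs1800562, rs1799945, rs855791
conservative_set <- function(records) {
  records <- tibble::as_tibble(records)
  have <- unique(records$trait)
  missing_bm <- setdiff(IRON_BIOMARKERS, have)
  if (length(missing_bm) > 0) {
    abort(paste0(
      "records must cover all four biomarkers; missing: ",
      paste(missing_bm, collapse = ", ")
    ))
  }
  wide <- records |>
    dplyr::filter(.data$trait %in% IRON_BIOMARKERS) |>
    dplyr::select("rsid", "trait", "beta") |>
    tidyr::pivot_wider(
      names_from = "trait", values_from = "beta", names_prefix = "beta_"
    )
  bi <- wide$beta_iron
  bf <- wide$beta_ferritin
  bs <- wide$beta_transferrin_saturation
  bt <- wide$beta_transferrin
  concordant <- !is.na(bi) & !is.na(bf) & !is.na(bs) & !is.na(bt) &
    bi != 0 & bf != 0 & bs != 0 & bt != 0 &
    sign(bi) == sign(bf) & sign(bi) == sign(bs) & sign(bi) == -sign(bt)
  out <- wide[concordant, , drop = FALSE]
  out$provenance <- paste0(
    "genome-wide significant for all four biomarkers; signs ",
    ifelse(out$beta_iron > 0, "+++-", "---+"),
    " over (iron, ferritin, tsat, transferrin)"
  )
  attr(out, "mode") <- "conservative"
  out
}

#' Liberal instrument set for one biomarker
#'
#' All SNPs associated with the given biomarker at genome-wide significance
#' (p < 5e-8); the per-biomarker analysis set of the liberal analyses.
#'
#' @param records Long-format exposure records (see [iron_associations()]).
#' @param biomarker One of `"iron"`, `"ferritin"`,
#'   `"transferrin_saturation"`, `"transferrin"`.
#' @return The biomarker's association records as a tibble (attribute `mode`
#'   set to `"liberal"`). Empty with a warning if no SNP qualifies.
#' @export
#' @examples
#' liberal_set(iron_associations(), "ferritin")  # 6 SNPs
liberal_set <- function(records, biomarker) {
  if (!biomarker %in% IRON_BIOMARKERS) {
    abort(paste0(
      "unknown biomarker '", biomarker, "'; valid labels: ",
      paste(IRON_BIOMARKERS, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(records) |>
    dplyr::filter(.data$trait == biomarker) |>
    significance_filter(5e-8)
  if (anyDuplicated(out$rsid)) abort("duplicate rsIDs in instrument set")
  if (nrow(out) == 0) {
    warn(paste0("no genome-wide significant SNPs for ", biomarker))
  }
  attr(out, "mode") <- "liberal"
  out
}

#' Variance in the exposure explained by a SNP
#'
#' For a standardized phenotype, `r2 = 2 * beta^2 * (1 - eaf) * eaf`, with
#' `beta` the per-allele effect in SD units and `eaf` the effect-allele
#' frequency.
#'
#' @param beta Per-SD effect estimate(s).
#' @param eaf Effect-allele frequency(ies), strictly inside (0, 1).
#' @return Numeric vector of r-squared values.
#' @export
#' @examples
#' variance_explained(-0.38, 0.67)  # 0.063854 (strongest transferrin SNP)
variance_explained <- function(beta, eaf) {
  if (any(!is.finite(eaf) | eaf <= 0 | eaf >= 1)) {
    abort("eaf must lie strictly inside (0, 1)")
  }
  2 * beta^2 * (1 - eaf) * eaf
}

#' Instrument-strength F statistic
#'
#' `F = r2 * (n - k - 1) / ((1 - r2) * k)`, with `n` the exposure GWAS sample
#' size and `k` the number of instruments the r-squared sums over (`k = 1`
#' for a single SNP). F > 10 is the conventional weak-instrument threshold.
#'
#' @param r2 Variance explained, in \eqn{[0, 1)}.
#' @param n Exposure GWAS sample size; must exceed `k + 1`.
#' @param k Number of instruments; default 1 (per-SNP F).
#' @return Numeric vector of F statistics.
#' @export
#' @examples
#' f_statistic(variance_explained(-0.38, 0.67), n = 48972)  # ~3340
f_statistic <- function(r2, n, k = 1) {
  if (any(!is.finite(r2) | r2 < 0 | r2 >= 1)) abort("r2 must lie in [0, 1)")
  if (any(k < 1)) abort("k must be >= 1")
  if (any(n <= k + 1)) abort("n must exceed k + 1")
  r2 * (n - k - 1) / ((1 - r2) * k)
}

#' Per-SNP and set-level instrument strength
#'
#' Adds `r2` and per-SNP `f` (k = 1) to each record and reports the
#' instrument-set totals (summed r-squared and the set-level F with
#' k = number of SNPs) as attributes `r2_sum` and `f_set`.
#'
#' @param records Association records with `beta`, `eaf` and `n` columns.
#' @return The records with `r2` and `f` columns appended.
#' @export
#' @examples
#' iron_associations("iron") |> instrument_strength()
instrument_strength <- function(records) {
  records <- tibble::as_tibble(records)
  out <- dplyr::mutate(
    records,
    r2 = variance_explained(.data$beta, .data$eaf),
    f = f_statistic(.data$r2, .data$n, k = 1)
  )
  r2_sum <- sum(out$r2)
  attr(out, "r2_sum") <- r2_sum
  attr(out, "f_set") <- if (nrow(out) >= 1 && all(out$n > nrow(out) + 1)) {
    f_statistic(min(r2_sum, 1 - 1e-12), unique(out$n)[1], k = nrow(out))
  } else {
    NA_real_
  }
  out
}
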
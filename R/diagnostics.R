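#' Leave-one-out IVW analysis
#'
#' Re-estimates the pooled IVW effect omitting each instrument in turn, to
#' show whether any single SNP drives the pooled estimate.
#'
#' @param dat Harmonized instruments (at least 2).
#' @param effects_model Passed to [mr_ivw()]; default multiplicative random
#'   effects.
#' @return A tibble with one row per omitted SNP: `omitted_rsid` followed by
#'   the [glance.mr_fit()] columns of the remaining-SNP IVW fit
#'   (`n_snp = J - 1` in every row).
#' @export
#' @examples
#' harmonize(liberal_set(iron_associations(), "iron"), als_associations()) |>
#'   mr_leave_one_out()
mr_leave_one_out <- function(dat, effects_model = c("mre", "fe")) {
  effects_model <- match.arg(effects_model)
  dat <- check_harmonized(dat, 2, "mr_leave_one_out")
  purrr::map_dfr(seq_len(nrow(dat)), function(j) {
    sub <- dat[-j, , drop = FALSE]
    attr(sub, "exposure") <- attr(dat, "exposure")
    dplyr::bind_cols(
      tibble::tibble(omitted_rsid = dat$rsid[j]),
      glance(mr_ivw(sub, effects_model))
    )
  })
}

#' Single-SNP (forest) results
#'
#' One Wald-ratio result per instrument, in input order — the per-SNP rows of
#' a forest plot.
#'
#' @param dat Harmonized instruments.
#' @return A tibble as returned by [mr_wald_ratio()], plus the exposure
#'   label when known.
#' @export
mr_single_snp <- function(dat) {
  dat <- tibble::as_tibble(dat)
  if (nrow(dat) == 0) {
    return(tibble::tibble(
      rsid = character(), beta = numeric(), se = numeric(), or = numeric(),
      ci_low = numeric(), ci_high = numeric(), pvalue = numeric()
    ))
  }
  out <- mr_wald_ratio(dat)
  out$exposure <- attr(dat, "exposure") %||% NA_character_
  out
}
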
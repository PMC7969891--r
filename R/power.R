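#' A-priori power for IVW MR with a binary outcome
#'
#' Normal-approximation power for a two-sided test of the causal log odds
#' ratio:
#' `power = Phi(|ln OR| * sqrt(n * r2 * cf * (1 - cf)) - z_(1 - alpha/2))`,
#' where `n` is the outcome GWAS size, `cf` the case fraction and `r2` the
#' variance in the exposure explained by the instrument set. At `or_alt = 1`
#' the power equals `alpha / 2` (the probability of rejecting in one tail).
#'
#' @param or_alt Odds ratio(s) under the alternative, per SD of exposure.
#' @param n Outcome GWAS sample size.
#' @param case_fraction Cases / n, strictly inside (0, 1).
#' @param r2 Variance explained by the instrument set, > 0.
#' @param alpha Two-sided test size; default 0.05.
#' @return Power value(s) in \[alpha/2, 1).
#' @export
#' @examples
#' mr_power(1.2, n = 80610, case_fraction = 20806 / 80610, r2 = 0.0394)
mr_power <- function(or_alt, n, case_fraction, r2, alpha = 0.05) {
  check_power_args(n, case_fraction, r2, alpha)
  if (any(or_alt <= 0)) abort("or_alt must be positive")
  lambda <- sqrt(n * r2 * case_fraction * (1 - case_fraction))
  pnorm(abs(log(or_alt)) * lambda - qnorm(1 - alpha / 2))
}

#' Detectable odds ratio at a target power
#'
#' Inverts [mr_power()]:
#' `|ln OR| = (z_power + z_(1 - alpha/2)) / sqrt(n * r2 * cf * (1 - cf))`;
#' the OR above 1 is returned.
#'
#' @param power Target power, strictly between `alpha / 2` and 1.
#' @inheritParams mr_power
#' @return The smallest detectable OR (>= 1).
#' @export
#' @examples
#' detectable_or(0.8, n = 80610, case_fraction = 20806 / 80610, r2 = 0.0394)
detectable_or <- function(power = 0.8, n, case_fraction, r2, alpha = 0.05) {
  check_power_args(n, case_fraction, r2, alpha)
  if (any(power <= alpha / 2) || any(power >= 1)) {
    abort("target power must lie strictly between alpha/2 and 1")
  }
  lambda <- sqrt(n * r2 * case_fraction * (1 - case_fraction))
  exp((qnorm(power) + qnorm(1 - alpha / 2)) / lambda)
}

check_power_args <- function(n, case_fraction, r2, alpha) {
  if (any(r2 <= 0)) abort("r2 must be > 0")
  if (any(n <= 0)) abort("n must be positive")
  if (any(case_fraction <= 0 | case_fraction >= 1)) {
    abort("case_fraction must lie strictly inside (0, 1)")
  }
  if (any(alpha <= 0 | alpha >= 1)) abort("alpha must lie in (0, 1)")
  invisible(TRUE)
}

#' Detectable-OR table per biomarker
#'
#' For each biomarker's instrument set (conservative or liberal, from the
#' packaged exposure table by default), sums the per-SNP variance explained
#' and reports the OR detectable at the target power against the ALS outcome
#' GWAS (n = 80,610; case fraction 20,806 / 80,610).
#'
#' @param mode `"conservative"` or `"liberal"`.
#' @param power Target power; default 0.8.
#' @param exposure_data Long-format exposure records; defaults to
#'   [iron_associations()].
#' @param n,case_fraction Outcome GWAS size and case fraction; default the
#'   ALS study values.
#' @param alpha Two-sided test size; default 0.05.
#' @return A tibble with one row per biomarker: `mode`, `exposure`, `n_snp`,
#'   `r2_sum`, `detectable_or`, `power`.
#' @export
#' @examples
#' power_table("conservative")
power_table <- function(mode = c("conservative", "liberal"), power = 0.8,
                        exposure_data = NULL, n = 80610,
                        case_fraction = 20806 / 80610, alpha = 0.05) {
  mode <- match.arg(mode)
  exposure_data <- exposure_data %||% iron_associations()
  purrr::map_dfr(IRON_BIOMARKERS, function(bm) {
    recs <- select_instrument_records(exposure_data, mode, bm)
    r2_sum <- sum(variance_explained(recs$beta, recs$eaf))
    tibble::tibble(
      mode = mode, exposure = bm, n_snp = nrow(recs), r2_sum = r2_sum,
      detectable_or = detectable_or(power, n, case_fraction, r2_sum, alpha),
      power = power
    )
  })
}
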
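#' Convert a log odds ratio and its SE to OR, 95% CI and p-value
#'
#' @param beta Log odds ratio(s).
#' @param se Standard error(s), strictly positive.
#' @return A tibble with columns `or`, `ci_low`, `ci_high`, `pvalue`
#'   (two-sided normal; 95% CI uses the 1.96 multiplier).
#' @export
#' @examples
#' to_odds_ratio(0.0385, 0.0432)
to_odds_ratio <- function(beta, se) {
  if (any(!is.finite(se) | se <= 0)) abort("se must be strictly positive")
  tibble::tibble(
    or = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    pvalue = 2 * pnorm(-abs(beta / se))
  )
}

# vectorised per-SNP Wald ratio; first-order delta SE by default
wald_ratio_stats <- function(bx, by, se_x, se_y, second_order = FALSE) {
  if (any(bx == 0)) abort("Wald ratio undefined for zero exposure beta")
  beta <- by / bx
  se <- if (second_order) {
    sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
  } else {
    se_y / abs(bx)
  }
  list(beta = beta, se = se)
}

#' Per-SNP Wald ratio estimates
#'
#' The causal log-OR per SD of exposure from a single instrument:
#' `by / bx`, with first-order delta-method SE `se_y / |bx|` (a
#' second-order SE incorporating the exposure uncertainty is available).
#'
#' @param dat Harmonized instruments (see [harmonize()]).
#' @param second_order Use the second-order delta SE (adds the `se_x`
#'   contribution); default `FALSE`, standard with strong instruments.
#' @return A tibble with one row per SNP: `rsid`, `beta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `pvalue`.
#' @export
mr_wald_ratio <- function(dat, second_order = FALSE) {
  dat <- check_harmonized(dat, 1, "mr_wald_ratio")
  w <- wald_ratio_stats(dat$bx, dat$by, dat$se_x, dat$se_y, second_order)
  dplyr::bind_cols(
    tibble::tibble(rsid = dat$rsid, beta = w$beta, se = w$se),
    to_odds_ratio(w$beta, w$se)
  )
}

#' Cochran's Q heterogeneity statistic across Wald ratios
#'
#' `Q = sum_j w_j (ratio_j - beta_hat)^2` with IVW weights
#' `w_j = bx_j^2 / se_yj^2`; `df = J - 1`.
#'
#' @param dat Harmonized instruments (at least 2).
#' @param beta_hat Pooled log-OR the ratios are compared against; defaults to
#'   the fixed-effect IVW estimate of `dat`.
#' @return A one-row tibble: `q_stat`, `q_df`, `q_pvalue` (upper-tail
#'   chi-squared).
#' @export
cochran_q <- function(dat, beta_hat = NULL) {
  dat <- check_harmonized(dat, 2, "cochran_q")
  ratios <- dat$by / dat$bx
  w <- dat$bx^2 / dat$se_y^2
  if (is.null(beta_hat)) beta_hat <- sum(w * ratios) / sum(w)
  q <- sum(w * (ratios - beta_hat)^2)
  df <- nrow(dat) - 1L
  tibble::tibble(
    q_stat = q, q_df = df, q_pvalue = pchisq(q, df, lower.tail = FALSE)
  )
}

# constructor for fitted MR objects
new_mr_fit <- function(method, dat, beta, se, n_snp,
                       q_stat = NA_real_, q_df = NA_integer_,
                       egger_intercept = NA_real_,
                       egger_intercept_se = NA_real_,
                       egger_intercept_p = NA_real_,
                       meta = list()) {
  orci <- to_odds_ratio(beta, se)
  structure(
    list(
      method = method,
      exposure = attr(dat, "exposure") %||% NA_character_,
      n_snp = n_snp,
      beta = beta, se = se,
      or = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high,
      pvalue = orci$pvalue,
      q_stat = q_stat, q_df = q_df,
      egger_intercept = egger_intercept,
      egger_intercept_se = egger_intercept_se,
      egger_intercept_p = egger_intercept_p,
      meta = meta,
      data = tibble::as_tibble(dat)
    ),
    class = "mr_fit"
  )
}

#' Inverse-variance-weighted MR estimate
#'
#' Pools the per-SNP Wald ratios with weights `w_j = bx_j^2 / se_yj^2`
#' (equivalently, weighted regression of `by` on `bx` through the origin).
#' The fixed-effect SE is `(sum w_j)^(-1/2)`; the multiplicative
#' random-effects SE (the default, standard in two-sample MR) multiplies it
#' by `max(1, sqrt(Q / (J - 1)))` so that under-dispersion never shrinks the
#' SE. Point estimates are identical between the two. A single instrument
#' reduces to the Wald ratio.
#'
#' @param dat Harmonized instruments.
#' @param effects_model `"mre"` (multiplicative random effects, default) or
#'   `"fe"` (fixed effect).
#' @return An object of class `mr_fit`; see [tidy.mr_fit()] and
#'   [glance.mr_fit()].
#' @export
#' @examples
#' harmonize(liberal_set(iron_associations(), "iron"), als_associations()) |>
#'   mr_ivw() |>
#'   glance()
mr_ivw <- function(dat, effects_model = c("mre", "fe")) {
  effects_model <- match.arg(effects_model)
  dat <- check_harmonized(dat, 1, "mr_ivw")
  J <- nrow(dat)
  if (any(dat$bx == 0)) abort("IVW undefined with a zero exposure beta")
  ratios <- dat$by / dat$bx
  w <- dat$bx^2 / dat$se_y^2
  beta <- sum(w * ratios) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  if (J >= 2) {
    qq <- cochran_q(dat, beta_hat = beta)
    q_stat <- qq$q_stat
    q_df <- qq$q_df
    scale <- if (effects_model == "mre") max(1, sqrt(q_stat / q_df)) else 1
  } else {
    q_stat <- NA_real_
    q_df <- NA_integer_
    scale <- 1
  }
  new_mr_fit(
    method = if (effects_model == "mre") "ivw_mre" else "ivw_fe",
    dat = dat, beta = beta, se = se_fe * scale, n_snp = J,
    q_stat = q_stat, q_df = q_df,
    meta = list(effects_model = effects_model)
  )
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects with
#' an unconstrained intercept, weights `1 / se_yj^2`, after orienting every
#' instrument to a non-negative exposure beta (joint sign flip of `bx`, `by`;
#' the fit is therefore invariant to allele coding). The slope estimates the
#' causal effect under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy. SEs are scaled by `max(1, sigma_hat)` where
#' `sigma_hat^2` is the weighted residual mean square on `J - 2` df (no
#' deflation below the fixed-effect SE). P-values for slope and intercept
#' use, by default, a t reference distribution on `J - 2` df, as in the
#' original MR-Egger formulation — with a handful of instruments the normal
#' reference is anti-conservative; `dist = "normal"` selects the two-sided
#' normal test instead. Confidence intervals use the 1.96 multiplier either
#' way, matching the reporting convention of the rest of the package.
#'
#' @param dat Harmonized instruments (at least 3).
#' @param dist Reference distribution for the slope and intercept tests:
#'   `"t"` (default, `J - 2` df) or `"normal"`.
#' @return An `mr_fit` whose `egger_intercept*` fields carry the pleiotropy
#'   intercept, its SE and p-value.
#' @export
mr_egger <- function(dat, dist = c("t", "normal")) {
  dist <- match.arg(dist)
  dat <- check_harmonized(dat, 3, "mr_egger")
  if (any(dat$bx == 0)) abort("MR-Egger orientation undefined for bx = 0")
  J <- nrow(dat)
  s <- sign(dat$bx)
  x <- dat$bx * s
  y <- dat$by * s
  w <- 1 / dat$se_y^2
  W <- sum(w)
  mx <- sum(w * x) / W
  my <- sum(w * y) / W
  sxx <- sum(w * (x - mx)^2)
  if (sxx <= 0) abort("exposure betas are constant; Egger slope undefined")
  sxy <- sum(w * (x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  sigma2 <- sum(w * resid^2) / (J - 2)
  infl <- max(1, sqrt(sigma2))
  se_slope <- sqrt(1 / sxx) * infl
  se_int <- sqrt(1 / W + mx^2 / sxx) * infl
  pfun <- if (dist == "t") {
    function(z) 2 * stats::pt(-abs(z), df = J - 2)
  } else {
    function(z) 2 * pnorm(-abs(z))
  }
  qq <- cochran_q(dat)
  fit <- new_mr_fit(
    method = "egger", dat = dat, beta = slope, se = se_slope, n_snp = J,
    q_stat = qq$q_stat, q_df = qq$q_df,
    egger_intercept = intercept,
    egger_intercept_se = se_int,
    egger_intercept_p = pfun(intercept / se_int),
    meta = list(sigma_hat = sqrt(sigma2), dist = dist)
  )
  fit$pvalue <- pfun(slope / se_slope)
  fit
}

# weighted-median point estimate from ratios and weights
weighted_median_point <- function(ratios, w) {
  ord <- order(ratios)
  b <- ratios[ord]
  p <- w[ord] / sum(w)
  s <- cumsum(p) - p / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' The weighted 50th percentile of the ordered Wald ratios (linear
#' interpolation of the cumulative weight midpoints), consistent when at
#' least half the weight comes from valid instruments. The SE is the
#' standard deviation of the estimate over parametric-bootstrap draws
#' (`bx*, by*` resampled from normals centred at the observed effects with
#' the observed SEs), under a fixed seed.
#'
#' @param dat Harmonized instruments (at least 3).
#' @param n_boot Bootstrap replicates; default 1000.
#' @param seed RNG seed for the bootstrap; default 0, recorded in the fit's
#'   metadata. The global RNG state is left untouched.
#' @return An `mr_fit`.
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed = 0) {
  dat <- check_harmonized(dat, 3, "mr_weighted_median")
  if (any(dat$bx == 0)) abort("weighted median undefined with bx = 0")
  J <- nrow(dat)
  ratios <- dat$by / dat$bx
  w <- dat$bx^2 / dat$se_y^2
  est <- weighted_median_point(ratios, w)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx_s <- rnorm(J, dat$bx, dat$se_x)
      by_s <- rnorm(J, dat$by, dat$se_y)
      bx_s[bx_s == 0] <- .Machine$double.eps
      weighted_median_point(by_s / bx_s, bx_s^2 / dat$se_y^2)
    }, numeric(1))
  })
  new_mr_fit(
    method = "weighted_median", dat = dat, beta = est, se = sd(boot),
    n_snp = J, meta = list(n_boot = n_boot, seed = seed)
  )
}

#' @describeIn mr_ivw Fixed-effect IVW shortcut.
#' @export
mr_ivw_fe <- function(dat) mr_ivw(dat, effects_model = "fe")

#' Tidy an MR fit into per-term estimates
#'
#' Broom-style: one row per model term on the log-OR scale (for MR-Egger,
#' both the causal slope and the pleiotropy intercept).
#'
#' @param x An `mr_fit`.
#' @param exponentiate Report `estimate` and confidence bounds on the OR
#'   scale; default `FALSE`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.mr_fit <- function(x, exponentiate = FALSE, ...) {
  out <- tibble::tibble(
    term = "causal_effect",
    estimate = x$beta, std.error = x$se,
    statistic = x$beta / x$se, p.value = x$pvalue,
    conf.low = x$beta - 1.96 * x$se, conf.high = x$beta + 1.96 * x$se
  )
  if (!is.na(x$egger_intercept)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "pleiotropy_intercept",
      estimate = x$egger_intercept, std.error = x$egger_intercept_se,
      statistic = x$egger_intercept / x$egger_intercept_se,
      p.value = x$egger_intercept_p,
      conf.low = x$egger_intercept - 1.96 * x$egger_intercept_se,
      conf.high = x$egger_intercept + 1.96 * x$egger_intercept_se
    ))
  }
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' One-row summary of an MR fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `exposure`, `n_snp`, `beta`, `se`,
#'   `or`, `ci_low`, `ci_high`, `pvalue`, `q_stat`, `q_df`,
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`.
#' @export
glance.mr_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    exposure = x$exposure,
    n_snp = x$n_snp,
    beta = x$beta, se = x$se,
    or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
    pvalue = x$pvalue,
    q_stat = x$q_stat, q_df = as.integer(x$q_df),
    egger_intercept = x$egger_intercept,
    egger_intercept_se = x$egger_intercept_se,
    egger_intercept_p = x$egger_intercept_p
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("<mr_fit> ", x$method,
      if (!is.na(x$exposure)) paste0(" [", x$exposure, "]"), "\n", sep = "")
  cat(sprintf(
    "  %d SNP(s): OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$n_snp, x$or, x$ci_low, x$ci_high, x$pvalue
  ))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  Cochran Q = %.3f on %d df\n", x$q_stat, x$q_df))
  }
  if (!is.na(x$egger_intercept)) {
    cat(sprintf(
      "  Egger intercept %.4f (SE %.4f), p = %.3g\n",
      x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p
    ))
  }
  invisible(x)
}
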
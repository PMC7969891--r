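#' MR-PRESSO: global heterogeneity and per-SNP outlier test
#'
#' Pleiotropy residual sum and outlier test. For each SNP the expected
#' outcome effect is taken from the leave-one-out IVW slope fitted on the
#' remaining instruments; the observed residual sum of squares
#' `RSS = sum_j r_j^2 / se_yj^2` (with `r_j = by_j - bx_j * slope_(-j)`) is
#' compared against its parametric null distribution: in each of `n_sim`
#' replicates `bx* ~ N(bx, se_x)` and `by* ~ N(bx * slope_(-j), se_y)` are
#' drawn, the leave-one-out slopes are refitted on the simulated data, and
#' RSS* recomputed. The global p-value is `(1 + #\{RSS* >= RSS\}) / (n_sim +
#' 1)`. Each SNP's weighted squared residual is compared against its own
#' simulated distribution and Bonferroni-adjusted (multiplied by J, capped at
#' 1). As in the published two-stage procedure, the outlier test is applied
#' only when the global test is significant at `alpha`: SNPs with adjusted p
#' below `alpha` are then outliers, and the outlier-corrected IVW estimate
#' on the remaining SNPs is reported. Set `outlier_gate = FALSE` to flag
#' outliers regardless of the global test.
#'
#' @param dat Harmonized instruments (at least 4).
#' @param n_sim Simulation replicates, at least 1000; default 5000.
#' @param alpha Significance level for the global gate and the outlier test
#'   on the adjusted p; default 0.05.
#' @param outlier_gate Run the outlier test only when `global_p < alpha`
#'   (default `TRUE`, the published two-stage behaviour).
#' @param seed RNG seed; the global RNG state is left untouched.
#' @param effects_model Effects model for the corrected IVW estimate.
#' @return An object of class `mr_presso`: `global_rss`, `global_p`,
#'   `per_snp` (tibble: `rsid`, `rss_obs`, `pvalue`, `p_adjusted`,
#'   `outlier`), `outliers`, `corrected` (an `mr_fit`, `NULL` when no
#'   outlier), `n_sim`, `alpha`, `seed`. Has [tidy()] and [glance()]
#'   methods.
#' @export
#' @examples
#' harmonize(liberal_set(iron_associations(), "transferrin"),
#'           als_associations()) |>
#'   mr_presso(n_sim = 1000, seed = 1)
mr_presso <- function(dat, n_sim = 5000, alpha = 0.05, seed = 0,
                      effects_model = c("mre", "fe"), outlier_gate = TRUE) {
  effects_model <- match.arg(effects_model)
  dat <- check_harmonized(dat, 4, "mr_presso")
  if (n_sim < 1000) abort("n_sim must be at least 1000")
  J <- nrow(dat)
  bx <- dat$bx
  by <- dat$by
  se_x <- dat$se_x
  se_y <- dat$se_y
  w <- 1 / se_y^2

  # leave-one-out IVW slopes via sum subtraction
  a <- bx * by * w
  b <- bx^2 * w
  slope_loo <- (sum(a) - a) / (sum(b) - b)
  r <- by - bx * slope_loo
  comp_obs <- w * r^2
  rss_obs <- sum(comp_obs)

  sim <- withr::with_seed(seed, {
    bx_s <- matrix(rnorm(n_sim * J, rep(bx, each = n_sim),
                         rep(se_x, each = n_sim)), n_sim, J)
    mu_y <- bx * slope_loo
    by_s <- matrix(rnorm(n_sim * J, rep(mu_y, each = n_sim),
                         rep(se_y, each = n_sim)), n_sim, J)
    wm <- matrix(w, n_sim, J, byrow = TRUE)
    a_s <- bx_s * by_s * wm
    b_s <- bx_s^2 * wm
    slope_s <- (rowSums(a_s) - a_s) / (rowSums(b_s) - b_s)
    comp_s <- wm * (by_s - bx_s * slope_s)^2
    list(rss = rowSums(comp_s), comp = comp_s)
  })

  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  p_raw <- colMeans(sweep(sim$comp, 2, comp_obs, `>=`))
  p_adj <- pmin(1, p_raw * J)
  outlier <- if (outlier_gate && global_p >= alpha) {
    rep(FALSE, J)
  } else {
    p_adj < alpha
  }
  per_snp <- tibble::tibble(
    rsid = dat$rsid, rss_obs = comp_obs,
    pvalue = p_raw, p_adjusted = p_adj, outlier = outlier
  )
  corrected <- if (any(outlier)) {
    fit <- mr_ivw(dat[!outlier, , drop = FALSE], effects_model)
    fit$method <- "presso_corrected"
    fit
  } else {
    NULL
  }
  structure(
    list(
      exposure = attr(dat, "exposure") %||% NA_character_,
      global_rss = rss_obs, global_p = global_p,
      per_snp = per_snp, outliers = dat$rsid[outlier],
      corrected = corrected,
      n_sim = n_sim, alpha = alpha, seed = seed,
      data = dat
    ),
    class = "mr_presso"
  )
}

#' @describeIn mr_presso Per-SNP outlier table.
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @export
tidy.mr_presso <- function(x, ...) x$per_snp

#' @describeIn mr_presso One-row global summary (`global_rss`, `global_p`,
#'   `n_outliers`, and the corrected estimate when outliers were removed).
#' @export
glance.mr_presso <- function(x, ...) {
  corr <- if (is.null(x$corrected)) {
    tibble::tibble(corrected_beta = NA_real_, corrected_se = NA_real_)
  } else {
    tibble::tibble(
      corrected_beta = x$corrected$beta, corrected_se = x$corrected$se
    )
  }
  dplyr::bind_cols(
    tibble::tibble(
      exposure = x$exposure,
      n_snp = nrow(x$per_snp),
      global_rss = x$global_rss, global_p = x$global_p,
      n_outliers = length(x$outliers),
      n_sim = x$n_sim, seed = x$seed
    ),
    corr
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("<mr_presso> global RSS ", format(x$global_rss, digits = 4),
      ", p = ", format(x$global_p, digits = 3),
      " (", x$n_sim, " simulations)\n", sep = "")
  if (length(x$outliers) == 0) {
    cat("  no outlier variants at alpha =", x$alpha, "\n")
  } else {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat(sprintf(
      "  corrected IVW: OR %.3f (95%% CI %.3f-%.3f)\n",
      x$corrected$or, x$corrected$ci_low, x$corrected$ci_high
    ))
  }
  invisible(x)
}
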
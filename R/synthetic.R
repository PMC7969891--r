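#' Simulate a two-sample MR summary dataset with known ground truth
#'
#' Generates paired exposure/outcome summary statistics under a linear causal
#' model on the scales of the packaged data (exposure in SD units, outcome in
#' log-odds): true per-SNP exposure effects `gamma_j ~ U(bx_range)`, direct
#' (pleiotropic) outcome effects `alpha_j ~ N(pleiotropy_mean,
#' pleiotropy_sd)`, observed `bx_j ~ N(gamma_j, se_x)` and `by_j ~ N(theta *
#' gamma_j + alpha_j, se_y)`. Standard errors follow the GWAS sampling
#' formulas `se_x = 1 / sqrt(2 f (1 - f) n_exp)` and `se_y = 1 / sqrt(2 f (1
#' - f) n_out cf (1 - cf))` with `f ~ U(eaf_range)`, so they are consistent
#' with the stated sample sizes. When `inside_violation` is nonzero,
#' pleiotropy is correlated with instrument strength through a Gaussian
#' copula (violating the InSIDE assumption by that correlation). An optional
#' outlier shifts one SNP's outcome effect by `outlier_shift` outcome SEs.
#'
#' @param n_snp Number of instruments.
#' @param theta True causal effect (log-odds of outcome per SD of exposure).
#' @param bx_range Range of true exposure effects (per SD); default
#'   `c(0.05, 0.3)`, spanning the packaged instruments' magnitudes.
#' @param n_exp,n_out Exposure and outcome GWAS sizes; defaults mirror the
#'   source studies (48,972 and 80,610).
#' @param case_fraction Outcome case fraction; default 20,806 / 80,610.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the direct effects
#'   (both 0 = all instruments valid).
#' @param inside_violation Copula correlation between instrument strength
#'   and pleiotropy, in \[-1, 1\]; 0 preserves InSIDE.
#' @param eaf_range Range of simulated allele frequencies.
#' @param outlier_idx,outlier_shift Index of a SNP receiving an additive
#'   outcome shift of `outlier_shift * se_y` (scale-free); `NULL` for none.
#' @param seed RNG seed; `NULL` uses (and advances) the current RNG state.
#' @return A tibble in harmonized-instrument format (`rsid`, `bx`, `se_x`,
#'   `eaf_x`, `by`, `se_y`, `eaf_y`, ...), directly consumable by the
#'   estimators. The generating parameters, including the latent `gamma` and
#'   `alpha` vectors, are stored in the `"config"` attribute.
#' @export
#' @examples
#' sim <- simulate_mr_dataset(n_snp = 50, theta = 0.1, seed = 1)
#' glance(mr_ivw(sim))
simulate_mr_dataset <- function(n_snp = 30, theta = 0,
                                bx_range = c(0.05, 0.3),
                                n_exp = 48972, n_out = 80610,
                                case_fraction = 20806 / 80610,
                                pleiotropy_mean = 0, pleiotropy_sd = 0,
                                inside_violation = 0,
                                eaf_range = c(0.1, 0.9),
                                outlier_idx = NULL, outlier_shift = 0,
                                seed = NULL) {
  if (n_snp < 1) abort("n_snp must be at least 1")
  if (length(bx_range) != 2 || bx_range[1] > bx_range[2] || bx_range[1] <= 0) {
    abort("bx_range must be an increasing positive interval")
  }
  if (abs(inside_violation) > 1) abort("inside_violation must lie in [-1, 1]")
  if (any(eaf_range <= 0 | eaf_range >= 1) || eaf_range[1] > eaf_range[2]) {
    abort("eaf_range must lie inside (0, 1)")
  }
  gen <- function() {
    gamma <- runif(n_snp, bx_range[1], bx_range[2])
    eaf <- runif(n_snp, eaf_range[1], eaf_range[2])
    se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * n_exp)
    se_y <- 1 / sqrt(
      2 * eaf * (1 - eaf) * n_out * case_fraction * (1 - case_fraction)
    )
    z <- rnorm(n_snp)
    if (inside_violation != 0 && diff(bx_range) > 0) {
      # Gaussian copula: map gamma through its uniform CDF to a normal score
      z_g <- qnorm(pmin(pmax(
        (gamma - bx_range[1]) / diff(bx_range), 1e-12), 1 - 1e-12))
      z <- inside_violation * z_g + sqrt(1 - inside_violation^2) * z
    }
    alpha <- pleiotropy_mean + pleiotropy_sd * z
    bx <- rnorm(n_snp, gamma, se_x)
    by <- rnorm(n_snp, theta * gamma + alpha, se_y)
    if (!is.null(outlier_idx)) {
      stopifnot(outlier_idx >= 1, outlier_idx <= n_snp)
      by[outlier_idx] <- by[outlier_idx] + outlier_shift * se_y[outlier_idx]
    }
    list(gamma = gamma, alpha = alpha, eaf = eaf,
         se_x = se_x, se_y = se_y, bx = bx, by = by)
  }
  d <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- tibble::tibble(
    rsid = sprintf("snp%03d", seq_len(n_snp)),
    effect_allele = "A", other_allele = "G",
    bx = d$bx, se_x = d$se_x, eaf_x = d$eaf, pval_x = NA_real_,
    by = d$by, se_y = d$se_y, eaf_y = d$eaf, pval_y = NA_real_,
    palindromic = FALSE, flipped = FALSE
  )
  attr(out, "exposure") <- "synthetic"
  attr(out, "config") <- list(
    n_snp = n_snp, theta = theta, bx_range = bx_range,
    n_exp = n_exp, n_out = n_out, case_fraction = case_fraction,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    inside_violation = inside_violation, eaf_range = eaf_range,
    outlier_idx = outlier_idx, outlier_shift = outlier_shift,
    seed = seed, gamma = d$gamma, alpha = d$alpha
  )
  out
}

#' Write a simulated dataset as an exposure/outcome TSV pair
#'
#' Emits two summary-statistics files in the format [read_gwas()] ingests,
#' so synthetic data can flow through the same pipeline as real exports.
#'
#' @param sim A dataset from [simulate_mr_dataset()].
#' @param exposure_path,outcome_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_simulated_pair <- function(sim, exposure_path, outcome_path) {
  sim <- tibble::as_tibble(sim)
  cfg <- attr(sim, "config")
  expo <- tibble::tibble(
    rsid = sim$rsid, effect_allele = sim$effect_allele,
    other_allele = sim$other_allele, eaf = sim$eaf_x,
    beta = sim$bx, se = sim$se_x,
    pvalue = pmax(2 * pnorm(-abs(sim$bx / sim$se_x)), .Machine$double.xmin),
    n = cfg$n_exp %||% NA_real_, trait = "synthetic_exposure"
  )
  outc <- tibble::tibble(
    rsid = sim$rsid, effect_allele = sim$effect_allele,
    other_allele = sim$other_allele, eaf = sim$eaf_y,
    beta = sim$by, se = sim$se_y,
    pvalue = pmax(2 * pnorm(-abs(sim$by / sim$se_y)), .Machine$double.xmin),
    n = cfg$n_out %||% NA_real_, trait = "synthetic_outcome"
  )
  readr::write_tsv(expo, exposure_path)
  readr::write_tsv(outc, outcome_path)
  invisible(c(exposure_path, outcome_path))
}

#' Calibration experiment over a grid of generator configurations
#'
#' Repeatedly simulates datasets from each configuration and summarises, per
#' estimator: the mean estimate, bias and RMSE against the true causal
#' effect, the rejection rate of the two-sided test at `alpha`, and
#' Monte-Carlo standard errors for both. For MR-Egger the pleiotropy
#' intercept is summarised as a separate `egger_intercept` row (its "truth"
#' is the configured `pleiotropy_mean`); for MR-PRESSO the row reports the
#' global-test rejection rate, with estimate columns `NA`.
#'
#' @param configs A list of configuration lists: arguments for
#'   [simulate_mr_dataset()] (anything omitted uses that function's
#'   defaults). Seeds are managed by the experiment, so configs should not
#'   set `seed`.
#' @param n_rep Replicates per configuration, at least 100.
#' @param alpha Test size for the rejection rates; default 0.05.
#' @param methods Estimators to evaluate: subset of `"ivw"`, `"egger"`,
#'   `"wm"`, `"presso"`; default IVW and Egger.
#' @param seed Master seed; one RNG stream drives all replicates.
#' @param effects_model IVW variant evaluated; default the package default
#'   (multiplicative random effects).
#' @param presso_n_sim,wm_n_boot Inner simulation sizes for MR-PRESSO and
#'   the weighted-median bootstrap.
#' @return A tibble with one row per configuration x summarised quantity:
#'   `config_id`, `theta`, `pleiotropy_mean`, `n_snp`, `method`, `truth`,
#'   `n_rep`, `mean_estimate`, `bias`, `rmse`, `mc_se` (of the mean
#'   estimate), `reject_rate`, `reject_mc_se`.
#' @export
#' @examples
#' run_calibration_experiment(
#'   list(list(theta = 0, n_snp = 10)), n_rep = 100, seed = 1
#' )
run_calibration_experiment <- function(configs, n_rep = 500, alpha = 0.05,
                                       methods = c("ivw", "egger"),
                                       seed = 1,
                                       effects_model = c("mre", "fe"),
                                       presso_n_sim = 1000,
                                       wm_n_boot = 500) {
  effects_model <- match.arg(effects_model)
  methods <- match.arg(methods, c("ivw", "egger", "wm", "presso"),
                       several.ok = TRUE)
  if (n_rep < 100) abort("n_rep must be at least 100")
  if (!is.list(configs) || length(configs) == 0) {
    abort("configs must be a nonempty list of configuration lists")
  }
  withr::with_seed(seed, {
    purrr::map_dfr(seq_along(configs), function(ci) {
      cfg <- configs[[ci]]
      reps <- purrr::map(seq_len(n_rep), function(r) {
        sim <- do.call(simulate_mr_dataset, cfg)
        out <- list()
        if ("ivw" %in% methods) {
          f <- mr_ivw(sim, effects_model)
          out$ivw <- c(est = f$beta, rej = as.numeric(f$pvalue < alpha))
        }
        if ("egger" %in% methods) {
          f <- mr_egger(sim)
          out$egger <- c(est = f$beta, rej = as.numeric(f$pvalue < alpha))
          out$egger_intercept <- c(
            est = f$egger_intercept,
            rej = as.numeric(f$egger_intercept_p < alpha)
          )
        }
        if ("wm" %in% methods) {
          f <- mr_weighted_median(sim, n_boot = wm_n_boot,
                                  seed = sample.int(2^30, 1))
          out$wm <- c(est = f$beta, rej = as.numeric(f$pvalue < alpha))
        }
        if ("presso" %in% methods) {
          f <- mr_presso(sim, n_sim = presso_n_sim, alpha = alpha,
                         seed = sample.int(2^30, 1))
          out$presso_global <- c(
            est = NA_real_, rej = as.numeric(f$global_p < alpha)
          )
        }
        out
      })
      theta <- cfg$theta %||% 0
      mu_a <- cfg$pleiotropy_mean %||% 0
      purrr::map_dfr(names(reps[[1]]), function(m) {
        est <- vapply(reps, function(r) r[[m]][["est"]], numeric(1))
        rej <- vapply(reps, function(r) r[[m]][["rej"]], numeric(1))
        truth <- if (m == "egger_intercept") mu_a else theta
        rate <- mean(rej)
        tibble::tibble(
          config_id = ci, theta = theta, pleiotropy_mean = mu_a,
          n_snp = cfg$n_snp %||% 30, method = m, truth = truth,
          n_rep = n_rep,
          mean_estimate = mean(est),
          bias = mean(est) - truth,
          rmse = sqrt(mean((est - truth)^2)),
          mc_se = stats::sd(est) / sqrt(n_rep),
          reject_rate = rate,
          reject_mc_se = sqrt(rate * (1 - rate) / n_rep)
        )
      })
    })
  })
}
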
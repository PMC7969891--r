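#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of MR results
#'
#' Odds ratios with 95% confidence intervals, one panel per exposure and one
#' row per method — the tabular layout of a multi-method forest plot.
#'
#' @param object An `mr_analysis` from [run_full_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_analysis <- function(object, ...) {
  dat <- object$results
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$or, y = .data$method)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.15
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~exposure, scales = "free_x") +
    ggplot2::labs(
      x = "OR for ALS per SD increase in biomarker (95% CI)", y = NULL,
      title = paste0("MR estimates (", object$manifest$mode, " analysis)")
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of per-SNP Wald ratios with the pooled estimate
#'
#' @param single_snp A tibble from [mr_single_snp()].
#' @param pooled Optional `mr_fit` whose pooled estimate is appended as the
#'   bottom row.
#' @return A ggplot object.
#' @export
plot_forest <- function(single_snp, pooled = NULL) {
  dat <- dplyr::select(
    tibble::as_tibble(single_snp), "rsid", "or", "ci_low", "ci_high"
  )
  if (!is.null(pooled)) {
    g <- glance(pooled)
    dat <- dplyr::bind_rows(dat, tibble::tibble(
      rsid = paste0("All (", g$method, ")"),
      or = g$or, ci_low = g$ci_low, ci_high = g$ci_high
    ))
  }
  dat$rsid <- factor(dat$rsid, levels = rev(dat$rsid))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$rsid)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.15
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Leave-one-out sensitivity plot
#'
#' @param loo A tibble from [mr_leave_one_out()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  dat <- tibble::as_tibble(loo)
  dat$omitted_rsid <- factor(dat$omitted_rsid, levels = rev(dat$omitted_rsid))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$omitted_rsid)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.15
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "IVW OR (95% CI) with SNP omitted", y = "Omitted SNP") +
    ggplot2::theme_minimal()
}
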
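#' Instrument records for one biomarker under a selection mode
#'
#' Conservative mode restricts to the SNPs concordant across all four
#' biomarkers ([conservative_set()]), taking the betas for the requested
#' biomarker; liberal mode returns the biomarker's own genome-wide
#' significant SNPs ([liberal_set()]).
#'
#' @param exposure_data Long-format exposure records covering the four
#'   biomarkers.
#' @param mode `"conservative"` or `"liberal"`.
#' @param biomarker Biomarker label.
#' @return A tibble of association records for the biomarker.
#' @export
select_instrument_records <- function(exposure_data,
                                      mode = c("conservative", "liberal"),
                                      biomarker) {
  mode <- match.arg(mode)
  if (mode == "conservative") {
    cons <- conservative_set(exposure_data)
    recs <- tibble::as_tibble(exposure_data) |>
      dplyr::filter(.data$trait == biomarker, .data$rsid %in% cons$rsid)
  } else {
    recs <- liberal_set(exposure_data, biomarker)
  }
  attr(recs, "mode") <- mode
  recs
}

#' Run the full MR analysis of iron-status biomarkers on ALS
#'
#' Orchestrates the complete analysis for each requested biomarker:
#' instrument selection (conservative concordance rule or liberal
#' per-biomarker sets), strength statistics (per-SNP R-squared and F, set
#' totals), harmonization against the outcome records (with a drop/flip
#' log), the requested estimators, and leave-one-out and single-SNP
#' diagnostics. Defaults reproduce the packaged iron-status / ALS analysis;
#' supply `exposure_data` / `outcome_data` to run the same pipeline on other
#' summary statistics.
#'
#' @param mode `"conservative"` or `"liberal"`.
#' @param exposures Biomarker subset; default all four.
#' @param methods Estimators to run: subset of `"ivw"`, `"egger"`, `"wm"`,
#'   `"presso"`. Methods whose minimum instrument count exceeds the
#'   harmonized set are skipped with a note in the manifest.
#' @param effects_model IVW variant, `"mre"` (default) or `"fe"`.
#' @param wm_n_boot Weighted-median bootstrap replicates.
#' @param presso_n_sim MR-PRESSO simulation replicates.
#' @param seed Seed driving the weighted-median bootstrap and MR-PRESSO.
#' @param exposure_data,outcome_data Association records; default the
#'   packaged GIS and AVS tables.
#' @param exclude_snps rsIDs removed from every instrument set before
#'   harmonization (e.g. `"rs1800562"` for the pleiotropy-motivated
#'   sensitivity re-run).
#' @param eaf_window Palindrome ambiguity half-width for [harmonize()].
#' @param out_dir Optional directory; when given, results, strength,
#'   leave-one-out, single-SNP and harmonization-log TSVs plus a JSON run
#'   manifest are written there.
#' @return An object of class `mr_analysis`: a list of tibbles `results`,
#'   `strength`, `leave_one_out`, `single_snp`, `harmonization`, and a
#'   `manifest` list echoing the configuration. `tidy()` returns `results`;
#'   `glance()` one row per exposure; `autoplot()` a forest plot.
#' @export
#' @examples
#' fit <- run_full_analysis("conservative", methods = "ivw")
#' tidy(fit)
run_full_analysis <- function(mode = c("conservative", "liberal"),
                              exposures = IRON_BIOMARKERS,
                              methods = c("ivw", "egger", "wm", "presso"),
                              effects_model = c("mre", "fe"),
                              wm_n_boot = 1000, presso_n_sim = 5000,
                              seed = 0,
                              exposure_data = NULL, outcome_data = NULL,
                              exclude_snps = NULL, eaf_window = 0.08,
                              out_dir = NULL) {
  mode <- match.arg(mode)
  effects_model <- match.arg(effects_model)
  methods <- match.arg(methods, c("ivw", "egger", "wm", "presso"),
                       several.ok = TRUE)
  bad <- setdiff(exposures, IRON_BIOMARKERS)
  if (length(bad) > 0) {
    abort(paste0("unknown exposure(s): ", paste(bad, collapse = ", ")))
  }
  exposure_data <- exposure_data %||% iron_associations()
  outcome_data <- outcome_data %||% als_associations()

  results <- list()
  strength <- list()
  loo <- list()
  singles <- list()
  harm_log <- list()
  notes <- character(0)

  for (bm in exposures) {
    recs <- select_instrument_records(exposure_data, mode, bm)
    if (!is.null(exclude_snps)) {
      recs <- dplyr::filter(recs, !.data$rsid %in% exclude_snps)
    }
    if (nrow(recs) == 0) {
      abort(paste0("empty instrument set for ", bm, " after selection"))
    }
    st <- instrument_strength(recs)
    strength[[bm]] <- st |>
      dplyr::select("rsid", "trait", "beta", "eaf", "r2", "f") |>
      dplyr::mutate(
        mode = mode, r2_sum = attr(st, "r2_sum"), f_set = attr(st, "f_set")
      )
    h <- harmonize(recs, outcome_data, eaf_window = eaf_window)
    if (nrow(h) == 0) {
      abort(paste0("empty instrument set for ", bm, " after harmonization"))
    }
    hl <- attr(h, "log")
    hl$exposure <- bm
    harm_log[[bm]] <- hl
    J <- nrow(h)

    res_bm <- list()
    if ("ivw" %in% methods) {
      res_bm$ivw <- glance(mr_ivw(h, effects_model))
    }
    if ("egger" %in% methods) {
      if (J >= 3) {
        res_bm$egger <- glance(mr_egger(h))
      } else {
        notes <- c(notes, paste0(bm, ": MR-Egger skipped (", J, " SNPs < 3)"))
      }
    }
    if ("wm" %in% methods) {
      if (J >= 3) {
        res_bm$wm <- glance(mr_weighted_median(h, wm_n_boot, seed = seed))
      } else {
        notes <- c(notes,
                   paste0(bm, ": weighted median skipped (", J, " SNPs < 3)"))
      }
    }
    if ("presso" %in% methods) {
      if (J >= 4) {
        pres <- mr_presso(h, n_sim = presso_n_sim, seed = seed,
                          effects_model = effects_model)
        g <- glance(pres)
        row <- glance(mr_ivw(h, effects_model))
        row$method <- "presso"
        row$presso_global_p <- g$global_p
        row$presso_n_outliers <- g$n_outliers
        if (!is.null(pres$corrected)) {
          corr <- glance(pres$corrected)
          corr$presso_global_p <- g$global_p
          corr$presso_n_outliers <- g$n_outliers
          row <- dplyr::bind_rows(row, corr)
        }
        res_bm$presso <- row
      } else {
        notes <- c(notes,
                   paste0(bm, ": MR-PRESSO skipped (", J, " SNPs < 4)"))
      }
    }
    if (length(res_bm) > 0) {
      rb <- dplyr::bind_rows(res_bm)
      rb$exposure <- bm
      rb$mode <- mode
      results[[bm]] <- rb
    }
    if (J >= 2) {
      lo <- mr_leave_one_out(h, effects_model)
      lo$exposure <- bm
      lo$mode <- mode
      loo[[bm]] <- lo
    }
    ss <- mr_single_snp(h)
    ss$exposure <- bm
    ss$mode <- mode
    singles[[bm]] <- ss
  }

  out <- structure(
    list(
      results = dplyr::bind_rows(results),
      strength = dplyr::bind_rows(strength),
      leave_one_out = dplyr::bind_rows(loo),
      single_snp = dplyr::bind_rows(singles),
      harmonization = dplyr::bind_rows(harm_log),
      manifest = list(
        package = "ironmr",
        version = as.character(utils::packageVersion("ironmr")),
        mode = mode, exposures = exposures, methods = methods,
        effects_model = effects_model, wm_n_boot = wm_n_boot,
        presso_n_sim = presso_n_sim, seed = seed,
        exclude_snps = exclude_snps, eaf_window = eaf_window,
        notes = notes
      )
    ),
    class = "mr_analysis"
  )
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

write_analysis <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mr_results(x$results, file.path(out_dir, "mr_results.tsv"))
  readr::write_tsv(x$strength, file.path(out_dir, "instrument_strength.tsv"))
  readr::write_tsv(x$leave_one_out, file.path(out_dir, "leave_one_out.tsv"))
  readr::write_tsv(x$single_snp, file.path(out_dir, "single_snp.tsv"))
  readr::write_tsv(x$harmonization, file.path(out_dir, "harmonization_log.tsv"))
  jsonlite::write_json(
    x$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(out_dir)
}

#' @export
tidy.mr_analysis <- function(x, ...) x$results

#' @export
glance.mr_analysis <- function(x, ...) {
  x$results |>
    dplyr::group_by(.data$exposure) |>
    dplyr::summarise(
      mode = .data$mode[1],
      n_methods = dplyr::n_distinct(.data$method),
      n_snp = max(.data$n_snp),
      all_ci_include_null = all(.data$ci_low <= 1 & .data$ci_high >= 1),
      .groups = "drop"
    )
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat("<mr_analysis> mode =", x$manifest$mode, "\n")
  print(dplyr::select(
    x$results, "exposure", "method", "n_snp", "or", "ci_low", "ci_high",
    "pvalue"
  ), n = Inf)
  if (length(x$manifest$notes) > 0) {
    cat("notes:\n")
    for (nt in x$manifest$notes) cat("  -", nt, "\n")
  }
  invisible(x)
}
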
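#' Packaged GIS consortium iron-status associations
#'
#' The 12 SNPs associated with at least one of the four biomarkers of
#' systemic iron status at genome-wide significance (p < 5e-8) in the GIS
#' consortium meta-analysis (N = 48,972 Europeans), exactly as printed in the
#' source table: one row per nonblank biomarker cell (25 rows in total over
#' iron, log-transformed ferritin, transferrin saturation and transferrin).
#' Betas are per SD of the biomarker (ferritin on the log scale); positions
#' are 1-based, build 37. The source table prints no per-cell p-values: a
#' row's presence encodes genome-wide significance for that biomarker, and
#' `pvalue` is `NA`.
#'
#' @param biomarker Optional biomarker label to restrict to: one of
#'   `"iron"`, `"ferritin"`, `"transferrin_saturation"`, `"transferrin"`.
#'   The default returns all 25 rows.
#' @return A tibble of association records (`rsid`, `chrom`, `pos`, `gene`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#'   `trait`), in table order.
#' @export
#' @examples
#' iron_associations("transferrin")  # 9 SNPs
#' iron_associations("iron")         # 5 SNPs
iron_associations <- function(biomarker = NULL) {
  path <- system.file("extdata", "gis_iron_snps.tsv", package = "ironmr")
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      rsid = readr::col_character(),
      pos = readr::col_integer(),
      gene = readr::col_character(),
      effect_allele = readr::col_character(),
      other_allele = readr::col_character(),
      eaf = readr::col_double(),
      trait = readr::col_character(),
      beta = readr::col_double(),
      se = readr::col_double()
    ),
    progress = FALSE
  )
  tab <- dplyr::mutate(tab, pvalue = NA_real_, n = as.numeric(GIS_N))
  tab <- dplyr::select(
    tab, "rsid", "chrom", "pos", "gene", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pvalue", "n", "trait"
  )
  if (!is.null(biomarker)) {
    if (!biomarker %in% IRON_BIOMARKERS) {
      abort(paste0(
        "unknown biomarker '", biomarker, "'; valid labels: ",
        paste(IRON_BIOMARKERS, collapse = ", ")
      ))
    }
    tab <- dplyr::filter(tab, .data$trait == biomarker)
  }
  tab
}

#' Packaged ALS outcome associations for the 12 iron-status SNPs
#'
#' Association estimates of the 12 iron-status instruments with amyotrophic
#' lateral sclerosis from the AVS GWAS meta-analysis (20,806 cases, 59,804
#' controls; 80,610 Europeans), as printed in the source table. Betas are
#' log-odds of ALS per effect allele.
#'
#' @return A tibble of 12 association records with columns `rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#'   `n_cases`, `n_controls`, `trait`.
#' @export
#' @examples
#' als_associations()
als_associations <- function() {
  path <- system.file("extdata", "als_avs_snps.tsv", package = "ironmr")
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      rsid = readr::col_character(),
      effect_allele = readr::col_character(),
      other_allele = readr::col_character(),
      eaf = readr::col_double(),
      beta = readr::col_double(),
      se = readr::col_double(),
      pvalue = readr::col_double()
    ),
    progress = FALSE
  )
  dplyr::mutate(
    tab,
    n = as.numeric(ALS_N),
    n_cases = as.numeric(ALS_CASES),
    n_controls = as.numeric(ALS_CONTROLS),
    trait = "als"
  )
}
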
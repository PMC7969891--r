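#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited summary-statistics file into the association-record
#' format used throughout the package, optionally renaming columns from an
#' external export's header via `column_map`. Rows violating the record
#' invariants (effect-allele frequency outside (0,1), non-positive standard
#' error, identical alleles, blank rsID, non-finite beta, p outside (0,1])
#' are dropped with a row-indexed warning; the rejected rows and the reason
#' for each are kept in the `"rejected"` attribute of the result.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Optional named character vector mapping canonical names
#'   (`rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`,
#'   and optionally `chrom`, `pos`, `n`, `trait`) to the column names used in
#'   the file, or the path to a YAML/JSON file holding such a mapping (see
#'   [read_column_map()]).
#' @param trait,n Optional trait label and GWAS sample size attached to every
#'   record (used when the file does not carry them).
#' @return A tibble of association records in file order, one row per valid
#'   input row, with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, `trait`.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' readr::write_tsv(als_associations()[1:3, 1:7], tsv)
#' read_gwas(tsv, trait = "als", n = 80610)
read_gwas <- function(path, column_map = NULL, trait = NULL, n = NULL) {
  if (!file.exists(path)) {
    abort(paste0("summary-statistics file not found: ", path))
  }
  if (is.character(column_map) && length(column_map) == 1 && file.exists(column_map)) {
    column_map <- read_column_map(column_map)
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0(
        "mapped column(s) absent from header: ",
        paste(missing_src, collapse = ", ")
      ))
    }
    raw <- dplyr::rename(raw, !!!column_map)
  }
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req) > 0) {
    abort(paste0(
      "required column(s) missing: ", paste(missing_req, collapse = ", "),
      " (supply a column_map?)"
    ))
  }
  for (opt in c("eaf", "pvalue", "chrom", "pos", "n", "trait")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA
  }
  out <- tibble::tibble(
    rsid = as.character(raw$rsid),
    chrom = as.character(raw$chrom),
    pos = suppressWarnings(as.integer(raw$pos)),
    effect_allele = toupper(as.character(raw$effect_allele)),
    other_allele = toupper(as.character(raw$other_allele)),
    eaf = as.numeric(raw$eaf),
    beta = as.numeric(raw$beta),
    se = as.numeric(raw$se),
    pvalue = as.numeric(raw$pvalue),
    n = if (is.null(n)) suppressWarnings(as.numeric(raw$n)) else n,
    trait = if (is.null(trait)) as.character(raw$trait) else trait
  )
  validate_associations(out, context = path)
}

#' Validate association records against the record invariants
#'
#' @param records A data frame of association records (see [read_gwas()]).
#' @param context Label used in diagnostics (e.g. the source file).
#' @return The valid rows as a tibble; rejected rows with a `reason` column
#'   are attached as `attr(, "rejected")`. Errors if no row is valid.
#' @export
validate_associations <- function(records, context = "records") {
  records <- tibble::as_tibble(records)
  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(is.na(records$rsid) | !nzchar(records$rsid), "rsid empty")
  reason <- flag(!is.finite(records$beta), "beta not finite")
  reason <- flag(!is.finite(records$se) | records$se <= 0, "se not > 0")
  reason <- flag(
    !is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1),
    "eaf outside (0,1)"
  )
  reason <- flag(
    records$effect_allele == records$other_allele,
    "effect_allele equals other_allele"
  )
  reason <- flag(
    !is.na(records$pvalue) & (records$pvalue <= 0 | records$pvalue > 1),
    "pvalue outside (0,1]"
  )
  bad <- !is.na(reason)
  if (any(bad)) {
    warn(paste0(
      context, ": rejected ", sum(bad), " row(s): ",
      paste0("row ", which(bad), " (", reason[bad], ")", collapse = "; ")
    ))
  }
  kept <- records[!bad, , drop = FALSE]
  if (nrow(kept) == 0) {
    abort(paste0(context, ": no valid association records"))
  }
  rejected <- records[bad, , drop = FALSE]
  rejected$reason <- reason[bad]
  attr(kept, "rejected") <- rejected
  kept
}

#' Read a column mapping from a YAML or JSON config file
#'
#' The file holds a flat mapping from canonical column names to the names in
#' an external GWAS export, e.g. `rsid: SNP`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named character vector usable as `column_map` in [read_gwas()].
#' @export
read_column_map <- function(path) {
  if (!file.exists(path)) abort(paste0("column-map file not found: ", path))
  m <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- vapply(m, as.character, character(1))
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    abort("column map must be a named mapping: canonical_name: file_column")
  }
  out
}

#' Write an MR results table to TSV
#'
#' Writes the fixed column layout used by the analysis pipeline (`exposure`,
#' `mode`, `method`, `nsnp`, `beta`, `se`, `or`, `ci_low`, `ci_high`,
#' `pvalue`, `q`, `egger_intercept`, `egger_intercept_p`), rendering floats
#' with 6 significant digits. Columns absent from `results` are written
#' empty.
#'
#' @param results A data frame of MR results, e.g. the `results` element of
#'   [run_full_analysis()] or rows built with [glance()] on fitted objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    abort("results must contain at least one row")
  }
  cols <- c(
    "exposure", "mode", "method", "nsnp", "beta", "se", "or", "ci_low",
    "ci_high", "pvalue", "q", "egger_intercept", "egger_intercept_p"
  )
  out <- tibble::as_tibble(results)
  if (!"nsnp" %in% names(out) && "n_snp" %in% names(out)) {
    out$nsnp <- out$n_snp
  }
  if (!"q" %in% names(out) && "q_stat" %in% names(out)) out$q <- out$q_stat
  for (col in cols) if (!col %in% names(out)) out[[col]] <- NA
  out <- out[cols]
  num <- vapply(out, is.numeric, logical(1)) & !names(out) %in% "nsnp"
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  readr::write_tsv(out, path, na = "")
  invisible(path)
}
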
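# harmonized fixture instruments for one biomarker under a selection mode
harmonized_fixture <- function(mode = "conservative", biomarker = "iron") {
  harmonize(
    select_instrument_records(iron_associations(), mode, biomarker),
    als_associations()
  )
}

# random harmonized instruments for property tests (valid, no pleiotropy
# structure implied; pure inputs for estimator algebra)
random_instruments <- function(n_snp, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      rsid = sprintf("rs%05d", seq_len(n_snp)),
      effect_allele = "A", other_allele = "G",
      bx = runif(n_snp, 0.03, 0.5) * sample(c(-1, 1), n_snp, replace = TRUE),
      se_x = runif(n_snp, 0.005, 0.03),
      eaf_x = runif(n_snp, 0.1, 0.9),
      by = rnorm(n_snp, 0, 0.03),
      se_y = runif(n_snp, 0.005, 0.05),
      eaf_y = runif(n_snp, 0.1, 0.9),
      palindromic = FALSE, flipped = FALSE
    )
  })
}

# jointly flip allele coding of selected rows of a harmonized set
flip_coding <- function(dat, idx) {
  dat$bx[idx] <- -dat$bx[idx]
  dat$by[idx] <- -dat$by[idx]
  dat$eaf_x[idx] <- 1 - dat$eaf_x[idx]
  dat$eaf_y[idx] <- 1 - dat$eaf_y[idx]
  dat
}
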
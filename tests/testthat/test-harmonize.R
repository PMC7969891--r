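mk_rec <- function(rsid, ea, oa, eaf, beta, se = 0.01, pvalue = 0.5,
                   trait = "x") {
  tibble::tibble(
    rsid = rsid, effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, pvalue = pvalue, n = 1e4, trait = trait
  )
}

test_that("allele alignment covers identity, swap, strand and palindromes", {
  ex <- mk_rec("rs8177240", "T", "G", 0.67, -0.38)

  same <- harmonize(ex, mk_rec("rs8177240", "T", "G", 0.664, 0.02))
  expect_false(same$flipped)
  expect_equal(same$by, 0.02)

  swapped <- harmonize(ex, mk_rec("rs8177240", "G", "T", 0.336, 0.02))
  expect_true(swapped$flipped)
  expect_equal(swapped$by, -0.02)
  expect_equal(swapped$eaf_y, 0.664)

  # strand complement: T/G on the other strand reads A/C
  strand <- harmonize(ex, mk_rec("rs8177240", "A", "C", 0.664, 0.02))
  expect_false(strand$flipped)
  expect_equal(strand$by, 0.02)
  strand_sw <- harmonize(ex, mk_rec("rs8177240", "C", "A", 0.336, 0.02))
  expect_true(strand_sw$flipped)
  expect_equal(strand_sw$by, -0.02)

  # palindromic C/G resolved by frequency concordance (both far from 0.5)
  pal_ex <- mk_rec("rs1799945", "C", "G", 0.85, -0.19)
  pal <- harmonize(pal_ex, mk_rec("rs1799945", "C", "G", 0.849, 0.01))
  expect_true(pal$palindromic)
  expect_false(pal$flipped)
  pal_opp <- harmonize(pal_ex, mk_rec("rs1799945", "C", "G", 0.151, 0.01))
  expect_true(pal_opp$flipped)
  expect_equal(pal_opp$by, -0.01)

  # ambiguous palindrome (frequency at 0.5) and irreconcilable alleles drop
  amb <- suppressWarnings(harmonize(
    dplyr::bind_rows(pal_ex, ex),
    dplyr::bind_rows(mk_rec("rs1799945", "C", "G", 0.50, 0.01),
                     mk_rec("rs8177240", "T", "G", 0.664, 0.02))
  ))
  expect_equal(amb$rsid, "rs8177240")
  log <- attr(amb, "log")
  expect_match(log$reason[log$rsid == "rs1799945"], "ambiguous")

  bad <- harmonize(
    dplyr::bind_rows(ex, pal_ex),
    dplyr::bind_rows(mk_rec("rs8177240", "A", "G", 0.664, 0.02),
                     mk_rec("rs1799945", "C", "G", 0.849, 0.01))
  )
  expect_equal(bad$rsid, "rs1799945")
  expect_match(
    attr(bad, "log")$reason[attr(bad, "log")$rsid == "rs8177240"],
    "irreconcilable"
  )

  indel <- harmonize(
    dplyr::bind_rows(mk_rec("rs9", "AT", "A", 0.3, 0.1), ex),
    dplyr::bind_rows(mk_rec("rs9", "AT", "A", 0.3, 0.01),
                     mk_rec("rs8177240", "T", "G", 0.664, 0.02))
  )
  expect_equal(indel$rsid, "rs8177240")
})

test_that("harmonization is involutive under outcome recoding", {
  ex <- mk_rec("rs1", "A", "G", 0.3, 0.2)
  ou <- mk_rec("rs1", "A", "G", 0.31, 0.05)
  base <- harmonize(ex, ou)
  recoded <- dplyr::mutate(
    ou, effect_allele = "G", other_allele = "A",
    eaf = 1 - eaf, beta = -beta
  )
  again <- harmonize(ex, recoded)
  expect_equal(again$by, base$by)
  expect_equal(again$eaf_y, base$eaf_y)
  expect_true(again$flipped)
})

test_that("fixture sets harmonize completely and silently", {
  cons <- harmonized_fixture("conservative", "iron")
  expect_equal(nrow(cons), 3)
  expect_true(all(attr(cons, "log")$action %in% c("keep", "flip")))

  # the full 12-SNP union is found in the outcome records
  expo <- dplyr::distinct(iron_associations(), rsid, .keep_all = TRUE)
  expect_silent(h12 <- harmonize(expo, als_associations()))
  expect_equal(nrow(h12), 12)
  expect_equal(length(attr(h12, "missing")), 0)
  expect_false(any(h12$flipped))  # tables are printed pre-aligned

  # absent SNPs are reported, not proxied
  extra <- dplyr::bind_rows(expo, mk_rec("rs0000", "A", "G", 0.2, 0.3))
  h <- harmonize(extra, als_associations())
  expect_equal(attr(h, "missing"), "rs0000")
  expect_error(
    harmonize(mk_rec("rs0000", "A", "G", 0.2, 0.3), als_associations()),
    "no exposure SNP"
  )
})

test_that("large post-alignment frequency gaps warn but do not drop", {
  ex <- mk_rec("rs1", "A", "G", 0.9, 0.2)
  ou <- mk_rec("rs1", "A", "G", 0.6, 0.05)
  expect_warning(h <- harmonize(ex, ou), "frequency gap")
  expect_equal(nrow(h), 1)
})

test_that("estimates are invariant to the allele coding of any subset", {
  dat <- random_instruments(8, seed = 42)
  for (idx in list(1, c(2, 5), 1:8)) {
    flp <- flip_coding(dat, idx)
    expect_equal(mr_ivw(flp)$beta, mr_ivw(dat)$beta, tolerance = 1e-12)
    expect_equal(mr_egger(flp)$beta, mr_egger(dat)$beta, tolerance = 1e-12)
    expect_equal(mr_egger(flp)$egger_intercept,
                 mr_egger(dat)$egger_intercept, tolerance = 1e-12)
    expect_equal(mr_weighted_median(flp, n_boot = 50, seed = 1)$beta,
                 mr_weighted_median(dat, n_boot = 50, seed = 1)$beta,
                 tolerance = 1e-12)
  }
})
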
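test_that("significance filtering applies a strict threshold with presence flags", {
  iron <- iron_associations("iron")
  expect_equal(nrow(significance_filter(iron, 5e-8)), 5)
  # presence-flag rows (NA p) pass only thresholds no stricter than 5e-8
  expect_equal(nrow(significance_filter(iron, 1e-9)), 0)

  recs <- tibble::tibble(
    rsid = c("a", "b"), effect_allele = "A", other_allele = "G",
    eaf = 0.5, beta = 0.1, se = 0.01, pvalue = c(5e-8, 4.9e-8), n = 1e4,
    trait = "x"
  )
  expect_equal(significance_filter(recs, 5e-8)$rsid, "b")  # strict <
  expect_equal(nrow(significance_filter(recs, 1e-10)), 0)
  expect_error(significance_filter(recs, 1), "strictly inside")
})

test_that("greedy LD pruning keeps the most significant SNP per clique", {
  two <- tibble::tibble(
    rsid = c("s1", "s2"), effect_allele = "A", other_allele = "G",
    eaf = 0.5, beta = 0.1, se = 0.01, pvalue = c(1e-9, 1e-10), n = 1e4,
    trait = "x"
  )
  ld <- tibble::tibble(rsid_a = "s1", rsid_b = "s2", r2 = 0.5)
  expect_equal(ld_prune(two, ld)$rsid, "s2")  # smaller p wins

  # r2 exactly at threshold keeps both (strict >)
  ld_eq <- tibble::tibble(rsid_a = "s1", rsid_b = "s2", r2 = 0.01)
  expect_equal(nrow(ld_prune(two, ld_eq)), 2)

  expect_error(
    ld_prune(two, tibble::tibble(rsid_a = "s1", rsid_b = "zz", r2 = 0)),
    "no LD value"
  )

  # all-zero matrix is the identity; all-ones keeps a single SNP
  twelve <- als_associations()
  ids <- twelve$rsid
  zero <- matrix(0, 12, 12, dimnames = list(ids, ids))
  expect_equal(ld_prune(twelve, zero)$rsid, ids)
  ones <- matrix(1, 12, 12, dimnames = list(ids, ids))
  expect_equal(nrow(ld_prune(twelve, ones)), 1)
  expect_equal(nrow(ld_prune(twelve, NULL, assume_unlinked = TRUE)), 12)
})

test_that("conservative concordance rule recovers the three-SNP set", {
  cs <- conservative_set(iron_associations())
  expect_setequal(cs$rsid, c("rs1800562", "rs1799945", "rs855791"))
  expect_false("rs7385804" %in% cs$rsid)  # blank ferritin/transferrin cells

  # globally sign-flipping one SNP (allele relabelling) keeps membership
  flipped <- iron_associations() |>
    dplyr::mutate(beta = ifelse(rsid == "rs855791", -beta, beta))
  expect_setequal(conservative_set(flipped)$rsid, cs$rsid)

  # a SNP raising all four biomarkers violates the transferrin sign rule
  allpos <- iron_associations() |>
    dplyr::mutate(beta = ifelse(rsid == "rs1799945", abs(beta), beta))
  expect_false("rs1799945" %in% conservative_set(allpos)$rsid)

  expect_error(
    conservative_set(dplyr::filter(iron_associations(), trait != "ferritin")),
    "missing: ferritin"
  )
})

test_that("liberal sets have the printed per-biomarker sizes", {
  iron <- iron_associations()
  sizes <- vapply(
    c(iron = "iron", ferritin = "ferritin",
      transferrin_saturation = "transferrin_saturation",
      transferrin = "transferrin"),
    function(bm) nrow(liberal_set(iron, bm)), integer(1)
  )
  expect_equal(unname(sizes), c(5L, 6L, 5L, 9L))
  union_ids <- unique(unlist(
    lapply(names(sizes), function(bm) liberal_set(iron, bm)$rsid)
  ))
  expect_equal(length(union_ids), 12)
  expect_error(liberal_set(iron, "serum_iron"), "unknown biomarker")
  empty <- dplyr::mutate(iron, pvalue = 0.5)
  expect_warning(liberal_set(empty, "iron"), "no genome-wide significant")
})

test_that("variance explained follows the standardized-phenotype formula", {
  expect_equal(variance_explained(-0.38, 0.67), 2 * 0.38^2 * 0.33 * 0.67)
  expect_equal(variance_explained(-0.38, 0.67), 0.0638537, tolerance = 1e-6)
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(0.1, 0.5), 0.005)
  expect_error(variance_explained(0.1, 1.2), "strictly inside")
})

test_that("F statistics reproduce the printed strength range", {
  r2_top <- variance_explained(-0.38, 0.67)
  expect_equal(round(f_statistic(r2_top, 48972, 1)), 3340)
  r2_bottom <- variance_explained(-0.04, 0.46)
  expect_equal(round(f_statistic(r2_bottom, 48972, 1)), 39)
  expect_equal(f_statistic(0, 48972, 1), 0)
  expect_error(f_statistic(1, 100, 1), "\\[0, 1\\)")
  expect_error(f_statistic(0.1, 2, 1), "exceed")

  # strictly increasing in r2 at fixed n, k
  grid <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(f_statistic(grid, 1000, 1)) > 0))

  # over every nonblank biomarker-SNP cell of the exposure table
  st <- instrument_strength(iron_associations())
  expect_equal(nrow(st), 25)
  expect_equal(round(min(st$f)), 39)
  expect_equal(round(max(st$f)), 3340)
  expect_true(all(st$f > 10))  # no weak instruments
  expect_equal(st$r2, 2 * st$beta^2 * (1 - st$eaf) * st$eaf)
})
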
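test_that("Wald ratios match hand arithmetic on the fixture", {
  cons <- harmonized_fixture("conservative", "iron")
  w <- mr_wald_ratio(cons)
  r562 <- w[w$rsid == "rs1800562", ]
  expect_equal(r562$beta, 0.02 / 0.33, tolerance = 1e-12)
  expect_equal(r562$se, 0.03 / 0.33, tolerance = 1e-12)
  expect_equal(r562$beta, 0.0606, tolerance = 1e-3)
  expect_equal(r562$se, 0.0909, tolerance = 1e-3)

  zero <- tibble::tibble(rsid = "z", bx = 0.5, se_x = 0.01, by = 0,
                         se_y = 0.02)
  expect_equal(mr_wald_ratio(zero)$beta, 0)
  bad <- dplyr::mutate(zero, bx = 0)
  expect_error(mr_wald_ratio(bad), "zero exposure beta")

  # second-order delta SE adds the exposure-uncertainty term
  w2 <- mr_wald_ratio(cons, second_order = TRUE)
  expect_true(all(w2$se >= w$se))
})

test_that("IVW pools the fixture to the hand-derived estimate", {
  cons <- harmonized_fixture("conservative", "iron")
  fit <- mr_ivw(cons)
  expect_equal(fit$beta, 0.038456, tolerance = 1e-4)
  expect_equal(fit$se, 0.043225, tolerance = 1e-4)
  expect_equal(fit$or, 1.0392, tolerance = 1e-3)
  expect_equal(fit$n_snp, 3)

  # single instrument reduces to the Wald ratio
  one <- cons[1, ]
  wald <- mr_wald_ratio(one)
  fit1 <- mr_ivw(one)
  expect_equal(fit1$beta, wald$beta)
  expect_equal(fit1$se, wald$se)

  # equal ratios: beta is that ratio, Q = 0, both effects models agree
  eq <- tibble::tibble(
    rsid = c("a", "b"), bx = c(0.2, 0.4), se_x = 0.01,
    by = c(0.02, 0.04), se_y = c(0.01, 0.02)
  )
  expect_equal(mr_ivw(eq)$beta, 0.1)
  expect_equal(mr_ivw(eq)$q_stat, 0)
  expect_equal(mr_ivw(eq, "fe")$se, mr_ivw(eq, "mre")$se)
  expect_error(mr_ivw(eq[0, ]), "at least 1")
})

test_that("IVW equals the weighted mean of Wald ratios on random instances", {
  skip_if_not_installed("metafor")
  for (s in 1:50) {
    dat <- random_instruments(sample(3:15, 1), seed = s)
    fit <- mr_ivw(dat, "fe")
    oracle <- metafor::rma(
      yi = dat$by / dat$bx, sei = dat$se_y / abs(dat$bx), method = "EE"
    )
    expect_equal(fit$beta, as.numeric(oracle$beta), tolerance = 1e-12)
    expect_equal(fit$se, as.numeric(oracle$se), tolerance = 1e-12)
  }
})

test_that("Cochran's Q matches hand computation and guards its domain", {
  cons <- harmonized_fixture("conservative", "iron")
  q <- cochran_q(cons)
  expect_equal(q$q_stat, 0.9029, tolerance = 1e-3)
  expect_equal(q$q_df, 2)

  eq <- tibble::tibble(rsid = c("a", "b"), bx = c(0.2, 0.4), se_x = 0.01,
                       by = c(0.02, 0.04), se_y = 0.01)
  expect_equal(cochran_q(eq)$q_stat, 0)
  expect_error(cochran_q(eq[1, ]), "at least 2")
})

test_that("Egger recovers exact WLS solutions on constructed data", {
  # collinear through the origin: intercept 0, slope = c
  col <- tibble::tibble(
    rsid = letters[1:5], bx = c(0.1, 0.15, 0.2, 0.3, 0.4), se_x = 0.01,
    by = 0.3 * c(0.1, 0.15, 0.2, 0.3, 0.4), se_y = c(1, 2, 1, 3, 2) / 100
  )
  fit <- mr_egger(col)
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$egger_intercept, 0, tolerance = 1e-12)

  # constant pleiotropy on oriented bx, equal weights: exact WLS solution
  cp <- dplyr::mutate(col, by = 0.25 * bx + 0.01, se_y = 0.02)
  fit2 <- mr_egger(cp)
  expect_equal(fit2$beta, 0.25, tolerance = 1e-12)
  expect_equal(fit2$egger_intercept, 0.01, tolerance = 1e-12)

  # cross-check SEs and t p-values against lm() weighted least squares
  dat <- random_instruments(12, seed = 7)
  s <- sign(dat$bx)
  lmfit <- summary(stats::lm(I(dat$by * s) ~ I(dat$bx * s),
                             weights = 1 / dat$se_y^2))
  ours <- mr_egger(dat)
  sigma <- lmfit$sigma
  expect_equal(ours$beta, lmfit$coefficients[2, 1], tolerance = 1e-10)
  expect_equal(ours$egger_intercept, lmfit$coefficients[1, 1],
               tolerance = 1e-10)
  expect_equal(ours$se,
               lmfit$coefficients[2, 2] / sigma * max(1, sigma),
               tolerance = 1e-10)
  if (sigma >= 1) {
    expect_equal(ours$pvalue, lmfit$coefficients[2, 4], tolerance = 1e-10)
  }
  expect_error(mr_egger(dat[1:2, ]), "at least 3")
})

test_that("weighted median interpolates the weighted 50th percentile", {
  eqw <- tibble::tibble(
    rsid = c("a", "b", "c"), bx = 0.2, se_x = 0.01,
    by = 0.2 * c(0.1, 0.2, 0.3), se_y = 0.01
  )
  expect_equal(mr_weighted_median(eqw, n_boot = 10, seed = 1)$beta, 0.2,
               tolerance = 1e-12)

  cons <- harmonized_fixture("conservative", "iron")
  fit <- mr_weighted_median(cons, seed = 0)
  expect_equal(fit$beta, 0.0559, tolerance = 1e-4)

  # bootstrap SE is reproducible under a fixed seed
  again <- mr_weighted_median(cons, seed = 0)
  expect_identical(fit$se, again$se)
  other <- mr_weighted_median(cons, seed = 99)
  expect_false(identical(fit$se, other$se))
  expect_error(mr_weighted_median(cons[1:2, ]), "at least 3")
})

test_that("odds-ratio conversion satisfies the reporting invariants", {
  null <- to_odds_ratio(0, 0.05)
  expect_equal(null$or, 1)
  expect_equal(null$ci_low, exp(-1.96 * 0.05))
  expect_equal(null$ci_low, 0.9067, tolerance = 1e-4)
  expect_equal(null$ci_high, 1.1030, tolerance = 1e-4)
  expect_equal(null$pvalue, 1)

  x <- to_odds_ratio(0.0385, 0.0432)
  expect_equal(x$or, 1.0393, tolerance = 1e-4)
  expect_equal(x$ci_low, 0.9549, tolerance = 1e-4)
  expect_equal(x$ci_high, 1.1311, tolerance = 1e-4)
  expect_error(to_odds_ratio(0.1, 0), "strictly positive")
})

test_that("pooled estimates lie within the span of the Wald ratios", {
  for (s in 1:20) {
    dat <- random_instruments(sample(3:12, 1), seed = 100 + s)
    ratios <- dat$by / dat$bx
    expect_gte(mr_ivw(dat)$beta, min(ratios))
    expect_lte(mr_ivw(dat)$beta, max(ratios))
    wm <- mr_weighted_median(dat, n_boot = 10, seed = 1)$beta
    expect_gte(wm, min(ratios))
    expect_lte(wm, max(ratios))
  }
  # Egger: holds for the exact-collinear case (intercept constrained at 0)
  col <- tibble::tibble(
    rsid = letters[1:4], bx = c(0.1, 0.2, 0.3, 0.4), se_x = 0.01,
    by = 0.15 * c(0.1, 0.2, 0.3, 0.4), se_y = 0.01
  )
  expect_equal(mr_egger(col)$beta, 0.15, tolerance = 1e-10)
})

test_that("tidy and glance expose broom-shaped summaries", {
  fit <- mr_egger(harmonized_fixture("liberal", "transferrin"))
  td <- tidy(fit)
  expect_equal(td$term, c("causal_effect", "pleiotropy_intercept"))
  expect_equal(td$estimate[2], fit$egger_intercept)
  tde <- tidy(fit, exponentiate = TRUE)
  expect_equal(tde$estimate[1], fit$or)
  g <- glance(fit)
  expect_equal(g$n_snp, 9)
  expect_equal(g$egger_intercept_p, fit$egger_intercept_p)
  expect_equal(g$ci_low, exp(g$beta - 1.96 * g$se))

  ivw <- mr_ivw(harmonized_fixture("conservative", "iron"))
  expect_equal(glance(ivw)$pvalue,
               2 * pnorm(-abs(ivw$beta / ivw$se)), tolerance = 1e-12)
  expect_output(print(ivw), "OR")
})
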
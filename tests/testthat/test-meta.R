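hand_est <- function() period_estimates(1:2, c(0.5, 0.7), c(0.01, 0.01))

test_that("fixed-effects pooling matches the inverse-variance formulas", {
  fx <- pool_fixed(hand_est())
  expect_equal(fx$estimate, 0.6)
  expect_equal(fx$se, sqrt(1 / 200))
  expect_equal(unname(fx$meta_weights), c(50, 50))
  expect_equal(fx$ci_low, 0.6 - qnorm(0.975) * sqrt(1 / 200))

  # unequal variances weight by precision
  est <- period_estimates(1:2, c(0.4, 0.8), c(0.01, 0.04))
  fx2 <- pool_fixed(est)
  expect_equal(fx2$estimate, (100 * 0.4 + 25 * 0.8) / 125)
  expect_equal(sum(fx2$meta_weights), 100)

  # a constant value pools to itself
  cst <- period_estimates(1:4, rep(0.43, 4), c(.01, .02, .03, .04))
  expect_equal(pool_fixed(cst)$estimate, 0.43)
  expect_equal(pool_fixed(cst)$chi2_het, 0)

  expect_error(pool_fixed(period_estimates(1, 0.5, 0.01)), "at least 2")
  expect_error(pool_fixed(period_estimates(1:2, c(.5, .6), c(0, .01))),
               "zero-variance")
})

test_that("heterogeneity statistic, df, and p-value follow the chi-square test", {
  het <- heterogeneity(hand_est())
  expect_equal(het$chi2, 2)
  expect_equal(het$df, 1)
  expect_equal(het$p, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(heterogeneity(period_estimates(1:3, rep(.5, 3), rep(.01, 3)))$chi2, 0)
  # the g = 18 rejection threshold used in reporting
  expect_lt(abs(qchisq(0.95, 17) - 27.59), 0.005)
})

test_that("DerSimonian-Laird tau2 matches the moment formula and truncates at 0", {
  t2 <- dl_tau2(hand_est())
  expect_equal(as.numeric(t2), 0.01)
  expect_false(attr(t2, "truncated"))

  same <- period_estimates(1:3, rep(0.5, 3), rep(0.01, 3))
  t0 <- dl_tau2(same)
  expect_identical(as.numeric(t0), 0)
  expect_true(attr(t0, "truncated"))

  # marginally below df still truncates to exactly 0, never negative
  near <- period_estimates(1:2, c(0.5, 0.5099), c(0.01, 0.01))
  expect_identical(as.numeric(dl_tau2(near)), 0)
})

test_that("random-effects pooling interpolates between fixed and averaged", {
  est <- hand_est()
  rd <- pool_random(est)
  expect_equal(rd$tau2, 0.01)
  expect_equal(rd$estimate, 0.6)
  expect_equal(rd$se, sqrt(0.02 / 2))

  # tau2 = 0 reduces exactly to fixed effects
  same <- period_estimates(1:3, c(0.5, 0.5, 0.501), c(0.01, 0.02, 0.03))
  expect_identical(as.numeric(dl_tau2(same)), 0)
  rd0 <- pool_random(same)
  fx0 <- pool_fixed(same)
  expect_equal(rd0$estimate, fx0$estimate, tolerance = 1e-15)
  expect_equal(rd0$se, fx0$se, tolerance = 1e-15)

  # huge injected tau2 converges to the simple average
  est2 <- period_estimates(1:3, c(0.2, 0.5, 0.9), c(0.01, 0.05, 0.2))
  rbig <- pool_random(est2, tau2 = 1e6)
  expect_equal(rbig$estimate, mean(est2$kappa), tolerance = 1e-4)
})

test_that("simple averaging uses equal weights and the variance-sum SE", {
  av <- pool_average(hand_est())
  expect_equal(av$estimate, 0.6)
  av2 <- pool_average(period_estimates(1:2, c(0.5, 0.7), c(0.01, 0.03)))
  expect_equal(av2$se, sqrt(0.04 / 4))
  one <- pool_average(period_estimates(7, 0.42, 0.02))
  expect_equal(one$estimate, 0.42)
  expect_equal(one$se, sqrt(0.02))
})

test_that("pooled estimates respect ordering and bounding properties", {
  set.seed(404)
  for (r in 1:50) {
    g <- sample(3:15, 1)
    est <- period_estimates(seq_len(g),
                            kappa = runif(g, -0.2, 0.95),
                            v = runif(g, 0.002, 0.1))
    fx <- pool_fixed(est); rd <- pool_random(est); av <- pool_average(est)
    for (p in list(fx, rd, av)) {
      expect_gte(p$estimate, min(est$kappa) - 1e-12)
      expect_lte(p$estimate, max(est$kappa) + 1e-12)
      expect_equal(sum(p$meta_weights), 100)
    }
    if (rd$tau2 > 0) expect_gte(rd$se, fx$se)
    # injected tau2 spans the family from fixed effects to the average
    expect_equal(pool_random(est, tau2 = 0)$estimate, fx$estimate,
                 tolerance = 1e-13)
    expect_equal(pool_random(est, tau2 = 1e8)$estimate, av$estimate,
                 tolerance = 1e-5)
  }
  # for two periods the random estimate does lie between fixed and average
  set.seed(405)
  for (r in 1:20) {
    est <- period_estimates(1:2, runif(2, 0, 0.9), runif(2, 0.002, 0.1))
    fx <- pool_fixed(est); rd <- pool_random(est); av <- pool_average(est)
    expect_gte(rd$estimate, min(fx$estimate, av$estimate) - 1e-12)
    expect_lte(rd$estimate, max(fx$estimate, av$estimate) + 1e-12)
  }
})

test_that("fixed and DL random pooling agree with metafor", {
  skip_if_not_installed("metafor")
  set.seed(505)
  for (r in 1:20) {
    g <- sample(2:20, 1)
    est <- period_estimates(seq_len(g),
                            kappa = runif(g, 0, 0.9),
                            v = runif(g, 0.001, 0.08))
    fx <- pool_fixed(est)
    rd <- pool_random(est)
    mf_fe <- metafor::rma(yi = est$kappa, vi = est$v, method = "FE")
    mf_dl <- metafor::rma(yi = est$kappa, vi = est$v, method = "DL")
    expect_equal(fx$estimate, as.numeric(mf_fe$beta), tolerance = 1e-8)
    expect_equal(fx$se, mf_fe$se, tolerance = 1e-8)
    expect_equal(fx$chi2_het, mf_fe$QE, tolerance = 1e-8)
    expect_equal(rd$tau2, mf_dl$tau2, tolerance = 1e-8)
    expect_equal(rd$estimate, as.numeric(mf_dl$beta), tolerance = 1e-8)
    expect_equal(rd$se, mf_dl$se, tolerance = 1e-8)
  }
})

test_that("collapsing tables sums cells and concentrates precision", {
  both <- collapse_tables(list(lowest_tab(), highest_tab()))
  expect_equal(unname(both["+c", "+c"]), 9 + 11)
  expect_equal(sum(both), 44)
  expect_identical(unclass(collapse_tables(list(lowest_tab()))),
                   unclass(lowest_tab()))
  sc <- category_scale(letters[1:5])
  other <- as_crosstab(unclass(lowest_tab()), sc)
  expect_error(collapse_tables(list(lowest_tab(), other)), "different scales")

  # c identical copies: same kappa, SE shrinks by sqrt(c)
  tab <- collapsed_tab()
  for (c_copies in c(2, 5)) {
    many <- collapse_tables(rep(list(tab), c_copies))
    expect_equal(weighted_kappa(many, "A4")$kappa,
                 weighted_kappa(tab, "A4")$kappa, tolerance = 1e-14)
    expect_equal(kappa_se(many, "A4"), kappa_se(tab, "A4") / sqrt(c_copies),
                 tolerance = 1e-12)
  }
})
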
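test_that("tabulate_pairs reproduces counts, margins, and handles edge cases", {
  tab <- lowest_tab()
  pairs <- tab_to_pairs(tab)
  tab2 <- tabulate_pairs(pairs$rater1, pairs$rater2)
  expect_identical(unclass(tab2), unclass(tab))
  expect_equal(unname(rowSums(tab2)), c(6, 13, 5, 0, 1))
  expect_equal(unname(colSums(tab2)), c(3, 15, 4, 1, 2))
  expect_equal(sum(tab2), 25)

  empty <- tabulate_pairs(character(0), character(0))
  expect_equal(sum(empty), 0)
  expect_equal(dim(empty), c(5, 5))

  one <- tabulate_pairs("+s", "+s")
  expect_equal(unname(one["+s", "+s"]), 1L)
  expect_equal(sum(one), 1)

  expect_error(tabulate_pairs("+s", "huh"), "unknown category label.*row.*1")
})

test_that("observed and expected agreement match hand-derived values", {
  ta <- collapsed_tab()
  expect_equal(observed_agreement(ta, "unweighted"), 260 / 354)
  expect_equal(observed_agreement(ta, "A4"), 311.25 / 354)
  expect_equal(expected_agreement(ta, "unweighted"), 49614 / 125316)
  expect_equal(expected_agreement(lowest_tab(), "unweighted"), 235 / 625)

  # all-ones weight matrix counts everything as agreement
  ones <- weight_matrix(matrix(1, 5, 5), quis_scale())
  expect_equal(observed_agreement(ta, ones), 1)
  # fully concentrated table: both margins degenerate
  conc <- as_crosstab(matrix(c(7, rep(0, 24)), 5, 5))
  expect_equal(expected_agreement(conc, "unweighted"), 1)

  empty <- tabulate_pairs(character(0), character(0))
  expect_error(observed_agreement(empty, "A4"), "empty")
  expect_error(expected_agreement(empty, "A4"), "empty")
})

test_that("weighted kappa reproduces the published period and collapsed values", {
  expect_lt(abs(weighted_kappa(lowest_tab(), "unweighted")$kappa - 0.30), 0.011)
  expect_lt(abs(weighted_kappa(highest_tab(), "unweighted")$kappa - 0.90), 0.011)
  est <- weighted_kappa(collapsed_tab(), "A4")
  expect_lt(abs(est$kappa - 0.60), 0.011)
  expect_lt(abs(est$ci_low - 0.53), 0.011)
  expect_lt(abs(est$ci_high - 0.67), 0.011)

  # perfect diagonal table gives kappa 1 under any valid scheme
  diag_tab <- as_crosstab(diag(c(3, 5, 2, 1, 4)))
  for (nm in c("unweighted", "linear", "A4", "C1"))
    expect_equal(weighted_kappa(diag_tab, nm)$kappa, 1)
})

test_that("weighted kappa equals the brute-force oracle on fuzzed tables", {
  set.seed(101)
  schemes <- lapply(scheme_names(), weight_scheme)
  for (r in 1:300) {
    tab <- random_table()
    W <- schemes[[sample(length(schemes), 1)]]
    if (oracle_pe(tab, W) >= 1 - 1e-9) next
    ct <- as_crosstab(tab)
    est <- weighted_kappa(ct, W)
    expect_equal(est$kappa, oracle_kappa(tab, W), tolerance = 1e-12)
    expect_equal(est$po_w, oracle_po(tab, W), tolerance = 1e-12)
    expect_equal(est$pe_w, oracle_pe(tab, W), tolerance = 1e-12)
    expect_equal(est$se, oracle_se(tab, W), tolerance = 1e-12)
    expect_true(est$kappa <= 1 + 1e-12)
    # kappa reaches 1 only with full weighted agreement
    if (est$po_w < 1 - 1e-12) expect_lt(est$kappa, 1)
  }
})

test_that("degenerate tables raise explicit errors instead of NaN", {
  # all mass in one diagonal cell: expected weighted agreement is 1
  conc <- as_crosstab(matrix(c(5, rep(0, 24)), 5, 5))
  expect_error(weighted_kappa(conc, "A4"), "undefined")
  expect_error(kappa_se(conc, "A4"), "undefined")
  # a single agreeing pair concentrates both margins: pe_w = 1
  expect_error(weighted_kappa(tabulate_pairs("N", "N"), "A4"), "undefined")
  # a single disagreeing pair is defined (pe_w = w_ij < 1), kappa = 0
  expect_equal(weighted_kappa(tabulate_pairs("N", "-p"), "A4")$kappa, 0)
  expect_error(weighted_kappa(tabulate_pairs(character(0), character(0)), "A4"),
               "empty")
  # mass confined to a weight-1 block under A1 degenerates, but not under A4
  blk <- as_crosstab(matrix(c(2, 1, 0, 0, 0, 3, 4, rep(0, 18)), 5, 5))
  expect_error(weighted_kappa(blk, "A1"), "undefined")
  expect_s3_class(weighted_kappa(blk, "A4"), "kappa_estimate")
})

test_that("the Fleiss standard error scales as 1/sqrt(n)", {
  tab <- collapsed_tab()
  se1 <- kappa_se(tab, "A4")
  se2 <- kappa_se(as_crosstab(unclass(tab) * 2L), "A4")
  expect_equal(se2, se1 / sqrt(2), tolerance = 1e-12)
  # CI half-width back-check against the published A4 interval
  expect_equal(qnorm(0.975) * se1, 0.07, tolerance = 0.01)
})

test_that("Wald intervals are centred, level-correct, and clipped", {
  expect_equal(wald_ci(0.5, 0, 0.05), c(0.5, 0.5))
  expect_equal(wald_ci(0.5, 0.1, 0.05), 0.5 + c(-1, 1) * 1.959964 * 0.1,
               tolerance = 1e-6)
  expect_equal(wald_ci(0.98, 0.05, 0.05)[2], 1)
  expect_equal(wald_ci(0.98, 0.05, 0.05, clip = FALSE)[2],
               0.98 + qnorm(0.975) * 0.05)
  ci90 <- wald_ci(0.2, 0.1, 0.10)
  expect_equal(ci90, 0.2 + c(-1, 1) * qnorm(0.95) * 0.1)
})

test_that("kappa is invariant under simultaneous permutation of the scale", {
  set.seed(202)
  for (r in 1:25) {
    tab <- random_table()
    W <- weight_scheme(sample(scheme_names(), 1))
    if (oracle_pe(tab, W) >= 1 - 1e-9) next
    perm <- sample(5)
    labs <- quis_scale()[perm]
    tab_p <- as_crosstab(tab[perm, perm], labs)
    W_p <- weight_matrix(unclass(W)[perm, perm], labs)
    expect_equal(weighted_kappa(tab_p, W_p)$kappa,
                 weighted_kappa(as_crosstab(tab), W)$kappa,
                 tolerance = 1e-13)
  }
})

test_that("scheme A1 equals the merged three-category analysis exactly", {
  # A1 treats the two positive and two negative categories as fully
  # interchangeable, so the five-category analysis collapses exactly to
  # the merged positive/neutral/negative table under the induced block
  # weights - which are the linear weights for three categories.
  sc3 <- category_scale(c("pos", "N", "neg"))
  W3 <- linear_weights(sc3)
  merge_tab <- function(tab) {
    grp <- c(1, 1, 2, 3, 3)
    m <- matrix(0L, 3, 3)
    for (i in 1:5) for (j in 1:5)
      m[grp[i], grp[j]] <- m[grp[i], grp[j]] + tab[i, j]
    as_crosstab(m, sc3)
  }
  set.seed(303)
  for (r in 1:100) {
    tab <- random_table()
    if (oracle_pe(tab, unclass(weight_scheme("A1"))) >= 1 - 1e-9) next
    k5 <- weighted_kappa(as_crosstab(tab), "A1")$kappa
    k3 <- weighted_kappa(merge_tab(tab), W3)$kappa
    expect_equal(k5, k3, tolerance = 1e-13)
  }
})
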
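test_that("per-position Welch agrees with stats::t.test to machine precision", {
  set.seed(101)
  for (rep in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1); np <- 50
    a <- matrix(rnorm(np * n1, sd = runif(1, 0.5, 2)), np, n1)
    b <- matrix(rnorm(np * n2, mean = runif(1, -1, 1)), np, n2)
    cmp <- welch_compare(a, b)
    for (i in sample(np, 10)) {
      tt <- t.test(a[i, ], b[i, ])
      expect_equal(cmp$t[i], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(cmp$df[i], unname(tt$parameter), tolerance = 1e-12)
      expect_equal(cmp$p_value[i], tt$p.value, tolerance = 1e-12)
    }
  }
})

test_that("Welch degenerate cases follow the stated conventions", {
  a <- matrix(rep(c(1, 2), each = 4), 2, 4, byrow = TRUE)
  cmp_same <- welch_compare(a, a)
  expect_equal(cmp_same$t, c(0, 0))
  expect_equal(cmp_same$p_value, c(1, 1))
  b <- a + 1  # zero variance, unequal means
  cmp_diff <- welch_compare(a, b)
  expect_equal(cmp_diff$p_value, c(0, 0))
  expect_error(welch_compare(a[, 1, drop = FALSE], a),
               class = "xgram_insufficient_replication")
})

test_that("Bonferroni flag uses the family size over tested positions", {
  set.seed(5)
  a <- matrix(rnorm(40), 10, 4); b <- matrix(rnorm(40), 10, 4)
  cmp <- welch_compare(a, b, family_alpha = 0.01)
  expect_equal(attr(cmp, "bonferroni_threshold"), 0.01 / 10)
  expect_equal(cmp$bonferroni, cmp$p_value < 0.001)
  # paper-style fixed family size: 0.01 over 9684 positions is of order 1e-6
  cmp2 <- welch_compare(a, b, family_alpha = 0.01, family_size = 9684)
  expect_equal(attr(cmp2, "bonferroni_threshold"), 0.01 / 9684)
  expect_lt(attr(cmp2, "bonferroni_threshold"), 1.1e-6)
  expect_gt(attr(cmp2, "bonferroni_threshold"), 1e-7)
})

test_that("BH and Storey q-values behave on edge cases and under the null", {
  expect_equal(estimate_fdr(rep(1, 5), "bh")$q_value, rep(1, 5))
  expect_equal(estimate_fdr(rep(1, 5), "storey")$q_value, rep(1, 5))
  expect_equal(estimate_fdr(0.03, "bh")$q_value, 0.03)
  expect_error(estimate_fdr(c(0.5, 1.2)), class = "xgram_bad_pvalues")

  set.seed(11)
  p <- runif(10000)
  st <- estimate_fdr(p, "storey")
  expect_gt(attr(st, "pi0"), 0.9)
  expect_lte(attr(st, "pi0"), 1)
  # q-values are monotone in p
  o <- order(p)
  expect_true(all(diff(st$q_value[o]) >= -1e-12))
  bh <- estimate_fdr(p, "bh")$q_value
  expect_equal(bh, p.adjust(p, "BH"))
  # Storey shrinks BH by pi0
  expect_true(all(st$q_value <= bh + 1e-12))
})

test_that("contrast and noise summaries match a hand computation", {
  # 2 replicates at 3 positions, values set by hand
  m <- cbind(c(1, 3, 5), c(2, 4, 6))
  nr <- contrast_noise(m)
  mu <- c(1.5, 3.5, 5.5); g <- 3.5
  expect_equal(nr$positions$contrast, abs(mu - g))
  expect_equal(nr$positions$sd, rep(sqrt(0.5), 3))
  expect_equal(nr$Omega, sqrt(0.5))
  expect_equal(nr$omega, mean(abs(mu - g)) / sqrt(0.5))
  expect_equal(nr$snr, g / sqrt(0.5))

  # all replicates equal to the global mean: omega = 0 ... but sd = 0 too,
  # so the ratio is flagged infinite rather than raised
  flat <- cbind(rep(2, 4), rep(2, 4))
  expect_equal(contrast_noise(flat)$omega, Inf)

  # constant signal + noise: contrast 0 in expectation, omega near 0
  set.seed(3)
  noisy <- matrix(5 + rnorm(2000, sd = 0.1), 500, 4)
  expect_lt(contrast_noise(noisy)$omega, 1)
})

test_that("contrast-to-noise collapses as the window approaches the list", {
  pl <- make_planted_network(5, 60, 0.5, 0.01, seed = 21)
  sim <- make_expression(pl$labels, conditions = "A", n_b = 1, n_a = 4,
                         sigma_b = 0, sigma_xi = 0.4, delta = 0,
                         seed = 21)
  ordn <- gene_ordering(sort(pl$labels$gene))
  nc <- noise_curve(sim$expression, sim$design, ordn, "A",
                    radii = c(5, 150, 300))
  expect_lt(nc$omega[3], nc$omega[1])
})

test_that("concordance reproduces closed forms and bounds Pearson", {
  x <- c(1, 2, 3)
  expect_equal(concordance(x, x)$rho_c, 1)
  xm <- x - mean(x)
  expect_equal(concordance(xm, -xm)$rho_c, -1)
  # direct evaluation with population moments: (1,2,3) vs (1,2,4) -> 6/7
  cc <- concordance(c(1, 2, 3), c(1, 2, 4))
  expect_equal(cc$rho_c, 6 / 7)
  expect_equal(cc$pearson, cor(c(1, 2, 3), c(1, 2, 4)))
  expect_error(concordance(1:3, 1:4))
  expect_true(is.na(concordance(rep(1, 3), rep(1, 3))$rho_c))

  set.seed(31)
  for (i in 1:30) {
    a <- rnorm(20, sd = runif(1, 0.5, 3)); b <- rnorm(20, mean = runif(1, -2, 2))
    cc <- concordance(a, b)
    expect_lte(abs(cc$rho_c), abs(cc$pearson) + 1e-12)
  }
  # equality iff means and variances agree: shifting breaks it
  a <- rnorm(50)
  expect_lt(concordance(a, a + 1)$rho_c, 1)
  expect_equal(concordance(a, a)$rho_c, 1)
})

test_that("identical laboratories give perfect concordance at every radius", {
  pl <- make_planted_network(4, 50, 0.5, 0.02, seed = 41)
  sim <- make_expression(pl$labels, conditions = c("A", "B"), n_b = 3,
                         n_a = 2, sigma_b = 0.2, sigma_xi = 0.3, seed = 41)
  ordn <- gene_ordering(sort(pl$labels$gene))
  rc <- reproducibility_curve(sim$expression, sim$expression, sim$design,
                              ordn, radii = c(0, 10, 40), conditions = c("B", "A"))
  expect_equal(rc$rho_c, rep(1, 3))
})
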
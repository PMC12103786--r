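test_that("the sceptical prior variance has the stated closed form and limits", {
  # z_rct = sqrt(2) z_alpha makes the ratio term 1, so tau^2 = sigma^2
  za <- qnorm(0.975)
  expect_equal(tau_squared(sqrt(2) * za, 0.3, za), 0.09, tolerance = 1e-12)
  # direct substitution: z = 4, sigma = 0.05
  expect_equal(tau_squared(4, 0.05, za), 0.05^2 / (16 / za^2 - 1), tolerance = 1e-12)
  expect_equal(tau_squared(4, 0.05, za), 7.898684e-4, tolerance = 1e-6)
  # prior widens with the original p-value (smaller z) and diverges at the boundary
  taus <- tau_squared(seq(4, 2.2, by = -0.2), 0.05, za)
  expect_true(all(diff(taus) > 0))
  expect_gt(tau_squared(za * (1 + 1e-9), 0.05, za), 1e6)
  expect_error(tau_squared(1.9, 0.05, za), "not significant")
})

test_that("the prior-data conflict tail probability matches the normal cdf", {
  expect_equal(box_tail(log(1.4), log(1.4), 0.02, 0.1), 0.5)
  expect_equal(box_tail(-0.2, 0, 0.01, 0.1), 0.0786496, tolerance = 1e-6)
  # non-inferiority margin 1.4, total predictive variance 0.04
  expect_equal(box_tail(0, log(1.4), 0.03, 0.1), 0.0462494, tolerance = 1e-6)
  # stronger benefit = smaller tail probability (monotone in theta_rwe)
  p <- box_tail(seq(0.2, -0.4, by = -0.1), 0, 0.01, 0.1)
  expect_true(all(diff(p) < 0))
  expect_error(box_tail(0, 0, -0.1, 0.1), "nonnegative")
})

test_that("closed-form sceptical z agrees with bisection on the success equation", {
  set.seed(101)
  n <- 1000
  z_o <- runif(n, 0.05, 6)
  z_r <- runif(n, 0, 6)
  cc <- exp(runif(n, log(0.05), log(50)))
  x_closed <- sceptical_z(z_o, z_r, cc)^2
  for (i in seq_len(n)) {
    x_oracle <- oracle_sceptical_x(z_o[i], z_r[i], cc[i])
    expect_equal(x_closed[i], x_oracle, tolerance = 1e-10,
                 label = sprintf("x at (%.3f, %.3f, %.3f)", z_o[i], z_r[i], cc[i]))
  }
})

test_that("nominal sceptical p-value reproduces known points and conventions", {
  # c = 1 closed form x = zo^2 zr^2 / (zo^2 + zr^2)
  expect_equal(sceptical_z(2, 2, 1), sqrt(2), tolerance = 1e-12)
  expect_equal(p_sceptical_nominal(p_from_z(2), p_from_z(2), 1),
               p_from_z(sqrt(2)), tolerance = 1e-12)
  # TRANSCEND-like inputs
  zs <- sceptical_z(z_from_p(0.10), z_from_p(0.002), 2.3)
  expect_equal(zs^2, 1.1864, tolerance = 1e-4)
  expect_equal(p_from_z(zs), 0.138, tolerance = 1e-3)
  # no replication evidence: z_rwe = 0 gives p_S = 0.5
  expect_equal(p_sceptical_nominal(0.01, 0.5, 1.7), 0.5)
  # one-sidedness: discordant replication flips the sign
  expect_lt(sceptical_z(2, -2, 1), 0)
  # wrong-direction original: not available
  expect_error(sceptical_z(-1, 2, 1), "opposite direction")
  expect_true(is.na(p_sceptical_nominal(0.6, 0.01, 1)))
  # x stays within [0, min(zo^2, zr^2)]
  set.seed(7)
  z_o <- runif(200, 0.1, 5); z_r <- runif(200, 0, 5); cc <- exp(runif(200, -2, 3))
  x <- sceptical_z(z_o, z_r, cc)^2
  expect_true(all(x >= 0 & x <= pmin(z_o^2, z_r^2) + 1e-12))
})

test_that("global-null success probability: limits, monotonicity, TTR bound", {
  expect_lt(t1e_nominal(1e-7, 1), 1e-12)
  expect_equal(t1e_nominal(0.0729, 1), 9.063e-4, tolerance = 1e-3)
  levels <- c(0.001, 0.01, 0.05, 0.1, 0.2, 0.3)
  for (cc in c(0.5, 1, 2, 10)) {
    t1 <- t1e_nominal(levels, rep(cc, length(levels)))
    expect_true(all(diff(t1) > 0))        # increasing in the level
    expect_true(all(t1 < levels^2))       # always below the two-trials rule
    expect_true(all(t1 > 0))
  }
  # empirically decreasing in c at a fixed level
  t_c <- t1e_nominal(rep(0.05, 4), c(0.5, 1, 2, 10))
  expect_true(all(diff(t_c) < 0))
  expect_error(t1e_nominal(0.6, 1), "\\(0, 0.5\\)")
  expect_error(t1e_nominal(0, 1), "\\(0, 0.5\\)")
})

test_that("quadrature T1E agrees with its Monte-Carlo oracle", {
  for (case in list(list(level = 0.138, c = 2.3), list(level = 0.0729, c = 1))) {
    mc <- oracle_t1e_mc(case$level, case$c, n = 2e6, seed = 2024)
    expect_lt(abs(t1e_nominal(case$level, case$c) - mc$estimate), 3 * mc$se)
  }
})

test_that("controlled sceptical p-value: branches, ordering, stringency", {
  # discordant-direction fixtures (PARADIGM-HF and POET-COPD configurations)
  expect_equal(p_sceptical_controlled(1e-6, 0.63, 0.6), 0.6395392, tolerance = 1e-6)
  expect_equal(p_sceptical_controlled(1e-6, 0.66, 0.7), 0.6752397, tolerance = 1e-6)
  # degenerate p_rwe = 1 flows through clipping to a value of 1 at 2 dp
  expect_equal(p_sceptical_controlled(1e-6, 1.00, 0.5), 1.00, tolerance = 1e-3)
  # wrong-direction original
  expect_true(is.na(p_sceptical_controlled(0.73, 0.95, 4.7)))
  expect_true(is.na(p_sceptical_controlled(0.5, 0.01, 1)))
  # z_rwe = 0
  expect_equal(p_sceptical_controlled(0.01, 0.5, 1), 0.5)

  set.seed(55)
  p1 <- runif(40, 1e-4, 0.49)
  p2 <- runif(40, 1e-4, 0.49)
  cc <- exp(runif(40, log(0.2), log(10)))
  ctrl <- p_sceptical_controlled(p1, p2, cc)
  nom <- p_sceptical_nominal(p1, p2, cc)
  # concordant case: recalibration can only make the p-value smaller
  expect_true(all(ctrl <= nom + 1e-12))
  # nominal success at alpha implies the two-trials rule at alpha
  for (alpha in c(0.025, 0.05, 0.1)) {
    hit <- nom <= alpha
    expect_true(all(pmax(p1, p2)[hit] <= alpha + 1e-12))
  }
})

test_that("nominal sceptical p-value is nondecreasing in the variance ratio", {
  cs <- c(0.2, 0.5, 1, 2, 5, 10, 25)
  for (pp in list(c(0.01, 0.01), c(0.001, 0.02), c(0.02, 0.001))) {
    ps <- p_sceptical_nominal(rep(pp[1], length(cs)), rep(pp[2], length(cs)), cs)
    expect_true(all(diff(ps) >= -1e-12))
  }
})

test_that("controlled p_S can fall below p_RCT at large c; p_TTR never can", {
  # fixed original p = 0.01, relative effect size 1: z_rwe = sqrt(c) z_rct
  p_rct <- 0.01
  z_o <- z_from_p(p_rct)
  cs <- seq(0.5, 50, by = 0.5)
  ps <- vapply(cs, function(cc) {
    p_sceptical_controlled(p_rct, p_from_z(sqrt(cc) * z_o), cc)
  }, numeric(1))
  pt <- vapply(cs, function(cc) p_ttr(p_rct, p_from_z(sqrt(cc) * z_o)), numeric(1))
  expect_true(any(ps < p_rct))
  expect_true(all(pt >= p_rct))
})
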
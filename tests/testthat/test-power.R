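test_that("two-trials-rule conditional power: closed form and zero rule", {
  # z = 4.116 is the TRITON-TIMI original (theta = -0.21, CI [-0.31, -0.11])
  expect_equal(power_ttr_conditional(4.116, 1, 0.025), 0.9844596, tolerance = 1e-6)
  expect_equal(power_ttr_conditional(4.116, 1, 0.025),
               pnorm(4.116 - qnorm(0.975)), tolerance = 1e-12)
  # non-significant original: power identically 0 (TRANSCEND, PRONOUNCE)
  expect_equal(power_ttr_conditional(z_from_p(0.10), 2.3, 0.025), 0)
  expect_equal(power_ttr_conditional(z_from_p(0.73), 4.7, 0.025), 0)
  # original exactly at the boundary, c = 1: power 1/2
  expect_equal(power_ttr_conditional(qnorm(0.975), 1, 0.025), 0.5)
  expect_error(power_ttr_conditional(2, -1, 0.025), "positive")
  expect_error(power_ttr_conditional(2, 1, 0.7), "\\(0, 0.5\\)")
})

test_that("two-trials-rule predictive power equals the averaged conditional power", {
  expect_equal(power_ttr_predictive(4.116, 1, 0.025), 0.936314, tolerance = 1e-6)
  za <- qnorm(0.975)
  for (z in c(2.2, 3, 4.116)) {
    for (cc in c(0.5, 1, 2)) {
      expect_equal(power_ttr_predictive(z, cc, 0.025),
                   oracle_predictive(z, cc, za), tolerance = 1e-6)
    }
  }
  expect_equal(power_ttr_predictive(50, 1, 0.025), 1)
  expect_equal(power_ttr_predictive(z_from_p(0.10), 2.3, 0.025), 0)
})

test_that("calibrated nominal level solves the defining equation", {
  for (alpha in c(0.1, 0.05, 0.025)) {
    for (cc in c(0.5, 1, 2)) {
      lambda <- calibrated_nominal_level(alpha, cc)
      expect_equal(t1e_nominal(lambda, cc), alpha^2, tolerance = 1e-8)
      expect_gt(lambda, alpha^2)
      # a pair sitting exactly at the nominal boundary has controlled p = alpha
      zl <- qnorm(1 - lambda)
      z_o <- zl * 1.7
      z_r <- zl * sqrt(1 + cc / (z_o^2 / zl^2 - 1))
      expect_equal(p_sceptical_controlled(p_from_z(z_o), p_from_z(z_r), cc),
                   alpha, tolerance = 1e-6)
    }
  }
  expect_error(calibrated_nominal_level(0.6, 1), "\\(0, 0.5\\)")
})

test_that("sceptical power is zero below the calibrated boundary, positive above", {
  # the three non-significant originals of the application
  expect_equal(power_sceptical_conditional(z_from_p(0.34), 19.9, 0.025), 0)
  expect_equal(power_sceptical_conditional(z_from_p(0.10), 2.3, 0.025), 0)
  expect_equal(power_sceptical_predictive(z_from_p(0.10), 2.3, 0.025), 0)
  expect_equal(power_sceptical_conditional(z_from_p(0.73), 4.7, 0.025), 0)
  # regression fixtures verified against Monte-Carlo in the simulation tests
  expect_equal(power_sceptical_conditional(3, 1, 0.025), 0.8943339, tolerance = 1e-6)
  expect_equal(power_sceptical_predictive(3, 2, 0.025), 0.9273373, tolerance = 1e-6)
})

test_that("sceptical predictive power equals the averaged conditional power", {
  for (z in c(2.5, 3, 4)) {
    for (cc in c(0.5, 1, 2)) {
      lambda <- calibrated_nominal_level(0.025, cc)
      zl <- qnorm(1 - lambda)
      zmin <- zl * sqrt(1 + cc / (z^2 / zl^2 - 1))
      expect_equal(power_sceptical_predictive(z, cc, 0.025),
                   oracle_predictive(z, cc, zmin), tolerance = 1e-6)
    }
  }
})

test_that("power orderings: sceptical >= TTR; averaging shrinks towards 1/2", {
  # the ordering holds for convincingly significant originals (the study
  # pairs of the application all have p_rct <= 0.002, z >= 2.878); near the
  # significance boundary the sceptical success threshold exceeds z_alpha
  # and the ordering can flip
  zs_tab2 <- c(2.878, 3.2, 3.7, 4.5)
  for (cc in c(0.5, 1, 2)) {
    ttr_c <- power_ttr_conditional(zs_tab2, cc, 0.025)
    sc_c <- power_sceptical_conditional(zs_tab2, cc, 0.025)
    expect_true(all(sc_c >= ttr_c - 1e-12))
    ttr_p <- power_ttr_predictive(zs_tab2, cc, 0.025)
    sc_p <- power_sceptical_predictive(zs_tab2, cc, 0.025)
    expect_true(all(sc_p >= ttr_p - 1e-12))
  }
  # predictive < conditional when conditional > 1/2, and vice versa
  zs <- c(2.05, 2.1, 2.5, 3, 3.5, 4.5)
  for (cc in c(0.5, 1, 2)) {
    for (flav in list(cbind(power_ttr_conditional(zs, cc, 0.025),
                            power_ttr_predictive(zs, cc, 0.025)),
                      cbind(power_sceptical_conditional(zs, cc, 0.025),
                            power_sceptical_predictive(zs, cc, 0.025)))) {
      hi <- flav[, 1] > 0.5
      expect_true(all(flav[hi, 2] < flav[hi, 1]))
      lo <- flav[, 1] < 0.5 & flav[, 1] > 0
      expect_true(all(flav[lo, 2] > flav[lo, 1]))
    }
  }
})

test_that("power is nondecreasing in the original evidence and in c", {
  zs <- seq(2.1, 5, by = 0.2)
  for (cc in c(0.5, 1, 2)) {
    expect_true(all(diff(power_ttr_conditional(zs, cc, 0.025)) >= 0))
    expect_true(all(diff(power_sceptical_conditional(zs, cc, 0.025)) >= 0))
  }
  cs <- c(0.25, 0.5, 1, 2, 4, 8)
  for (z in c(2.5, 3.5)) {
    expect_true(all(diff(vapply(cs, function(cc) power_ttr_conditional(z, cc, 0.025), 1)) >= 0))
    expect_true(all(diff(vapply(cs, function(cc) power_sceptical_conditional(z, cc, 0.025), 1)) >= 0))
  }
})

test_that("conditional Type-I error of the sceptical method is bounded by 2 alpha", {
  alpha <- 0.025
  expect_equal(t1e_sceptical_conditional(2.5, 1, alpha), 0.0288516, tolerance = 1e-5)
  expect_equal(t1e_sceptical_conditional(1.2, 1, alpha), 0)  # below the boundary
  for (cc in c(0.5, 1, 2)) {
    # z range spanning conditional powers ~0.2 to ~0.94
    zs <- seq(1.8, 6, by = 0.05)
    pow <- power_sceptical_conditional(zs, cc, alpha)
    keep <- pow > 0.2 & pow < 0.95
    expect_gt(sum(keep), 10)
    expect_true(all(t1e_sceptical_conditional(zs[keep], cc, alpha) <= 2 * alpha))
  }
})

test_that("the generic power interface dispatches and reports the calibrated level", {
  r <- replication_power(p_rct = 1.925e-5, c = 1, alpha = 0.025,
                         method = "ttr", flavor = "conditional")
  expect_equal(r$value, 0.9844, tolerance = 1e-3)
  r2 <- replication_power(z_rct = 3, c = 1, method = "sceptical", flavor = "conditional")
  expect_equal(r2$value, power_sceptical_conditional(3, 1, 0.025))
  expect_equal(r2$nominal_threshold_level, calibrated_nominal_level(0.025, 1))
  expect_error(replication_power(c = 1), "z_rct or p_rct")
})
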
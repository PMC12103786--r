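# Shared helpers: independent oracles and small synthetic fixtures.

# Independent oracle for the nominal sceptical z: solve the success equation
# z_r^2 = x + c x^2 / (z_o^2 - x) for x = z_S^2 by plain bisection on
# (0, min(z_o^2, z_r^2)).  Kept free of the closed form it cross-checks.
oracle_sceptical_x <- function(z_o, z_r, c) {
  zo2 <- z_o^2
  zr2 <- z_r^2
  if (zr2 == 0) return(0)
  h <- function(x) x + c * x^2 / (zo2 - x) - zr2
  lo <- 0
  hi <- min(zo2, zr2) * (1 - 1e-14)
  if (h(hi) < 0) return(min(zo2, zr2))  # boundary root within tolerance
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Monte-Carlo oracle for the global-null success probability of the nominal
# sceptical p-value at a one-sided level.
oracle_t1e_mc <- function(level, c, n, seed) {
  set.seed(seed)
  z_o <- rnorm(n)
  z_r <- rnorm(n)
  zl <- qnorm(1 - level)
  ok <- z_o > 0
  zs <- rep(-Inf, n)
  zs[ok] <- sceptical_z(z_o[ok], z_r[ok], c)
  hits <- mean(zs >= zl)
  list(estimate = hits, se = sqrt(hits * (1 - hits) / n))
}

# Average a conditional-power kernel over the original estimate's sampling
# distribution by quadrature (the predictive-power oracle): the success
# threshold stays fixed at the observed original, the truth is resampled.
oracle_predictive <- function(z_rct, c, threshold) {
  integrate(function(s) {
    dnorm(s) * pnorm(sqrt(c) * (z_rct + s) - threshold)
  }, lower = -10, upper = 10, rel.tol = 1e-10)$value
}

# A summaries CSV on disk for I/O tests.
write_summary_csv <- function(path, p_rct = c("<0.0001", "0.10"),
                              p_rwe = c("0.007", "0.002"),
                              c_ratio = c(1.0, 2.3),
                              medicare = c(FALSE, FALSE),
                              study_id = c("A", "B")) {
  writeLines(c(
    "study_id,p_rct,p_rwe,c,medicare",
    paste(study_id, p_rct, p_rwe, c_ratio, medicare, sep = ",")
  ), path)
  path
}
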
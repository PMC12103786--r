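# Reverse-Bayes sceptical p-value machinery.
#
# The sceptical prior is a normal prior centred at the margin whose variance
# tau^2 is chosen so that it renders the original (RCT) finding just
# non-convincing at the level being challenged.  Replication success is
# significant prior-data conflict between that prior and the RWE estimate,
# assessed through the prior-predictive tail probability of Box.

#' Variance of the sceptical prior
#'
#' The sufficiently sceptical prior variance
#' \eqn{\tau^2 = \sigma^2_{RCT} / (z^2_{RCT} / z^2_\alpha - 1)}: the flattest
#' normal prior (centred at the margin) under which the original result is no
#' longer convincing at the challenged level.  It widens as the original
#' p-value grows and diverges as \eqn{z_{RCT} \to z_\alpha}.
#'
#' @param z_rct signed z-score of the RCT (positive = intended direction).
#' @param sigma_rct standard error of the RCT log hazard-ratio estimate.
#' @param z_alpha normal quantile of the challenged level.
#' @return prior variance (log-HR squared units).
#' @export
tau_squared <- function(z_rct, sigma_rct, z_alpha) {
  if (any(sigma_rct <= 0)) stop("sigma_rct must be positive", call. = FALSE)
  if (any(z_rct^2 <= z_alpha^2)) {
    stop("sceptical prior undefined: original result not significant at the challenged level",
         call. = FALSE)
  }
  sigma_rct^2 / (z_rct^2 / z_alpha^2 - 1)
}

#' Prior-data conflict tail probability
#'
#' Box's tail probability of the replication estimate under the
#' prior-predictive distribution of the sceptical prior,
#' \eqn{p_{Box} = \Phi\{(\hat\theta_{RWE} - \delta) / \sqrt{\tau^2 +
#' \sigma^2_{RWE}}\}} with \eqn{\delta} the margin on the log-HR scale.
#' Smaller values indicate stronger conflict, i.e. more replication success.
#'
#' @param theta_rwe RWE log hazard-ratio estimate.
#' @param delta non-inferiority margin on the log-HR scale (0 for superiority).
#' @param tau2 sceptical prior variance (>= 0).
#' @param sigma_rwe RWE standard error (> 0).
#' @return tail probability.
#' @export
box_tail <- function(theta_rwe, delta, tau2, sigma_rwe) {
  if (any(tau2 < 0)) stop("tau2 must be nonnegative", call. = FALSE)
  if (any(sigma_rwe <= 0)) stop("sigma_rwe must be positive", call. = FALSE)
  stats::pnorm((theta_rwe - delta) / sqrt(tau2 + sigma_rwe^2))
}

#' Nominal sceptical z-value
#'
#' The nominal sceptical z is the largest z-threshold at which the sceptical
#' prior is still in significant conflict with the replication estimate.  Its
#' square \eqn{x = z_S^2} solves \eqn{(c - 1) x^2 + (z^2_{RCT} + z^2_{RWE}) x
#' - z^2_{RCT} z^2_{RWE} = 0} and is evaluated in the numerically stable form
#' \eqn{x = 2P / (A + \sqrt{A^2 + 4 (c - 1) P})} with
#' \eqn{A = z^2_{RCT} + z^2_{RWE}}, \eqn{P = z^2_{RCT} z^2_{RWE}}.
#' One-sidedness: \code{sign(z_S) = sign(z_rwe)}, so replication success is
#' only possible when the replication estimate points the same way as the
#' original.
#'
#' @param z_rct signed RCT z-score; must be positive (intended direction).
#' @param z_rwe signed RWE z-score.
#' @param c variance ratio \eqn{\sigma^2_{RCT} / \sigma^2_{RWE}} (> 0).
#' @return signed nominal sceptical z.
#' @export
sceptical_z <- function(z_rct, z_rwe, c) {
  if (any(z_rct <= 0)) {
    stop("sceptical z not available: RCT effect estimate in the opposite direction",
         call. = FALSE)
  }
  if (any(c <= 0)) stop("variance ratio c must be positive", call. = FALSE)
  zo2 <- z_rct^2
  zr2 <- z_rwe^2
  A <- zo2 + zr2
  P <- zo2 * zr2
  # discriminant >= (zo2 - zr2)^2 >= 0; guard rounding
  disc <- pmax(A^2 + 4 * (c - 1) * P, 0)
  x <- ifelse(P == 0, 0, 2 * P / (A + sqrt(disc)))
  sign(z_rwe) * sqrt(x)
}

#' Nominal sceptical p-value
#'
#' \eqn{p_S = 1 - \Phi(z_S)} with \code{\link{sceptical_z}}.  Returns
#' \code{NA} when the RCT estimate is in the wrong direction
#' (\code{p_rct >= 0.5}), where the sceptical prior construction is
#' unavailable.
#'
#' @param p_rct,p_rwe one-sided margin-referenced p-values.
#' @param c variance ratio (> 0).
#' @return nominal sceptical p-value (possibly \code{NA}).
#' @export
p_sceptical_nominal <- function(p_rct, p_rwe, c) {
  z_rct <- z_from_p(p_rct)
  z_rwe <- z_from_p(p_rwe)
  out <- rep(NA_real_, length(z_rct))
  ok <- z_rct > 0
  if (any(ok)) {
    out[ok] <- p_from_z(sceptical_z(z_rct[ok], z_rwe[ok], rep_len(c, length(z_rct))[ok]))
  }
  out
}

#' Overall Type-I error of the nominal sceptical p-value
#'
#' Probability of nominal replication success at a given one-sided level when
#' both true effects sit at the margin (the global null) and the two
#' z-statistics are independent standard normal.  Success requires
#' \eqn{z_{RCT} > z_\ell} and \eqn{z_{RWE} \ge z_\ell \sqrt{1 + c /
#' (z^2_{RCT} / z^2_\ell - 1)}}, giving the one-dimensional integral
#' \deqn{T(\ell, c) = \int_{z_\ell}^{\infty} \phi(u)\,
#'   \bar\Phi\{ z_\ell \sqrt{1 + c / (u^2 / z^2_\ell - 1)} \}\, du,}
#' evaluated by adaptive quadrature on \eqn{(z_\ell (1 + 10^{-12}),
#' z_\ell + 10)}; the integrand vanishes at the lower limit and the upper
#' truncation error is bounded by \eqn{\bar\Phi(z_\ell + 10)}.
#' The result always lies below \eqn{\ell^2}, the Type-I error of the
#' two-trials rule at the same level.
#'
#' @param level nominal one-sided level in (0, 0.5).
#' @param c variance ratio (> 0).
#' @return success probability under the global null.
#' @export
t1e_nominal <- function(level, c) {
  if (length(level) > 1 || length(c) > 1) {
    return(mapply(t1e_nominal, level = level, c = c))
  }
  if (!is.finite(level) || level <= 0 || level >= 0.5) {
    stop("level must lie in (0, 0.5)", call. = FALSE)
  }
  if (c <= 0) stop("variance ratio c must be positive", call. = FALSE)
  zl <- stats::qnorm(1 - level)
  f <- function(u) {
    stats::dnorm(u) *
      stats::pnorm(zl * sqrt(1 + c / (u^2 / zl^2 - 1)), lower.tail = FALSE)
  }
  int <- stats::integrate(f, lower = zl * (1 + 1e-12), upper = zl + 10,
                          abs.tol = 1e-12, rel.tol = 1e-10,
                          stop.on.error = FALSE)
  if (!int$message %in% c("OK", "roundoff error was detected")) {
    int <- stats::integrate(f, lower = zl * (1 + 1e-12), upper = zl + 10,
                            abs.tol = 1e-10, rel.tol = 1e-8)
  }
  min(max(int$value, 0), level^2)
}

#' Controlled (exactly calibrated) sceptical p-value
#'
#' Recalibration of the nominal sceptical p-value so that thresholding at any
#' one-sided level \eqn{\alpha} yields overall Type-I error exactly
#' \eqn{\alpha^2} under the global null, for every variance ratio c — the
#' same operating characteristic as the two-trials rule.  Computed forward as
#' \eqn{q = \sqrt{T(p_S^{nominal}(|z_{RCT}|, |z_{RWE}|, c), c)}} with
#' \code{\link{t1e_nominal}}; the reported value is \eqn{q} when the
#' replication estimate is concordant with the original (\eqn{z_{RWE} > 0})
#' and \eqn{1 - q} when it is discordant, and exactly 0.5 at
#' \eqn{z_{RWE} = 0}.  \code{NA} when \code{p_rct >= 0.5} (original estimate
#' in the wrong direction, e.g. PRONOUNCE).
#'
#' @param p_rct,p_rwe one-sided margin-referenced p-values.
#' @param c variance ratio (> 0).
#' @return controlled sceptical p-value (possibly \code{NA}).
#' @examples
#' p_sceptical_controlled(0.10, 0.002, 2.3)  # TRANSCEND-like pair, ~0.064
#' @export
p_sceptical_controlled <- function(p_rct, p_rwe, c) {
  n <- max(length(p_rct), length(p_rwe), length(c))
  p_rct <- rep_len(p_rct, n); p_rwe <- rep_len(p_rwe, n); c <- rep_len(c, n)
  vapply(seq_len(n), function(i) {
    .p_sceptical_controlled1(p_rct[i], p_rwe[i], c[i])
  }, numeric(1))
}

.p_sceptical_controlled1 <- function(p_rct, p_rwe, c) {
  .p_sceptical_controlled_z(z_from_p(p_rct), z_from_p(p_rwe), c)
}

# z-scale entry point; clips to the same range as the p-value clipping so
# that extreme evidence yields a finite sceptical level inside (0, 0.5)
.p_sceptical_controlled_z <- function(z_rct, z_rwe, c) {
  zmax <- stats::qnorm(1 - .P_CLIP)
  z_rct <- min(max(z_rct, -zmax), zmax)
  z_rwe <- min(max(z_rwe, -zmax), zmax)
  if (z_rct <= 0) return(NA_real_)
  if (z_rwe == 0) return(0.5)
  p_nom <- p_from_z(sceptical_z(z_rct, abs(z_rwe), c))
  # z_rct > 0 and |z_rwe| > 0 give z_S > 0, but p_nom can round to 0.5 when
  # z_rwe is within floating-point noise of 0; keep it inside (0, 0.5)
  p_nom <- min(p_nom, 0.5 - 1e-12)
  q <- sqrt(t1e_nominal(p_nom, c))
  if (z_rwe > 0) q else 1 - q
}
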
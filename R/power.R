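# Replication power for the two-trials rule and the controlled sceptical
# p-value.  Conditional power treats the original point estimate as the
# truth; predictive power additionally averages over the sampling
# distribution of the original estimate, which shrinks extreme powers
# towards 1/2.

.level_cache <- new.env(parent = emptyenv())

#' Calibrated nominal level for the controlled sceptical p-value
#'
#' The nominal one-sided level \eqn{\lambda} at which the nominal sceptical
#' p-value has overall Type-I error exactly \eqn{\alpha^2} under the global
#' null, i.e. the root of \eqn{T(\lambda, c) = \alpha^2} (see
#' \code{\link{t1e_nominal}}).  Thresholding the controlled sceptical
#' p-value at \eqn{\alpha} is equivalent to thresholding the nominal one at
#' \eqn{\lambda}.  Always \eqn{\lambda > \alpha^2} because
#' \eqn{T(\ell, c) < \ell^2}.  Results are cached per \eqn{(\alpha, c)}.
#'
#' @param alpha one-sided level in (0, 0.5).
#' @param c variance ratio (> 0).
#' @return the calibrated nominal level.
#' @export
calibrated_nominal_level <- function(alpha, c) {
  if (length(alpha) > 1 || length(c) > 1) {
    return(mapply(calibrated_nominal_level, alpha = alpha, c = c))
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 0.5) {
    stop("alpha must lie in (0, 0.5)", call. = FALSE)
  }
  key <- sprintf("%.17g|%.17g", alpha, c)
  if (!is.null(.level_cache[[key]])) return(.level_cache[[key]])
  g <- function(l) t1e_nominal(l, c) - alpha^2
  lo <- alpha^2 * 0.9
  hi <- 0.5 - 1e-9
  if (g(lo) >= 0 || g(hi) <= 0) {
    stop("calibration failed: no root in bracket for alpha = ", alpha,
         ", c = ", c, call. = FALSE)
  }
  lambda <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-12)$root
  .level_cache[[key]] <- lambda
  lambda
}

# replication z-threshold for nominal success at level lambda given the
# original z; exists only for z_rct > z_lambda
.z_min_sceptical <- function(z_rct, z_lambda, c) {
  z_lambda * sqrt(1 + c / (z_rct^2 / z_lambda^2 - 1))
}

#' Conditional replication power of the two-trials rule
#'
#' Probability that the replication is significant at \code{alpha}, taking
#' the original point estimate as the true effect, so that
#' \eqn{z_{RWE} \sim N(\sqrt{c}\, z_{RCT}, 1)}:
#' \eqn{\Phi(\sqrt{c}\, z_{RCT} - z_{1-\alpha})}.  Exactly 0 when the
#' original itself is not significant (\eqn{p_{RCT} > \alpha}) — the
#' two-trials rule can then never succeed.
#'
#' @param z_rct signed z-score of the original study.
#' @param c variance ratio (> 0).
#' @param alpha one-sided level in (0, 0.5).
#' @return success probability.
#' @export
power_ttr_conditional <- function(z_rct, c, alpha) {
  .check_power_args(c, alpha)
  za <- stats::qnorm(1 - alpha)
  ifelse(z_rct < za, 0, stats::pnorm(sqrt(c) * z_rct - za))
}

#' Predictive replication power of the two-trials rule
#'
#' Conditional power averaged over the sampling distribution of the original
#' estimate; in closed form the replication z is marginally
#' \eqn{N(\sqrt{c}\, z_{RCT},\, 1 + c)}, giving
#' \eqn{\Phi\{(\sqrt{c}\, z_{RCT} - z_{1-\alpha}) / \sqrt{1 + c}\}}.
#' Zero when the original is not significant.
#'
#' @inheritParams power_ttr_conditional
#' @return success probability.
#' @export
power_ttr_predictive <- function(z_rct, c, alpha) {
  .check_power_args(c, alpha)
  za <- stats::qnorm(1 - alpha)
  ifelse(z_rct < za, 0, stats::pnorm((sqrt(c) * z_rct - za) / sqrt(1 + c)))
}

#' Conditional replication power of the controlled sceptical p-value
#'
#' With \eqn{\lambda} the calibrated nominal level for \code{alpha}
#' (\code{\link{calibrated_nominal_level}}) and \eqn{z_\lambda} its normal
#' quantile, success requires \eqn{z_{RWE} \ge z_{min} = z_\lambda \sqrt{1 +
#' c / (z^2_{RCT} / z^2_\lambda - 1)}}.  Under the conditional sampling model
#' \eqn{z_{RWE} \sim N(\sqrt{c}\, z_{RCT}, 1)} the power is
#' \eqn{\Phi(\sqrt{c}\, z_{RCT} - z_{min})}.  For \eqn{z_{RCT} \le z_\lambda}
#' the finite success threshold ceases to exist and the power is 0.
#'
#' @inheritParams power_ttr_conditional
#' @return success probability.
#' @export
power_sceptical_conditional <- function(z_rct, c, alpha) {
  .check_power_args(c, alpha)
  lambda <- calibrated_nominal_level(alpha, c)
  zl <- stats::qnorm(1 - lambda)
  ifelse(z_rct <= zl, 0,
         stats::pnorm(sqrt(c) * z_rct - .z_min_sceptical(pmax(z_rct, zl * (1 + 1e-12)), zl, c)))
}

#' Predictive replication power of the controlled sceptical p-value
#'
#' As \code{\link{power_sceptical_conditional}} but averaging over the
#' original estimate's sampling distribution:
#' \eqn{\Phi\{(\sqrt{c}\, z_{RCT} - z_{min}) / \sqrt{1 + c}\}}, zero below
#' the calibrated boundary.
#'
#' @inheritParams power_ttr_conditional
#' @return success probability.
#' @export
power_sceptical_predictive <- function(z_rct, c, alpha) {
  .check_power_args(c, alpha)
  lambda <- calibrated_nominal_level(alpha, c)
  zl <- stats::qnorm(1 - lambda)
  ifelse(z_rct <= zl, 0,
         stats::pnorm((sqrt(c) * z_rct -
                         .z_min_sceptical(pmax(z_rct, zl * (1 + 1e-12)), zl, c)) / sqrt(1 + c)))
}

#' Conditional Type-I error of the controlled sceptical p-value
#'
#' Probability of replication success when the replication's true effect sits
#' at the null/margin, conditional on the observed original:
#' \eqn{\Phi(-z_{min})}, 0 below the calibrated boundary.  Whenever the
#' conditional power to detect the original effect is below 95% this is
#' bounded by \eqn{2\alpha} — the price of the sceptical p-value's extra
#' power relative to the two-trials rule.
#'
#' @inheritParams power_ttr_conditional
#' @return conditional Type-I error.
#' @export
t1e_sceptical_conditional <- function(z_rct, c, alpha) {
  .check_power_args(c, alpha)
  lambda <- calibrated_nominal_level(alpha, c)
  zl <- stats::qnorm(1 - lambda)
  ifelse(z_rct <= zl, 0,
         stats::pnorm(-.z_min_sceptical(pmax(z_rct, zl * (1 + 1e-12)), zl, c)))
}

#' Replication power, generic interface
#'
#' Dispatcher over method (\code{"ttr"}, \code{"sceptical"}) and flavor
#' (\code{"conditional"}, \code{"predictive"}); accepts the original study
#' either as a z-score or as a one-sided p-value.
#'
#' @param z_rct signed original z-score (alternative to \code{p_rct}).
#' @param c variance ratio (> 0).
#' @param alpha one-sided level, default 0.025.
#' @param method \code{"ttr"} or \code{"sceptical"}.
#' @param flavor \code{"conditional"} or \code{"predictive"}.
#' @param p_rct one-sided original p-value (alternative to \code{z_rct}).
#' @return data frame with \code{method}, \code{flavor}, \code{level},
#'   \code{value} and, for the sceptical method, the calibrated
#'   \code{nominal_threshold_level}.
#' @export
replication_power <- function(z_rct = NULL, c, alpha = 0.025,
                              method = c("ttr", "sceptical"),
                              flavor = c("conditional", "predictive"),
                              p_rct = NULL) {
  method <- match.arg(method)
  flavor <- match.arg(flavor)
  if (is.null(z_rct)) {
    if (is.null(p_rct)) stop("supply z_rct or p_rct", call. = FALSE)
    z_rct <- z_from_p(p_rct)
  }
  fun <- switch(paste(method, flavor, sep = "."),
                ttr.conditional = power_ttr_conditional,
                ttr.predictive = power_ttr_predictive,
                sceptical.conditional = power_sceptical_conditional,
                sceptical.predictive = power_sceptical_predictive)
  data.frame(
    method = method, flavor = flavor, level = alpha,
    value = fun(z_rct, c, alpha),
    nominal_threshold_level = if (method == "sceptical") {
      calibrated_nominal_level(alpha, c)
    } else NA_real_
  )
}

.check_power_args <- function(c, alpha) {
  if (any(c <= 0)) stop("variance ratio c must be positive", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 0.5)) stop("alpha must lie in (0, 0.5)", call. = FALSE)
}
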
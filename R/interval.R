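# One-sided confidence limits for the combined effect by inversion of the
# controlled sceptical p-value: the upper limit is the margin delta at which
# the squared controlled sceptical p-value equals 1 - conf.

# controlled sceptical p of a single pair evaluated against margin delta
# (log-HR scale); all p-values re-derived from (theta, se, delta)
.controlled_p_at_delta <- function(delta, theta_rct, se_rct, theta_rwe, se_rwe) {
  .p_sceptical_controlled_z((delta - theta_rct) / se_rct,
                            (delta - theta_rwe) / se_rwe,
                            se_rct^2 / se_rwe^2)
}

#' Upper confidence limit by inversion of the controlled sceptical p-value
#'
#' Finds the margin \eqn{\delta = \theta_u} at which the controlled sceptical
#' p-value of the pair — with both one-sided p-values re-derived from
#' \eqn{(\hat\theta, \sigma, \delta)} — satisfies
#' \eqn{p_S(\delta)^2 = 1 - conf}.  For the default \code{conf = 0.975} this
#' is the point where the squared sceptical p-value equals 0.025.
#' Exponentiation gives an upper limit on the hazard-ratio scale directly
#' comparable to a non-inferiority (or superiority) margin.
#'
#' The root is located by bisection on
#' \eqn{[\min(\hat\theta) - 10 \max(\sigma),\, \max(\hat\theta) + 10
#' \max(\sigma)]} to absolute tolerance 1e-8 (the objective is monotone in
#' \eqn{\delta} but has no closed-form derivative).  If the controlled
#' p-value never crosses the target inside the bracket the limit is
#' \code{NA} with a diagnostic attribute.
#'
#' @param theta_rct,theta_rwe log hazard-ratio estimates.
#' @param se_rct,se_rwe standard errors (> 0).
#' @param conf one-sided confidence level, default 0.975.
#' @return data frame with \code{conf}, \code{theta_u} (log-HR) and
#'   \code{hr_u} (= exp(theta_u)); \code{NA} entries when no root exists.
#' @export
sceptical_upper_limit <- function(theta_rct, se_rct, theta_rwe, se_rwe,
                                  conf = 0.975) {
  if (length(theta_rct) > 1) {
    out <- mapply(sceptical_upper_limit, theta_rct, se_rct, theta_rwe, se_rwe,
                  MoreArgs = list(conf = conf), SIMPLIFY = FALSE)
    return(do.call(rbind, out))
  }
  if (se_rct <= 0 || se_rwe <= 0) stop("standard errors must be positive", call. = FALSE)
  if (conf <= 0.5 || conf >= 1) stop("conf must lie in (0.5, 1)", call. = FALSE)
  target <- sqrt(1 - conf)
  f <- function(delta) {
    p <- .controlled_p_at_delta(delta, theta_rct, se_rct, theta_rwe, se_rwe)
    if (is.na(p)) 0.5 else p  # NA only for z_rct <= 0, where p >= 0.5 anyway
  }
  lo <- min(theta_rct, theta_rwe) - 10 * max(se_rct, se_rwe)
  hi <- max(theta_rct, theta_rwe) + 10 * max(se_rct, se_rwe)
  # controlled p decreases in delta: above target at lo, below at hi if a root exists
  if (f(lo) < target || f(hi) > target) {
    return(data.frame(conf = conf, theta_u = NA_real_, hr_u = NA_real_))
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > target) lo <- mid else hi <- mid
    if (hi - lo < 1e-8) break
  }
  theta_u <- (lo + hi) / 2
  data.frame(conf = conf, theta_u = theta_u, hr_u = exp(theta_u))
}

#' Compare sceptical and meta-analytic upper limits
#'
#' Returns both one-sided upper limits on the hazard-ratio scale: the
#' sceptical-inversion limit (\code{\link{sceptical_upper_limit}}) and the
#' fixed-effect meta-analytic limit (\code{\link{meta_fixed}} at the matching
#' one-sided level), and flags the qualitative disagreement where the pooled
#' interval claims significance (meta upper limit < 1) while the sceptical
#' limit stays above 1 — the situation that arises when one of the two
#' estimates points the wrong way, as for PARADIGM-HF, IMPACT and POET-COPD.
#'
#' @inheritParams sceptical_upper_limit
#' @return data frame with \code{sceptical_hr_u}, \code{meta_hr_u},
#'   \code{disagreement}.
#' @export
compare_upper_limits <- function(theta_rct, se_rct, theta_rwe, se_rwe,
                                 conf = 0.975) {
  sc <- sceptical_upper_limit(theta_rct, se_rct, theta_rwe, se_rwe, conf)
  z <- stats::qnorm(conf)
  meta <- meta_fixed(theta_rct, se_rct, theta_rwe, se_rwe)
  meta_hr_u <- exp(meta$theta_pooled + z * meta$se_pooled)
  data.frame(
    sceptical_hr_u = sc$hr_u,
    meta_hr_u = meta_hr_u,
    disagreement = !is.na(sc$hr_u) & meta_hr_u < 1 & sc$hr_u > 1
  )
}
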
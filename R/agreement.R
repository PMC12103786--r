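# Two-trials rule and the fixed-effect meta-analytic comparator.

#' Two-trials rule p-value
#'
#' \eqn{p_{TTR} = \max\{p_{RCT}, p_{RWE}\}}: success at a one-sided level
#' \eqn{\alpha} iff both studies are individually significant at
#' \eqn{\alpha} with estimates in the intended direction.  It can never be
#' smaller than either of its arguments.
#'
#' @param p_rct,p_rwe one-sided margin-referenced p-values in (0, 1].
#' @return the two-trials-rule p-value.
#' @export
p_ttr <- function(p_rct, p_rwe) {
  if (any(p_rct <= 0 | p_rct > 1) || any(p_rwe <= 0 | p_rwe > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  pmax(p_rct, p_rwe)
}

#' Fixed-effect meta-analysis of an RCT/RWE pair
#'
#' Inverse-variance pooling: weights \eqn{w = 1/\sigma^2}, pooled effect
#' \eqn{\sum w \hat\theta / \sum w}, pooled standard error
#' \eqn{(\sum w)^{-1/2}}, with two-sided 95% limits.  An infinite standard
#' error gives that study zero weight, so the degenerate single-study case is
#' recovered as a limit.
#'
#' Note that the studies entering a fixed-effect pool are treated as
#' interchangeable, which the sceptical p-value deliberately avoids; the
#' pooled interval can flag a significant combined effect even when one of
#' the two estimates points the wrong way.
#'
#' @param theta_rct,theta_rwe log hazard-ratio estimates.
#' @param se_rct,se_rwe standard errors (> 0, \code{Inf} allowed).
#' @return data frame with \code{theta_pooled}, \code{se_pooled},
#'   \code{ci_lo}, \code{ci_hi} (log-HR scale).
#' @export
meta_fixed <- function(theta_rct, se_rct, theta_rwe, se_rwe) {
  if (any(se_rct <= 0) || any(se_rwe <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  w1 <- 1 / se_rct^2
  w2 <- 1 / se_rwe^2
  if (any(w1 + w2 == 0)) stop("at least one study must have finite se", call. = FALSE)
  theta <- (w1 * ifelse(w1 > 0, theta_rct, 0) + w2 * ifelse(w2 > 0, theta_rwe, 0)) / (w1 + w2)
  se <- 1 / sqrt(w1 + w2)
  data.frame(
    theta_pooled = theta,
    se_pooled = se,
    ci_lo = theta - .Z975 * se,
    ci_hi = theta + .Z975 * se
  )
}
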
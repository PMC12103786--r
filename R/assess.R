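# Per-pair replication-success assessment: the ReplicationResult schema.

#' Assess replication success for summary pairs
#'
#' Computes, per pair, the two-trials-rule p-value, the nominal and the
#' controlled sceptical p-value, and success flags at a one-sided level
#' \code{alpha}.  Censored p-values (transcribed as "<0.0001") enter the
#' computation as \code{censored_sub}.  The sceptical p-values are \code{NA}
#' when the original estimate points the wrong way (\eqn{p_{RCT} \ge 0.5});
#' an \code{NA} sceptical p-value counts as failure.
#'
#' @param summaries a \code{summary_pair} data frame
#'   (\code{\link{summary_pair}}, \code{\link{read_summaries}}).
#' @param alpha one-sided level, default 0.025.
#' @param censored_sub value substituted for censored p-values at computation
#'   time, default 1e-6.
#' @return data frame with one row per pair: \code{study_id}, \code{p_ttr},
#'   \code{p_s_nominal}, \code{p_s_controlled}, \code{success_ttr},
#'   \code{success_sceptical}, \code{alpha}, and diagnostics \code{z_rct},
#'   \code{z_rwe}, \code{c}, \code{medicare}.
#' @export
assess_summaries <- function(summaries, alpha = 0.025, censored_sub = 1e-6) {
  summaries <- validate_summary_pair(summaries)
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)", call. = FALSE)
  if (censored_sub <= 0 || censored_sub >= 1) {
    stop("censored_sub must lie in (0, 1)", call. = FALSE)
  }
  p_rct <- ifelse(summaries$p_rct_censored, censored_sub, summaries$p_rct)
  p_rwe <- ifelse(summaries$p_rwe_censored, censored_sub, summaries$p_rwe)
  ps_nom <- p_sceptical_nominal(p_rct, p_rwe, summaries$c)
  ps_ctrl <- p_sceptical_controlled(p_rct, p_rwe, summaries$c)
  res <- data.frame(
    study_id = summaries$study_id,
    p_ttr = p_ttr(p_rct, p_rwe),
    p_s_nominal = ps_nom,
    p_s_controlled = ps_ctrl,
    stringsAsFactors = FALSE
  )
  res$success_ttr <- res$p_ttr <= alpha
  res$success_sceptical <- !is.na(ps_ctrl) & ps_ctrl <= alpha
  res$alpha <- alpha
  res$z_rct <- z_from_p(p_rct)
  res$z_rwe <- z_from_p(p_rwe)
  res$c <- summaries$c
  res$medicare <- summaries$medicare
  res
}

#' Assess replication success for study pairs
#'
#' Reduces the pairs to margin-referenced summaries
#' (\code{\link{summarize_pairs}}), assesses them with
#' \code{\link{assess_summaries}}, and appends the fixed-effect meta-analytic
#' comparator columns.
#'
#' @param pairs a \code{study_pair} data frame.
#' @inheritParams assess_summaries
#' @return the \code{\link{assess_summaries}} data frame plus
#'   \code{meta_theta}, \code{meta_ci_lo}, \code{meta_ci_hi}.
#' @export
assess_pairs <- function(pairs, alpha = 0.025) {
  pairs <- validate_study_pair(pairs)
  res <- assess_summaries(summarize_pairs(pairs), alpha = alpha)
  meta <- meta_fixed(pairs$theta_rct, pairs$se_rct, pairs$theta_rwe, pairs$se_rwe)
  res$meta_theta <- meta$theta_pooled
  res$meta_ci_lo <- meta$ci_lo
  res$meta_ci_hi <- meta$ci_hi
  res
}
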
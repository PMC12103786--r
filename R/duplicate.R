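# Reproduction of the RCT DUPLICATE replication-success analysis from the
# published per-study summary statistics (29 pairs): one-sided p-values of
# the RCT and of the pooled claims-data emulation, both referenced to the
# trial's margin, and the variance ratio c.  Ten of the 29 pairs could not
# include Medicare data in the pooled emulation (medicare = FALSE).

#' Load the embedded RCT DUPLICATE summary table
#'
#' Returns the 29 study pairs as a \code{summary_pair} data frame, with
#' p-values as printed ("<0.0001" entries flagged as censored) and the
#' Medicare-availability flag (FALSE for the 10 pairs emulated without
#' Medicare data).  The published two-trials-rule and sceptical p-value
#' columns are attached as attributes \code{"p_ttr_printed"} /
#' \code{"p_s_printed"} for cross-checking.  The embedded table is verified
#' against simple checksums (row count, Medicare split, sum of variance
#' ratios) at load time.
#'
#' @return a \code{summary_pair} data frame with 29 rows.
#' @export
load_duplicate_table1 <- function() {
  path <- system.file("extdata", "duplicate_table1.csv",
                      package = "scepticalRWE", mustWork = TRUE)
  x <- read_summaries(path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(x) != 29 || sum(!x$medicare) != 10 || sum(x$medicare) != 19 ||
      abs(sum(x$c) - 84.2) > 1e-9) {
    stop("embedded duplicate_table1 fixture failed its checksum", call. = FALSE)
  }
  attr(x, "p_ttr_printed") <- raw$p_ttr_printed
  attr(x, "p_s_printed") <- raw$p_s_printed
  x
}

#' Reproduce the RCT DUPLICATE replication-success report
#'
#' Runs \code{\link{assess_summaries}} on the embedded 29-pair table and
#' tabulates the headline quantities: successes at the one-sided level
#' \code{alpha} under the controlled sceptical p-value and the two-trials
#' rule, the Medicare-stratified success counts, and the number of original
#' trials significant at \code{alpha}.  A pair whose sceptical p-value is
#' \code{NA} (original estimate in the wrong direction, PRONOUNCE) counts as
#' a failure.
#'
#' @param alpha one-sided level, default 0.025.
#' @param censored_sub substitution for p-values printed as "<0.0001",
#'   default 1e-6.
#' @param summaries optional \code{summary_pair} table to analyse instead of
#'   the embedded fixture.
#' @return object of class \code{"duplicate_report"}: a list with
#'   \code{per_study} (the assessment data frame), the headline counts
#'   \code{n_success_sceptical}, \code{n_success_ttr}, \code{n_rct_significant},
#'   the subgroup counts \code{n_success_medicare}/\code{n_medicare} and
#'   \code{n_success_nonmedicare}/\code{n_nonmedicare}, and the inputs
#'   \code{alpha}, \code{censored_sub}.
#' @export
duplicate_report <- function(alpha = 0.025, censored_sub = 1e-6,
                             summaries = load_duplicate_table1()) {
  res <- assess_summaries(summaries, alpha = alpha, censored_sub = censored_sub)
  p_rct_eff <- ifelse(summaries$p_rct_censored, censored_sub, summaries$p_rct)
  med <- res$medicare
  out <- list(
    per_study = res,
    n_success_sceptical = sum(res$success_sceptical),
    n_success_ttr = sum(res$success_ttr),
    n_rct_significant = sum(p_rct_eff <= alpha),
    n_medicare = sum(med),
    n_success_medicare = sum(res$success_sceptical & med),
    n_nonmedicare = sum(!med),
    n_success_nonmedicare = sum(res$success_sceptical & !med),
    alpha = alpha,
    censored_sub = censored_sub
  )
  class(out) <- "duplicate_report"
  out
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat("RCT DUPLICATE replication-success report (one-sided alpha =",
      format(x$alpha), ")\n")
  cat(sprintf("  successes, controlled sceptical p: %d / %d\n",
              x$n_success_sceptical, nrow(x$per_study)))
  cat(sprintf("  successes, two-trials rule:        %d / %d\n",
              x$n_success_ttr, nrow(x$per_study)))
  cat(sprintf("  Medicare-inclusive subgroup:       %d / %d\n",
              x$n_success_medicare, x$n_medicare))
  cat(sprintf("  non-Medicare subgroup:             %d / %d\n",
              x$n_success_nonmedicare, x$n_nonmedicare))
  cat(sprintf("  originals significant at alpha:    %d\n", x$n_rct_significant))
  invisible(x)
}

#' Success proportions across a grid of levels
#'
#' Re-thresholds the per-study controlled sceptical and two-trials-rule
#' p-values at each level in \code{alphas} and returns the success
#' proportions; proportions are nonincreasing as the level decreases.
#'
#' @param alphas numeric vector of one-sided levels in (0, 0.5).
#' @inheritParams duplicate_report
#' @return data frame with \code{alpha}, \code{prop_sceptical},
#'   \code{prop_ttr}.
#' @export
sensitivity_scan <- function(alphas, censored_sub = 1e-6,
                             summaries = load_duplicate_table1()) {
  if (any(alphas <= 0 | alphas >= 0.5)) stop("levels must lie in (0, 0.5)", call. = FALSE)
  res <- assess_summaries(summaries, alpha = 0.025, censored_sub = censored_sub)
  n <- nrow(res)
  data.frame(
    alpha = alphas,
    prop_sceptical = vapply(alphas, function(a) {
      sum(!is.na(res$p_s_controlled) & res$p_s_controlled <= a) / n
    }, numeric(1)),
    prop_ttr = vapply(alphas, function(a) sum(res$p_ttr <= a) / n, numeric(1))
  )
}

#' Shrinkage data series for study-level estimates
#'
#' For pairs supplied on the estimate scale, returns the margin-referenced
#' effects \eqn{\hat\theta_{RCT} - \log(margin)} and
#' \eqn{\hat\theta_{RWE} - \log(margin)} per study; points below the
#' diagonal are emulations whose estimate is shrunken towards the
#' null/margin relative to the original.  Requires a \code{study_pair} table
#' (the embedded p-value fixture carries no raw estimates).
#'
#' @param pairs a \code{study_pair} data frame.
#' @param drop character vector of study ids to omit (e.g. \code{"RECORD1"}).
#' @return data frame with \code{study_id}, \code{rct_margin_effect},
#'   \code{rwe_margin_effect}, \code{shrunken}.
#' @export
shrinkage_series <- function(pairs, drop = character()) {
  pairs <- validate_study_pair(pairs)
  pairs <- pairs[!pairs$study_id %in% drop, , drop = FALSE]
  delta <- log(pairs$margin_hr)
  x <- pairs$theta_rct - delta
  y <- pairs$theta_rwe - delta
  data.frame(
    study_id = pairs$study_id,
    rct_margin_effect = x,
    rwe_margin_effect = y,
    shrunken = y > x  # closer to (or beyond) the margin than the original
  )
}
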
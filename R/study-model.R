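#' @keywords internal
"_PACKAGE"

# z orientation used throughout: positive z = evidence for benefit /
# non-inferiority, z = (log(margin) - theta_hat) / se.  One-sided p-values
# are p = 1 - Phi(z), so p < 0.5 means the estimate is on the good side of
# the margin.

.P_CLIP <- 1e-16
.Z975 <- 1.959964  # sub-rounded 97.5% normal quantile, used for all CI <-> se conversions

#' Convert a one-sided p-value to a signed z-score
#'
#' Inverse-normal transformation \eqn{z = \Phi^{-1}(1 - p)} with the
#' convention that positive z means evidence in the intended direction
#' (benefit, or non-inferiority relative to the margin). p-values are
#' clipped into \code{[1e-16, 1 - 1e-16]} before inversion so that
#' degenerate inputs such as p = 1 yield a large finite z rather than
#' minus infinity.
#'
#' @param p numeric vector of one-sided p-values in (0, 1].
#' @return numeric vector of signed z-scores.
#' @examples
#' z_from_p(c(0.5, 0.025))
#' @export
z_from_p <- function(p) {
  if (!is.numeric(p) || any(!is.na(p) & (p <= 0 | p > 1))) {
    stop("p must be a one-sided p-value in (0, 1]", call. = FALSE)
  }
  stats::qnorm(pmin(pmax(p, .P_CLIP), 1 - .P_CLIP), lower.tail = FALSE)
}

#' Convert a signed z-score to a one-sided p-value
#'
#' @param z numeric vector of signed z-scores (positive = intended direction).
#' @return one-sided p-values \eqn{1 - \Phi(z)}.
#' @export
p_from_z <- function(z) {
  stats::pnorm(z, lower.tail = FALSE)
}

#' Standard error from a 95% confidence interval on the hazard-ratio scale
#'
#' @param lower,upper 95% CI limits on the HR scale.
#' @return standard error of the log hazard ratio.
#' @export
se_from_ci <- function(lower, upper) {
  if (any(lower <= 0 | upper <= 0 | upper <= lower)) {
    stop("need 0 < lower < upper for a hazard-ratio CI", call. = FALSE)
  }
  (log(upper) - log(lower)) / (2 * .Z975)
}

#' Construct a set of RCT/RWE study pairs
#'
#' A \code{study_pair} data frame holds one RCT and its RWE emulation on the
#' log hazard-ratio scale, together with the non-inferiority margin on the
#' hazard-ratio scale (1 for superiority designs).
#'
#' @param study_id character identifier.
#' @param theta_rct,theta_rwe log hazard-ratio estimates.
#' @param se_rct,se_rwe standard errors (> 0).
#' @param margin_hr non-inferiority margin on the HR scale (> 0); must be 1
#'   for superiority designs.
#' @param design one of \code{"superiority"}, \code{"non_inferiority"},
#'   \code{"unknown"}.
#' @param medicare logical, whether the pooled emulation included Medicare
#'   data.
#' @return data frame of class \code{"study_pair"}.
#' @export
study_pair <- function(study_id, theta_rct, se_rct, theta_rwe, se_rwe,
                       margin_hr = 1, design = "unknown", medicare = NA) {
  n <- length(study_id)
  x <- data.frame(
    study_id = as.character(study_id),
    theta_rct = as.numeric(theta_rct), se_rct = as.numeric(se_rct),
    theta_rwe = as.numeric(theta_rwe), se_rwe = as.numeric(se_rwe),
    margin_hr = rep_len(as.numeric(margin_hr), n),
    design = rep_len(as.character(design), n),
    medicare = rep_len(as.logical(medicare), n),
    stringsAsFactors = FALSE
  )
  validate_study_pair(x)
}

validate_study_pair <- function(x) {
  stopifnot(is.data.frame(x))
  if (any(x$se_rct <= 0) || any(x$se_rwe <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  if (any(x$margin_hr <= 0)) stop("margin_hr must be positive", call. = FALSE)
  bad <- x$design == "superiority" & x$margin_hr != 1
  if (any(bad)) {
    stop("superiority designs must have margin_hr = 1 (rows: ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  if (!all(x$design %in% c("superiority", "non_inferiority", "unknown"))) {
    stop("design must be superiority, non_inferiority or unknown", call. = FALSE)
  }
  class(x) <- c("study_pair", "data.frame")
  x
}

#' Construct a set of summary pairs
#'
#' The reduced representation of a study pair: one-sided p-values already
#' referenced to the margin, plus the variance ratio
#' \eqn{c = \sigma^2_{RCT} / \sigma^2_{RWE}}.  p-values transcribed from
#' censored table entries ("<0.0001") keep their censoring flag; a
#' substitution value is applied only at computation time.
#'
#' @param study_id character identifier.
#' @param p_rct,p_rwe one-sided margin-referenced p-values in (0, 1].
#' @param c variance ratio (> 0).
#' @param p_rct_censored,p_rwe_censored logical censoring flags.
#' @param medicare logical Medicare-availability flag.
#' @return data frame of class \code{"summary_pair"}.
#' @export
summary_pair <- function(study_id, p_rct, p_rwe, c,
                         p_rct_censored = FALSE, p_rwe_censored = FALSE,
                         medicare = NA) {
  n <- length(study_id)
  x <- data.frame(
    study_id = as.character(study_id),
    p_rct = as.numeric(p_rct), p_rwe = as.numeric(p_rwe),
    c = as.numeric(c),
    p_rct_censored = rep_len(as.logical(p_rct_censored), n),
    p_rwe_censored = rep_len(as.logical(p_rwe_censored), n),
    medicare = rep_len(as.logical(medicare), n),
    direction_valid = as.numeric(p_rct) < 0.5,
    stringsAsFactors = FALSE
  )
  validate_summary_pair(x)
}

validate_summary_pair <- function(x) {
  stopifnot(is.data.frame(x))
  if (any(x$p_rct <= 0 | x$p_rct > 1) || any(x$p_rwe <= 0 | x$p_rwe > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (any(x$c <= 0)) stop("variance ratio c must be positive", call. = FALSE)
  x$direction_valid <- x$p_rct < 0.5
  class(x) <- c("summary_pair", "data.frame")
  x
}

#' Reduce study pairs to margin-referenced summary statistics
#'
#' Computes, per arm, \eqn{z = (\log margin - \hat\theta) / se} and the
#' one-sided p-value \eqn{p = 1 - \Phi(z)}, plus the variance ratio
#' \eqn{c = se_{RCT}^2 / se_{RWE}^2}.
#'
#' @param pairs a \code{study_pair} data frame.
#' @return a \code{summary_pair} data frame.
#' @export
summarize_pairs <- function(pairs) {
  pairs <- validate_study_pair(pairs)
  delta <- log(pairs$margin_hr)
  z_rct <- (delta - pairs$theta_rct) / pairs$se_rct
  z_rwe <- (delta - pairs$theta_rwe) / pairs$se_rwe
  summary_pair(
    study_id = pairs$study_id,
    p_rct = p_from_z(z_rct),
    p_rwe = p_from_z(z_rwe),
    c = pairs$se_rct^2 / pairs$se_rwe^2,
    medicare = pairs$medicare
  )
}

# ---- CSV input / output ----------------------------------------------------

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x
}

.num_col <- function(x, col, path, positive = FALSE) {
  v <- suppressWarnings(as.numeric(x[[col]]))
  bad <- which(is.na(v) & !(is.na(x[[col]]) | x[[col]] == ""))
  if (length(bad) > 0) {
    stop("non-numeric value in ", path, ", column '", col, "', row ", bad[1],
         call. = FALSE)
  }
  if (positive) {
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0) {
      stop("nonpositive value in ", path, ", column '", col, "', row ", bad[1],
           call. = FALSE)
    }
  }
  v
}

#' Read study pairs from CSV
#'
#' The file must provide \code{study_id}, the RCT and RWE effects either as
#' \code{theta_*}/\code{se_*} (log-HR scale) or as \code{hr_*} with
#' \code{lo95_*}/\code{hi95_*} (HR scale), plus optional \code{margin_hr},
#' \code{design} and \code{medicare} columns.
#'
#' @param path CSV file path.
#' @return a \code{study_pair} data frame.
#' @export
read_pairs <- function(path) {
  x <- .read_csv_checked(path, "study_id")
  get_arm <- function(arm) {
    th <- paste0("theta_", arm); se <- paste0("se_", arm)
    if (all(c(th, se) %in% names(x))) {
      list(theta = .num_col(x, th, path),
           se = .num_col(x, se, path, positive = TRUE))
    } else {
      hr <- paste0("hr_", arm); lo <- paste0("lo95_", arm); hi <- paste0("hi95_", arm)
      if (!all(c(hr, lo, hi) %in% names(x))) {
        stop("missing column(s) in ", path, ": need ", th, "/", se, " or ",
             hr, "/", lo, "/", hi, call. = FALSE)
      }
      list(theta = log(.num_col(x, hr, path, positive = TRUE)),
           se = se_from_ci(.num_col(x, lo, path, positive = TRUE),
                           .num_col(x, hi, path, positive = TRUE)))
    }
  }
  rct <- get_arm("rct"); rwe <- get_arm("rwe")
  study_pair(
    study_id = x$study_id,
    theta_rct = rct$theta, se_rct = rct$se,
    theta_rwe = rwe$theta, se_rwe = rwe$se,
    margin_hr = if ("margin_hr" %in% names(x)) .num_col(x, "margin_hr", path, positive = TRUE) else 1,
    design = if ("design" %in% names(x)) x$design else "unknown",
    medicare = if ("medicare" %in% names(x)) as.logical(x$medicare) else NA
  )
}

#' Read summary pairs from CSV
#'
#' Columns: \code{study_id, p_rct, p_rwe, c, medicare}; the p-value columns
#' accept the literal censored token \code{"<0.0001"}, which is recorded via
#' the censoring flags and substituted only at computation time.
#'
#' @param path CSV file path.
#' @return a \code{summary_pair} data frame.
#' @export
read_summaries <- function(path) {
  x <- .read_csv_checked(path, c("study_id", "p_rct", "p_rwe", "c"))
  parse_p <- function(col) {
    raw <- trimws(x[[col]])
    cens <- grepl("^<", raw)
    v <- suppressWarnings(as.numeric(ifelse(cens, sub("^<\\s*", "", raw), raw)))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop("non-numeric value in ", path, ", column '", col, "', row ", bad[1],
           call. = FALSE)
    }
    list(p = v, censored = cens)
  }
  pr <- parse_p("p_rct"); pw <- parse_p("p_rwe")
  summary_pair(
    study_id = x$study_id,
    p_rct = pr$p, p_rwe = pw$p, c = .num_col(x, "c", path, positive = TRUE),
    p_rct_censored = pr$censored, p_rwe_censored = pw$censored,
    medicare = if ("medicare" %in% names(x)) as.logical(x$medicare) else NA
  )
}

#' Write summary pairs to CSV
#'
#' Censored p-values are written back as their literal token
#' \code{"<0.0001"} so that a write/read round trip is lossless.
#'
#' @param summaries a \code{summary_pair} data frame.
#' @param path output CSV path.
#' @export
write_summaries <- function(summaries, path) {
  summaries <- validate_summary_pair(summaries)
  out <- data.frame(
    study_id = summaries$study_id,
    p_rct = ifelse(summaries$p_rct_censored, "<0.0001", as.character(summaries$p_rct)),
    p_rwe = ifelse(summaries$p_rwe_censored, "<0.0001", as.character(summaries$p_rwe)),
    c = as.character(summaries$c),
    medicare = as.character(summaries$medicare),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write replication results to CSV
#'
#' @param results data frame of per-study replication results (as returned
#'   by \code{\link{assess_pairs}}); \code{NA} entries become empty cells.
#' @param path output CSV path.
#' @export
write_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, na = "")
  invisible(path)
}
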
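# Monte-Carlo harness: synthetic study pairs and empirical verification of
# Type-I error and power for the two-trials rule and the sceptical p-value.

#' Simulation configuration for synthetic study pairs
#'
#' True effects are on the log hazard-ratio scale; estimates are drawn
#' independently per arm as \eqn{\hat\theta \sim N(\theta_{true}, \sigma^2)}
#' with \eqn{\sigma_{RWE} = \sigma_{RCT} / \sqrt{c}}.  The global null sets
#' both truths to \code{log(margin_hr)}.
#'
#' @param theta_true_rct,theta_true_rwe true log hazard ratios.
#' @param sigma_rct standard error of the RCT estimate (> 0).
#' @param c variance ratio (> 0).
#' @param margin_hr margin on the HR scale, default 1.
#' @param n_pairs number of replicate pairs.
#' @param seed integer RNG seed.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(theta_true_rct = 0, theta_true_rwe = 0,
                       sigma_rct = 0.1, c = 1, margin_hr = 1,
                       n_pairs = 1000L, seed = 1L) {
  stopifnot(sigma_rct > 0, c > 0, margin_hr > 0, n_pairs >= 1)
  structure(list(
    theta_true_rct = theta_true_rct, theta_true_rwe = theta_true_rwe,
    sigma_rct = sigma_rct, sigma_rwe = sigma_rct / sqrt(c), c = c,
    margin_hr = margin_hr, n_pairs = as.integer(n_pairs),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate synthetic study pairs
#'
#' Draws \code{n_pairs} independent RCT/RWE estimate pairs under the
#' configuration's sampling model.  The draw sequence is seeded once and
#' consumed pairwise (RCT then RWE per pair), so enlarging \code{n_pairs}
#' extends the collection without reshuffling earlier pairs.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{study_pair} data frame with \code{n_pairs} rows.
#' @export
generate_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_pairs
  set.seed(config$seed)
  draws <- matrix(stats::rnorm(2 * n), nrow = 2)
  study_pair(
    study_id = sprintf("sim-%06d", seq_len(n)),
    theta_rct = config$theta_true_rct + config$sigma_rct * draws[1, ],
    se_rct = config$sigma_rct,
    theta_rwe = config$theta_true_rwe + config$sigma_rwe * draws[2, ],
    se_rwe = config$sigma_rwe,
    margin_hr = config$margin_hr,
    design = if (config$margin_hr == 1) "superiority" else "non_inferiority"
  )
}

# margin-referenced z-scores for simulated pairs, without data-frame overhead
.sim_z <- function(config) {
  n <- config$n_pairs
  set.seed(config$seed)
  draws <- matrix(stats::rnorm(2 * n), nrow = 2)
  delta <- log(config$margin_hr)
  list(
    z_rct = (delta - config$theta_true_rct) / config$sigma_rct - draws[1, ],
    z_rwe = (delta - config$theta_true_rwe) / config$sigma_rwe - draws[2, ]
  )
}

#' Empirical overall Type-I error (or success rate) of a replication metric
#'
#' Simulates pairs under \code{config} (for a Type-I error estimate the
#' truths should sit at the margin) and returns the empirical probability of
#' replication success at level \code{alpha} with a binomial standard error.
#' Methods: \code{"ttr"} (both p-values at or below \code{alpha}),
#' \code{"sceptical_controlled"} (controlled sceptical p at or below
#' \code{alpha}, decided through the equivalent nominal threshold
#' \code{\link{calibrated_nominal_level}}), \code{"sceptical_nominal"}
#' (nominal sceptical p at or below \code{alpha}).
#'
#' @param config a \code{\link{sim_config}}.
#' @param alpha one-sided level.
#' @param method one of \code{"ttr"}, \code{"sceptical_controlled"},
#'   \code{"sceptical_nominal"}.
#' @return list with \code{estimate}, \code{se}, \code{n}, \code{method},
#'   \code{alpha}.
#' @export
estimate_t1e <- function(config, alpha = 0.025,
                         method = c("ttr", "sceptical_controlled", "sceptical_nominal")) {
  stopifnot(inherits(config, "sim_config"))
  method <- match.arg(method)
  .check_power_args(config$c, alpha)
  z <- .sim_z(config)
  hit <- .success_from_z(z$z_rct, z$z_rwe, config$c, alpha, method)
  p <- mean(hit)
  list(estimate = p, se = sqrt(p * (1 - p) / config$n_pairs),
       n = config$n_pairs, method = method, alpha = alpha)
}

.success_from_z <- function(z_rct, z_rwe, c, alpha, method) {
  if (method == "ttr") {
    za <- stats::qnorm(1 - alpha)
    return(z_rct >= za & z_rwe >= za)
  }
  level <- if (method == "sceptical_controlled") {
    # controlled p <= alpha  <=>  nominal p <= calibrated level (T1E monotone)
    calibrated_nominal_level(alpha, c)
  } else {
    alpha
  }
  zl <- stats::qnorm(1 - level)
  ok <- z_rct > 0
  zs <- rep(-Inf, length(z_rct))
  zs[ok] <- sceptical_z(z_rct[ok], z_rwe[ok], c)
  zs >= zl
}

#' Empirical replication power of a metric
#'
#' Takes \code{config$theta_true_rct} as the observed original estimate (with
#' standard error \code{sigma_rct}) and simulates the replication arm:
#' conditional power fixes the original estimate as the truth for the
#' replication (replication z \eqn{\sim N(\sqrt{c} z_{RCT}, 1)}); predictive
#' power first resamples the original estimate from its sampling
#' distribution (marginal replication z \eqn{\sim N(\sqrt{c} z_{RCT},
#' 1 + c)}).  Success is decided with the original fixed at its observed
#' value.
#'
#' @param config a \code{\link{sim_config}}; \code{theta_true_rct} plays the
#'   role of the observed original estimate.
#' @param alpha one-sided level.
#' @param method \code{"ttr"} or \code{"sceptical"} (controlled).
#' @param flavor \code{"conditional"} or \code{"predictive"}.
#' @return list with \code{estimate}, \code{se}, \code{n}, \code{analytic}
#'   (the closed-form power at the same point).
#' @export
estimate_power <- function(config, alpha = 0.025,
                           method = c("ttr", "sceptical"),
                           flavor = c("conditional", "predictive")) {
  stopifnot(inherits(config, "sim_config"))
  method <- match.arg(method)
  flavor <- match.arg(flavor)
  .check_power_args(config$c, alpha)
  delta <- log(config$margin_hr)
  z_rct <- (delta - config$theta_true_rct) / config$sigma_rct
  set.seed(config$seed)
  sd_r <- if (flavor == "conditional") 1 else sqrt(1 + config$c)
  z_rwe <- stats::rnorm(config$n_pairs, mean = sqrt(config$c) * z_rct, sd = sd_r)
  hit <- .success_from_z(rep(z_rct, config$n_pairs), z_rwe, config$c, alpha,
                         if (method == "ttr") "ttr" else "sceptical_controlled")
  # the TTR additionally requires a significant original
  if (method == "ttr" && p_from_z(z_rct) > alpha) hit <- rep(FALSE, length(hit))
  p <- mean(hit)
  analytic <- switch(paste(method, flavor, sep = "."),
                     ttr.conditional = power_ttr_conditional(z_rct, config$c, alpha),
                     ttr.predictive = power_ttr_predictive(z_rct, config$c, alpha),
                     sceptical.conditional = power_sceptical_conditional(z_rct, config$c, alpha),
                     sceptical.predictive = power_sceptical_predictive(z_rct, config$c, alpha))
  list(estimate = p, se = sqrt(p * (1 - p) / config$n_pairs),
       n = config$n_pairs, method = method, flavor = flavor,
       analytic = analytic)
}
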
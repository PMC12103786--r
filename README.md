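# scepticalRWE

Statistical assessment of replication success when a randomized controlled
trial (RCT) is emulated with real-world evidence (RWE), on the log
hazard-ratio scale and with support for non-inferiority margins.

The regulatory default for "did the emulation replicate the trial?" is the
two-trials rule, p_TTR = max{p_RCT, p_RWE}: both studies significant in the
same direction.  It ignores effect sizes and the relative precision of the
two studies.  This package implements the reverse-Bayes *sceptical p-value*
as an alternative: the original finding is challenged by a sceptical prior
centred at the margin with variance τ² = σ²_RCT / (z²_RCT/z²_α − 1), and
replication success is significant prior-data conflict with the RWE
estimate, assessed through the prior-predictive tail probability
Φ{(θ̂_RWE − δ) / √(τ² + σ²_RWE)} with δ the log margin.  The resulting
p-value p_S depends on p_RCT, p_RWE and the variance ratio
c = σ²_RCT/σ²_RWE, so original and replication are no longer
interchangeable.  The package provides:

* the nominal sceptical p-value and its exactly calibrated ("controlled")
  version, whose threshold at one-sided α has overall Type-I error exactly
  α² for every c — the operating characteristic of the two-trials rule —
  computed via the global-null integral T(ℓ, c) by adaptive quadrature;
* one-sided confidence limits for the combined effect by test inversion
  (`sceptical_upper_limit()`), and a fixed-effect meta-analytic comparator;
* conditional and predictive replication power for both rules, with the
  calibrated success threshold and the 2α bound on the conditional Type-I
  error;
* the 29 RCT DUPLICATE study pairs as an embedded fixture and a pipeline
  reproducing the published replication-success counts;
* a Monte-Carlo harness (`sim_config()`, `estimate_t1e()`,
  `estimate_power()`) verifying the operating characteristics, and a small
  command line (`inst/scripts/scepticalrwe.R`) over the same functions.

## Worked example

Replication assessment for two published pairs from their summary
statistics (one-sided, margin-referenced p-values and variance ratio):

```r
library(scepticalRWE)

s <- summary_pair(
  study_id = c("TRANSCEND", "PARADIGM-HF"),
  p_rct = c(0.10, 1e-6), p_rwe = c(0.002, 0.63), c = c(2.3, 0.6)
)
assess_summaries(s, alpha = 0.025)[, c("study_id", "p_ttr", "p_s_controlled",
                                       "success_ttr", "success_sceptical")]
#>      study_id p_ttr p_s_controlled success_ttr success_sceptical
#> 1   TRANSCEND  0.10     0.06267617       FALSE             FALSE
#> 2 PARADIGM-HF  0.63     0.63953916       FALSE             FALSE
```

TRANSCEND's original was not significant (p_RCT = 0.10), so the two-trials
rule is stuck at 0.10; the controlled sceptical p-value (0.063) credits the
strong emulation but still falls short of α = 0.025.  PARADIGM-HF's
emulation pointed the wrong way, and the discordant branch pushes the
sceptical p-value above 0.5.  The full published analysis:

```r
duplicate_report(alpha = 0.025, censored_sub = 1e-6)
#> RCT DUPLICATE replication-success report (one-sided alpha = 0.025 )
#>   successes, controlled sceptical p: 20 / 29
#>   successes, two-trials rule:        20 / 29
#>   Medicare-inclusive subgroup:       16 / 19
#>   non-Medicare subgroup:             4 / 10
#>   originals significant at alpha:    26
```

Replication power for a TRITON-TIMI-like original (θ̂ = −0.21, 95% CI
[−0.31, −0.11], so z = 4.116) at c = 1:

```r
power_ttr_conditional(4.116, c = 1, alpha = 0.025)        # 0.9844596
power_ttr_predictive(4.116, c = 1, alpha = 0.025)         # 0.936314
power_sceptical_conditional(4.116, c = 1, alpha = 0.025)  # 0.9936263
```

Averaging over the original estimate's uncertainty (predictive power)
pulls the conditional 98.4% down to 93.6%.

See `vignette("sceptical-rwe-methods")` for the model, the calibration, the
numerical choices and the known limitations.

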
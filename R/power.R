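# Statistical power for two-sample MR with a binary outcome, in the
# style of the mRnd calculator: asymptotic normal approximation for the
# Wald test of the log odds ratio.

#' Power of a binary-outcome MR study
#'
#' Under the asymptotic normal approximation, the non-centrality of the
#' log-OR test is z = ln(OR) * sqrt(n * r2 * K * (1 - K)) with K the
#' case fraction of the outcome GWAS and r2 the variance in the exposure
#' explained by the instruments; power is
#' `pnorm(-z_crit + z) + pnorm(-z_crit - z)` with
#' `z_crit = qnorm(1 - alpha/2)`. At OR = 1 this returns exactly alpha.
#'
#' @param n Outcome GWAS sample size.
#' @param case_fraction Proportion of cases in (0, 1).
#' @param r2 Variance explained by the instruments, in (0, 1).
#' @param or_alt Odds ratio under the alternative (> 0).
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @return Power in (0, 1).
#' @export
#' @examples
#' mr_power_binary(79429, 7495 / 79429, 0.0259, or_alt = 1.212)
mr_power_binary <- function(n, case_fraction, r2, or_alt, alpha = 0.05) {
  if (n <= 0) stop("n must be positive")
  if (case_fraction <= 0 || case_fraction >= 1) stop("case_fraction must lie in (0, 1)")
  if (r2 <= 0 || r2 >= 1) stop("r2 must lie in (0, 1)")
  if (or_alt <= 0) stop("or_alt must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  b <- log(or_alt)
  z_eff <- b * sqrt(n * r2 * case_fraction * (1 - case_fraction))
  z_crit <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-z_crit + z_eff) + stats::pnorm(-z_crit - z_eff)
}

#' Minimum detectable odds ratio at a target power
#'
#' Bisects on the log odds ratio in each direction until the power
#' matches `power_target` to within 1e-6, returning the harmful
#' (OR > 1) and protective (OR < 1) bounds. Under the symmetric normal
#' approximation the two bounds are reciprocal.
#'
#' @inheritParams mr_power_binary
#' @param power_target Target power in (alpha, 1).
#' @return List with `or_upper` (> 1) and `or_lower` (< 1).
#' @export
detectable_or <- function(n, case_fraction, r2, alpha = 0.05,
                          power_target = 0.8) {
  if (power_target <= alpha || power_target >= 1) {
    stop("power_target must lie in (alpha, 1)")
  }
  solve_dir <- function(sign) {
    lo <- 0
    hi <- 0.1
    while (mr_power_binary(n, case_fraction, r2, exp(sign * hi), alpha) <
             power_target) {
      hi <- hi * 2
      if (hi > 100) stop("detectable OR search failed to bracket the target")
    }
    for (iter in seq_len(200)) {
      mid <- (lo + hi) / 2
      p <- mr_power_binary(n, case_fraction, r2, exp(sign * mid), alpha)
      if (abs(p - power_target) < 1e-6) return(exp(sign * mid))
      if (p < power_target) lo <- mid else hi <- mid
    }
    stop("detectable OR bisection did not converge in 200 iterations")
  }
  list(or_upper = solve_dir(1), or_lower = solve_dir(-1))
}
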
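# Causal estimators on a harmonized instrument set.
#
# Each estimator combines per-variant Wald ratios by/bx (outcome effect
# over exposure effect, on the log-odds scale for binary outcomes) into a
# single causal estimate. Confidence intervals use the normal multiplier
# 1.959964 except for MR-Egger, which uses the t quantile with k - 2
# degrees of freedom.

.Z95 <- 1.959964

#' Construct an MR estimate
#'
#' @param method Method label.
#' @param n_snp Number of instruments used.
#' @param beta,se Estimate and standard error on the log-OR scale.
#' @param pvalue Two-sided p-value.
#' @param ci_mult Half-width multiplier for the 95% CI (normal 1.959964,
#'   or a t quantile).
#' @return Object of class `mr_estimate` with log-scale fields `beta`,
#'   `se`, `ci_low`, `ci_high`, `pvalue` and OR-scale fields `or`,
#'   `or_ci_low`, `or_ci_high`.
#' @export
mr_estimate <- function(method, n_snp, beta, se, pvalue, ci_mult = .Z95) {
  stopifnot(se > 0)
  ci_low <- beta - ci_mult * se
  ci_high <- beta + ci_mult * se
  structure(
    list(method = method, n_snp = as.integer(n_snp), beta = beta, se = se,
         ci_low = ci_low, ci_high = ci_high,
         pvalue = min(max(pvalue, .Machine$double.xmin), 1),
         or = exp(beta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high)),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s (%d SNPs): beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
    x$method, x$n_snp, x$beta, x$se, x$or, x$or_ci_low, x$or_ci_high, x$pvalue
  ))
  invisible(x)
}

#' Wald ratio estimate from a single instrument
#'
#' The single-variant causal estimate by/bx with first-order delta-method
#' standard error se_y/|bx| (uncertainty in the exposure effect is
#' neglected, the standard convention for strong instruments).
#'
#' @param inst One-row data frame or list with `bx`, `by`, `se_y` (and
#'   optionally `rsid`).
#' @return An [mr_estimate()].
#' @export
mr_wald_ratio <- function(inst) {
  if (inst$bx == 0) stop("undefined Wald ratio: exposure effect is zero")
  beta <- inst$by / inst$bx
  se <- inst$se_y / abs(inst$bx)
  mr_estimate("wald_ratio", 1L, beta, se, 2 * stats::pnorm(-abs(beta / se)))
}

#' Inverse-variance weighted estimate
#'
#' Combines Wald ratios with weights equal to the inverse outcome
#' variance (1/se_y^2), equivalent to weighted least-squares regression
#' of the outcome effects on the exposure effects through the origin.
#' The fixed-effect model takes the analytic SE; the multiplicative
#' random-effects model inflates it by sqrt(Q/(k-1)) when Cochran's Q
#' exceeds its degrees of freedom (never deflates).
#'
#' @param set A [harmonized_set()].
#' @param model `"fixed"` or `"random"`.
#' @return An [mr_estimate()] with method `"ivw_fe"` or `"ivw_re"`.
#' @export
mr_ivw <- function(set, model = c("fixed", "random")) {
  model <- match.arg(model)
  ins <- set$instruments
  k <- nrow(ins)
  if (k == 0L) stop("empty instrument set")
  if (k == 1L) {
    warning("single instrument: IVW degrades to the Wald ratio")
    est <- mr_wald_ratio(ins[1, ])
    return(mr_estimate(paste0("ivw_", substr(model, 1, 1), "e"), 1L,
                       est$beta, est$se, est$pvalue))
  }
  w <- 1 / ins$se_y^2
  beta <- sum(ins$bx * ins$by * w) / sum(ins$bx^2 * w)
  se <- 1 / sqrt(sum(ins$bx^2 * w))
  if (model == "random") {
    q <- sum(((ins$by - beta * ins$bx) / ins$se_y)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  mr_estimate(if (model == "fixed") "ivw_fe" else "ivw_re", k, beta, se,
              2 * stats::pnorm(-abs(beta / se)))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure
#' effects with a free intercept, weights 1/se_y^2, after orienting every
#' instrument so its exposure effect is non-negative. The slope is the
#' causal estimate; a non-zero intercept indicates directional horizontal
#' pleiotropy. Standard errors use a multiplicative random-effects model
#' with the residual variance floored at 1, and p-values are two-sided t
#' with k - 2 degrees of freedom.
#'
#' @param set A [harmonized_set()] with at least 3 instruments.
#' @return A list of class `mr_egger_result` with elements `slope` (an
#'   [mr_estimate()]), `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(set) {
  ins <- set$instruments
  k <- nrow(ins)
  if (k < 3L) stop("MR-Egger needs at least 3 instruments (got ", k, ")")
  flip <- sign(ins$bx)
  flip[flip == 0] <- 1
  bx <- ins$bx * flip
  by <- ins$by * flip
  w <- 1 / ins$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  # summary.lm scales coefficient SEs by the residual sd; refloor at 1 so
  # an under-dispersed fit does not shrink them below the fixed-effect SE.
  sigma <- summary(fit)$sigma
  infl <- max(1, sigma) / sigma
  slope <- cf["bx", "Estimate"]
  slope_se <- cf["bx", "Std. Error"] * infl
  int <- cf["(Intercept)", "Estimate"]
  int_se <- cf["(Intercept)", "Std. Error"] * infl
  df <- k - 2L
  slope_p <- 2 * stats::pt(-abs(slope / slope_se), df)
  int_p <- 2 * stats::pt(-abs(int / int_se), df)
  structure(
    list(
      slope = mr_estimate("egger", k, slope, slope_se, slope_p,
                          ci_mult = stats::qt(0.975, df)),
      intercept = int, intercept_se = int_se, intercept_p = int_p
    ),
    class = "mr_egger_result"
  )
}

#' @export
print.mr_egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

# Weighted median of ratio estimates r with normalized weights w:
# sort by r, interpolate r linearly in the cumulative weight midpoints
# S_j = sum_{i<=j} w_i - w_j/2 at S = 0.5.
.weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(s)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE: resample bx* ~ N(bx, se_x^2), by* ~ N(by, se_y^2)
# and recompute `estimator(bx*, by*)` n_boot times.
.bootstrap_se <- function(ins, estimator, n_boot, seed) {
  set.seed(seed)
  k <- nrow(ins)
  est <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, ins$bx, ins$se_x)
    by <- stats::rnorm(k, ins$by, ins$se_y)
    estimator(bx, by)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted median estimate
#'
#' The weighted 50th percentile of the ordered per-variant Wald ratios,
#' with weights proportional to bx^2/se_y^2 (the inverse variance of each
#' ratio under the delta method). Consistent when instruments carrying at
#' least half of the weight are valid. The standard error comes from a
#' seeded parametric bootstrap that resamples both exposure and outcome
#' effects from their sampling distributions.
#'
#' @param set A [harmonized_set()] with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An [mr_estimate()].
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = 1) {
  ins <- set$instruments
  k <- nrow(ins)
  if (k < 3L) stop("weighted median needs at least 3 instruments (got ", k, ")")
  if (n_boot < 100) stop("n_boot must be at least 100")
  wm <- function(bx, by) .weighted_median(by / bx, bx^2 / ins$se_y^2)
  beta <- wm(ins$bx, ins$by)
  se <- .bootstrap_se(ins, wm, n_boot, seed)
  mr_estimate("weighted_median", k, beta, se, 2 * stats::pnorm(-abs(beta / se)))
}

# Mode of the weighted normal-kernel density of the ratios, evaluated on
# a 512-point grid. Bandwidth: modified Silverman rule scaled by phi.
.mode_of_ratios <- function(r, w, phi) {
  if (length(unique(r)) == 1L) return(r[1])
  s <- min(stats::sd(r), stats::mad(r))
  h <- phi * 0.9 * s * length(r)^(-1 / 5)
  if (h <= 0) return(.weighted_median(r, w))
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- as.vector(w %*% stats::dnorm(outer(r, grid, "-") / h)) / h
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The mode of the kernel-smoothed distribution of per-variant Wald
#' ratios: the causal effect of the largest homogeneous cluster of
#' instruments. The simple mode weights every instrument equally; the
#' weighted mode uses inverse-variance weights bx^2/se_y^2. The kernel is
#' normal with bandwidth phi * 0.9 * min(sd, 1.4826 * MAD) * k^(-1/5)
#' evaluated on a 512-point grid; standard errors come from the same
#' parametric bootstrap as the weighted median.
#'
#' @param set A [harmonized_set()] with at least 3 instruments.
#' @param weighted Use inverse-variance weights?
#' @param phi Bandwidth scale factor (default 1).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @return An [mr_estimate()] with method `"simple_mode"` or
#'   `"weighted_mode"`.
#' @export
mr_mode <- function(set, weighted = FALSE, phi = 1, n_boot = 1000, seed = 1) {
  ins <- set$instruments
  k <- nrow(ins)
  if (k < 3L) stop("mode estimator needs at least 3 instruments (got ", k, ")")
  stopifnot(phi > 0)
  weights_of <- function(bx) {
    if (weighted) bx^2 / ins$se_y^2 else rep(1, k)
  }
  mode_fn <- function(bx, by) {
    w <- weights_of(bx)
    .mode_of_ratios(by / bx, w / sum(w), phi)
  }
  beta <- mode_fn(ins$bx, ins$by)
  se <- .bootstrap_se(ins, mode_fn, n_boot, seed)
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode", k, beta, se,
              2 * stats::pnorm(-abs(beta / se)))
}

#' Run the five standard estimators on one harmonized set
#'
#' Convenience wrapper returning the inverse-variance weighted,
#' MR-Egger, weighted median, simple mode and weighted mode estimates.
#' Sets with fewer than 3 instruments yield a partial result (IVW only,
#' or the Wald ratio for a single instrument) with a warning.
#'
#' @param set A [harmonized_set()].
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed RNG seed.
#' @param ivw_model IVW variant, `"fixed"` (default) or `"random"`.
#' @return Named list of [mr_estimate()] objects (the Egger entry is the
#'   slope; the full regression is attached as attribute `egger`).
#' @export
mr_all_methods <- function(set, n_boot = 1000, seed = 1,
                           ivw_model = "fixed") {
  k <- n_instruments(set)
  if (k < 3L) {
    warning("only ", k, " instrument(s): reporting IVW/Wald only")
    return(list(ivw = mr_ivw(set, ivw_model)))
  }
  eg <- mr_egger(set)
  out <- list(
    ivw = mr_ivw(set, ivw_model),
    egger = eg$slope,
    weighted_median = mr_weighted_median(set, n_boot, seed),
    simple_mode = mr_mode(set, weighted = FALSE, n_boot = n_boot, seed = seed),
    weighted_mode = mr_mode(set, weighted = TRUE, n_boot = n_boot, seed = seed)
  )
  attr(out, "egger") <- eg
  out
}
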
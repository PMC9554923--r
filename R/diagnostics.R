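# Heterogeneity, pleiotropy, sensitivity and instrument-strength
# diagnostics for a harmonized instrument set.

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum(((by - beta_hat * bx) / se_y)^2) over instruments, chi-square
#' with k - 1 degrees of freedom under homogeneity of the per-variant
#' causal estimates. The reference estimate defaults to the fixed-effect
#' inverse-variance weighted estimate on the same set.
#'
#' @param set A [harmonized_set()] with at least 2 instruments.
#' @param beta_hat Reference causal estimate; default fixed-effect IVW.
#' @return List of class `heterogeneity_result` with `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(set, beta_hat = NULL) {
  ins <- set$instruments
  k <- nrow(ins)
  if (k < 2L) stop("Cochran's Q needs at least 2 instruments")
  if (is.null(beta_hat)) beta_hat <- mr_ivw(set, "fixed")$beta
  q <- sum(((ins$by - beta_hat * ins$bx) / ins$se_y)^2)
  df <- k - 1L
  structure(
    list(Q = q, df = df, pvalue = stats::pchisq(q, df, lower.tail = FALSE)),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("<heterogeneity> Q = %.3f on %d df, p = %.3g\n",
              x$Q, x$df, x$pvalue))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the fixed-effect IVW estimate k times, omitting one
#' instrument each time, to expose estimates driven by a single variant.
#'
#' @param set A [harmonized_set()] with at least 3 instruments.
#' @return Data frame with one row per omitted rsid: `omitted`, `n_snp`,
#'   `beta`, `se`, `or`, `pvalue`, ordered as the input instruments.
#' @export
leave_one_out <- function(set) {
  ins <- set$instruments
  k <- nrow(ins)
  if (k < 3L) stop("leave-one-out needs at least 3 instruments")
  rows <- lapply(seq_len(k), function(i) {
    sub <- set
    sub$instruments <- ins[-i, , drop = FALSE]
    est <- mr_ivw(sub, "fixed")
    data.frame(omitted = ins$rsid[i], n_snp = k - 1L, beta = est$beta,
               se = est$se, or = est$or, pvalue = est$pvalue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' A non-zero Egger intercept indicates that the instruments' average
#' pleiotropic effect is directional, violating the exclusion
#' restriction. P-value is two-sided t with k - 2 degrees of freedom.
#'
#' @param set A [harmonized_set()] with at least 3 instruments.
#' @return List with `intercept`, `se`, `pvalue`.
#' @export
egger_intercept_test <- function(set) {
  eg <- mr_egger(set)
  list(intercept = eg$intercept, se = eg$intercept_se,
       pvalue = eg$intercept_p)
}

#' Variance in the exposure explained by the instruments
#'
#' Summary-data approximation: each variant contributes
#' r2_j = t_j^2 / (t_j^2 + n - 2) with t_j = beta_j / se_j, and the
#' contributions are summed. This is the only estimate computable when
#' allele frequencies are not available; it assumes approximately
#' independent instruments.
#'
#' @param records Data frame of exposure records with `beta` and `se`.
#' @param n Exposure GWAS sample size (> 2).
#' @return Total r-squared (numeric scalar).
#' @export
instrument_r2 <- function(records, n) {
  if (n <= 2) stop("n must exceed 2")
  stopifnot(all(records$se > 0))
  t2 <- (records$beta / records$se)^2
  sum(t2 / (t2 + n - 2))
}

#' Instrument-strength F-statistic
#'
#' F = r2 * (n - k - 1) / (k * (1 - r2)), where r2 is the variance in
#' the exposure explained by the k instruments and n the exposure GWAS
#' sample size. F below 10 conventionally flags weak instruments.
#'
#' @param r2 Explained variance in [0, 1).
#' @param n Exposure GWAS sample size (> k + 1).
#' @param k Number of instruments.
#' @return List of class `instrument_strength` with `r2`, `n`, `k`, `F`
#'   and logical `weak`.
#' @export
f_statistic <- function(r2, n, k) {
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1)")
  if (k < 1) stop("k must be at least 1")
  if (n <= k + 1) stop("n must exceed k + 1")
  f <- r2 * (n - k - 1) / (k * (1 - r2))
  structure(
    list(r2 = r2, n = as.integer(n), k = as.integer(k), F = f,
         weak = f < 10),
    class = "instrument_strength"
  )
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("<instrument_strength> F = %.3f (r2 = %.4g, n = %d, k = %d)%s\n",
              x$F, x$r2, x$n, x$k,
              if (x$weak) " [WEAK: F < 10]" else ""))
  invisible(x)
}
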
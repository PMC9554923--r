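# Generator of paired exposure/outcome GWAS summary statistics with
# known ground truth, for parameter-recovery and operating-characteristic
# studies. Summary statistics are drawn directly from their asymptotic
# sampling distributions: observed bx_j ~ N(gamma_j, se_x^2) and
# by_j ~ N(beta_causal * gamma_j + alpha_j, se_y^2), where gamma_j is the
# true per-variant exposure effect and alpha_j a direct (pleiotropic)
# outcome effect. This matches exactly the model the estimators assume;
# it deliberately omits LD between instruments and winner's curse.

#' Simulation configuration for synthetic summary statistics
#'
#' Default effect scales emulate a homocysteine-sized quantitative-trait
#' GWAS paired with a large case-control outcome GWAS: true exposure
#' effects around 0.07 SD per allele with spread 0.03, exposure SEs of
#' 0.008 and outcome (log-odds) SEs of 0.03, sample sizes 44,147 and
#' 79,429.
#'
#' @param k Number of instruments (>= 3).
#' @param beta_causal True causal effect (log-OR per exposure unit).
#' @param gamma_mean,gamma_sd Mean (> 0) and SD of true exposure effects;
#'   draws are truncated away from zero at |gamma| >= gamma_sd / 10 to
#'   keep Wald ratios stable.
#' @param pleiotropy `"none"`, `"balanced"` (direct effects centred on
#'   zero) or `"directional"` (centred on `alpha_mean`).
#' @param alpha_mean Mean direct effect (directional pleiotropy only).
#' @param alpha_sd SD of direct effects.
#' @param se_x,se_y Sampling standard errors of the exposure and outcome
#'   effect estimates.
#' @param n_exp,n_out Nominal GWAS sample sizes carried into the datasets.
#' @param seed RNG seed; the same seed yields bit-identical datasets.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(k = 50, beta_causal = 0, gamma_mean = 0.07,
                       gamma_sd = 0.03,
                       pleiotropy = c("none", "balanced", "directional"),
                       alpha_mean = 0, alpha_sd = 0,
                       se_x = 0.008, se_y = 0.03,
                       n_exp = 44147, n_out = 79429, seed = 1) {
  pleiotropy <- match.arg(pleiotropy)
  if (k < 3) stop("k must be at least 3")
  if (gamma_mean <= 0) stop("gamma_mean must be positive")
  if (se_x <= 0 || se_y <= 0) stop("se_x and se_y must be positive")
  if (alpha_sd < 0) stop("alpha_sd must be non-negative")
  if (pleiotropy != "none" && alpha_sd == 0 && alpha_mean == 0) {
    stop("pleiotropy regime '", pleiotropy,
         "' needs a non-zero alpha_sd or alpha_mean")
  }
  structure(
    list(k = as.integer(k), beta_causal = beta_causal,
         gamma_mean = gamma_mean, gamma_sd = gamma_sd,
         pleiotropy = pleiotropy, alpha_mean = alpha_mean,
         alpha_sd = alpha_sd, se_x = se_x, se_y = se_y,
         n_exp = as.integer(n_exp), n_out = as.integer(n_out),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a simulation configuration from a key = value text file
#'
#' Lines of the form `key = value` (or `key: value`); keys are the
#' arguments of [sim_config()]; `#` starts a comment.
#'
#' @param path File path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "pleiotropy") vals[i] else as.numeric(vals[i])
  })
  names(args) <- keys
  unknown <- setdiff(keys, names(formals(sim_config)))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, args)
}

#' Simulate one pair of exposure/outcome summary datasets
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` ([summary_dataset()]s, one
#'   record per instrument with consistent arbitrary alleles) and
#'   `truth` (data frame of the true `gamma`, `alpha` per variant, plus
#'   attribute `beta_causal`).
#' @export
simulate_summary_stats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$k
  gamma <- stats::rnorm(k, config$gamma_mean, config$gamma_sd)
  floor_g <- config$gamma_sd / 10
  for (iter in seq_len(100)) {
    tiny <- abs(gamma) < floor_g
    if (!any(tiny)) break
    gamma[tiny] <- stats::rnorm(sum(tiny), config$gamma_mean, config$gamma_sd)
  }
  alpha <- switch(config$pleiotropy,
    none = rep(0, k),
    balanced = stats::rnorm(k, 0, config$alpha_sd),
    directional = stats::rnorm(k, config$alpha_mean, config$alpha_sd)
  )
  bx <- stats::rnorm(k, gamma, config$se_x)
  by <- stats::rnorm(k, config$beta_causal * gamma + alpha, config$se_y)
  rsid <- sprintf("rs%06d", seq_len(k))
  mk <- function(beta, se, n, trait, type, cases = NULL) {
    summary_dataset(
      trait = trait, trait_type = type, n_total = n, n_cases = cases,
      records = data.frame(
        rsid = rsid, effect_allele = "A", other_allele = "G",
        beta = beta, se = se, pval = 2 * stats::pnorm(-abs(beta / se)),
        n = n, stringsAsFactors = FALSE
      )
    )
  }
  truth <- data.frame(rsid = rsid, gamma = gamma, alpha = alpha,
                      stringsAsFactors = FALSE)
  attr(truth, "beta_causal") <- config$beta_causal
  list(
    exposure = mk(bx, rep(config$se_x, k), config$n_exp,
                  "simulated exposure", "quantitative"),
    outcome = mk(by, rep(config$se_y, k), config$n_out,
                 "simulated outcome", "binary"),
    truth = truth
  )
}

.SIM_METHODS <- c("ivw", "egger", "weighted_median", "simple_mode",
                  "weighted_mode", "egger_intercept")

#' Monte-Carlo operating characteristics of the estimators
#'
#' Repeats [simulate_summary_stats()] `n_reps` times (per-replicate seeds
#' derived deterministically from the config seed) and summarises each
#' requested method: mean estimate, empirical SE, bias against the true
#' causal effect, 95%-CI coverage of the truth, and rejection rate at
#' the two-sided 5% level. The pseudo-method `"egger_intercept"`
#' summarises the Egger intercept against the mean pleiotropic effect
#' instead of the causal effect.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates (>= 100).
#' @param methods Subset of `r paste0('"', .SIM_METHODS, '"', collapse = ", ")`.
#' @param n_boot Bootstrap replicates for median/mode SEs (kept small by
#'   default; only their SEs, never their point estimates, depend on it).
#' @return Data frame with one row per method and columns `method`,
#'   `truth`, `mean_estimate`, `empirical_se`, `bias`, `coverage`,
#'   `rejection_rate`.
#' @export
run_simulation_study <- function(config, n_reps = 500,
                                 methods = c("ivw", "egger"),
                                 n_boot = 200) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 100) stop("n_reps must be at least 100")
  unknown <- setdiff(methods, .SIM_METHODS)
  if (length(unknown)) {
    stop("unknown method label(s): ", paste(unknown, collapse = ", "),
         "; valid: ", paste(.SIM_METHODS, collapse = ", "))
  }
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  alpha_true <- switch(config$pleiotropy, directional = config$alpha_mean, 0)

  one_rep <- function(s) {
    cfg <- config
    cfg$seed <- s
    sim <- simulate_summary_stats(cfg)
    hset <- build_harmonized_set(sim$exposure, sim$outcome)
    res <- list()
    need_eg <- any(c("egger", "egger_intercept") %in% methods)
    eg <- if (need_eg) mr_egger(hset) else NULL
    for (m in methods) {
      est <- switch(m,
        ivw = mr_ivw(hset, "fixed"),
        egger = eg$slope,
        weighted_median = mr_weighted_median(hset, n_boot = n_boot, seed = s),
        simple_mode = mr_mode(hset, weighted = FALSE, n_boot = n_boot, seed = s),
        weighted_mode = mr_mode(hset, weighted = TRUE, n_boot = n_boot, seed = s),
        egger_intercept = NULL
      )
      res[[m]] <- if (m == "egger_intercept") {
        ci <- stats::qt(0.975, n_instruments(hset) - 2L) * eg$intercept_se
        c(beta = eg$intercept, lo = eg$intercept - ci, hi = eg$intercept + ci,
          p = eg$intercept_p)
      } else {
        c(beta = est$beta, lo = est$ci_low, hi = est$ci_high, p = est$pvalue)
      }
    }
    res
  }
  reps <- lapply(rep_seeds, one_rep)

  rows <- lapply(methods, function(m) {
    mat <- do.call(rbind, lapply(reps, `[[`, m))
    truth <- if (m == "egger_intercept") alpha_true else config$beta_causal
    data.frame(
      method = m, truth = truth,
      mean_estimate = mean(mat[, "beta"]),
      empirical_se = stats::sd(mat[, "beta"]),
      bias = mean(mat[, "beta"]) - truth,
      coverage = mean(mat[, "lo"] <= truth & truth <= mat[, "hi"]),
      rejection_rate = mean(mat[, "p"] < 0.05),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
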
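# Study orchestration: instrument selection, optional clumping,
# harmonization, all five estimators, diagnostics and power for one or
# more outcome datasets, collected in a serializable study report.

#' Run a full two-sample MR study
#'
#' For each outcome dataset: select exposure instruments below the
#' p-value threshold, optionally clump them against a user-supplied LD
#' matrix and position table, harmonize against the outcome, run the
#' five estimators, and compute heterogeneity, Egger-intercept,
#' leave-one-out, instrument-strength and power diagnostics on the same
#' harmonized set. Outcomes with fewer than three surviving instruments
#' yield a partial block (IVW/Wald only) with a warning.
#'
#' @param exposure A [summary_dataset()] for the exposure.
#' @param outcomes Named list of [summary_dataset()]s, one per outcome;
#'   block order follows this list.
#' @param p_threshold Instrument-selection p-value threshold.
#' @param positions,ld Optional clumping inputs (see [clump()]); when
#'   `NULL` the instruments are assumed already independent.
#' @param clump_kb,clump_r2 Clumping parameters.
#' @param drop_palindromic Drop palindromic variants at harmonization.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed RNG seed; the report is deterministic given the seed.
#' @param alpha,power_target Significance level and target power for the
#'   minimum-detectable-OR section (binary outcomes with case counts).
#' @return Object of class `study_report`.
#' @export
run_study <- function(exposure, outcomes, p_threshold = 5e-8,
                      positions = NULL, ld = NULL,
                      clump_kb = 10000, clump_r2 = 0.001,
                      drop_palindromic = TRUE, n_boot = 1000, seed = 1,
                      alpha = 0.05, power_target = 0.8) {
  stopifnot(inherits(exposure, "summary_dataset"), is.list(outcomes))
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes)))) {
    stop("outcomes must be a named list")
  }
  selected <- select_instruments(exposure, p_threshold)
  if (!is.null(positions) && !is.null(ld)) {
    selected <- clump(selected, positions, ld, clump_kb, clump_r2)
  }
  blocks <- lapply(names(outcomes), function(label) {
    hset <- build_harmonized_set(selected, outcomes[[label]],
                                 drop_palindromic)
    k <- n_instruments(hset)
    estimates <- mr_all_methods(hset, n_boot = n_boot, seed = seed)
    used <- selected$records[selected$records$rsid %in% hset$instruments$rsid, ]
    r2 <- instrument_r2(used, exposure$n_total)
    strength <- f_statistic(r2, exposure$n_total, k)
    power <- NULL
    if (!is.null(hset$outcome_cases)) {
      kf <- hset$outcome_cases / hset$outcome_n
      dor <- detectable_or(hset$outcome_n, kf, r2, alpha, power_target)
      power <- list(alpha = alpha, power_target = power_target,
                    case_fraction = kf, r2 = r2,
                    or_upper = dor$or_upper, or_lower = dor$or_lower)
    }
    list(
      outcome = label,
      harmonization = list(n_instruments = k, exclusions = hset$exclusions),
      estimates = estimates,
      heterogeneity = if (k >= 2) cochran_q(hset) else NULL,
      egger_intercept = if (k >= 3) egger_intercept_test(hset) else NULL,
      leave_one_out = if (k >= 3) leave_one_out(hset) else NULL,
      strength = strength,
      power = power
    )
  })
  names(blocks) <- names(outcomes)
  structure(
    list(
      outcomes = blocks,
      metadata = list(
        seed = seed, n_boot = n_boot, p_threshold = p_threshold,
        clump_kb = clump_kb, clump_r2 = clump_r2,
        drop_palindromic = drop_palindromic,
        package_version = as.character(utils::packageVersion("mrkit"))
      )
    ),
    class = "study_report"
  )
}

#' Replicate the bundled homocysteine / aneurysm study
#'
#' Runs [run_study()] on the bundled instrument table for the three
#' aneurysm outcomes in the order IA, UIA, aSAH with the study's default
#' parameters (instrument p < 5e-8, palindromic variants dropped, 1000
#' bootstrap replicates). The bundled records are pre-aligned and
#' pre-clumped, so harmonization passes them through and no LD input is
#' needed.
#'
#' @param seed RNG seed for the bootstrap standard errors.
#' @param n_boot Bootstrap replicates.
#' @return A `study_report` with outcome blocks IA, UIA, aSAH.
#' @export
run_table1_study <- function(seed = 1, n_boot = 1000) {
  fixtures <- lapply(c(IA = "IA", UIA = "UIA", aSAH = "aSAH"),
                     load_table1_fixture)
  run_study(
    exposure = fixtures$IA$exposure,
    outcomes = lapply(fixtures, `[[`, "outcome"),
    n_boot = n_boot, seed = seed
  )
}

#' Flat table of estimates from a study report
#'
#' @param report A `study_report`.
#' @return Data frame with columns `outcome`, `method`, `n_snp`, `beta`,
#'   `se`, `or`, `ci_low_or`, `ci_high_or`, `pvalue`; one row per
#'   outcome x method.
#' @export
estimates_table <- function(report) {
  stopifnot(inherits(report, "study_report"))
  rows <- lapply(report$outcomes, function(b) {
    do.call(rbind, lapply(b$estimates, function(e) {
      data.frame(outcome = b$outcome, method = e$method, n_snp = e$n_snp,
                 beta = e$beta, se = e$se, or = e$or,
                 ci_low_or = e$or_ci_low, ci_high_or = e$or_ci_high,
                 pvalue = e$pvalue, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.study_report <- function(x, ...) {
  tab <- estimates_table(x)
  cat(sprintf("<study_report> %d outcome(s), seed %d\n",
              length(x$outcomes), x$metadata$seed))
  print(format(tab, digits = 4), row.names = FALSE)
  for (b in x$outcomes) {
    cat(sprintf(
      "%s: %d instrument(s)%s; Q = %.3f (p = %.3g); Egger intercept p = %.3g; F = %.1f\n",
      b$outcome, b$harmonization$n_instruments,
      if (nrow(b$harmonization$exclusions)) {
        paste0(" [excluded: ",
               paste(b$harmonization$exclusions$rsid, collapse = ", "), "]")
      } else "",
      b$heterogeneity$Q, b$heterogeneity$pvalue,
      b$egger_intercept$pvalue, b$strength$F
    ))
  }
  invisible(x)
}

#' Write a study report to TSV or structured JSON
#'
#' The TSV format emits the flat estimate table followed by keyed
#' diagnostic sections; the JSON format serializes the full report and
#' can be read back with [read_report()] to an equal structure. Output
#' is bit-stable for a fixed report.
#'
#' @param report A `study_report`.
#' @param sink Output file path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(report, sink, format = c("tsv", "json")) {
  stopifnot(inherits(report, "study_report"))
  if (length(format) == 1L && !format %in% c("tsv", "json")) {
    stop("unknown report format '", format, "'; valid: tsv, json")
  }
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(.report_to_list(report), sink, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    return(invisible(NULL))
  }
  con <- file(sink, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(paste0(...), con)
  wr("# estimates")
  tab <- estimates_table(report)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  for (b in report$outcomes) {
    wr("# diagnostics\t", b$outcome)
    wr("n_instruments\t", b$harmonization$n_instruments)
    if (nrow(b$harmonization$exclusions)) {
      for (i in seq_len(nrow(b$harmonization$exclusions))) {
        wr("excluded\t", b$harmonization$exclusions$rsid[i], "\t",
           b$harmonization$exclusions$reason[i])
      }
    }
    if (!is.null(b$heterogeneity)) {
      wr("cochran_q\t", b$heterogeneity$Q, "\t", b$heterogeneity$df, "\t",
         b$heterogeneity$pvalue)
    }
    if (!is.null(b$egger_intercept)) {
      wr("egger_intercept\t", b$egger_intercept$intercept, "\t",
         b$egger_intercept$se, "\t", b$egger_intercept$pvalue)
    }
    wr("instrument_r2\t", b$strength$r2)
    wr("f_statistic\t", b$strength$F)
    if (!is.null(b$power)) {
      wr("detectable_or\t", b$power$or_upper, "\t", b$power$or_lower,
         "\tpower\t", b$power$power_target)
    }
  }
  wr("# metadata")
  for (key in names(report$metadata)) {
    wr(key, "\t", report$metadata[[key]])
  }
  invisible(NULL)
}

.report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "data.frame")) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(unclass(report))
}

#' Read back a JSON study report
#'
#' @param path Path to a file written by [write_report()] with
#'   `format = "json"`.
#' @return A `study_report` (estimate entries regain class
#'   `mr_estimate`).
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$outcomes <- lapply(raw$outcomes, function(b) {
    b$estimates <- lapply(b$estimates, function(e) {
      e$n_snp <- as.integer(e$n_snp)
      structure(e, class = "mr_estimate")
    })
    if (!is.null(b$heterogeneity)) {
      b$heterogeneity$df <- as.integer(b$heterogeneity$df)
      b$heterogeneity <- structure(b$heterogeneity,
                                   class = "heterogeneity_result")
    }
    if (!is.null(b$strength)) {
      b$strength$n <- as.integer(b$strength$n)
      b$strength$k <- as.integer(b$strength$k)
      b$strength <- structure(b$strength, class = "instrument_strength")
    }
    b
  })
  structure(raw, class = "study_report")
}
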
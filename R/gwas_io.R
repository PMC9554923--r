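#' Default column dialect for summary-statistic tables
#'
#' Maps the internal field names used throughout the package to the column
#' headers of a tab-separated GWAS summary-statistics file. The default
#' mirrors common GWAS-SSF-style exports. Users can rename entries to match
#' their own files; the *names* of the vector are the internal fields, the
#' *values* are the column headers expected in the file.
#'
#' @return Named character vector mapping internal fields to column names.
#' @export
#' @examples
#' default_dialect()
default_dialect <- function() {
  c(
    rsid = "rsid", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n"
  )
}

.MANDATORY_FIELDS <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
.RECORD_FIELDS <- c(
  "rsid", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)

#' Construct a summary dataset
#'
#' A summary dataset holds per-variant association statistics for one trait
#' in one GWAS, together with trait metadata. Records are stored as a
#' data frame with one row per variant; rsIDs must be unique.
#'
#' @param trait Trait label.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_total Total GWAS sample size.
#' @param n_cases Number of cases (binary traits only).
#' @param records Data frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `chrom`, `pos`,
#'   `eaf`, `n`, `pre_aligned`.
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(trait, trait_type = c("quantitative", "binary"),
                            n_total, n_cases = NULL, records) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait), length(trait) == 1L)
  n_total <- as.integer(n_total)
  if (is.na(n_total) || n_total <= 0L) stop("n_total must be a positive integer")
  if (!is.null(n_cases)) {
    n_cases <- as.integer(n_cases)
    if (is.na(n_cases) || n_cases <= 0L) stop("n_cases must be a positive integer")
    if (n_cases > n_total) stop("n_cases cannot exceed n_total")
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (f in setdiff(.RECORD_FIELDS, names(records))) records[[f]] <- NA
  if (!"pre_aligned" %in% names(records)) records$pre_aligned <- FALSE
  if (anyDuplicated(records$rsid)) {
    dup <- unique(records$rsid[duplicated(records$rsid)])
    stop("duplicate rsid(s): ", paste(dup, collapse = ", "))
  }
  records$effect_allele <- toupper(records$effect_allele)
  records$other_allele <- toupper(records$other_allele)
  rownames(records) <- NULL
  structure(
    list(
      trait = trait, trait_type = trait_type,
      n_total = n_total, n_cases = n_cases,
      records = records[, c(.RECORD_FIELDS, "pre_aligned")]
    ),
    class = "summary_dataset"
  )
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf(
    "<summary_dataset> trait '%s' (%s), n = %d%s, %d variant record(s)\n",
    x$trait, x$trait_type, x$n_total,
    if (!is.null(x$n_cases)) sprintf(" (%d cases)", x$n_cases) else "",
    nrow(x$records)
  ))
  invisible(x)
}

#' Number of variant records in a summary dataset
#' @param dataset A `summary_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(dataset) nrow(dataset$records)

# Validate one parsed record; returns NULL if valid, else a reason string.
.record_problem <- function(rec, require_alleles = TRUE) {
  if (is.na(rec$rsid) || !nzchar(rec$rsid)) return("missing rsid")
  if (require_alleles) {
    ok_allele <- function(a) !is.na(a) && a %in% c("A", "C", "G", "T")
    if (!ok_allele(rec$effect_allele)) return("invalid effect_allele")
    if (!ok_allele(rec$other_allele)) return("invalid other_allele")
    if (rec$effect_allele == rec$other_allele) return("identical alleles")
  }
  if (is.na(rec$beta) || !is.finite(rec$beta)) return("missing beta")
  if (is.na(rec$se) || rec$se <= 0) return("non-positive se")
  if (is.na(rec$pval) || rec$pval <= 0 || rec$pval > 1) return("p-value outside (0,1]")
  if (!is.na(rec$eaf) && (rec$eaf <= 0 || rec$eaf >= 1)) return("eaf outside (0,1)")
  if (!is.na(rec$n) && rec$n <= 0) return("non-positive n")
  if (!is.na(rec$pos) && rec$pos < 0) return("negative pos")
  NULL
}

#' Read a tab-separated summary-statistics table
#'
#' Reads a GWAS summary-statistics file into a [summary_dataset()]. Column
#' headers are resolved through `dialect`; the fields `rsid`,
#' `effect_allele`, `other_allele`, `beta`, `se` and `pval` are mandatory.
#' Rows violating record invariants (non-positive SE, p outside (0,1],
#' malformed alleles, ...) are dropped with a message; the drop count and
#' reasons are attached as attributes `n_dropped` and `drop_reasons`.
#'
#' A soft consistency check compares each row's stated p-value with the
#' two-sided normal p implied by |beta/se|; disagreement beyond a factor of
#' two raises a warning (never an error), since printed p-values are often
#' rounded or derived from a different test.
#'
#' @param source Path to a tab-separated file with a header row.
#' @param dialect Named character vector as in [default_dialect()].
#' @param trait,trait_type,n_total,n_cases Trait metadata passed to
#'   [summary_dataset()]; `n_total` defaults to the maximum of the `n`
#'   column when present.
#' @return A `summary_dataset`.
#' @export
read_summary_table <- function(source, dialect = default_dialect(),
                               trait = "trait",
                               trait_type = c("quantitative", "binary"),
                               n_total = NULL, n_cases = NULL) {
  trait_type <- match.arg(trait_type)
  dialect <- c(dialect, default_dialect()[setdiff(names(default_dialect()), names(dialect))])
  raw <- tryCatch(
    utils::read.delim(source, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("NA", "")),
    error = function(e) stop("cannot read summary table: ", conditionMessage(e))
  )
  if (nrow(raw) == 0L) stop("empty summary table: ", source)
  missing_cols <- .MANDATORY_FIELDS[!dialect[.MANDATORY_FIELDS] %in% names(raw)]
  if (length(missing_cols)) {
    stop(
      "missing mandatory column(s): ",
      paste(sprintf("%s (expected header '%s')", missing_cols, dialect[missing_cols]),
            collapse = ", ")
    )
  }
  rec <- data.frame(rsid = as.character(raw[[dialect[["rsid"]]]]),
                    stringsAsFactors = FALSE)
  get_col <- function(field, cast) {
    col <- dialect[[field]]
    if (col %in% names(raw)) cast(raw[[col]]) else rep(cast(NA), nrow(raw))
  }
  rec$chrom <- get_col("chrom", as.character)
  rec$pos <- get_col("pos", as.integer)
  rec$effect_allele <- toupper(get_col("effect_allele", as.character))
  rec$other_allele <- toupper(get_col("other_allele", as.character))
  rec$eaf <- get_col("eaf", as.numeric)
  rec$beta <- get_col("beta", as.numeric)
  rec$se <- get_col("se", as.numeric)
  rec$pval <- get_col("pval", as.numeric)
  rec$n <- get_col("n", as.integer)
  # optional flag column for records already aligned to a common effect
  # allele (no allele labels available); such rows skip allele checks
  rec$pre_aligned <- if ("pre_aligned" %in% names(raw)) {
    as.logical(raw$pre_aligned)
  } else {
    rep(FALSE, nrow(raw))
  }
  rec$pre_aligned[is.na(rec$pre_aligned)] <- FALSE

  if (anyDuplicated(rec$rsid)) {
    dup <- unique(rec$rsid[duplicated(rec$rsid)])
    stop("duplicate rsid(s) in ", source, ": ", paste(dup, collapse = ", "))
  }

  problems <- vapply(seq_len(nrow(rec)),
                     function(i) {
                       p <- .record_problem(rec[i, ],
                                            require_alleles = !rec$pre_aligned[i])
                       if (is.null(p)) NA_character_ else p
                     }, character(1))
  dropped <- !is.na(problems)
  if (any(dropped)) {
    message(sum(dropped), " row(s) dropped while reading ", source, ": ",
            paste(sprintf("%s (%s)", rec$rsid[dropped], problems[dropped]),
                  collapse = "; "))
  }
  keep <- rec[!dropped, , drop = FALSE]
  if (nrow(keep)) {
    implied <- 2 * stats::pnorm(-abs(keep$beta / keep$se))
    off <- implied > 0 & (keep$pval / implied > 2 | implied / keep$pval > 2)
    if (any(off, na.rm = TRUE)) {
      warning(sum(off, na.rm = TRUE), " record(s) have a stated p-value ",
              "differing from the normal p implied by |beta/se| by more ",
              "than a factor of 2 (e.g. ", keep$rsid[which(off)[1]], ")")
    }
  }
  if (is.null(n_total)) {
    if (all(is.na(keep$n))) stop("n_total not given and no 'n' column present")
    n_total <- max(keep$n, na.rm = TRUE)
  }
  ds <- summary_dataset(trait, trait_type, n_total, n_cases, keep)
  attr(ds, "n_dropped") <- sum(dropped)
  attr(ds, "drop_reasons") <- stats::setNames(problems[dropped], rec$rsid[dropped])
  ds
}

#' Write a summary dataset to a tab-separated file
#'
#' Emits the record table under the given dialect, one row per variant,
#' `NA` for missing optional fields. Records without a per-variant `n`
#' inherit the dataset-level sample size, and a `pre_aligned` column is
#' appended when any record carries the flag, so the file re-reads to an
#' equivalent dataset through [read_summary_table()].
#'
#' @param dataset A `summary_dataset`.
#' @param sink Output file path or connection.
#' @param dialect Named character vector as in [default_dialect()].
#' @export
write_summary_table <- function(dataset, sink, dialect = default_dialect()) {
  stopifnot(inherits(dataset, "summary_dataset"))
  dialect <- c(dialect, default_dialect()[setdiff(names(default_dialect()), names(dialect))])
  out <- dataset$records[, .RECORD_FIELDS]
  out$n[is.na(out$n)] <- dataset$n_total
  names(out) <- dialect[.RECORD_FIELDS]
  if (any(dataset$records$pre_aligned)) {
    out$pre_aligned <- dataset$records$pre_aligned
  }
  utils::write.table(out, sink, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}
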
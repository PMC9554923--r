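#' Select genome-wide significant instruments
#'
#' Keeps the exposure records with association p-value below the
#' threshold, preserving the input order. The conventional genome-wide
#' significance threshold of 5e-8 is the default.
#'
#' @param exposure A [summary_dataset()].
#' @param p_threshold Significance threshold in (0,1).
#' @return A `summary_dataset` with the retained records.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8) {
  stopifnot(inherits(exposure, "summary_dataset"),
            p_threshold > 0, p_threshold <= 1)
  keep <- exposure$records$pval < p_threshold
  if (!any(keep)) {
    stop("no instruments: no record has p < ", format(p_threshold))
  }
  out <- exposure
  out$records <- exposure$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Read a square LD correlation matrix from a tab-separated file
#'
#' The file must have an rsid header row and a leading rsid column; cell
#' (i, j) holds the pairwise r-squared between variants i and j.
#'
#' @param path File path.
#' @return A symmetric numeric matrix with rsid dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("LD matrix must be square with matching rsid row/column names")
  }
  m
}

#' Read variant positions from a 3-column TSV (rsid, chrom, pos)
#' @param path File path.
#' @return Data frame with columns `rsid`, `chrom`, `pos`.
#' @export
read_positions <- function(path) {
  pos <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos")
  if (!all(need %in% names(pos))) {
    stop("positions file must have columns: ", paste(need, collapse = ", "))
  }
  pos$pos <- as.integer(pos$pos)
  pos
}

#' Greedy LD clumping of candidate instruments
#'
#' Prunes correlated variants so that retained instruments are
#' approximately independent. Candidates are ranked by ascending p-value
#' (ties broken lexicographically by rsid); the best remaining variant is
#' taken as an index variant and every remaining variant on the same
#' chromosome within `window_kb` kilobases *and* with r-squared at least
#' `r2_max` against it is removed. The defaults (10,000 kb window,
#' r-squared < 0.001) enforce near-complete independence.
#'
#' @param candidates A [summary_dataset()] of candidate instruments.
#' @param positions Data frame with columns `rsid`, `chrom`, `pos`
#'   covering every candidate.
#' @param ld Symmetric r-squared matrix with rsid dimnames covering every
#'   candidate (unit diagonal).
#' @param window_kb Clumping distance in kilobases.
#' @param r2_max r-squared threshold; pairs at or above it are clumped.
#' @return A `summary_dataset` of retained index variants, in the
#'   original input order.
#' @export
clump <- function(candidates, positions, ld, window_kb = 10000,
                  r2_max = 0.001) {
  stopifnot(inherits(candidates, "summary_dataset"))
  rec <- candidates$records
  missing_pos <- setdiff(rec$rsid, positions$rsid)
  if (length(missing_pos)) {
    stop("no position for candidate(s): ", paste(missing_pos, collapse = ", "))
  }
  missing_ld <- setdiff(rec$rsid, rownames(ld))
  if (length(missing_ld)) {
    stop("no LD entry for candidate(s): ", paste(missing_ld, collapse = ", "))
  }
  if (any(abs(ld - t(ld)) > 1e-8)) stop("LD matrix is not symmetric")
  idx <- match(rec$rsid, positions$rsid)
  chrom <- positions$chrom[idx]
  pos <- positions$pos[idx]

  ord <- order(rec$pval, rec$rsid)
  alive <- rep(TRUE, nrow(rec))
  retained <- character(0)
  for (i in ord) {
    if (!alive[i]) next
    retained <- c(retained, rec$rsid[i])
    same_chr <- alive & chrom == chrom[i]
    near <- same_chr & abs(pos - pos[i]) <= window_kb * 1000
    linked <- near & ld[rec$rsid, rec$rsid[i]] >= r2_max
    linked[i] <- FALSE
    alive[linked] <- FALSE
    alive[i] <- FALSE
  }
  out <- candidates
  out$records <- rec[rec$rsid %in% retained, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous) variant has complementary alleles — A/T or
#' C/G — so its strand orientation cannot be inferred from the alleles
#' alone.
#'
#' @param effect_allele,other_allele Single-base alleles in {A,C,G,T}.
#' @return Logical.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele); b <- toupper(other_allele)
  if (!all(c(a, b) %in% c("A", "C", "G", "T"))) {
    stop("alleles must be one of A, C, G, T (got '", a, "'/'", b, "')")
  }
  (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "C" && b == "G") || (a == "G" && b == "C")
}

.complement <- function(a) c(A = "T", T = "A", C = "G", G = "C")[[a]]

#' Harmonize one exposure/outcome record pair to a common effect allele
#'
#' Aligns the outcome effect to the exposure's effect allele. Identical
#' allele pairs pass through; swapped pairs flip the sign of the outcome
#' beta (and reflect the allele frequency); strand-complement pairs are
#' complemented first and then treated the same way. Palindromic variants
#' are excluded when `drop_palindromic` is `TRUE` (the default), because
#' their strand cannot be resolved from alleles alone. Records carrying a
#' `pre_aligned` flag pass through unchanged.
#'
#' @param exposure_rec,outcome_rec One-row data frames (rows of a
#'   `summary_dataset`'s records) sharing an rsid.
#' @param drop_palindromic Drop A/T and C/G variants?
#' @return A list with either `instrument` (data frame row with `rsid`,
#'   `bx`, `se_x`, `by`, `se_y`) or `exclusion` (reason string).
#' @export
harmonize_pair <- function(exposure_rec, outcome_rec, drop_palindromic = TRUE) {
  if (exposure_rec$rsid != outcome_rec$rsid) {
    stop("rsid mismatch: ", exposure_rec$rsid, " vs ", outcome_rec$rsid)
  }
  instrument <- function(by) {
    list(instrument = data.frame(
      rsid = exposure_rec$rsid, bx = exposure_rec$beta,
      se_x = exposure_rec$se, by = by, se_y = outcome_rec$se,
      stringsAsFactors = FALSE
    ))
  }
  pre_x <- isTRUE(exposure_rec$pre_aligned)
  pre_y <- isTRUE(outcome_rec$pre_aligned)
  if (pre_x && pre_y) return(instrument(outcome_rec$beta))

  ea_x <- exposure_rec$effect_allele; oa_x <- exposure_rec$other_allele
  ea_y <- outcome_rec$effect_allele; oa_y <- outcome_rec$other_allele
  if (is_palindromic(ea_x, oa_x) && drop_palindromic) {
    return(list(exclusion = "palindromic"))
  }
  if (ea_y == ea_x && oa_y == oa_x) return(instrument(outcome_rec$beta))
  if (ea_y == oa_x && oa_y == ea_x) return(instrument(-outcome_rec$beta))
  cea <- .complement(ea_y); coa <- .complement(oa_y)
  if (cea == ea_x && coa == oa_x) return(instrument(outcome_rec$beta))
  if (cea == oa_x && coa == ea_x) return(instrument(-outcome_rec$beta))
  list(exclusion = "allele mismatch")
}

#' Construct a harmonized instrument set
#'
#' @param instruments Data frame with columns `rsid`, `bx`, `se_x`,
#'   `by`, `se_y`.
#' @param exposure_n,outcome_n GWAS sample sizes.
#' @param outcome_cases Case count for binary outcomes (optional).
#' @param exclusions Data frame with columns `rsid`, `reason`.
#' @return An object of class `harmonized_set`.
#' @export
harmonized_set <- function(instruments, exposure_n, outcome_n,
                           outcome_cases = NULL,
                           exclusions = data.frame(rsid = character(0),
                                                   reason = character(0))) {
  instruments <- as.data.frame(instruments, stringsAsFactors = FALSE)
  stopifnot(all(c("rsid", "bx", "se_x", "by", "se_y") %in% names(instruments)),
            all(instruments$se_x > 0), all(instruments$se_y > 0),
            !anyDuplicated(instruments$rsid))
  if (any(exclusions$rsid %in% instruments$rsid)) {
    stop("exclusions overlap retained instruments")
  }
  rownames(instruments) <- NULL
  structure(
    list(instruments = instruments,
         exposure_n = as.integer(exposure_n),
         outcome_n = as.integer(outcome_n),
         outcome_cases = if (is.null(outcome_cases)) NULL else as.integer(outcome_cases),
         exclusions = exclusions),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %d instrument(s), %d exclusion(s)\n",
              nrow(x$instruments), nrow(x$exclusions)))
  if (nrow(x$exclusions)) {
    cat(paste(sprintf("  - %s: %s", x$exclusions$rsid, x$exclusions$reason),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Number of instruments in a harmonized set
#' @param set A `harmonized_set`.
#' @return Integer.
#' @export
n_instruments <- function(set) nrow(set$instruments)

#' Harmonize an exposure dataset against an outcome dataset
#'
#' Pairs every exposure instrument with the matching outcome record and
#' harmonizes the pair via [harmonize_pair()]. Instruments absent from
#' the outcome dataset are excluded with reason `"absent from outcome"`
#' (no proxy-variant search is attempted). Output order follows the
#' exposure dataset.
#'
#' @param exposure A [summary_dataset()] of selected/clumped instruments.
#' @param outcome A [summary_dataset()] for the outcome trait.
#' @param drop_palindromic Passed to [harmonize_pair()].
#' @return A [harmonized_set()].
#' @export
build_harmonized_set <- function(exposure, outcome, drop_palindromic = TRUE) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  inst <- list(); excl_rsid <- character(0); excl_reason <- character(0)
  out_rec <- outcome$records
  for (i in seq_len(nrow(exposure$records))) {
    erec <- exposure$records[i, ]
    j <- match(erec$rsid, out_rec$rsid)
    if (is.na(j)) {
      excl_rsid <- c(excl_rsid, erec$rsid)
      excl_reason <- c(excl_reason, "absent from outcome")
      next
    }
    h <- harmonize_pair(erec, out_rec[j, ], drop_palindromic)
    if (!is.null(h$instrument)) {
      inst[[length(inst) + 1L]] <- h$instrument
    } else {
      excl_rsid <- c(excl_rsid, erec$rsid)
      excl_reason <- c(excl_reason, h$exclusion)
    }
  }
  if (!length(inst)) {
    stop("no instruments: no exposure record could be harmonized with the outcome")
  }
  harmonized_set(
    do.call(rbind, inst),
    exposure_n = exposure$n_total,
    outcome_n = outcome$n_total,
    outcome_cases = outcome$n_cases,
    exclusions = data.frame(rsid = excl_rsid, reason = excl_reason,
                            stringsAsFactors = FALSE)
  )
}
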
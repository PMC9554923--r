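# Homocysteine / intracranial-aneurysm worked example.
#
# Eleven SNPs associated with plasma homocysteine (exposure GWAS of 44,147
# European-ancestry subjects) and their effects in three intracranial-
# aneurysm outcome datasets from a GWAS of 7,495 cases and 71,934 controls:
# IA (any rupture status, 7,495 cases), unruptured IA (UIA, 2,070 cases)
# and aneurysmal subarachnoid hemorrhage (aSAH, 5,140 cases). Values are
# embedded as code constants so tests are bit-exact and need no I/O.
#
# The published table prints no alleles or allele frequencies, so these
# records carry a `pre_aligned` sentinel: harmonization passes them
# through unchanged rather than attempting allele alignment. Two outcome
# cells (rs234709 and rs1801133 in UIA) are unavailable and are simply
# absent from that dataset; no proxy variants exist for them.

.table1 <- function() {
  data.frame(
    rsid = c("rs9369898", "rs7130284", "rs4660306", "rs42648", "rs234709",
             "rs2275565", "rs2251468", "rs1801222", "rs1801133", "rs154657",
             "rs12780845"),
    gene = c("MUT", "NOX4", "MMACHC", "GTPB10", "CBS", "MTR", "HNF1A",
             "CUBN", "MTHFR", "DPEP1", "CUBN"),
    hcy_beta = c(0.045, -0.124, 0.044, -0.040, -0.072, -0.054, -0.051,
                 0.045, 0.158, 0.096, 0.053),
    hcy_se = c(0.007, 0.013, 0.007, 0.007, 0.007, 0.009, 0.007, 0.007,
               0.007, 0.007, 0.009),
    hcy_p = c(2.17e-10, 1.88e-20, 2.33e-09, 1.97e-08, 3.90e-24, 1.96e-10,
              1.28e-12, 8.43e-10, 4.34e-104, 1.74e-43, 7.80e-10),
    ia_beta = c(-0.010, -0.020, -0.004, -0.002, -0.030, -0.066, -0.019,
                0.017, 0.034, -0.018, -0.007),
    ia_se = c(0.023, 0.040, 0.023, 0.023, 0.023, 0.026, 0.022, 0.022,
              0.024, 0.023, 0.024),
    ia_p = c(0.669, 0.609, 0.868, 0.918, 0.190, 0.010, 0.390, 0.431,
             0.165, 0.434, 0.780),
    uia_beta = c(0.004, -0.018, -0.011, -0.004, NA, -0.058, -0.003, 0.029,
                 NA, 0.008, 0.005),
    uia_se = c(0.040, 0.070, 0.041, 0.040, NA, 0.047, 0.040, 0.041, NA,
               0.040, 0.042),
    uia_p = c(0.93, 0.80, 0.78, 0.91, NA, 0.22, 0.95, 0.48, NA, 0.83, 0.91),
    asah_beta = c(-0.016, -0.017, 0.001, -0.002, -0.022, -0.062, -0.021,
                  0.010, 0.035, -0.016, -0.015),
    asah_se = c(0.027, 0.046, 0.028, 0.027, 0.026, 0.030, 0.025, 0.025,
                0.028, 0.027, 0.029),
    asah_p = c(0.56, 0.72, 0.99, 0.94, 0.39, 0.04, 0.39, 0.70, 0.21, 0.56,
               0.59),
    stringsAsFactors = FALSE
  )
}

.HCY_N <- 44147L
.OUTCOME_N_TOTAL <- 79429L
.OUTCOME_CASES <- c(IA = 7495L, UIA = 2070L, aSAH = 5140L)

#' Load the bundled homocysteine / intracranial-aneurysm instrument table
#'
#' Returns the eleven-SNP instrument set for plasma homocysteine paired
#' with one of three intracranial-aneurysm outcome datasets: `"IA"`
#' (aneurysm of any rupture status), `"UIA"` (unruptured only) or
#' `"aSAH"` (aneurysmal subarachnoid hemorrhage, i.e. ruptured). The
#' exposure dataset always has 11 records (n = 44,147); the outcome
#' dataset has 11 records for IA and aSAH and 9 for UIA, where two
#' instruments were unavailable and have no proxy. Because the source
#' table prints effect sizes already aligned to a common allele but no
#' allele labels, all records carry a `pre_aligned` flag that makes
#' harmonization pass them through unchanged.
#'
#' @param outcome One of `"IA"`, `"UIA"`, `"aSAH"`.
#' @return A list with elements `exposure` and `outcome`, both
#'   [summary_dataset()] objects.
#' @export
#' @examples
#' fx <- load_table1_fixture("IA")
#' n_records(fx$exposure)  # 11
#' n_records(fx$outcome)   # 11
load_table1_fixture <- function(outcome = c("IA", "UIA", "aSAH")) {
  if (length(outcome) == 1L && !outcome %in% c("IA", "UIA", "aSAH")) {
    stop("unknown outcome '", outcome, "'; valid labels: IA, UIA, aSAH")
  }
  outcome <- match.arg(outcome)
  tab <- .table1()
  prefix <- c(IA = "ia", UIA = "uia", aSAH = "asah")[[outcome]]
  mk_records <- function(beta, se, pval) {
    data.frame(
      rsid = tab$rsid, chrom = NA_character_, pos = NA_integer_,
      effect_allele = NA_character_, other_allele = NA_character_,
      eaf = NA_real_, beta = beta, se = se, pval = pval,
      n = NA_integer_, pre_aligned = TRUE, stringsAsFactors = FALSE
    )
  }
  expo <- summary_dataset(
    trait = "plasma homocysteine", trait_type = "quantitative",
    n_total = .HCY_N,
    records = mk_records(tab$hcy_beta, tab$hcy_se, tab$hcy_p)
  )
  out_rec <- mk_records(tab[[paste0(prefix, "_beta")]],
                        tab[[paste0(prefix, "_se")]],
                        tab[[paste0(prefix, "_p")]])
  out_rec <- out_rec[!is.na(out_rec$beta), , drop = FALSE]
  outc <- summary_dataset(
    trait = outcome, trait_type = "binary",
    n_total = .OUTCOME_N_TOTAL, n_cases = .OUTCOME_CASES[[outcome]],
    records = out_rec
  )
  list(exposure = expo, outcome = outc)
}
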
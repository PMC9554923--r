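# Small instrument sets with hand-computable estimates.

toy_set <- function(bx, by, se_y, se_x = rep(0.01, length(bx))) {
  harmonized_set(
    data.frame(rsid = sprintf("snp%d", seq_along(bx)),
               bx = bx, se_x = se_x, by = by, se_y = se_y,
               stringsAsFactors = FALSE),
    exposure_n = 10000L, outcome_n = 20000L, outcome_cases = 2000L
  )
}

# Exactly proportional ratios: every estimator returns 0.5.
toy_a <- function() toy_set(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20),
                            rep(0.05, 3))

# Heterogeneous ratios (0.2, 0.5, 0.6) with equal outcome SEs.
toy_b <- function() toy_set(c(0.1, 0.2, 0.4), c(0.02, 0.10, 0.24),
                            rep(0.05, 3))

# A valid synthetic dataset for IO round-trips.
io_dataset <- function(n = 5) {
  summary_dataset(
    trait = "test trait", trait_type = "quantitative", n_total = 1000L,
    records = data.frame(
      rsid = sprintf("rs%d", seq_len(n)),
      chrom = as.character(rep_len(1:3, n)),
      pos = seq_len(n) * 1000L,
      effect_allele = rep_len(c("A", "C", "G"), n),
      other_allele = rep_len(c("G", "T", "A"), n),
      eaf = seq(0.1, 0.5, length.out = n),
      beta = seq(-0.2, 0.2, length.out = n),
      se = rep(0.05, n),
      pval = 2 * pnorm(-abs(seq(-0.2, 0.2, length.out = n) / 0.05)),
      n = rep(1000L, n),
      stringsAsFactors = FALSE
    )
  )
}

# Build a one-row record for harmonize_pair tests.
variant_row <- function(rsid, ea, oa, beta, se = 0.05, pre_aligned = FALSE) {
  data.frame(rsid = rsid, chrom = NA_character_, pos = NA_integer_,
             effect_allele = ea, other_allele = oa, eaf = NA_real_,
             beta = beta, se = se, pval = 0.5, n = NA_integer_,
             pre_aligned = pre_aligned, stringsAsFactors = FALSE)
}

# Brute-force greedy clumping oracle: direct re-statement of the rule
# on explicit loops, independent of the package implementation.
clump_oracle <- function(rec, positions, ld, window_kb, r2_max) {
  ord <- order(rec$pval, rec$rsid)
  ids <- rec$rsid[ord]
  chrom <- positions$chrom[match(ids, positions$rsid)]
  pos <- positions$pos[match(ids, positions$rsid)]
  alive <- rep(TRUE, length(ids))
  kept <- character(0)
  for (i in seq_along(ids)) {
    if (!alive[i]) next
    kept <- c(kept, ids[i])
    alive[i] <- FALSE
    for (j in seq_along(ids)) {
      if (!alive[j]) next
      if (chrom[j] == chrom[i] &&
          abs(pos[j] - pos[i]) <= window_kb * 1000 &&
          ld[ids[j], ids[i]] >= r2_max) {
        alive[j] <- FALSE
      }
    }
  }
  kept
}
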
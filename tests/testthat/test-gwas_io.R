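test_that("summary tables round-trip through TSV field-for-field", {
  ds <- io_dataset(5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(ds, path)
  back <- read_summary_table(path, trait = ds$trait, n_total = ds$n_total)
  expect_equal(back$records[, names(back$records) != "pre_aligned"],
               ds$records[, names(ds$records) != "pre_aligned"])
  expect_equal(attr(back, "n_dropped"), 0L)

  # optional fields absent -> NA columns that survive the round trip
  ds2 <- summary_dataset("t", "quantitative", 100L, records = data.frame(
    rsid = "rs1", effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.02, pval = 1e-6, stringsAsFactors = FALSE
  ))
  write_summary_table(ds2, path)
  raw <- read.delim(path)
  expect_true(all(is.na(raw$eaf)))
  back2 <- read_summary_table(path, n_total = 100L)
  expect_equal(back2$records$beta, 0.1)
})

test_that("pre-aligned datasets survive TSV export and re-import", {
  fx <- load_table1_fixture("UIA")
  exp_path <- withr::local_tempfile(fileext = ".tsv")
  out_path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(fx$exposure, exp_path)
  write_summary_table(fx$outcome, out_path)
  # rows without alleles re-read because the pre_aligned flag is carried;
  # the published p-values are rounded, so the soft consistency check
  # warns without dropping anything
  expect_warning(exposure <- read_summary_table(exp_path, trait = "hcy"),
                 "factor of 2")
  outcome <- read_summary_table(out_path, trait = "UIA",
                                trait_type = "binary")
  expect_equal(n_records(exposure), 11L)
  expect_identical(exposure$n_total, 44147L)  # filled from the n column
  expect_identical(exposure$records$beta, fx$exposure$records$beta)
  hs <- build_harmonized_set(exposure, outcome)
  expect_equal(n_instruments(hs), 9L)
})

test_that("empty dataset writes a header-only file", {
  ds <- io_dataset(3)
  ds$records <- ds$records[0, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(ds, path)
  expect_length(readLines(path), 1L)
})

test_that("invalid rows are dropped with a counted reason", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "rsid\teffect_allele\tother_allele\tbeta\tse\tpval",
    "rs1\tA\tG\t0.10\t0.02\t0.0000006",
    "rs2\tA\tG\t0.10\t0\t0.001",
    "rs3\tA\tA\t0.10\t0.02\t0.001",
    "rs4\tX\tG\t0.10\t0.02\t0.001"
  ), path)
  expect_message(ds <- read_summary_table(path, n_total = 500L), "dropped")
  expect_equal(n_records(ds), 1L)
  expect_equal(attr(ds, "n_dropped"), 3L)
  expect_match(attr(ds, "drop_reasons")[["rs2"]], "se")
})

test_that("structural problems are fatal and named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\teffect_allele\tother_allele\tbeta\tpval",
               "rs1\tA\tG\t0.1\t0.001"), path)
  expect_error(read_summary_table(path, n_total = 100L), "se")

  writeLines(c("rsid\teffect_allele\tother_allele\tbeta\tse\tpval",
               "rs1\tA\tG\t0.1\t0.02\t0.001",
               "rs1\tA\tG\t0.2\t0.02\t0.001"), path)
  expect_error(read_summary_table(path, n_total = 100L), "rs1")

  writeLines("rsid\teffect_allele\tother_allele\tbeta\tse\tpval", path)
  expect_error(read_summary_table(path, n_total = 100L), "empty")
})

test_that("column dialect remapping resolves nonstandard headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tA2\tEffect\tStdErr\tP",
               "rs1\ta\tg\t0.1\t0.02\t6e-7"), path)
  ds <- read_summary_table(
    path,
    dialect = c(rsid = "SNP", effect_allele = "A1", other_allele = "A2",
                beta = "Effect", se = "StdErr", pval = "P"),
    n_total = 100L
  )
  expect_equal(ds$records$rsid, "rs1")
  expect_equal(ds$records$effect_allele, "A")  # case normalized
})

test_that("stated p-values inconsistent with beta/se raise a soft warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\teffect_allele\tother_allele\tbeta\tse\tpval",
               "rs1\tA\tG\t0.10\t0.05\t0.9"), path)
  expect_warning(ds <- read_summary_table(path, n_total = 100L), "factor of 2")
  expect_equal(n_records(ds), 1L)  # warning, not a drop
})

test_that("duplicate rsids are rejected at construction", {
  rec <- io_dataset(2)$records
  rec$rsid <- c("rs1", "rs1")
  expect_error(summary_dataset("t", "quantitative", 100L, records = rec),
               "duplicate")
  expect_error(
    summary_dataset("t", "binary", 100L, n_cases = 200L,
                    records = io_dataset(2)$records),
    "n_cases"
  )
})
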
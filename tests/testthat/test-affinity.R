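test_that("annotation strings parse with units normalized to molar", {
  r <- parse_affinity("Kd=2nM")
  expect_equal(r$measurement, "Kd")
  expect_equal(r$qualifier, "=")
  expect_equal(r$value_molar, 2e-9)
  expect_false(is.na(r$delta_g))

  r2 <- parse_affinity("IC50~5uM")
  expect_equal(r2$measurement, "IC50")
  expect_equal(r2$value_molar, 5e-6)
  expect_true(is.na(r2$delta_g))

  r3 <- parse_affinity("Ki>10mM")
  expect_equal(r3$qualifier, ">")
  expect_equal(r3$value_molar, 1e-2)
  expect_true(is.na(r3$delta_g))

  # micro sign and whitespace are tolerated; unknown tokens are not
  expect_equal(parse_affinity("Kd = 3 µM")$value_molar, 3e-6)
  expect_error(parse_affinity("Kx=2nM"), "unrecognized")
  expect_error(parse_affinity("Kd=2furlongs"), "unrecognized")
  expect_error(parse_affinity(""), "empty")
})

test_that("the free-energy relation matches its closed form", {
  cfg <- plc_config()
  expect_identical(dg_from_constant(1), 0)
  expect_equal(dg_from_constant(1e-9), 8.31446e-3 * 298.15 * log(1e-9),
               tolerance = 1e-12)
  expect_equal(dg_from_constant(1e-6), -34.24805, tolerance = 1e-5)
  # strictly increasing in k
  ks <- 10^seq(-12, 2, by = 0.5)
  expect_true(all(diff(dg_from_constant(ks)) > 0))
  expect_error(dg_from_constant(0), "domain")
  expect_error(dg_from_constant(-1), "domain")
})

test_that("records round-trip through their formatted annotation", {
  raws <- c("Kd=2nM", "Ki<=500pM", "IC50~5uM", "EC50>1mM", "Kd=1.5e-2M")
  for (raw in raws) {
    r <- parse_affinity(raw)
    r2 <- parse_affinity(format_affinity(r))
    expect_equal(r2$measurement, r$measurement, label = raw)
    expect_equal(r2$qualifier, r$qualifier, label = raw)
    expect_equal(r2$value_molar, r$value_molar, label = raw)
  }
})

test_that("merge deduplicates by precedence and drops invalid constants", {
  recs <- list(
    parse_affinity("Kd=2nM", "1ABC", "ATP", "biolip"),
    parse_affinity("Kd=2nM", "1ABC", "ATP", "moad"),
    parse_affinity("Ki=5e3M", "2DEF", "LIG", "moad"),
    parse_affinity("EC50=1uM", "3GHI", "LIG", "other"))
  m <- merge_sources(recs)
  expect_equal(nrow(m$table), 2L)
  expect_equal(m$table$provenance[m$table$entry_id == "1ABC"],
               "biolip+moad")
  # the invalid Ki is a logged drop, not a silent one
  expect_true("invalid-affinity" %in% m$dropped$reason)
  expect_false("2DEF" %in% m$table$entry_id)
  # an EC50-only entry is retained
  expect_true("3GHI" %in% m$table$entry_id)
})

test_that("merge is idempotent", {
  recs <- list(parse_affinity("Kd=2nM", "1ABC", "ATP", "biolip"),
               parse_affinity("Ki=4uM", "1ABC", "ATP", "moad"))
  m1 <- merge_sources(recs)
  m2 <- merge_sources(m1$table)
  expect_identical(m1$table, m2$table)
})

test_that("dialect adapters read constructed source rows", {
  biolip <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("pdb_id\tligand\taffinity",
               "1abc\tATP\tKd=2nM",
               "2def\tGDP\tnot-a-measurement"), biolip)
  out <- read_affinity_table(biolip, dialect = "biolip")
  expect_length(out$records, 1L)
  expect_equal(out$records[[1]]$entry_id, "1ABC")
  expect_equal(out$records[[1]]$source, "biolip")
  expect_equal(nrow(out$quarantine), 1L)

  moad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("PDB_ID,Ligand,Affinity", "3ghi,HEM,Ki=10uM"), moad)
  out2 <- read_affinity_table(moad, dialect = "moad")
  expect_equal(out2$records[[1]]$measurement, "Ki")
  expect_equal(out2$records[[1]]$value_molar, 1e-5)

  merged <- merge_sources(c(out$records, out2$records))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_affinity_csv(merged, csv)
  back <- read.csv(csv, stringsAsFactors = FALSE)
  expect_setequal(back$entry_id, c("1ABC", "3GHI"))
  expect_true(all(c("value_molar", "delta_g_kj_mol", "qualifier") %in%
                    names(back)))
})
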
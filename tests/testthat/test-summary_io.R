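test_that("summary TSV read/write round-trips all fields exactly", {
  ds <- summary_dataset(data.frame(
    variant_id = c("rs10", "rs11"),
    chrom = c("10", "17"), pos = c(1234L, NA),
    effect_allele = c("A", "C"), other_allele = c("G", "T"),
    eaf = c(0.31731, NA),
    beta = c(0.123456789012345, -2.5e-3),
    se = c(0.01, 0.07),
    pvalue = c(NA, 0.9714),
    n = c(3225, NA), info = c(0.98, NA),
    stringsAsFactors = FALSE),
    trait_name = "testosterone", trait_scale = "log_transformed",
    sex_stratum = "men")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(ds, path)
  back <- read_summary_tsv(path, trait_scale = "log_transformed",
                           sex_stratum = "men", trait_name = "testosterone")
  expect_identical(as.data.frame(back), as.data.frame(ds))
  expect_identical(attr(back, "trait_scale"), "log_transformed")

  # a second round trip is still the identity
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_tsv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("mandatory columns and row-level validity are enforced", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\teffect_allele\tother_allele\tbeta",
               "rs1\tA\tG\t0.1"), path)
  expect_error(read_summary_tsv(path), "se")

  expect_error(summary_dataset(data.frame(
    variant_id = "rs1", effect_allele = "A", other_allele = "G",
    beta = 0.1, se = -0.01)), "rs1")
  expect_error(summary_dataset(data.frame(
    variant_id = "rs1", effect_allele = "A", other_allele = "A",
    beta = 0.1, se = 0.01)), "allele")
  expect_error(summary_dataset(data.frame(
    variant_id = c("rs1", "rs1"), effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01)), "duplicate")
})

test_that("p-values inconsistent with beta/se warn but do not error", {
  expect_warning(summary_dataset(data.frame(
    variant_id = "rs1", effect_allele = "A", other_allele = "G",
    beta = 0.5, se = 0.1, pvalue = 0.9)), "inconsistent")
  # rounded published p passes
  expect_silent(summary_dataset(data.frame(
    variant_id = "rs1", effect_allele = "A", other_allele = "G",
    beta = 0.5, se = 0.1, pvalue = signif(2 * pnorm(-5), 2))))
})

test_that("LD matrix reader validates shape, symmetry, diagonal and clips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\trs1\trs2",
               "ref_allele\tA\tC",
               "rs1\t1.0000001\t0.6",
               "rs2\t0.6\t1"), path)
  ld <- read_ld_matrix(path)
  expect_equal(unclass(ld)[1, 1], 1.0)  # clipped
  expect_equal(unclass(ld)[1, 2], 0.6)
  expect_identical(attr(ld, "ref_alleles"), c(rs1 = "A", rs2 = "C"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\trs1\trs2\trs3",
               "rs1\t1\t0\t0",
               "rs2\t0\t1\t0"), bad)
  expect_error(read_ld_matrix(bad), "square")

  asym <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\trs1\trs2",
               "rs1\t1\t0.5",
               "rs2\t0.2\t1"), asym)
  expect_error(read_ld_matrix(asym), "asymmetry")

  baddiag <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\trs1\trs2",
               "rs1\t0.9\t0.5",
               "rs2\t0.5\t1"), baddiag)
  expect_error(read_ld_matrix(baddiag), "diagonal")
})

test_that("LD matrix write/read round-trips", {
  cfg <- sim_config(n_variants = 5, ld_structure = "ar1", ld_rho = 0.5)
  ld <- make_ld_matrix(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  back <- read_ld_matrix(path)
  expect_equal(unclass(back), unclass(ld), ignore_attr = TRUE)
  expect_identical(unname(attr(back, "ref_alleles")),
                   unname(attr(ld, "ref_alleles")))
})

test_that("LD sign alignment flips rows and columns and is an involution", {
  r <- matrix(c(1, 0.6, 0.6, 1), 2)
  ld <- ld_matrix(r, c("rs1", "rs2"), ref_alleles = c("A", "C"),
                  other_alleles = c("G", "T"))
  flipped <- align_ld_to_effect_alleles(ld, c(rs1 = "A", rs2 = "T"))
  expect_equal(unclass(flipped)[1, 2], -0.6)
  expect_equal(diag(unclass(flipped)), c(rs1 = 1, rs2 = 1))
  # flip back: involution
  again <- align_ld_to_effect_alleles(flipped, c(rs1 = "A", rs2 = "C"))
  expect_equal(unclass(again), unclass(ld), ignore_attr = TRUE)
  # eigenvalues preserved under sign flips
  expect_equal(eigen(unclass(flipped), only.values = TRUE)$values,
               eigen(unclass(ld), only.values = TRUE)$values)
  # no flips needed: identity
  same <- align_ld_to_effect_alleles(ld, c(rs1 = "A", rs2 = "C"))
  expect_equal(unclass(same), unclass(ld), ignore_attr = TRUE)
  # allele matching neither -> error naming the variant
  expect_error(align_ld_to_effect_alleles(ld, c(rs1 = "A", rs2 = "A")), "rs2")
})

test_that("harmonize aligns swapped alleles, flips signs, and joins LD", {
  exposure <- toy_exposure()
  outcome <- summary_dataset(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = "10", pos = c(100L, 200L, 300L),
    effect_allele = c("G", "C", "G"),   # rs1 swapped relative to exposure
    other_allele = c("A", "T", "A"),
    eaf = c(0.7, 0.2, 0.4),
    beta = c(-0.05, 0.02, 0.01),
    se = c(0.02, 0.02, 0.02),
    pvalue = NA, n = NA, info = 1,
    stringsAsFactors = FALSE),
    trait_name = "cad", trait_scale = "log_odds")
  ld <- ld_matrix(diag(3), c("rs1", "rs2", "rs3"),
                  ref_alleles = c("A", "C", "G"),
                  other_alleles = c("G", "T", "A"))
  h <- harmonize(exposure, outcome, ld)
  expect_identical(h$variant_ids, c("rs1", "rs2", "rs3"))
  expect_equal(h$beta_outcome, c(0.05, 0.02, 0.01))  # rs1 sign flipped
  expect_equal(h$beta_exposure, exposure$beta)
  expect_identical(h$outcome_scale, "log_odds")

  # identical alleles on both sides: betas unchanged (idempotence)
  outcome2 <- summary_dataset(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.2, 0.4), beta = c(0.05, 0.02, 0.01), se = 0.02,
    stringsAsFactors = FALSE), trait_scale = "log_odds")
  h2 <- harmonize(exposure, outcome2, ld)
  expect_equal(h2$beta_outcome, c(0.05, 0.02, 0.01))
})

test_that("palindromic variants are dropped in the ambiguity band, oriented by frequency outside it", {
  exposure <- summary_dataset(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "A", "C"), other_allele = c("T", "T", "G"),
    eaf = c(0.50, 0.2, 0.3), beta = c(0.1, 0.1, 0.1), se = 0.01,
    stringsAsFactors = FALSE), trait_scale = "log_transformed")
  outcome <- summary_dataset(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "T", "C"), other_allele = c("T", "A", "G"),
    eaf = c(0.50, 0.8, 0.3), beta = c(0.1, 0.1, 0.1), se = 0.01,
    stringsAsFactors = FALSE), trait_scale = "log_odds")
  ld <- ld_matrix(diag(3), c("rs1", "rs2", "rs3"))
  msgs <- capture_messages(h <- harmonize(exposure, outcome, ld))
  expect_true(any(grepl("rs1", msgs)))          # eaf 0.5: dropped, logged
  expect_identical(h$variant_ids, c("rs2", "rs3"))
  expect_identical(h$log$reason[h$log$variant_id == "rs1"],
                   "palindromic_ambiguous")
  # rs2: swapped labels but frequencies on opposite sides of 0.5 -> flip
  expect_equal(h$beta_outcome, c(-0.1, 0.1))
})

test_that("harmonize errors on empty or fully dropped intersections", {
  exposure <- toy_exposure()
  other <- summary_dataset(data.frame(
    variant_id = "rs99", effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01, stringsAsFactors = FALSE))
  ld <- ld_matrix(diag(3), c("rs1", "rs2", "rs3"))
  expect_error(harmonize(exposure, other, ld), "no shared variants")

  mismatch <- summary_dataset(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "G"), other_allele = c("C", "A", "C"),
    beta = 0.1, se = 0.01, stringsAsFactors = FALSE))
  expect_error(suppressMessages(harmonize(exposure, mismatch, ld)),
               "all shared variants dropped")
})
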
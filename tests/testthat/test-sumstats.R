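test_that("write then read is the identity on valid summary statistics", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = c("1", "2", "X"),
                   BP = c(12345, 6789, 1e7), EA = c("A", "C", "T"),
                   OA = c("G", "T", "A"), EAF = c(0.31, 0.052, 0.499),
                   BETA = c(-0.0128, 0.214159, 0), SE = c(0.0061, 0.05, 0.02),
                   P = c(0.0359, 1.9e-5, 1), N = c(3757, 3757, 8299))
  x <- gwas_sumstats(df, "metab_1", "continuous", quiet = TRUE)
  expect_equal(nrow(x), 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  y <- read_sumstats(path, trait_id = "metab_1", quiet = TRUE)
  expect_equal(as.data.frame(y), as.data.frame(x), tolerance = 1e-12)
  # the file itself preserves sign and at least 6 significant digits
  lines <- readLines(path)
  expect_match(lines[2], "-0.0128")
  expect_match(lines[3], "0.214159")
})

test_that("empty record set writes a header-only file", {
  df <- data.frame(SNP = character(), CHR = character(), BP = numeric(),
                   EA = character(), OA = character(), EAF = numeric(),
                   BETA = numeric(), SE = numeric(), P = numeric(),
                   N = numeric())
  x <- gwas_sumstats(df, "empty", "continuous", quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  expect_length(readLines(path), 1L)
})

test_that("rows violating record invariants are dropped with a count", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   CHR = "1", BP = 1:5, EA = c("A", "A", "AT", "A", "A"),
                   OA = c("G", "G", "C", "A", "G"),
                   EAF = c(0.3, 0.3, 0.3, 0.3, 1.2),
                   BETA = 0.1, SE = c(0.02, 0, 0.02, 0.02, 0.02),
                   P = 0.5, N = 1000)
  expect_message(x <- gwas_sumstats(df, "t", "continuous"),
                 "dropped 4 invalid")
  expect_equal(x$SNP, "rs1")
  expect_equal(attr(x, "n_dropped"), 4L)
})

test_that("inconsistent p-values are flagged but kept", {
  df <- data.frame(SNP = c("rs1", "rs2"), CHR = "1", BP = 1:2, EA = "A",
                   OA = "G", EAF = 0.3, BETA = c(0.1, 0.1),
                   SE = c(0.02, 0.02), P = c(2 * pnorm(-5), 0.5), N = 1000)
  expect_message(x <- gwas_sumstats(df, "t", "continuous"),
                 "inconsistent with beta/se")
  expect_equal(nrow(x), 2L)
})

test_that("missing required columns and empty files are fatal", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tEA\tOA\tEAF\tBETA\tP\tN",
               "rs1\t1\t100\tA\tG\t0.3\t0.1\t0.5\t1000"), path)
  expect_error(read_sumstats(path, quiet = TRUE), "SE")
  writeLines(character(), path)
  expect_error(read_sumstats(path, quiet = TRUE), "empty")
})

test_that("gzip-compressed input and dialect mapping are honoured", {
  df <- data.frame(variant_id = "rs1", chromosome = "2",
                   base_pair_location = 500, effect_allele = "C",
                   other_allele = "T", effect_allele_frequency = 0.2,
                   beta = -0.04, standard_error = 0.01, p_value = 6.3e-5,
                   n = 8299)
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "wt")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  x <- read_sumstats(path, trait_id = "gz", dialect = gwas_catalog_dialect(),
                     quiet = TRUE)
  expect_equal(x$BETA, -0.04)
  expect_equal(x$SNP, "rs1")
})

test_that("harmonization aligns the outcome to the exposure effect allele", {
  ex <- make_ss(data.frame(EA = "A", OA = "G", BETA = 0.2), trait = "X")
  # swapped alleles: sign flip
  ou <- make_ss(data.frame(EA = "G", OA = "A", BETA = 0.1, EAF = 0.7), trait = "Y")
  h <- harmonize(ex, ou, quiet = TRUE)
  expect_equal(h$beta_y, -0.1)
  # identical coding: untouched
  ou2 <- make_ss(data.frame(EA = "A", OA = "G", BETA = 0.1), trait = "Y")
  expect_equal(harmonize(ex, ou2, quiet = TRUE)$beta_y, 0.1)
  # strand flip: complement alleles resolve to aligned, no sign change
  ou3 <- make_ss(data.frame(EA = "T", OA = "C", BETA = 0.1), trait = "Y")
  expect_equal(harmonize(ex, ou3, quiet = TRUE)$beta_y, 0.1)
  # strand flip + swap: complement then swapped, sign flips
  ou4 <- make_ss(data.frame(EA = "C", OA = "T", BETA = 0.1), trait = "Y")
  expect_equal(harmonize(ex, ou4, quiet = TRUE)$beta_y, -0.1)
  # incompatible allele sets are dropped
  ou5 <- make_ss(data.frame(EA = "C", OA = "G", BETA = 0.1), trait = "Y")
  expect_equal(nrow(harmonize(ex, ou5, quiet = TRUE)), 0L)
})

test_that("palindromic SNPs follow the configured policy", {
  ex <- make_ss(data.frame(EA = c("A", "A"), OA = c("T", "T"),
                           EAF = c(0.50, 0.10), BETA = 0.2), trait = "X")
  ou <- make_ss(data.frame(EA = c("A", "A"), OA = c("T", "T"),
                           EAF = c(0.50, 0.10), BETA = 0.1), trait = "Y")
  expect_equal(nrow(harmonize(ex, ou, "drop_ambiguous", quiet = TRUE)), 1L)
  expect_equal(nrow(harmonize(ex, ou, "drop_all", quiet = TRUE)), 0L)
  expect_equal(nrow(harmonize(ex, ou, "keep", quiet = TRUE)), 2L)
})

test_that("zero shared SNPs yields an empty set with a warning", {
  ex <- make_ss(data.frame(SNP = "rs1"), trait = "X")
  ou <- make_ss(data.frame(SNP = "rs999"), trait = "Y")
  expect_warning(h <- harmonize(ex, ou, quiet = TRUE), "no shared SNPs")
  expect_equal(nrow(h), 0L)
})

test_that("relabelling outcome alleles with negated betas leaves harmonization invariant", {
  withr::with_seed(42, {
    n <- 20
    ex <- make_ss(data.frame(EA = sample(c("A", "C"), n, TRUE),
                             BETA = rnorm(n, 0, 0.1)), trait = "X")
    ou_df <- data.frame(EA = ex$EA, OA = ex$OA, BETA = rnorm(n, 0, 0.1),
                        EAF = runif(n, 0.1, 0.9))
    ou <- make_ss(ou_df, trait = "Y")
    flipped <- ou_df
    flipped$EA <- ou_df$OA
    flipped$OA <- ou_df$EA
    flipped$BETA <- -ou_df$BETA
    flipped$EAF <- 1 - ou_df$EAF
    ou_flip <- make_ss(flipped, trait = "Y")
    h1 <- harmonize(ex, ou, quiet = TRUE)
    h2 <- harmonize(ex, ou_flip, quiet = TRUE)
    expect_equal(h1$beta_y, h2$beta_y)
    expect_equal(h1$SNP, h2$SNP)
  })
})
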
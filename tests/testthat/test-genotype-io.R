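# PLINK 1 binary round trips, two-bit decoding, QC filtering and
# population-scaled standardization.

test_that("bed/bim/fam round trip reproduces dosages exactly, including missing", {
  set.seed(42)
  n <- 17; m <- 9                       # n not divisible by 4 exercises padding
  G <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), n, m)
  prefix <- file.path(tempdir(), "rt")
  write_plink(G, prefix)
  src <- read_plink(prefix)
  expect_equal(gs_nsamples(src), n)
  expect_equal(gs_nsnps(src), m)
  expect_identical(gs_materialize(src), unname(G) * 1.0)
  # repeated iteration yields identical blocks
  expect_identical(gs_fetch(src, 3:5), gs_fetch(src, 3:5))
})

test_that("two-bit codes decode per the PLINK 1 layout (hand-built byte)", {
  # codes packed low bits first: samples (2,1,NA,0) -> 00 10 01 11 -> 0xD8
  prefix <- file.path(tempdir(), "byte")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xD8)), con)
  close(con)
  writeLines("1\trs1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeLines(sprintf("F%d\tI%d\t0\t0\t0\t-9", 1:4, 1:4),
             paste0(prefix, ".fam"))
  src <- read_plink(prefix)
  expect_equal(drop(gs_fetch(src, 1)), c(2, 1, NA, 0))
})

test_that("malformed bed files are rejected", {
  prefix <- file.path(tempdir(), "bad")
  writeLines("1\trs1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeLines(sprintf("F%d\tI%d\t0\t0\t0\t-9", 1:4, 1:4),
             paste0(prefix, ".fam"))
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0xD8)), con); close(con)
  expect_error(read_plink(prefix), "magic")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xD8, 0xD8)), con); close(con)
  expect_error(read_plink(prefix), "dimensions")
})

test_that("sources stream in bim-order blocks of the requested size", {
  G <- matrix(rbinom(10 * 5, 2, 0.3), 10, 5)
  src <- matrix_source(G, block_size = 2L)
  blocks <- gs_blocks(src)
  expect_equal(lengths(blocks), c(2L, 2L, 1L))
  expect_equal(unlist(blocks), 1:5)
  reassembled <- do.call(cbind, lapply(blocks, gs_fetch, src = src))
  expect_equal(reassembled, G * 1.0)
})

test_that("QC filters by first-failing rule in fixed order and counts exactly", {
  set.seed(7)
  n <- 200
  G <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
  G[1:10, 2] <- NA                      # 5% missing -> fails missingness
  G[, 3] <- rbinom(n, 2, 0.004)         # maf ~ 0.004 -> fails MAF
  G[, 4] <- 0L                          # monomorphic -> fails MAF
  G[, 5] <- rep(c(0L, 2L), n / 2)       # no hets at f=0.5 -> fails HWE hard
  meta <- data.frame(snp_id = paste0("s", 1:6),
                     chr = c("1", "1", "1", "1", "1", "6"),
                     pos = c(1e5, 2e5, 3e5, 4e5, 5e5, 30e6),
                     a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  qc <- apply_qc(matrix_source(G, meta))
  expect_equal(qc$report$n_fail_missing, 1L)
  expect_equal(qc$report$n_fail_maf, 2L)
  expect_equal(qc$report$n_fail_hwe, 1L)
  expect_equal(qc$report$n_fail_region, 1L)  # SNP 6 in MHC
  expect_equal(qc$report$n_pass_snps, 1L)
  expect_equal(with(qc$report, n_pass_snps + n_fail_missing + n_fail_maf +
                      n_fail_hwe + n_fail_region), qc$report$n_input_snps)
  expect_equal(gs_meta(qc$source)$snp_id, "s1")
  expect_error(apply_qc(matrix_source(matrix(0L, 50, 2))), "empty panel")
})

test_that("HWE chi-square matches the hand calculation", {
  # counts (30, 40, 30) at N = 100: p = 0.5, expected (25, 50, 25),
  # chi2 = 25/25 + 100/50 + 25/25 = 4
  expect_equal(hwe_test(30, 40, 30), pchisq(4, 1, lower.tail = FALSE))
  expect_equal(hwe_test(50, 0, 0), 1)   # monomorphic: no information
})

test_that("standardization is population-scaled, mean-imputed and idempotent", {
  # hand example: [0,1,2,1], mean 1, sum of centered squares 2, scale
  # sqrt(2/4), standardized (-sqrt 2, 0, sqrt 2, 0)
  z <- standardize_block(matrix(c(0, 1, 2, 1), 4, 1))
  expect_equal(drop(z), c(-sqrt(2), 0, sqrt(2), 0))
  expect_equal(sum(z^2), 4)
  expect_equal(standardize_block(z), z, tolerance = 1e-12)
  # missing entries imputed to the column mean (4/3) before centering
  z2 <- standardize_block(matrix(c(0, 2, NA, 2), 4, 1))
  x <- c(0, 2, 4 / 3, 2); x <- x - mean(x)
  expect_equal(drop(z2), x / sqrt(sum(x^2) / 4))
  expect_error(standardize_block(matrix(1, 4, 1)), "zero-variance")
})

test_that("tr(XX'/M) equals N for any standardized panel", {
  for (seed in 1:3) {
    X <- std_panel(50, 30, seed = seed)
    expect_equal(sum(X^2) / ncol(X), 50, tolerance = 1e-6)
  }
  # and through the source interface with missing data present
  set.seed(11)
  G <- matrix(sample(c(0:2, NA), 40 * 12, TRUE, c(.4, .3, .29, .01)), 40, 12)
  G[1, colSums(!is.na(G) & G > 0) == 0] <- 1   # guard monomorphic columns
  src <- standardize_source(matrix_source(G))
  X <- gs_materialize(src)
  expect_equal(sum(X^2) / ncol(X), 40, tolerance = 1e-6)
  expect_true(max(abs(colMeans(X))) < 1e-8)
})

test_that("QC result does not depend on block boundaries", {
  set.seed(3)
  G <- matrix(rbinom(100 * 30, 2, runif(30, 0.002, 0.5)[col(matrix(0, 100, 30))]), 100, 30)
  for (bs in c(4L, 7L, 30L)) {
    src <- matrix_source(G, block_size = bs)
    expect_equal(gs_meta(apply_qc(src)$source)$snp_id,
                 gs_meta(apply_qc(matrix_source(G))$source)$snp_id)
  }
})
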
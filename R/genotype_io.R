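# PLINK 1 binary input, QC filtering and standardization, exposed as a
# streaming "genotype_source" so downstream passes never need all of X in
# memory at once.

# two-bit genotype codes -> dosage of allele A1 (00 hom A1 = 2, 01 missing,
# 10 het = 1, 11 hom A2 = 0), expanded per byte (4 samples, low bits first)
.plink_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      m <- matrix(NA_real_, 256L, 4L)
      for (byte in 0:255) {
        for (j in 0:3) {
          code <- bitwAnd(bitwShiftR(byte, 2L * j), 3L)
          m[byte + 1L, j + 1L] <- switch(code + 1L, 2, NA_real_, 1, 0)
        }
      }
      lut <<- m
    }
    lut
  }
})

new_genotype_source <- function(fetch_raw, n, meta, block_size = 1024L,
                                subclass = character()) {
  stopifnot(is.function(fetch_raw), nrow(meta) >= 1L)
  structure(
    list(fetch_raw = fetch_raw, n = as.integer(n), meta = meta,
         block_size = as.integer(block_size), center = NULL, scale = NULL),
    class = c(subclass, "genotype_source"))
}

#' Number of samples / SNPs in a genotype source
#' @param src a `genotype_source`
#' @return integer
#' @export
gs_nsamples <- function(src) src$n

#' @rdname gs_nsamples
#' @export
gs_nsnps <- function(src) nrow(src$meta)

#' Per-SNP metadata of a genotype source
#'
#' @param src a `genotype_source`
#' @return data.frame with columns `snp_id`, `chr`, `pos`, `a1`, `a2` and,
#'   after [apply_qc()], the QC statistics `maf`, `missing_rate`, `hwe_p`.
#' @export
gs_meta <- function(src) src$meta

#' Fetch a block of genotype columns
#'
#' Returns raw hard-call dosages (0/1/2 copies of allele A1, `NA` for missing)
#' or, if the source has been passed through [standardize_source()],
#' mean-imputed standardized dosages with each column scaled so its sum of
#' squares equals the sample size N.
#'
#' @param src a `genotype_source`
#' @param cols integer indices of SNP columns to fetch (in `gs_meta()` order)
#' @return an N x length(cols) numeric matrix
#' @export
gs_fetch <- function(src, cols) {
  cols <- as.integer(cols)
  if (length(cols) && (min(cols) < 1L || max(cols) > gs_nsnps(src)))
    stop("SNP index out of range")
  g <- src$fetch_raw(cols)
  if (!is.null(src$center)) {
    mu <- src$center[cols]
    sc <- src$scale[cols]
    # mean imputation: missing entries become 0 after centering
    for (k in seq_along(cols)) {
      x <- g[, k]
      x[is.na(x)] <- mu[k]
      g[, k] <- (x - mu[k]) / sc[k]
    }
  }
  g
}

#' Partition the SNP columns of a source into streaming blocks
#' @param src a `genotype_source`
#' @param block_size maximum SNPs per block (defaults to the source's own)
#' @return list of integer index vectors covering `1:gs_nsnps(src)` in order
#' @export
gs_blocks <- function(src, block_size = src$block_size) {
  m <- gs_nsnps(src)
  if (m == 0L) return(list())
  starts <- seq(1L, m, by = block_size)
  lapply(starts, function(s) s:min(s + block_size - 1L, m))
}

#' Materialize a genotype source as a dense matrix
#' @inheritParams gs_fetch
#' @export
gs_materialize <- function(src, cols = seq_len(gs_nsnps(src))) {
  gs_fetch(src, cols)
}

#' Restrict a genotype source to a subset of SNP columns
#'
#' The returned source streams from the parent; metadata and any
#' standardization parameters are subset accordingly.
#'
#' @param src a `genotype_source`
#' @param cols integer indices to keep, in the order given
#' @return a `genotype_source`
#' @export
subset_source <- function(src, cols) {
  cols <- as.integer(cols)
  if (length(cols) == 0L) stop("cannot subset a genotype source to zero SNPs")
  parent <- src
  out <- new_genotype_source(
    fetch_raw = function(j) parent$fetch_raw(cols[j]),
    n = parent$n, meta = parent$meta[cols, , drop = FALSE],
    block_size = parent$block_size)
  if (!is.null(parent$center)) {
    out$center <- parent$center[cols]
    out$scale <- parent$scale[cols]
  }
  out$standardized <- parent$standardized
  out$sample_ids <- parent$sample_ids
  rownames(out$meta) <- NULL
  out
}

#' @export
print.genotype_source <- function(x, ...) {
  cat(sprintf("<genotype_source> %d samples x %d SNPs (%s)\n",
              gs_nsamples(x), gs_nsnps(x),
              if (is.null(x$center)) "raw dosages" else "standardized"))
  invisible(x)
}

#' Open PLINK 1 binary genotypes as a streaming source
#'
#' Reads the `.bim`/`.fam` sidecars eagerly and decodes the SNP-major `.bed`
#' payload lazily in column blocks, so memory use is independent of the
#' number of SNPs.
#'
#' @param prefix path prefix of the fileset (`prefix.bed` etc.), or the
#'   `.bed` path itself
#' @param block_size SNPs per streamed block
#' @return a `genotype_source` of raw dosages (copies of bim allele 1)
#' @export
read_plink <- function(prefix, block_size = 1024L) {
  prefix <- sub("\\.bed$", "", prefix)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bimdf <- utils::read.table(bim, header = FALSE, colClasses = "character")
  if (ncol(bimdf) != 6L) stop("bim must have 6 columns")
  meta <- data.frame(snp_id = bimdf[[2L]], chr = bimdf[[1L]],
                     pos = as.integer(bimdf[[4L]]),
                     a1 = bimdf[[5L]], a2 = bimdf[[6L]],
                     stringsAsFactors = FALSE)
  famdf <- utils::read.table(fam, header = FALSE, colClasses = "character")
  n <- nrow(famdf)
  sample_ids <- famdf[[2L]]
  m <- nrow(meta)
  hdr <- readBin(bed, "raw", n = 3L)
  if (length(hdr) < 3L || hdr[1L] != as.raw(0x6c) || hdr[2L] != as.raw(0x1b))
    stop("not a PLINK 1 bed file (bad magic bytes): ", bed)
  if (hdr[3L] != as.raw(0x01))
    stop("only SNP-major bed files are supported")
  bps <- ceiling(n / 4)
  expect_size <- 3 + bps * m
  if (file.info(bed)$size != expect_size)
    stop(sprintf(
      "bed payload (%d bytes) does not match fam/bim dimensions (expected %d)",
      file.info(bed)$size, expect_size))
  fetch_raw <- function(cols) {
    out <- matrix(NA_real_, n, length(cols))
    if (length(cols) == 0L) return(out)
    con <- file(bed, "rb")
    on.exit(close(con))
    lut <- .plink_lut()
    # group contiguous runs so sequential blocks are a single seek+read
    runs <- split(cols, cumsum(c(1L, diff(cols) != 1L)))
    at <- 1L
    for (run in runs) {
      seek(con, where = 3 + (run[1L] - 1) * bps)
      bytes <- readBin(con, "raw", n = bps * length(run))
      v <- lut[as.integer(bytes) + 1L, , drop = FALSE]
      g <- matrix(t(v), nrow = 4L * bps)[seq_len(n), , drop = FALSE]
      out[, at:(at + length(run) - 1L)] <- g
      at <- at + length(run)
    }
    out
  }
  out <- new_genotype_source(fetch_raw, n, meta, block_size,
                             subclass = "bed_source")
  out$sample_ids <- sample_ids
  out
}

#' Sample identifiers of a genotype source
#' @param src a `genotype_source`
#' @export
gs_sample_ids <- function(src) {
  if (is.null(src$sample_ids)) paste0("I", seq_len(gs_nsamples(src)))
  else src$sample_ids
}

#' Wrap an in-memory dosage matrix as a genotype source
#' @param dosage N x M matrix of 0/1/2 dosages (NA = missing)
#' @param meta per-SNP metadata (defaults to one pseudo-chromosome)
#' @param block_size SNPs per streamed block
#' @export
matrix_source <- function(dosage, meta = NULL, block_size = 1024L) {
  dosage <- as.matrix(dosage)
  if (is.null(meta)) {
    meta <- data.frame(
      snp_id = sprintf("snp%05d", seq_len(ncol(dosage))), chr = "1",
      pos = seq_len(ncol(dosage)) * 10000L, a1 = "A", a2 = "B",
      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(meta) == ncol(dosage))
  new_genotype_source(function(cols) dosage[, cols, drop = FALSE],
                      nrow(dosage), meta, block_size,
                      subclass = "matrix_source")
}

#' Write genotypes to a PLINK 1 bed/bim/fam fileset
#'
#' @param dosage N x M matrix of hard-call dosages (copies of allele 1;
#'   NA = missing), or a raw `genotype_source`
#' @param prefix output path prefix
#' @param meta optional per-SNP metadata (taken from the source if given one)
#' @return the prefix, invisibly
#' @export
write_plink <- function(dosage, prefix, meta = NULL) {
  if (inherits(dosage, "genotype_source")) {
    if (!is.null(dosage$center) || isTRUE(dosage$standardized))
      stop("write_plink needs raw hard-call dosages, not standardized values")
    meta <- gs_meta(dosage)
    dosage <- gs_materialize(dosage)
  }
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(meta)) meta <- gs_meta(matrix_source(dosage))
  bps <- ceiling(n / 4)
  # dosage -> two-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  codes <- matrix(3L, bps * 4L, m)
  d <- dosage
  code <- ifelse(is.na(d), 1L, ifelse(d == 2, 0L, ifelse(d == 1, 2L, 3L)))
  codes[seq_len(n), ] <- code
  shift <- rep(c(0L, 2L, 4L, 6L), bps)
  byte_id <- rep(seq_len(bps), each = 4L)
  packed <- vapply(seq_len(m), function(j) {
    as.raw(tapply(bitwShiftL(codes[, j], shift), byte_id, function(v)
      Reduce(bitwOr, v)))
  }, raw(bps))
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.vector(packed), con)
  close(con)
  utils::write.table(
    data.frame(meta$chr, meta$snp_id, 0, meta$pos, meta$a1, meta$a2),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(paste0("F", seq_len(n)), paste0("I", seq_len(n)),
               0, 0, 0, -9),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Hardy-Weinberg equilibrium chi-square test (1 df)
#'
#' Compares observed genotype counts against the counts expected from the
#' in-sample allele frequency, without continuity correction. Monomorphic
#' SNPs return p = 1 (they carry no HWE information and are removed by the
#' MAF filter anyway).
#'
#' @param n_hom1,n_het,n_hom2 genotype counts
#' @return vector of p-values
#' @export
hwe_test <- function(n_hom1, n_het, n_hom2) {
  nobs <- n_hom1 + n_het + n_hom2
  p <- (2 * n_hom1 + n_het) / (2 * pmax(nobs, 1L))
  q <- 1 - p
  e1 <- nobs * p^2; eh <- nobs * 2 * p * q; e2 <- nobs * q^2
  stat <- ifelse(eh == 0, 0,
                 (n_hom1 - e1)^2 / pmax(e1, .Machine$double.eps) +
                 (n_het - eh)^2 / pmax(eh, .Machine$double.eps) +
                 (n_hom2 - e2)^2 / pmax(e2, .Machine$double.eps))
  ifelse(nobs == 0 | eh == 0, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-SNP summary statistics
#'
#' Single streaming pass computing allele-1 frequency, folded minor allele
#' frequency, missingness and the HWE p-value for every SNP.
#'
#' @param src a raw (un-standardized) `genotype_source`
#' @return data.frame with `freq_a1`, `maf`, `missing_rate`, `hwe_p`
#' @export
snp_stats <- function(src) {
  n <- gs_nsamples(src)
  res <- lapply(gs_blocks(src), function(cols) {
    g <- src$fetch_raw(cols)
    nmiss <- colSums(is.na(g))
    n2 <- colSums(g == 2, na.rm = TRUE)
    n1 <- colSums(g == 1, na.rm = TRUE)
    n0 <- colSums(g == 0, na.rm = TRUE)
    nobs <- n - nmiss
    f <- ifelse(nobs > 0, (2 * n2 + n1) / (2 * pmax(nobs, 1L)), NA_real_)
    data.frame(freq_a1 = f, maf = pmin(f, 1 - f),
               missing_rate = nmiss / n,
               hwe_p = hwe_test(n2, n1, n0))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' QC thresholds for SNP filtering
#'
#' Defaults follow common biobank practice: at most 1% missing calls, minor
#' allele frequency at least 1%, HWE exact threshold 1e-7, and exclusion of
#' the MHC region (chr6:25-35 Mb, 1-based inclusive).
#'
#' @param max_missing maximum per-SNP missing-call fraction
#' @param min_maf minimum folded minor allele frequency
#' @param hwe_alpha HWE chi-square p-value threshold
#' @param exclude_regions data.frame(chr, start, end) of 1-based inclusive
#'   intervals to drop, or NULL
#' @export
qc_thresholds <- function(max_missing = 0.01, min_maf = 0.01,
                          hwe_alpha = 1e-7,
                          exclude_regions = data.frame(
                            chr = "6", start = 25e6, end = 35e6)) {
  stopifnot(max_missing > 0, max_missing < 1, min_maf > 0, min_maf < 1,
            hwe_alpha > 0, hwe_alpha < 1)
  if (!is.null(exclude_regions))
    stopifnot(all(exclude_regions$start < exclude_regions$end))
  structure(list(max_missing = max_missing, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, exclude_regions = exclude_regions),
            class = "qc_thresholds")
}

.chr_norm <- function(chr) sub("^chr", "", tolower(as.character(chr)))

.in_regions <- function(chr, pos, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(rep(FALSE, length(chr)))
  chr <- .chr_norm(chr)
  hit <- rep(FALSE, length(chr))
  for (r in seq_len(nrow(regions))) {
    hit <- hit | (chr == .chr_norm(regions$chr[r]) &
                  pos >= regions$start[r] & pos <= regions$end[r])
  }
  hit
}

#' Apply SNP-level quality control
#'
#' Filters follow a fixed first-failing order -- missingness, then MAF, then
#' HWE, then region exclusion -- so the counts in the report are reproducible.
#'
#' @param src a raw `genotype_source`
#' @param thresholds a [qc_thresholds()] object
#' @return list with `source` (the filtered source, with QC statistics merged
#'   into its metadata) and `report` (pass/fail counts by first-failing rule)
#' @export
apply_qc <- function(src, thresholds = qc_thresholds()) {
  if (!is.null(src$center) || isTRUE(src$standardized))
    stop("apply QC before standardization")
  st <- snp_stats(src)
  meta <- gs_meta(src)
  fail_missing <- st$missing_rate > thresholds$max_missing
  fail_maf <- !fail_missing & (is.na(st$maf) | st$maf < thresholds$min_maf)
  fail_hwe <- !fail_missing & !fail_maf & st$hwe_p < thresholds$hwe_alpha
  fail_region <- !fail_missing & !fail_maf & !fail_hwe &
    .in_regions(meta$chr, meta$pos, thresholds$exclude_regions)
  keep <- !(fail_missing | fail_maf | fail_hwe | fail_region)
  report <- list(n_input_snps = nrow(meta), n_pass_snps = sum(keep),
                 n_fail_missing = sum(fail_missing),
                 n_fail_maf = sum(fail_maf), n_fail_hwe = sum(fail_hwe),
                 n_fail_region = sum(fail_region))
  if (!any(keep)) stop("QC removed every SNP: empty panel")
  out <- subset_source(src, which(keep))
  out$meta <- cbind(out$meta, st[keep, , drop = FALSE])
  rownames(out$meta) <- NULL
  list(source = out, report = report)
}

#' Standardize a genotype source (population scaling)
#'
#' Computes per-SNP means on non-missing calls and scales so each column of
#' the imputed, centered matrix has sum of squares exactly N. Under this
#' scaling tr(XX'/M) = N, which downstream trace identities rely on.
#'
#' @param src a raw `genotype_source` (QC already applied)
#' @return a `genotype_source` whose [gs_fetch()] yields standardized columns
#' @export
standardize_source <- function(src) {
  if (!is.null(src$center) || isTRUE(src$standardized)) return(src)
  n <- gs_nsamples(src)
  acc <- lapply(gs_blocks(src), function(cols) {
    g <- src$fetch_raw(cols)
    mu <- colMeans(g, na.rm = TRUE)
    ss <- colSums(sweep(g, 2L, mu)^2, na.rm = TRUE)
    cbind(mu, sqrt(ss / n))
  })
  acc <- do.call(rbind, acc)
  if (any(acc[, 2L] == 0))
    stop("zero-variance SNP column; remove monomorphic SNPs with apply_qc()")
  out <- src
  out$center <- acc[, 1L]
  out$scale <- acc[, 2L]
  # matrix-backed panels that fit comfortably in memory are standardized
  # once up front, so repeated fits over the same panel only slice
  if (inherits(src, "matrix_source") && n * gs_nsnps(src) <= 5e7) {
    X <- gs_fetch(out, seq_len(gs_nsnps(out)))
    cached <- new_genotype_source(function(cols) X[, cols, drop = FALSE],
                                  n, out$meta, out$block_size,
                                  subclass = "matrix_source")
    cached$standardized <- TRUE
    cached$sample_ids <- src$sample_ids
    cached$ld_blocks <- src$ld_blocks
    return(cached)
  }
  out
}

#' Standardize a single dosage block
#'
#' Missing values are mean-imputed per column, then each column is centered
#' and rescaled so its sum of squares equals the number of samples.
#'
#' @param block N x b dosage matrix (NA = missing)
#' @return standardized numeric matrix
#' @export
standardize_block <- function(block) {
  block <- as.matrix(block)
  n <- nrow(block)
  out <- block
  for (k in seq_len(ncol(block))) {
    x <- block[, k]
    mu <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- mu
    x <- x - mean(x)
    s <- sqrt(sum(x^2) / n)
    if (s == 0) stop("zero-variance column in standardize_block")
    out[, k] <- x / s
  }
  out
}
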
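# Phenotype preparation: inverse rank-normal transform, covariate
# residualization, and LD-block handling around the target SNP.

#' Inverse rank-normal transform
#'
#' Maps trait values to normal quantiles of their ranks using Blom offsets,
#' `qnorm((rank - 3/8) / (N + 1/4))`. The transform is invariant to any
#' strictly monotone rescaling of the input, which makes downstream tests
#' insensitive to the phenotype's measurement scale. Ties receive average
#' ranks; if more than 20% of values are tied a warning is raised.
#'
#' @param y numeric vector without missing values
#' @return transformed vector with the same names/order
#' @export
inverse_rank_normalize <- function(y) {
  if (anyNA(y)) stop("missing phenotype values; drop those samples upstream")
  n <- length(y)
  if (length(unique(y)) == 1L)
    stop("constant phenotype: no rank information to normalize")
  if ((n - length(unique(y))) / n > 0.2)
    warning("more than 20% tied phenotype values; using average ranks")
  r <- rank(y, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Build a covariate matrix with an intercept
#'
#' @param ... named numeric vectors or a single data.frame/matrix
#' @param n number of samples (required when no covariates are given)
#' @return numeric matrix whose first column is the intercept
#' @export
covariate_matrix <- function(..., n = NULL) {
  args <- list(...)
  if (length(args) == 1L && (is.data.frame(args[[1L]]) || is.matrix(args[[1L]])))
    W <- as.matrix(args[[1L]])
  else if (length(args)) W <- do.call(cbind, args)
  else W <- NULL
  if (is.null(W)) {
    if (is.null(n)) stop("give covariates or a sample count")
    return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  }
  cbind(intercept = 1, W)
}

# least-squares residual with rank handling; shared by the covariate and
# LD-block projections
.ols_residual <- function(y, X, warn_label) {
  if (is.null(X) || ncol(X) == 0L) return(y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    warning(sprintf("%s: %d collinear column(s) dropped", warn_label,
                    ncol(X) - qrX$rank))
  as.vector(qr.resid(qrX, y))
}

#' Residualize a phenotype on fixed-effect covariates
#'
#' Returns `y - W (W'W)^-1 W'y`. An intercept column is appended if absent,
#' so the residual is always centered. Collinear covariate columns are
#' dropped with a warning.
#'
#' @param y numeric phenotype vector
#' @param W covariate matrix (rows = samples) or NULL for intercept only
#' @return residual vector, orthogonal to every covariate column
#' @export
residualize_covariates <- function(y, W = NULL) {
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  if (nrow(W) != n) stop("covariate rows do not match phenotype length")
  if (!any(apply(W, 2L, function(c) all(c == c[1L] & c[1L] != 0))))
    W <- cbind(1, W)
  .ols_residual(y, W, "residualize_covariates")
}

#' Read LD block definitions from a BED3 file
#'
#' Input is 0-based half-open (UCSC BED); intervals are converted to 1-based
#' inclusive coordinates internally.
#'
#' @param path BED3 file (chrom, chromStart, chromEnd)
#' @return data.frame(chr, start, end), 1-based inclusive
#' @export
read_ld_blocks <- function(path) {
  b <- utils::read.table(path, header = FALSE,
                         colClasses = c("character", "numeric", "numeric"))
  out <- data.frame(chr = .chr_norm(b[[1L]]), start = b[[2L]] + 1,
                    end = b[[3L]], stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("malformed LD block interval")
  out
}

#' SNPs in the LD block containing a target SNP
#'
#' Returns the indices of all panel SNPs (the target included) that fall in
#' the LD block containing the target. Without a block map, a +/- `fallback_bp`
#' window around the target is used instead.
#'
#' @param target_index index of the target SNP in `panel_meta`
#' @param panel_meta per-SNP metadata (columns `chr`, `pos`)
#' @param blocks data.frame(chr, start, end) of 1-based inclusive LD blocks,
#'   or NULL to use the window fallback
#' @param fallback_bp half-width of the fallback window in base pairs
#' @return integer vector of panel indices, always containing `target_index`
#' @export
ld_block_for_target <- function(target_index, panel_meta, blocks = NULL,
                                fallback_bp = 1e6) {
  tchr <- .chr_norm(panel_meta$chr[target_index])
  tpos <- panel_meta$pos[target_index]
  if (!is.null(blocks)) {
    bl <- blocks[.chr_norm(blocks$chr) == tchr &
                 blocks$start <= tpos & blocks$end >= tpos, , drop = FALSE]
    if (nrow(bl) == 0L) {
      if (is.null(fallback_bp))
        stop("target SNP not covered by any LD block and fallback disabled")
      lo <- tpos - fallback_bp; hi <- tpos + fallback_bp
    } else {
      lo <- bl$start[1L]; hi <- bl$end[1L]
    }
  } else {
    if (is.null(fallback_bp)) stop("no LD blocks given and fallback disabled")
    lo <- tpos - fallback_bp; hi <- tpos + fallback_bp
  }
  idx <- which(.chr_norm(panel_meta$chr) == tchr &
               panel_meta$pos >= lo & panel_meta$pos <= hi)
  sort(unique(c(idx, target_index)))
}

#' Regress the additive effects of an LD block out of a phenotype
#'
#' Joint OLS residual of the (already covariate-residualized) phenotype on
#' all standardized SNPs of the block, with an intercept. Used before the
#' marginal-epistasis fit when targets were selected from a GWAS, where
#' additive signal in the target's LD block would otherwise inflate the test.
#'
#' @param y numeric phenotype vector
#' @param block_genotypes N x b matrix of standardized block SNPs (possibly
#'   zero columns, in which case `y` is returned unchanged)
#' @return residual vector orthogonal to every block SNP
#' @export
regress_out_ld_block <- function(y, block_genotypes) {
  if (is.null(block_genotypes) || ncol(as.matrix(block_genotypes)) == 0L)
    return(y)
  X <- cbind(1, as.matrix(block_genotypes))
  if (ncol(X) - 1L >= length(y))
    stop("LD block has as many SNPs as samples; cannot regress out")
  .ols_residual(y, X, "regress_out_ld_block")
}
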
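# GWAS target selection, LD pruning, exhaustive pairwise interaction tests
# and genomic-inflation diagnostics.

#' Genome-wide association scan
#'
#' Per-SNP simple regression of the (already normalized and
#' covariate-residualized) phenotype on each standardized genotype column.
#' Residualizing the phenotype once instead of refitting covariates per SNP
#' is the phenotype-side Frisch-Waugh approximation; an exact per-SNP
#' multiple regression is available with `exact = TRUE`.
#'
#' @param genotypes a `genotype_source` (standardized internally)
#' @param y phenotype vector (inverse rank normalized and residualized
#'   upstream, or pass `covariates` with `exact = TRUE`)
#' @param threshold genome-wide significance threshold (default 5e-8)
#' @param covariates covariate matrix used only when `exact = TRUE`
#' @param exact refit covariates jointly with each SNP
#' @return data.frame(snp_id, chr, pos, beta, se, p, significant), beta on
#'   the standardized-genotype scale
#' @export
gwas_scan <- function(genotypes, y, threshold = 5e-8, covariates = NULL,
                      exact = FALSE) {
  src <- standardize_source(genotypes)
  n <- gs_nsamples(src)
  if (length(y) != n) stop("phenotype length does not match sample count")
  meta <- gs_meta(src)
  if (exact) {
    W <- covariate_matrix(covariates, n = n)
    res <- lapply(seq_len(gs_nsnps(src)), function(j) {
      fit <- stats::lm.fit(cbind(gs_fetch(src, j), W), y)
      co <- fit$coefficients[1L]
      dfres <- n - fit$rank
      rss <- sum(fit$residuals^2)
      R <- chol2inv(qr.R(fit$qr))
      se <- sqrt(R[1L, 1L] * rss / dfres)
      c(co, se, 2 * stats::pt(-abs(co / se), dfres))
    })
    out <- do.call(rbind, res)
    beta <- out[, 1L]; se <- out[, 2L]; p <- out[, 3L]
  } else {
    y <- y - mean(y)
    syy <- sum(y^2)
    stats_ <- lapply(gs_blocks(src), function(cols) {
      Z <- gs_fetch(src, cols)
      b <- drop(crossprod(Z, y)) / n    # slope: sum(x*y)/sum(x^2), sum x^2 = n
      rss <- pmax(syy - n * b^2, 0)
      se <- sqrt(rss / (n - 2) / n)
      cbind(b, se)
    })
    st <- do.call(rbind, stats_)
    beta <- st[, 1L]; se <- st[, 2L]
    p <- 2 * stats::pt(-abs(beta / se), n - 2)
  }
  data.frame(snp_id = meta$snp_id, chr = meta$chr, pos = meta$pos,
             beta = beta, se = se, p = p, significant = p < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' LD-prune a set of SNPs
#'
#' Greedy pass in genomic-position order over the candidate list: within a
#' sliding window of `window` candidate SNPs, whenever a pair has squared
#' Pearson correlation above `r2_threshold` the SNP appearing later in
#' position order is removed; the window then advances one SNP. Deterministic.
#'
#' @param candidates integer indices into the source's panel, e.g. the
#'   significant SNPs of a [gwas_scan()]
#' @param genotypes the `genotype_source` the indices refer to
#' @param r2_threshold squared-correlation cutoff (default 0.1)
#' @param window window size in SNPs (default 500)
#' @return the surviving subset of `candidates`, in position order
#' @export
ld_prune <- function(candidates, genotypes, r2_threshold = 0.1,
                     window = 500L) {
  if (length(candidates) <= 1L) return(candidates)
  src <- standardize_source(genotypes)
  meta <- gs_meta(src)
  ord <- order(.chr_norm(meta$chr[candidates]), meta$pos[candidates])
  cand <- candidates[ord]
  G <- gs_fetch(src, cand)              # N x k standardized candidates
  n <- nrow(G)
  # window positions run over the surviving list; at each position every
  # pair in the window is examined and the later-position member of the
  # first offending pair is removed, until the window is clean
  keep <- seq_len(length(cand))
  i <- 1L
  while (i <= length(keep)) {
    repeat {
      win <- keep[i:min(length(keep), i + window - 1L)]
      if (length(win) < 2L) break
      R2 <- (crossprod(G[, win, drop = FALSE]) / n)^2
      R2[lower.tri(R2, diag = TRUE)] <- 0
      bad <- which(R2 > r2_threshold, arr.ind = TRUE)
      if (nrow(bad) == 0L) break
      first <- bad[order(bad[, 1L], bad[, 2L])[1L], ]
      keep <- setdiff(keep, win[first[2L]])
    }
    i <- i + 1L
  }
  cand[keep]
}

#' Pairwise gene-gene interaction regression
#'
#' OLS of the preprocessed phenotype on {1, x_t, x_j, x_t * x_j}; reports the
#' interaction coefficient, its standard error and two-sided p-value. Used
#' to localize which partner SNPs drive a marginal-epistasis signal.
#'
#' @param x_t,x_j standardized genotype columns of the target and partner
#' @param y preprocessed phenotype vector
#' @param r2_skip skip (return NA with a flag) when the two SNPs are nearly
#'   collinear, r^2 above this value
#' @return list(beta, se, p, skipped)
#' @export
pairwise_interaction_test <- function(x_t, x_j, y, r2_skip = 0.99) {
  if (stats::cor(x_t, x_j)^2 > r2_skip)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, skipped = TRUE))
  X <- cbind(1, x_t, x_j, x_t * x_j)
  fit <- stats::lm.fit(X, y)
  dfres <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  R <- chol2inv(qr.R(fit$qr))
  se <- sqrt(R[4L, 4L] * rss / dfres)
  beta <- fit$coefficients[4L]
  list(beta = unname(beta), se = se,
       p = 2 * stats::pt(-abs(beta / se), dfres), skipped = FALSE)
}

#' Genomic inflation factor
#'
#' `lambda_gc`: the median 1-df chi-square statistic implied by the p-values
#' divided by the null median 0.4549364. Values near 1 indicate calibration.
#' An optional bootstrap over the p-values attaches a percentile confidence
#' interval.
#'
#' @param p vector of p-values in (0, 1]
#' @param n_boot bootstrap draws for the CI (0 = no CI)
#' @param conf confidence level
#' @param seed seed for the bootstrap
#' @return list(lambda, ci) with `ci` NULL when `n_boot = 0`
#' @export
genomic_inflation <- function(p, n_boot = 0L, conf = 0.95, seed = 1L) {
  if (length(p) < 20L) stop("need at least 20 p-values for lambda_gc")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  ref <- stats::qchisq(0.5, df = 1)     # 0.4549364
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / ref
  ci <- NULL
  if (n_boot > 0L) {
    rng <- .seeded_rng(seed, "lambda_boot")
    boots <- rng(vapply(seq_len(n_boot), function(b)
      stats::median(sample(chisq, replace = TRUE)) / ref, numeric(1)))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  }
  list(lambda = lambda, ci = ci)
}
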
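# Randomized Method-of-Moments core. The phenotype covariance is modeled as
#   Sigma = sigma2_g * XX'/M + sigma2_gxg * E_t E_t'/M_e + sigma2_e * I
# and the components are estimated by solving the normal equations
#   T sigma2 = q,  T_kl = tr(K_k K_l),  q_k = y' K_k y.
# Off-diagonal trace terms between two genotype-derived kernels are
# approximated with a Hutchinson sketch over B shared probe vectors; every
# term involving the identity kernel, and all of q, are computed exactly.
# Standard errors come from the sandwich Cov[sigma2] = T^-1 Cov[q] T^-1 with
# the plug-in estimate Cov[q]_kl = 2 y' K_k Sigma~ K_l y.

#' Define a variance component for the moment solver
#'
#' A component is the kernel `K = Z Z' / divisor` described by a streaming
#' block provider for the columns of Z, or the identity kernel.
#'
#' @param label component name (e.g. `"additive"`, `"gxg"`, `"noise"`)
#' @param kind one of `"genotype_additive"`, `"interaction"`, `"identity"`
#' @param blocks for non-identity kinds, a function `(i)` returning the i-th
#'   N x b_i block of Z, or a list of matrices
#' @param nblock number of blocks (inferred for a list)
#' @param divisor the kernel divisor M_k; must equal the total column count
#'   of Z for non-identity kinds
#' @return a `component_def`
#' @export
component_def <- function(label,
                          kind = c("genotype_additive", "interaction",
                                   "identity"),
                          blocks = NULL, nblock = NULL, divisor = 1L) {
  kind <- match.arg(kind)
  if (kind != "identity") {
    if (is.list(blocks) && !is.function(blocks)) {
      blk_list <- blocks
      blocks <- function(i) blk_list[[i]]
      if (is.null(nblock)) nblock <- length(blk_list)
    }
    stopifnot(is.function(blocks), !is.null(nblock), divisor >= 1)
  } else {
    blocks <- NULL; nblock <- 0L; divisor <- 1L
  }
  structure(list(label = label, kind = kind, blocks = blocks,
                 nblock = as.integer(nblock), divisor = as.numeric(divisor)),
            class = "component_def")
}

#' Draw the shared Hutchinson probe matrix
#'
#' B independent N(0, I_N) probe vectors, reproducible from the seed. One
#' probe set is shared by every component of a fit so each Z'V product is
#' computed once.
#'
#' @param n sample count
#' @param B number of probe vectors (default 100)
#' @param seed integer seed
#' @param dist `"normal"` (default) or `"rademacher"` probe entries
#' @return a `probe_set` with fields `V` (N x B), `B`, `seed`
#' @export
draw_probes <- function(n, B = 100L, seed = 1L, dist = c("normal",
                                                         "rademacher")) {
  dist <- match.arg(dist)
  stopifnot(n >= 1, B >= 1)
  rng <- .seeded_rng(seed, "probes")
  V <- rng({
    if (dist == "normal") matrix(stats::rnorm(n * B), n, B)
    else matrix(sample(c(-1, 1), n * B, replace = TRUE), n, B)
  })
  structure(list(V = V, B = as.integer(B), seed = as.integer(seed),
                 dist = dist), class = "probe_set")
}

#' Stream one component against the probes and the phenotype
#'
#' A single pass over the blocks of Z accumulates everything later stages
#' need: `U = Z Z' V` (N x B), `w_raw = Z Z' y`, and the squared Frobenius
#' norm of Z (which gives the exact trace of the kernel). For the identity
#' component the inputs are returned unchanged.
#'
#' @param comp a [component_def()]
#' @param probes a [draw_probes()] probe set
#' @param y phenotype vector (already normalized/residualized)
#' @return a `component_sketch`
#' @export
sketch_component <- function(comp, probes, y) {
  n <- length(y)
  if (nrow(probes$V) != n) stop("probe rows do not match phenotype length")
  if (comp$kind == "identity") {
    return(structure(list(label = comp$label, U = probes$V, w_raw = y,
                          fro2 = n, ncols = n, divisor = 1,
                          identity = TRUE, probe_seed = probes$seed),
                     class = "component_sketch"))
  }
  U <- matrix(0, n, probes$B)
  w <- numeric(n)
  fro2 <- 0
  ncols <- 0L
  Vy <- cbind(probes$V, y)
  for (i in seq_len(comp$nblock)) {
    Z <- comp$blocks(i)
    if (is.null(Z) || ncol(Z) == 0L) next
    if (nrow(Z) != n) stop("component block rows do not match sample count")
    Ct <- crossprod(Z, Vy)              # b x (B+1)
    P <- unname(Z %*% Ct)               # N x (B+1)
    U <- U + P[, seq_len(probes$B), drop = FALSE]
    w <- w + P[, probes$B + 1L]
    fro2 <- fro2 + sum(Z * Z)
    ncols <- ncols + ncol(Z)
  }
  if (ncols != comp$divisor)
    stop(sprintf("component '%s': divisor %g != column count %d",
                 comp$label, comp$divisor, ncols))
  structure(list(label = comp$label, U = U, w_raw = w, fro2 = fro2,
                 ncols = ncols, divisor = comp$divisor, identity = FALSE,
                 probe_seed = probes$seed),
            class = "component_sketch")
}

#' Assemble the estimated moment matrix T
#'
#' Entries between two genotype-derived kernels use the Hutchinson sketch,
#' `T_kl ~ (1/(B M_k M_l)) sum_b (Z_k Z_k' v_b) . (Z_l Z_l' v_b)`. Entries
#' involving the identity kernel are exact: `tr(K_k) = ||Z_k||_F^2 / M_k`
#' and `tr(I I) = N`.
#'
#' @param sketches list of [sketch_component()] results sharing one probe set
#' @param probes the shared probe set
#' @return C x C symmetric matrix, labeled by component
#' @export
assemble_T <- function(sketches, probes) {
  seeds <- vapply(sketches, function(s) s$probe_seed, integer(1))
  if (length(unique(seeds)) != 1L)
    stop("sketches were computed with different probe sets")
  C <- length(sketches)
  Th <- matrix(0, C, C)
  labs <- vapply(sketches, `[[`, character(1), "label")
  dimnames(Th) <- list(labs, labs)
  for (k in seq_len(C)) for (l in k:C) {
    sk <- sketches[[k]]; sl <- sketches[[l]]
    if (sk$identity && sl$identity) {
      v <- sk$ncols                     # N
    } else if (sl$identity) {
      v <- sk$fro2 / sk$divisor
    } else if (sk$identity) {
      v <- sl$fro2 / sl$divisor
    } else {
      v <- sum(sk$U * sl$U) / (probes$B * sk$divisor * sl$divisor)
    }
    Th[k, l] <- v; Th[l, k] <- v
  }
  Th
}

#' Per-probe Hutchinson terms for one T entry
#'
#' Returns the B individual probe estimates whose mean is `T_hat[k,l]`;
#' their spread gives a Monte-Carlo standard error for the entry.
#'
#' @inheritParams assemble_T
#' @param k,l component indices (non-identity)
#' @export
probe_terms <- function(sketches, k, l) {
  sk <- sketches[[k]]; sl <- sketches[[l]]
  if (sk$identity || sl$identity)
    stop("identity entries are exact; no probe terms")
  colSums(sk$U * sl$U) / (sk$divisor * sl$divisor)
}

#' Exact moment vector q
#'
#' `q_k = y' K_k y = (y . Z_k Z_k' y) / M_k`, computed without any
#' randomization from the streamed sketches.
#'
#' @inheritParams assemble_T
#' @param y phenotype vector
#' @return named C-vector
#' @export
compute_q <- function(sketches, y) {
  q <- vapply(sketches, function(s) {
    if (s$identity) sum(y^2) else sum(y * s$w_raw) / s$divisor
  }, numeric(1))
  names(q) <- vapply(sketches, `[[`, character(1), "label")
  q
}

#' Solve the normal equations for the variance components
#'
#' Unconstrained solve of `T sigma2 = q`; negative estimates are allowed and
#' flagged downstream rather than truncated.
#'
#' @param T_hat moment matrix from [assemble_T()]
#' @param q moment vector from [compute_q()]
#' @param max_condition condition-number guard; an ill-conditioned T usually
#'   means two components are nearly collinear kernels
#' @return named vector of variance-component estimates
#' @export
solve_normal_equations <- function(T_hat, q, max_condition = 1e12) {
  kap <- kappa(T_hat, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop(sprintf(
      "moment matrix is ill-conditioned (kappa = %.3g); components [%s] are nearly collinear",
      kap, paste(colnames(T_hat), collapse = ", ")))
  s <- solve(T_hat, q)
  names(s) <- names(q)
  s
}

#' Plug-in covariance of the moment vector q
#'
#' `Cov[q]_kl = 2 sum_t sigma2_t w_k' K_t w_l` with `w_k = K_k y`, i.e. the
#' model covariance `Sigma` replaced by its plug-in estimate. Given the
#' estimates, this is computed exactly (one extra streaming pass per
#' component); no probe randomness enters.
#'
#' @param components list of [component_def()]s (same order as `sketches`)
#' @param sketches their [sketch_component()] results
#' @param sigma2 variance-component estimates
#' @param y phenotype vector
#' @return C x C symmetric matrix
#' @export
plugin_cov_q <- function(components, sketches, sigma2, y) {
  C <- length(sketches)
  n <- length(y)
  W <- vapply(sketches, function(s) s$w_raw / s$divisor, numeric(n)) # w_k = K_k y
  Covq <- matrix(0, C, C)
  for (t in seq_len(C)) {
    if (sigma2[t] == 0) next
    comp <- components[[t]]
    if (comp$kind == "identity") {
      A <- W
    } else {
      A <- matrix(0, n, C)
      for (i in seq_len(comp$nblock)) {
        Z <- comp$blocks(i)
        if (is.null(Z) || ncol(Z) == 0L) next
        A <- A + Z %*% crossprod(Z, W)
      }
      A <- A / comp$divisor
    }
    Covq <- Covq + 2 * sigma2[t] * crossprod(W, A)
  }
  Covq <- (Covq + t(Covq)) / 2
  dimnames(Covq) <- list(names(sigma2), names(sigma2))
  Covq
}

#' Sandwich covariance of the variance-component estimates
#'
#' `Cov[sigma2] = T^-1 Cov[q] T^-1`, symmetrized; any negative diagonal
#' entries (possible with a sketched T) are clipped to zero with a warning.
#'
#' @inheritParams solve_normal_equations
#' @param Cov_q plug-in covariance from [plugin_cov_q()]
#' @export
cov_sigma <- function(T_hat, Cov_q, max_condition = 1e12) {
  kap <- kappa(T_hat, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop("moment matrix is ill-conditioned; cannot form the sandwich")
  Ti <- solve(T_hat)
  S <- Ti %*% Cov_q %*% Ti
  S <- (S + t(S)) / 2
  if (any(diag(S) < 0)) {
    warning("negative variance on the sandwich diagonal clipped to 0")
    diag(S) <- pmax(diag(S), 0)
  }
  dimnames(S) <- dimnames(Cov_q)
  S
}

#' Two-sided Wald test for one variance component
#'
#' @param sigma2 estimate vector
#' @param cov_sigma2 covariance from [cov_sigma()]
#' @param k component index to test
#' @return list(z, p, negative_flag); the estimate is reported even when the
#'   negative flag is set
#' @export
test_component <- function(sigma2, cov_sigma2, k) {
  se <- sqrt(cov_sigma2[k, k])
  if (se == 0) stop("zero standard error for component ", k)
  z <- sigma2[[k]] / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), negative_flag = sigma2[[k]] < 0)
}

#' Heritability fractions from variance-component estimates
#'
#' The marginal-epistasis fraction is the gxg estimate over the total of all
#' components, with negative components floored at zero in the denominator
#' (and flagged). The additive fraction is computed the same way.
#'
#' @param sigma2 named estimates including `additive`, `gxg` and `noise`
#' @return list(h2_gxg, h2_additive, floored) where `floored` names any
#'   negative components zeroed in the denominator
#' @export
heritability_fractions <- function(sigma2) {
  total <- sum(pmax(sigma2, 0))
  if (total <= 0) stop("non-positive total variance; cannot form fractions")
  floored <- names(sigma2)[sigma2 < 0]
  list(h2_gxg = unname(sigma2["gxg"]) / total,
       h2_additive = unname(sigma2["additive"]) / total,
       floored = floored)
}

#' Variance explained by a GWAS hit
#'
#' On the standardized-genotype, unit-variance-phenotype scale the variance
#' explained by a single SNP is the square of its effect size.
#'
#' @param beta_standardized GWAS effect size per standard deviation of
#'   genotype, on a variance-1 phenotype
#' @export
gwas_h2 <- function(beta_standardized) beta_standardized^2

#' Ratio of marginal-epistasis to GWAS-tagged variance
#'
#' Computed from unrounded estimates; `NA` when the GWAS fraction is zero.
#'
#' @param h2_gxg marginal-epistasis variance fraction
#' @param h2_gwas squared standardized GWAS effect
#' @export
gxg_gwas_ratio <- function(h2_gxg, h2_gwas) {
  ifelse(h2_gwas > 0, h2_gxg / h2_gwas, NA_real_)
}

#' Dense exact moments (testing oracle)
#'
#' Materializes every kernel and computes T, q and the plug-in Cov[q] by
#' full matrix products. Intended for tests and small problems only.
#'
#' @param Z_list list of dense Z matrices (one per non-identity component)
#' @param divisors kernel divisors matching `Z_list`
#' @param y phenotype vector
#' @param include_identity append the identity component (default TRUE)
#' @param sigma2 optional estimates for the plug-in Cov[q]
#' @param max_n guard on dense materialization
#' @return list(T_exact, q, Cov_q, K) with `Cov_q` NULL unless `sigma2` given
#' @export
exact_moments_oracle <- function(Z_list, divisors, y,
                                 include_identity = TRUE, sigma2 = NULL,
                                 max_n = 2000L) {
  n <- length(y)
  if (n > max_n) stop("dense oracle restricted to N <= ", max_n)
  K <- lapply(seq_along(Z_list), function(k)
    tcrossprod(Z_list[[k]]) / divisors[k])
  if (include_identity) K <- c(K, list(diag(n)))
  C <- length(K)
  T_exact <- matrix(0, C, C)
  for (k in seq_len(C)) for (l in k:C) {
    v <- sum(K[[k]] * K[[l]])           # tr(K_k K_l) for symmetric kernels
    T_exact[k, l] <- v; T_exact[l, k] <- v
  }
  q <- vapply(K, function(Kk) drop(crossprod(y, Kk %*% y)), numeric(1))
  Cov_q <- NULL
  if (!is.null(sigma2)) {
    stopifnot(length(sigma2) == C)
    Sig <- Reduce(`+`, Map(function(s, Kk) s * Kk, sigma2, K))
    Cov_q <- matrix(0, C, C)
    for (k in seq_len(C)) for (l in seq_len(C))
      Cov_q[k, l] <- 2 * drop(crossprod(y, K[[k]] %*% Sig %*% (K[[l]] %*% y)))
    Cov_q <- (Cov_q + t(Cov_q)) / 2
  }
  list(T_exact = T_exact, q = q, Cov_q = Cov_q, K = K)
}
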
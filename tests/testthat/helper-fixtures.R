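# Shared fixtures and independent oracles used across test files.

# small standardized genotype matrix (dense), via the simulator; common
# frequencies so tiny fixtures cannot come out monomorphic
std_panel <- function(n, m, seed = 1, ld_mode = "independent") {
  src <- standardize_source(simulate_genotypes(
    n, m, maf_range = c(0.2, 0.5), ld_mode = ld_mode, seed = seed))
  gs_materialize(src)
}

# independent Frobenius-objective oracle: least-squares fit of vec(y y') on
# the vectorized kernels, solved by lm's QR (never by the package's own
# normal equations)
frobenius_ls_oracle <- function(K_list, y) {
  A <- vapply(K_list, as.vector, numeric(length(y)^2))
  target <- as.vector(tcrossprod(y))
  unname(stats::lm.fit(A, target)$coefficients)
}

# exact T by streaming-free cross-products: tr(K_k K_l) for K = ZZ'/M is
# ||Z_k' Z_l||_F^2 / (M_k M_l); identity entries analytic
exact_T_cross <- function(Z_list, divisors, n) {
  C <- length(Z_list) + 1L
  T_ <- matrix(0, C, C)
  for (k in seq_along(Z_list)) for (l in seq_along(Z_list)) {
    Ckl <- crossprod(Z_list[[k]], Z_list[[l]])
    T_[k, l] <- sum(Ckl^2) / (divisors[k] * divisors[l])
  }
  for (k in seq_along(Z_list))
    T_[k, C] <- T_[C, k] <- sum(Z_list[[k]]^2) / divisors[k]
  T_[C, C] <- n
  T_
}

# brute-force transcription of the sliding-window LD pruning rule, written
# independently of ld_prune: at each window position, repeatedly find the
# first offending pair among all pairs in the window and remove its
# later-position member, until the window is clean; then shift by one SNP
brute_force_prune <- function(G, r2_threshold = 0.1, window = 500L) {
  keep <- seq_len(ncol(G))
  i <- 1L
  while (i <= length(keep)) {
    repeat {
      win <- keep[i:min(length(keep), i + window - 1L)]
      pair <- NULL
      if (length(win) > 1L) {
        for (a in seq_along(win)) {
          for (b in seq_along(win)) {
            if (b <= a) next
            if (stats::cor(G[, win[a]], G[, win[b]])^2 > r2_threshold) {
              pair <- b; break
            }
          }
          if (!is.null(pair)) break
        }
      }
      if (is.null(pair)) break
      keep <- setdiff(keep, win[pair])
    }
    i <- i + 1L
  }
  keep
}

# components over a dense matrix, split into blocks, for the sketching API
dense_components <- function(X, E, split_at = 2L) {
  split_blocks <- function(Z) {
    cuts <- unique(c(seq(1L, ncol(Z), by = max(1L, ceiling(ncol(Z) / split_at))),
                     ncol(Z) + 1L))
    lapply(seq_len(length(cuts) - 1L), function(i)
      Z[, cuts[i]:(cuts[i + 1L] - 1L), drop = FALSE])
  }
  list(
    component_def("additive", "genotype_additive", split_blocks(X),
                  divisor = ncol(X)),
    component_def("gxg", "interaction", split_blocks(E), divisor = ncol(E)),
    component_def("noise", "identity"))
}
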
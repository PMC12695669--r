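# End-to-end marginal epistasis fit for one target SNP: phenotype
# normalization, covariate and LD-block residualization, component
# construction, shared-probe sketching, the moment solve and the Wald test.

#' Test a target SNP for marginal epistasis
#'
#' Jointly fits three variance components to a quantitative trait: a
#' genome-wide additive component over all SNPs outside the target's LD
#' block, an interaction component pairing the target SNP with every retained
#' SNP (optionally restricted to the target's chromosome, `"local"`, or to
#' the other chromosomes, `"distal"`), and residual noise. The interaction
#' component's two-sided Wald p-value tests the null of no marginal
#' epistasis at the target.
#'
#' The phenotype is inverse rank normalized, residualized on the covariates,
#' and the additive effects of the target's LD block are regressed out
#' (required for calibration when targets are selected from a GWAS).
#'
#' @param genotypes a `genotype_source` (QC already applied; standardized
#'   internally if not already)
#' @param y numeric phenotype vector, one value per sample
#' @param target index of the target SNP in the panel
#' @param covariates optional covariate matrix/data.frame (no intercept
#'   needed; one is added)
#' @param B number of Hutchinson probe vectors (default 100)
#' @param seed integer seed driving the probes (and the permutation when
#'   `permute = TRUE`)
#' @param scope `"genome"`, `"local"` or `"distal"` interaction scope
#' @param ld_blocks optional LD block map `data.frame(chr, start, end)`
#'   (1-based inclusive, e.g. from [read_ld_blocks()]); without it a +/- 1 Mb
#'   window around the target defines the block
#' @param permute if TRUE, the rows of the interaction design are permuted
#'   (negative control)
#' @param normalize apply the inverse rank-normal transform (default TRUE)
#' @param regress_ld_block regress the target's LD-block SNPs out of the
#'   phenotype before fitting (default TRUE)
#' @param rescale_columns re-standardize interaction product columns
#' @param probes optionally, a pre-drawn [draw_probes()] probe set to share
#'   across fits on the same samples
#' @return a `mepi_fit` with estimates, covariance, per-component z/p,
#'   heritability fractions and diagnostic flags
#' @export
fit_marginal_epistasis <- function(genotypes, y, target, covariates = NULL,
                                   B = 100L, seed = 1L,
                                   scope = c("genome", "local", "distal"),
                                   ld_blocks = NULL, permute = FALSE,
                                   normalize = TRUE, regress_ld_block = TRUE,
                                   rescale_columns = FALSE, probes = NULL) {
  scope <- match.arg(scope)
  src <- standardize_source(genotypes)
  n <- gs_nsamples(src)
  m <- gs_nsnps(src)
  meta <- gs_meta(src)
  if (length(y) != n) stop("phenotype length does not match sample count")
  if (target < 1L || target > m) stop("target index out of range")

  # phenotype pipeline: ivrt -> covariates -> LD-block regress-out
  if (normalize) y <- inverse_rank_normalize(y)
  y <- residualize_covariates(y, covariates)
  block_idx <- ld_block_for_target(target, meta, blocks = ld_blocks)
  if (regress_ld_block)
    y <- regress_out_ld_block(y, gs_fetch(src, block_idx))

  additive_idx <- setdiff(seq_len(m), block_idx)
  if (length(additive_idx) == 0L)
    stop("no SNPs left outside the target's LD block for the additive component")
  perm <- if (permute) permutation_from_seed(n, seed) else NULL
  spec <- interaction_spec(target, excluded_indices = block_idx,
                           scope = scope, rescale_columns = rescale_columns,
                           permutation = perm)
  inter_idx <- interaction_columns(spec, meta)
  if (length(inter_idx) == 0L)
    stop("no SNPs available for the '", scope, "' interaction scope")

  if (is.null(probes)) probes <- draw_probes(n, B = B, seed = seed)
  x_t <- drop(gs_fetch(src, target))

  add_blocks <- .index_blocks(additive_idx, src$block_size)
  int_blocks <- .index_blocks(inter_idx, src$block_size)
  comp_add <- component_def(
    "additive", "genotype_additive",
    blocks = function(i) gs_fetch(src, add_blocks[[i]]),
    nblock = length(add_blocks), divisor = length(additive_idx))
  comp_gxg <- component_def(
    "gxg", "interaction",
    blocks = function(i)
      build_interaction_block(x_t, gs_fetch(src, int_blocks[[i]]), spec),
    nblock = length(int_blocks), divisor = length(inter_idx))
  comp_id <- component_def("noise", "identity")
  components <- list(comp_add, comp_gxg, comp_id)

  sketches <- lapply(components, sketch_component, probes = probes, y = y)
  T_hat <- assemble_T(sketches, probes)
  q <- compute_q(sketches, y)
  sigma2 <- solve_normal_equations(T_hat, q)
  Cov_q <- plugin_cov_q(components, sketches, sigma2, y)
  cov_s <- cov_sigma(T_hat, Cov_q)
  tests <- lapply(seq_along(sigma2), function(k)
    test_component(sigma2, cov_s, k))
  h2 <- heritability_fractions(sigma2)

  structure(list(
    sigma2 = sigma2, cov_sigma2 = cov_s, se = sqrt(diag(cov_s)),
    z = vapply(tests, `[[`, numeric(1), "z"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    negative_flag = vapply(tests, `[[`, logical(1), "negative_flag"),
    h2_gxg = h2$h2_gxg, h2_additive = h2$h2_additive,
    T_hat = T_hat, q = q,
    target = target, target_id = meta$snp_id[target], scope = scope,
    permuted = permute, B = probes$B, seed = seed,
    n = n, m_additive = length(additive_idx),
    m_interaction = length(inter_idx),
    ld_block_size = length(block_idx)),
    class = "mepi_fit")
}

.index_blocks <- function(idx, block_size) {
  if (length(idx) == 0L) return(list())
  split(idx, ceiling(seq_along(idx) / block_size))
}

#' @export
print.mepi_fit <- function(x, ...) {
  cat(sprintf(
    "Marginal epistasis fit: target %s (scope %s%s), N = %d, B = %d\n",
    x$target_id, x$scope, if (x$permuted) ", permuted" else "", x$n, x$B))
  tab <- data.frame(estimate = x$sigma2, se = x$se, z = x$z, p = x$p,
                    negative = x$negative_flag)
  print(format(tab, digits = 4))
  cat(sprintf("h2_gxg = %.4g   h2_additive = %.4g\n",
              x$h2_gxg, x$h2_additive))
  invisible(x)
}

#' Collect fits into a result table
#'
#' One row per (target, scope) fit, in the layout written by the `test`
#' command of the command-line interface.
#'
#' @param fits list of `mepi_fit` objects
#' @return data.frame
#' @export
fits_to_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(target = f$target_id, scope = f$scope,
               permuted = f$permuted,
               sigma2_g = f$sigma2[["additive"]],
               sigma2_gxg = f$sigma2[["gxg"]],
               sigma2_e = f$sigma2[["noise"]],
               se_gxg = f$se[["gxg"]], z_gxg = f$z[2L], p_gxg = f$p[2L],
               h2_gxg = f$h2_gxg, negative_gxg = f$negative_flag[2L],
               B = f$B, seed = f$seed, n = f$n,
               m_additive = f$m_additive, m_interaction = f$m_interaction,
               stringsAsFactors = FALSE)
  }))
}
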
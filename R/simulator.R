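# Synthetic genotypes and phenotypes reproducing the architectures used to
# validate the estimator: null (additive-only), power grids over the
# interaction variance, regional (local/distal) signal placement, and a set
# of model-misspecification scenarios under which the test should stay
# calibrated.

#' Simulate hard-call genotypes
#'
#' Biallelic dosages for N samples at M SNPs with allele frequencies drawn
#' uniformly from `maf_range`. `ld_mode = "independent"` draws
#' Binomial(2, f_j) per SNP; `ld_mode = "blocky"` builds haplotypes by a
#' first-order copying process within blocks of `block_snps` SNPs sharing a
#' block frequency, giving adjacent-SNP correlation ~ `adj_r` that decays
#' geometrically with distance. SNPs are split evenly over `n_chr`
#' chromosomes at 10 kb spacing, and the generating block intervals are
#' attached to the source (`ld_block_map()`), with single-SNP blocks in
#' independent mode.
#'
#' @param n,m sample and SNP counts
#' @param maf_range allele-frequency range, within [0.01, 0.5]
#' @param ld_mode `"independent"` or `"blocky"`
#' @param block_snps SNPs per LD block (blocky mode)
#' @param adj_r target adjacent-SNP haplotype correlation (blocky mode)
#' @param n_chr number of chromosomes to spread the SNPs over
#' @param seed integer seed
#' @return a `genotype_source` of raw dosages with an attached LD block map
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.01, 0.5),
                               ld_mode = c("independent", "blocky"),
                               block_snps = 25L, adj_r = 0.6, n_chr = 2L,
                               seed = 1L) {
  ld_mode <- match.arg(ld_mode)
  stopifnot(maf_range[1] >= 0.01, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  rng <- .seeded_rng(seed, "genotypes")
  chr <- as.character(rep(seq_len(n_chr), each = ceiling(m / n_chr))[1:m])
  pos <- integer(m)
  for (cc in unique(chr)) {
    k <- sum(chr == cc)
    pos[chr == cc] <- seq_len(k) * 10000L
  }
  meta <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)), chr = chr,
                     pos = pos, a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  if (ld_mode == "independent") {
    G <- rng({
      f <- stats::runif(m, maf_range[1], maf_range[2])
      matrix(stats::rbinom(n * m, 2L, rep(f, each = n)), n, m)
    })
    blocks <- data.frame(chr = chr, start = pos, end = pos,
                         stringsAsFactors = FALSE)
  } else {
    block_id <- paste(chr, ceiling(stats::ave(pos, chr,
      FUN = seq_along) / block_snps))
    G <- matrix(0L, n, m)
    rng({
      for (b in unique(block_id)) {
        cols <- which(block_id == b)
        f <- stats::runif(1, maf_range[1], maf_range[2])
        for (h in 1:2) {
          H <- matrix(0L, n, length(cols))
          H[, 1L] <- stats::rbinom(n, 1L, f)
          if (length(cols) > 1L) for (j in 2:length(cols)) {
            copy <- stats::rbinom(n, 1L, adj_r)
            H[, j] <- copy * H[, j - 1L] +
              (1L - copy) * stats::rbinom(n, 1L, f)
          }
          G[, cols] <- G[, cols] + H
        }
      }
    })
    blocks <- do.call(rbind, lapply(unique(block_id), function(b) {
      cols <- which(block_id == b)
      data.frame(chr = chr[cols[1L]], start = min(pos[cols]),
                 end = max(pos[cols]), stringsAsFactors = FALSE)
    }))
  }
  src <- matrix_source(G, meta)
  src$ld_blocks <- blocks
  src
}

#' LD block map attached to a simulated source
#' @param src a `genotype_source`
#' @return data.frame(chr, start, end) or NULL
#' @export
ld_block_map <- function(src) src$ld_blocks

#' Configuration of a simulated trait architecture
#'
#' Defaults follow the validation settings: additive variance 0.3 (the
#' approximate median additive heritability of the analyzed traits; the
#' null-calibration runs use 0.25), 10% of SNPs causal for the additive
#' component and 10% (disjoint, outside the target's LD block) causal for
#' the interaction component, total variance 1.
#'
#' @param sigma2_g,sigma2_gxg additive and marginal-epistasis variance
#'   components; `sigma2_e` defaults to `1 - sigma2_g - sigma2_gxg`
#' @param sigma2_e residual variance, or NULL for the unit-total default
#' @param p_causal_additive,p_causal_gxg causal SNP fractions
#' @param target target SNP index, or NULL to draw one from the seed
#' @param scenario trait-generation scenario: `"baseline"`, `"null"` (alias
#'   for baseline with `sigma2_gxg = 0`), or a misspecification scenario
#'   `"nonlinear_covariate"`, `"hidden_gxe"`, `"heavy_tail"`,
#'   `"heteroskedastic"`, `"untyped_causal"`, `"maf_ld_arch"`
#' @param covariate_quad quadratic coefficient of the nonlinear covariate
#'   scenario
#' @param gxe_share variance share of the hidden gene-environment term
#' @param het_slope slope of the heteroskedastic noise scale
#' @param visible_every in `untyped_causal`, every `visible_every`-th SNP of
#'   the (denser) simulated panel is exposed to the estimator
#' @param maf_ld_a exponent offset of the MAF-dependent architecture:
#'   per-SNP effect variance proportional to `(f(1-f))^(1+a)`
#' @param seed integer seed; identical configs give bit-identical phenotypes
#' @export
sim_config <- function(sigma2_g = 0.3, sigma2_gxg = 0, sigma2_e = NULL,
                       p_causal_additive = 0.1, p_causal_gxg = 0.1,
                       target = NULL, scenario = "baseline",
                       covariate_quad = 0.5, gxe_share = 0.1,
                       het_slope = 0.5, visible_every = 3L,
                       maf_ld_a = 0.25, seed = 1L) {
  scenarios <- c("baseline", "null", "nonlinear_covariate", "hidden_gxe",
                 "heavy_tail", "heteroskedastic", "untyped_causal",
                 "maf_ld_arch")
  if (!scenario %in% scenarios)
    stop("unknown scenario: ", scenario)
  if (scenario == "null") { scenario <- "baseline"; sigma2_gxg <- 0 }
  if (is.null(sigma2_e)) sigma2_e <- 1 - sigma2_g - sigma2_gxg
  stopifnot(sigma2_g >= 0, sigma2_gxg >= 0, sigma2_e >= 0)
  structure(list(sigma2_g = sigma2_g, sigma2_gxg = sigma2_gxg,
                 sigma2_e = sigma2_e,
                 p_causal_additive = p_causal_additive,
                 p_causal_gxg = p_causal_gxg, target = target,
                 scenario = scenario, covariate_quad = covariate_quad,
                 gxe_share = gxe_share, het_slope = het_slope,
                 visible_every = as.integer(visible_every),
                 maf_ld_a = maf_ld_a, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a phenotype with additive and marginal-epistasis effects
#'
#' `y = X beta + E_t alpha + e`: additive effects `beta_j ~ N(0,
#' sigma2_g/|M_a|)` on a random causal set M_a, interaction effects
#' `alpha_j ~ N(0, sigma2_gxg/|M_e|)` on a disjoint causal set M_e drawn
#' outside the target's LD block, gaussian noise unless the scenario says
#' otherwise. Standardized genotype columns have unit variance, so the
#' expected variance contributions match the configured components.
#'
#' @param genotypes a `genotype_source`
#' @param cfg a [sim_config()]
#' @return list(y, truth): `truth` carries the target, causal sets, effect
#'   vectors, any scenario covariates the analyst should adjust for, and (in
#'   `untyped_causal`) the indices of the SNPs visible to the estimator
#' @export
simulate_phenotype <- function(genotypes, cfg) {
  src <- standardize_source(genotypes)
  n <- gs_nsamples(src); m <- gs_nsnps(src)
  meta <- gs_meta(src)
  rng_arch <- .seeded_rng(cfg$seed, "arch")
  target <- if (is.null(cfg$target)) rng_arch(sample.int(m, 1L)) else
    as.integer(cfg$target)
  block_idx <- ld_block_for_target(target, meta,
                                   blocks = ld_block_map(genotypes))
  n_a <- max(1L, round(cfg$p_causal_additive * m))
  n_e <- max(1L, round(cfg$p_causal_gxg * m))
  sets <- rng_arch({
    M_a <- sort(sample.int(m, n_a))
    pool <- setdiff(setdiff(seq_len(m), M_a), block_idx)
    if (cfg$sigma2_gxg > 0 && length(pool) == 0L)
      stop("no SNPs available for the interaction causal set")
    M_e <- if (length(pool)) sort(sample(pool, min(n_e, length(pool)))) else
      integer()
    list(M_a = M_a, M_e = M_e)
  })
  M_a <- sets$M_a; M_e <- sets$M_e

  # additive effects; MAF-dependent variance under the maf_ld_arch scenario
  beta <- rng_arch({
    if (cfg$scenario == "maf_ld_arch") {
      maf <- snp_stats(genotypes)$maf[M_a]
      v <- (maf * (1 - maf))^(1 + cfg$maf_ld_a)
      v <- v / sum(v) * cfg$sigma2_g
      stats::rnorm(length(M_a), 0, sqrt(v))
    } else {
      stats::rnorm(length(M_a), 0, sqrt(cfg$sigma2_g / length(M_a)))
    }
  })
  alpha <- rng_arch({
    if (cfg$sigma2_gxg > 0 && length(M_e))
      stats::rnorm(length(M_e), 0, sqrt(cfg$sigma2_gxg / length(M_e)))
    else numeric(length(M_e))
  })

  g_add <- drop(gs_fetch(src, M_a) %*% beta)
  x_t <- drop(gs_fetch(src, target))
  g_gxg <- if (length(M_e)) x_t * drop(gs_fetch(src, M_e) %*% alpha) else
    numeric(n)

  ms <- apply_misspecification(g_add + g_gxg, genotypes, cfg)
  truth <- list(target = target, M_a = M_a, M_e = M_e, beta = beta,
                alpha = alpha, block_idx = block_idx,
                sigma2 = c(g = cfg$sigma2_g, gxg = cfg$sigma2_gxg,
                           e = cfg$sigma2_e),
                realized = c(var_add = stats::var(g_add),
                             var_gxg = stats::var(g_gxg)),
                covariates = ms$covariates,
                visible_idx = if (cfg$scenario == "untyped_causal")
                  seq(1L, m, by = cfg$visible_every) else NULL,
                scenario = cfg$scenario, seed = cfg$seed)
  list(y = ms$y, truth = truth)
}

#' Add scenario-specific noise and nuisance terms to a genetic value
#'
#' Given the noiseless genetic component of a simulated trait, draws the
#' residual term (and any nuisance structure) according to the scenario:
#' gaussian noise for `baseline` and `maf_ld_arch`/`untyped_causal` (whose
#' misspecification is structural, not in the noise), scaled t(3) noise for
#' `heavy_tail`, covariate-dependent noise scale for `heteroskedastic`, an
#' observed covariate entering quadratically for `nonlinear_covariate`, and
#' a hidden gene-environment product term for `hidden_gxe`. Noise and
#' scenario draws use separate seed streams, so a scenario with a zero-sized
#' effect (e.g. `gxe_share = 0`) reproduces the baseline trait exactly.
#'
#' @param y noiseless genetic value (N-vector)
#' @param genotypes the `genotype_source` the trait was simulated from
#' @param cfg a [sim_config()]
#' @return list(y, covariates): `covariates` holds any observed covariate
#'   columns the analyst is expected to adjust for (NULL otherwise)
#' @export
apply_misspecification <- function(y, genotypes, cfg) {
  n <- length(y)
  rng_noise <- .seeded_rng(cfg$seed, "noise")
  rng_scen <- .seeded_rng(cfg$seed, "scenario")
  se <- sqrt(cfg$sigma2_e)
  covariates <- NULL
  eps <- switch(cfg$scenario,
    heavy_tail = rng_noise(stats::rt(n, df = 3) / sqrt(3) * se),
    rng_noise(stats::rnorm(n, 0, se)))
  if (cfg$scenario == "heteroskedastic") {
    w <- rng_scen(stats::rnorm(n))
    eps <- eps * (1 + cfg$het_slope * w) / sqrt(1 + cfg$het_slope^2)
    covariates <- cbind(w = w)
  } else if (cfg$scenario == "nonlinear_covariate") {
    w <- rng_scen(stats::rnorm(n))
    y <- y + w + cfg$covariate_quad * (w^2 - 1)
    covariates <- cbind(w = w)
  } else if (cfg$scenario == "hidden_gxe") {
    extra <- rng_scen({
      m <- gs_nsnps(genotypes)
      idx <- sort(sample.int(m, max(1L, round(0.1 * m))))
      gam <- stats::rnorm(length(idx))
      u <- drop(gs_fetch(standardize_source(genotypes), idx) %*% gam)
      u <- u / stats::sd(u)
      e_hidden <- stats::rnorm(n)
      sqrt(cfg$gxe_share) * u * e_hidden
    })
    y <- y + extra
  } else if (!cfg$scenario %in% c("baseline", "heavy_tail",
                                  "untyped_causal", "maf_ld_arch")) {
    stop("unknown scenario: ", cfg$scenario)
  }
  list(y = y + eps, covariates = covariates)
}
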
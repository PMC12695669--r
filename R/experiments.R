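# Replicated simulation experiments: type-I calibration with GWAS-selected
# targets, power/accuracy grids over the interaction variance, and
# calibration under model misspecification.

#' Type-I calibration experiment with GWAS-selected targets
#'
#' Mirrors the null-calibration design: simulate additive-only traits on a
#' fixed genotype panel, run a GWAS, LD-prune the significant SNPs, and test
#' each selected target for marginal epistasis with the target's LD block
#' regressed out. Replicates accumulate until `n_targets` tests are
#' collected. Under the null the pooled p-values should be uniform: the
#' rejection rate at `alpha` should sit inside its binomial confidence
#' interval and the genomic inflation factor near 1.
#'
#' @param genotypes fixed genotype panel (a `genotype_source`)
#' @param n_targets number of target tests to accumulate
#' @param cfg trait architecture, e.g. `sim_config(sigma2_g = 0.25,
#'   sigma2_gxg = 0)`; the gxg component must be 0
#' @param select_threshold GWAS p-value threshold used to select targets.
#'   At genome-wide panel sizes this is 5e-8; at reduced panel sizes a more
#'   liberal threshold is needed for any SNP to be selected
#' @param max_targets_per_rep cap on targets taken per replicate (most
#'   significant first)
#' @param max_reps stop after this many replicates regardless
#' @param B probe vectors per fit
#' @param alpha nominal test level summarized in the report
#' @param discovery_threshold genome-wide marginal-epistasis threshold
#' @param n_boot bootstrap draws for the lambda_gc interval
#' @param seed master seed
#' @return list: `tests` (one row per target test), `rejection_rate`,
#'   `rejection_ci` (binomial 95% CI around `alpha`), `lambda` (+ CI),
#'   `n_discoveries` at the discovery threshold, `n_reps_used`
#' @export
run_calibration_experiment <- function(genotypes, n_targets = 300L,
                                       cfg = sim_config(sigma2_g = 0.25,
                                                        sigma2_gxg = 0),
                                       select_threshold = 5e-4,
                                       max_targets_per_rep = 5L,
                                       max_reps = 1000L, B = 100L,
                                       alpha = 0.05,
                                       discovery_threshold = 5e-8,
                                       n_boot = 1000L, seed = 1L) {
  if (cfg$sigma2_gxg != 0) stop("calibration experiment requires a null architecture")
  src <- standardize_source(genotypes)
  blocks <- ld_block_map(genotypes)
  rows <- list()
  rep_i <- 0L
  while (length(rows) < n_targets && rep_i < max_reps) {
    rep_i <- rep_i + 1L
    rep_seed <- seed + rep_i * 101L
    cfg_i <- cfg; cfg_i$seed <- rep_seed
    sim <- simulate_phenotype(genotypes, cfg_i)
    y_gwas <- residualize_covariates(inverse_rank_normalize(sim$y),
                                     sim$truth$covariates)
    scan <- gwas_scan(src, y_gwas, threshold = select_threshold)
    sig <- which(scan$significant)
    if (!length(sig)) next
    pruned <- ld_prune(sig, src)
    pruned <- pruned[order(scan$p[pruned])]
    targets <- utils::head(pruned, max_targets_per_rep)
    for (j in seq_along(targets)) {
      fit <- fit_marginal_epistasis(
        src, sim$y, target = targets[j],
        covariates = sim$truth$covariates, B = B,
        seed = rep_seed + j, ld_blocks = blocks)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = rep_i, target = targets[j],
        sigma2_gxg = fit$sigma2[["gxg"]], z = fit$z[2L], p = fit$p[2L])
      if (length(rows) >= n_targets) break
    }
  }
  tests <- do.call(rbind, rows)
  n <- nrow(tests)
  rate <- mean(tests$p < alpha)
  half <- 1.96 * sqrt(alpha * (1 - alpha) / n)
  lam <- if (n >= 20L) genomic_inflation(tests$p, n_boot = n_boot,
                                         seed = seed)
         else list(lambda = NA_real_, ci = NULL)
  list(tests = tests, alpha = alpha, rejection_rate = rate,
       rejection_ci = c(alpha - half, alpha + half),
       lambda = lam$lambda, lambda_ci = lam$ci,
       # published benchmark for this design at biobank scale (N ~ 290k,
       # causal ratio 0.01 / 0.1); not desk-reproducible, kept for context
       lambda_reference_full_scale = c(0.958, 1.053),
       n_discoveries = sum(tests$p < discovery_threshold),
       discovery_threshold = discovery_threshold,
       n_reps_used = rep_i, seed = seed)
}

#' Pick representative target SNPs spanning the MAF range
#'
#' Returns the panel SNPs whose minor allele frequencies are closest to the
#' requested values (distinct SNPs, in the order given).
#'
#' @param genotypes a `genotype_source`
#' @param mafs target minor allele frequencies (defaults mirror the
#'   validation choice of rare/intermediate/common targets)
#' @export
representative_targets <- function(genotypes, mafs = c(0.01, 0.14, 0.49)) {
  maf <- snp_stats(genotypes)$maf
  chosen <- integer()
  for (f in mafs) {
    d <- abs(maf - f)
    d[chosen] <- Inf
    chosen <- c(chosen, which.min(d))
  }
  chosen
}

#' Power and accuracy experiment over an interaction-variance grid
#'
#' Simulates traits with additive variance `sigma2_g` and each value of
#' `sigma2_gxg_grid` in turn (targets rotating over `targets`), fits the
#' marginal epistasis test, and reports empirical power at each `alpha` with
#' bootstrap confidence intervals plus the mean and bias of the estimated
#' interaction component.
#'
#' @param genotypes fixed genotype panel
#' @param sigma2_gxg_grid interaction variances to simulate (the validation
#'   grid spans 0.001 to 0.1)
#' @param n_reps replicates per grid value
#' @param targets target SNP indices to rotate over (default: three SNPs
#'   spanning the MAF range, via [representative_targets()])
#' @param cfg base architecture (additive variance defaults to 0.3)
#' @param alphas p-value thresholds at which power is reported
#' @param B probe vectors per fit
#' @param n_boot bootstrap draws for the power CIs
#' @param seed master seed
#' @return list: `results` (per replicate), `summary` (per grid value:
#'   power at each alpha with CIs, mean estimate, bias)
#' @export
run_power_experiment <- function(genotypes,
                                 sigma2_gxg_grid = c(0.005, 0.02, 0.05),
                                 n_reps = 50L, targets = NULL,
                                 cfg = sim_config(sigma2_g = 0.3),
                                 alphas = c(0.05, 5e-8), B = 100L,
                                 n_boot = 1000L, seed = 1L) {
  src <- standardize_source(genotypes)
  blocks <- ld_block_map(genotypes)
  if (is.null(targets)) targets <- representative_targets(genotypes)
  rows <- list()
  for (gi in seq_along(sigma2_gxg_grid)) {
    s2 <- sigma2_gxg_grid[gi]
    for (r in seq_len(n_reps)) {
      rep_seed <- seed + gi * 100000L + r * 101L
      cfg_i <- cfg
      cfg_i$sigma2_gxg <- s2
      cfg_i$sigma2_e <- 1 - cfg$sigma2_g - s2
      cfg_i$target <- targets[(r - 1L) %% length(targets) + 1L]
      cfg_i$seed <- rep_seed
      sim <- simulate_phenotype(genotypes, cfg_i)
      fit <- fit_marginal_epistasis(src, sim$y, target = cfg_i$target,
                                    covariates = sim$truth$covariates,
                                    B = B, seed = rep_seed,
                                    ld_blocks = blocks)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma2_gxg_true = s2, rep = r, target = cfg_i$target,
        sigma2_gxg_hat = fit$sigma2[["gxg"]], se = fit$se[["gxg"]],
        p = fit$p[2L])
    }
  }
  results <- do.call(rbind, rows)
  rng <- .seeded_rng(seed, "power_boot")
  summ <- do.call(rbind, lapply(sigma2_gxg_grid, function(s2) {
    d <- results[results$sigma2_gxg_true == s2, ]
    out <- data.frame(sigma2_gxg_true = s2,
                      mean_estimate = mean(d$sigma2_gxg_hat),
                      bias = mean(d$sigma2_gxg_hat) - s2,
                      mc_se = stats::sd(d$sigma2_gxg_hat) / sqrt(nrow(d)))
    for (a in alphas) {
      hits <- d$p < a
      pow <- mean(hits)
      ci <- rng(stats::quantile(vapply(seq_len(n_boot), function(b)
        mean(sample(hits, replace = TRUE)), numeric(1)),
        c(0.025, 0.975)))
      out[[sprintf("power_%g", a)]] <- pow
      out[[sprintf("power_%g_lo", a)]] <- ci[[1L]]
      out[[sprintf("power_%g_hi", a)]] <- ci[[2L]]
    }
    out
  }))
  list(results = results, summary = summ, targets = targets, seed = seed)
}

#' Calibration under model misspecification
#'
#' For each scenario, simulates traits with no marginal epistasis
#' (`sigma2_gxg = 0`) under the scenario's misspecified generative process,
#' fits the test at a random target per replicate (scenario covariates, where
#' observed, are adjusted for), and reports the rejection rate at `alpha`
#' with its binomial confidence interval. `untyped_causal` simulates a
#' denser hidden panel and exposes every third SNP to the estimator.
#'
#' @param genotypes genotype panel used for all scenarios except
#'   `untyped_causal` (which simulates its own denser panel with matched N)
#' @param scenarios scenario names (see [sim_config()])
#' @param n_reps replicates per scenario
#' @param sigma2_g additive variance of the null architecture
#' @param alpha nominal level
#' @param B probe vectors per fit
#' @param seed master seed
#' @return data.frame: scenario, n_reps, rejection_rate, ci_lo, ci_hi
#' @export
run_misspec_experiment <- function(genotypes,
                                   scenarios = c("nonlinear_covariate",
                                                 "hidden_gxe", "heavy_tail",
                                                 "heteroskedastic",
                                                 "untyped_causal",
                                                 "maf_ld_arch"),
                                   n_reps = 300L, sigma2_g = 0.3,
                                   alpha = 0.05, B = 100L, seed = 1L) {
  out <- lapply(seq_along(scenarios), function(si) {
    scen <- scenarios[si]
    if (scen == "untyped_causal") {
      hidden <- simulate_genotypes(gs_nsamples(genotypes),
                                   3L * gs_nsnps(genotypes),
                                   ld_mode = "blocky",
                                   seed = seed + 7L)
      sim_src <- hidden
    } else sim_src <- genotypes
    blocks <- ld_block_map(sim_src)
    m <- gs_nsnps(sim_src)
    p <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      rep_seed <- seed + si * 100000L + r * 101L
      cfg <- sim_config(sigma2_g = sigma2_g, sigma2_gxg = 0,
                        scenario = scen, seed = rep_seed)
      sim <- simulate_phenotype(sim_src, cfg)
      if (is.null(sim$truth$visible_idx)) {
        fit_src <- sim_src
        target <- sim$truth$target
      } else {
        vis <- sim$truth$visible_idx
        fit_src <- subset_source(sim_src, vis)
        fit_src$ld_blocks <- blocks
        # nearest visible SNP stands in for the (possibly hidden) target
        target <- which.min(abs(vis - sim$truth$target))
      }
      fit <- fit_marginal_epistasis(fit_src, sim$y, target = target,
                                    covariates = sim$truth$covariates,
                                    B = B, seed = rep_seed,
                                    ld_blocks = blocks)
      p[r] <- fit$p[2L]
    }
    rate <- mean(p < alpha)
    half <- 1.96 * sqrt(alpha * (1 - alpha) / n_reps)
    data.frame(scenario = scen, n_reps = n_reps, rejection_rate = rate,
               ci_lo = alpha - half, ci_hi = alpha + half,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
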
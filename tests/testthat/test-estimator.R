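# The randomized MoM core against dense oracles: sketches, moment matrix,
# exact q, the solve, the plug-in covariance and the Wald test.

make_instance <- function(n = 60, m = 12, seed = 1, target = 1L) {
  X <- std_panel(n, m, seed = seed)
  E <- X[, -target, drop = FALSE] * X[, target]
  set.seed(seed + 100)
  y <- rnorm(n)
  list(X = X, E = E, y = y)
}

test_that("probe draws are seed-reproducible with identity covariance", {
  p1 <- draw_probes(30, B = 50, seed = 3)
  expect_identical(p1$V, draw_probes(30, B = 50, seed = 3)$V)
  expect_false(identical(p1$V, draw_probes(30, B = 50, seed = 4)$V))
  big <- draw_probes(50, B = 10000, seed = 1)
  S <- tcrossprod(big$V) / big$B        # sample covariance of probe rows
  expect_lt(max(abs(S - diag(50))), 4 / sqrt(big$B))
  # the estimator defaults to 100 probe vectors
  expect_equal(eval(formals(draw_probes)$B), 100L)
})

test_that("streamed sketches equal dense products and are deterministic", {
  inst <- make_instance(20, 8, seed = 2)
  probes <- draw_probes(20, B = 6, seed = 5)
  comps <- dense_components(inst$X, inst$E, split_at = 3L)
  sk <- sketch_component(comps[[1]], probes, inst$y)
  expect_equal(sk$U, inst$X %*% crossprod(inst$X, probes$V),
               tolerance = 1e-10)
  expect_equal(sk$w_raw, drop(inst$X %*% crossprod(inst$X, inst$y)),
               tolerance = 1e-10)
  expect_equal(sk$fro2, sum(inst$X^2))
  sk2 <- sketch_component(comps[[1]], probes, inst$y)
  expect_identical(sk$U, sk2$U)         # two passes, bit-identical
  ski <- sketch_component(comps[[3]], probes, inst$y)
  expect_identical(ski$U, probes$V)
  expect_identical(ski$w_raw, inst$y)
})

test_that("identity entries of T are exact and the pure-identity model closes", {
  inst <- make_instance(40, 10, seed = 3)
  probes <- draw_probes(40, B = 4, seed = 1)
  comps <- dense_components(inst$X, inst$E)
  sks <- lapply(comps, sketch_component, probes = probes, y = inst$y)
  Th <- assemble_T(sks, probes)
  # standardized X: tr(K1) = N exactly
  expect_equal(Th["additive", "noise"], 40, tolerance = 1e-9)
  expect_equal(Th["noise", "noise"], 40)
  expect_true(isSymmetric(Th))
  # single identity component: T = [N], sigma2_e = ||y||^2 / N
  id_sk <- list(sketch_component(component_def("noise", "identity"),
                                 probes, inst$y))
  T1 <- assemble_T(id_sk, probes)
  expect_equal(T1[1, 1], 40)
  q1 <- compute_q(id_sk, inst$y)
  expect_equal(unname(solve_normal_equations(T1, q1)),
               sum(inst$y^2) / 40)
})

test_that("stochastic T entries converge to the dense trace", {
  inst <- make_instance(30, 10, seed = 4)
  probes <- draw_probes(30, B = 5000, seed = 2)
  comps <- dense_components(inst$X, inst$E)
  sks <- lapply(comps, sketch_component, probes = probes, y = inst$y)
  Th <- assemble_T(sks, probes)
  Tex <- exact_T_cross(list(inst$X, inst$E), c(10, 9), 30)
  for (k in 1:2) for (l in 1:2) {
    terms <- probe_terms(sks, k, l)
    se <- sd(terms) / sqrt(length(terms))
    expect_lt(abs(Th[k, l] - Tex[k, l]), 3 * se)
  }
})

test_that("q is exact and zero for a zero phenotype", {
  inst <- make_instance(50, 20, seed = 5)
  probes <- draw_probes(50, B = 2, seed = 9)
  comps <- dense_components(inst$X, inst$E)
  sks <- lapply(comps, sketch_component, probes = probes, y = inst$y)
  q <- compute_q(sks, inst$y)
  K1 <- tcrossprod(inst$X) / 20
  expect_equal(unname(q["additive"]),
               drop(crossprod(inst$y, K1 %*% inst$y)), tolerance = 1e-10)
  expect_equal(unname(q["noise"]), sum(inst$y^2))
  sks0 <- lapply(comps, sketch_component, probes = probes,
                 y = numeric(50))
  expect_equal(unname(compute_q(sks0, numeric(50))), rep(0, 3))
})

test_that("the MoM solution with exact T equals the Frobenius least-squares argmin", {
  inst <- make_instance(45, 14, seed = 6)
  oracle <- exact_moments_oracle(list(inst$X, inst$E), c(14, 13), inst$y)
  sigma_mom <- solve_normal_equations(oracle$T_exact, oracle$q)
  sigma_frob <- frobenius_ls_oracle(oracle$K, inst$y)
  expect_equal(unname(sigma_mom), sigma_frob, tolerance = 1e-8)
  # ill-conditioned T: duplicated component
  Tbad <- oracle$T_exact
  Tbad[2, ] <- Tbad[1, ]; Tbad[, 2] <- Tbad[, 1]
  expect_error(solve_normal_equations(Tbad, oracle$q), "ill-conditioned")
})

test_that("dense oracle traces agree with the algebraic identity", {
  X <- std_panel(40, 12, seed = 7)
  y <- rnorm(40)
  o <- exact_moments_oracle(list(X), 12, y)
  expect_equal(o$T_exact[1, 1], sum(crossprod(X)^2) / 144, tolerance = 1e-10)
  expect_equal(o$T_exact[2, 2], 40)     # tr(I I) = N
  expect_error(exact_moments_oracle(list(X), 12, rnorm(3000)), "N <= ")
})

test_that("plug-in Cov[q] matches the dense oracle and degenerates correctly", {
  inst <- make_instance(100, 15, seed = 8)
  probes <- draw_probes(100, B = 10, seed = 3)
  comps <- dense_components(inst$X, inst$E)
  sks <- lapply(comps, sketch_component, probes = probes, y = inst$y)
  sigma2 <- c(additive = 0.3, gxg = 0.1, noise = 0.6)
  Cq <- plugin_cov_q(comps, sks, sigma2, inst$y)
  oracle <- exact_moments_oracle(list(inst$X, inst$E), c(15, 14), inst$y,
                                 sigma2 = sigma2)
  expect_equal(unname(Cq), oracle$Cov_q, tolerance = 1e-8)
  expect_equal(unname(plugin_cov_q(comps, sks, c(0, 0, 0), inst$y)),
               matrix(0, 3, 3))
  # identity-only closed form: Cov[q] = 2 sigma2_e ||y||^2
  id_comp <- list(component_def("noise", "identity"))
  id_sk <- list(sketch_component(id_comp[[1]], probes, inst$y))
  expect_equal(unname(plugin_cov_q(id_comp, id_sk, c(noise = 0.5),
                                   inst$y))[1, 1],
               2 * 0.5 * sum(inst$y^2))
})

test_that("sandwich covariance reproduces the analytic identity-model limit", {
  set.seed(10)
  n <- 5000
  y <- rnorm(n, sd = sqrt(0.7))
  probes <- draw_probes(n, B = 2, seed = 1)
  comp <- list(component_def("noise", "identity"))
  sk <- list(sketch_component(comp[[1]], probes, y))
  Th <- assemble_T(sk, probes)
  q <- compute_q(sk, y)
  s2 <- solve_normal_equations(Th, q)
  Cq <- plugin_cov_q(comp, sk, s2, y)
  S <- cov_sigma(Th, Cq)
  # Var(sigma2_e) -> 2 sigma^4 / N for gaussian y
  expect_equal(S[1, 1], 2 * s2[[1]]^2 / n, tolerance = 0.05)
  expect_equal(unname(cov_sigma(Th, matrix(0, 1, 1))), matrix(0, 1, 1))
})

test_that("reported standard errors shrink like 1/N in the small-signal regime", {
  # under a pure-noise trait Cov[q] ~ 2 sigma^4 tr(K^2) and the gxg SE
  # scales as 1/N once N exceeds the panel size; heritable signal adds
  # slower-decaying terms, so the clean law is checked at the null
  Ns <- c(500, 2000, 8000)
  ses <- vapply(Ns, function(n) {
    mean(vapply(1:6, function(r) {
      src <- simulate_genotypes(n, 200, seed = 300 + r)
      sim <- simulate_phenotype(src, sim_config(sigma2_g = 0,
                                                sigma2_gxg = 0,
                                                target = 50L,
                                                seed = 170 + r))
      fit <- fit_marginal_epistasis(src, sim$y, target = 50L, B = 100,
                                    seed = 7, ld_blocks = ld_block_map(src))
      fit$se[["gxg"]]
    }, numeric(1)))
  }, numeric(1))
  slope <- coef(lm(log(ses) ~ log(Ns)))[2]
  expect_lt(abs(slope + 1), 0.2)
})

test_that("Wald test, heritability fractions and ratios behave", {
  cov2 <- diag(c(1e-4, 4e-4, 1e-4))
  s2 <- c(additive = 0.3, gxg = 0.0392, noise = 0.66)
  t2 <- test_component(s2, cov2, 2)
  expect_equal(t2$z, 0.0392 / 0.02)
  expect_equal(t2$p, 2 * pnorm(-abs(t2$z)))
  expect_false(t2$negative_flag)
  tneg <- test_component(c(additive = 0.3, gxg = -0.01, noise = 0.7),
                         cov2, 2)
  expect_true(tneg$negative_flag)
  expect_equal(test_component(c(a = 0, b = 1), diag(2), 1)$p, 1)
  expect_error(test_component(s2, matrix(0, 3, 3), 2), "zero standard error")

  h <- heritability_fractions(c(additive = 0.3, gxg = 0.01, noise = 0.69))
  expect_equal(h$h2_gxg, 0.01)
  expect_equal(h$h2_additive, 0.3)
  hneg <- heritability_fractions(c(additive = 0.5, gxg = -0.1, noise = 0.5))
  expect_equal(hneg$h2_gxg, -0.1)       # numerator kept, denominator floored
  expect_equal(hneg$floored, "gxg")
  expect_error(heritability_fractions(c(additive = -1, gxg = 0, noise = 0)),
               "non-positive")
  expect_equal(gwas_h2(0.1), 0.01)
  expect_equal(gxg_gwas_ratio(2e-3, 1e-3), 2)
  expect_true(is.na(gxg_gwas_ratio(1e-3, 0)))
})

test_that("full fits are deterministic given a seed and record their context", {
  src <- simulate_genotypes(400, 150, ld_mode = "blocky", seed = 21)
  cfg <- sim_config(sigma2_gxg = 0.1, target = 30L, seed = 2)
  sim <- simulate_phenotype(src, cfg)
  f1 <- fit_marginal_epistasis(src, sim$y, target = 30L, B = 40, seed = 9,
                               ld_blocks = ld_block_map(src))
  f2 <- fit_marginal_epistasis(src, sim$y, target = 30L, B = 40, seed = 9,
                               ld_blocks = ld_block_map(src))
  expect_identical(f1$sigma2, f2$sigma2)
  expect_identical(f1$p, f2$p)
  expect_equal(f1$B, 40L)
  expect_equal(f1$m_additive + f1$ld_block_size, 150)
  tab <- fits_to_table(list(f1))
  expect_true(all(c("sigma2_gxg", "p_gxg", "h2_gxg", "B", "seed") %in%
                    names(tab)))
  # local + distal interaction sizes partition the genome scope
  fl <- fit_marginal_epistasis(src, sim$y, target = 30L, B = 10, seed = 9,
                               scope = "local", ld_blocks = ld_block_map(src))
  fd <- fit_marginal_epistasis(src, sim$y, target = 30L, B = 10, seed = 9,
                               scope = "distal", ld_blocks = ld_block_map(src))
  expect_equal(fl$m_interaction + fd$m_interaction, f1$m_interaction)
})

test_that("fits stream over lazily generated panels without materializing X", {
  # column blocks are regenerated deterministically on every fetch; the
  # full matrix (500 x 20,000 ~ 80 MB) never exists, and peak allocation
  # stays far below it
  n <- 500L; m <- 20000L
  # deterministic arithmetic dosages: re-fetchable without RNG state
  lazy_col <- function(j)
    as.numeric(((seq_len(n) * 7919L + j * 104729L) %% 1009L) %% 3L)
  meta <- data.frame(snp_id = sprintf("s%05d", 1:m),
                     chr = rep(c("1", "2"), each = m / 2),
                     pos = rep(seq_len(m / 2) * 100000L, 2),
                     a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  src <- margepi:::new_genotype_source(
    function(cols) vapply(cols, lazy_col, numeric(n)),
    n, meta, block_size = 256L)
  set.seed(77)
  y <- rnorm(n)
  base_mb <- sum(gc(reset = TRUE)[, 2])
  fit <- fit_marginal_epistasis(src, y, target = 40L, B = 20, seed = 1)
  peak_delta_mb <- sum(gc()[, 6]) - base_mb
  expect_true(all(is.finite(fit$sigma2)))
  expect_equal(fit$m_additive + fit$ld_block_size, m)
  # R's high-water mark includes transient uncollected block garbage, so
  # the bound is loose; a dense pipeline (X plus a standardized copy plus
  # kernel products) would need several hundred MB
  expect_lt(peak_delta_mb, 160)
  # identical to the materialized computation
  ref_src <- matrix_source(vapply(1:m, lazy_col, numeric(n)), meta,
                           block_size = 256L)
  ref <- fit_marginal_epistasis(ref_src, y, target = 40L, B = 20, seed = 1)
  expect_equal(fit$sigma2, ref$sigma2, tolerance = 1e-10)
  expect_equal(fit$p, ref$p, tolerance = 1e-10)
})
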
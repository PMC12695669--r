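---
title: "Estimating marginal epistasis variance components with randomized method of moments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating marginal epistasis variance components with randomized method of moments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(margepi)
```

## The model

Exhaustive scans over all SNP pairs are statistically and computationally
punishing. A useful middle ground is *marginal epistasis*: for one target
SNP $t$, aggregate the interaction effects between $t$ and every other SNP
into a single variance component and test that component. margepi fits, for
an $N \times M$ standardized genotype matrix $X$, centered phenotype
$\mathbf{y}$ and interaction design $E_t = X_{-t} \odot X_{:t}$ (the
elementwise product of the target's genotype with every other column),

$$\mathbf{y} = X\beta + E_t \alpha_t + \epsilon, \qquad
\beta \sim \mathcal N\!\left(0, \tfrac{\sigma^2_g}{M} I\right),\;
\alpha_t \sim \mathcal N\!\left(0, \tfrac{\sigma^2_{gxg,t}}{M-1} I\right),\;
\epsilon \sim \mathcal N(0, \sigma^2_e I).$$

The phenotype covariance is then
$\Sigma = \sigma^2_g K_1 + \sigma^2_{gxg,t} K_{2,t} + \sigma^2_e K_3$ with
$K_1 = XX^\top/M$, $K_{2,t} = E_tE_t^\top/(M-1)$ and $K_3 = I_N$. The
interaction effects are modeled independent of the main effects
(uncoordinated epistasis).

## Method-of-moments estimation

Matching $\mathbf{y}\mathbf{y}^\top$ to its expectation in the Frobenius
norm gives linear normal equations $T\sigma^2 = \mathbf{q}$, with
$T_{kl} = \mathrm{tr}(K_kK_l)$ and $q_k = \mathbf{y}^\top K_k \mathbf{y}$
(`solve_normal_equations()`). Negative component estimates are allowed and
flagged, never truncated. Standard errors come from the sandwich
$\mathrm{Cov}[\tilde\sigma^2] = T^{-1}\mathrm{Cov}[\mathbf{q}]\,T^{-1}$
with the plug-in
$\mathrm{Cov}[\mathbf{q}]_{kl} = 2\,\mathbf{y}^\top K_k \tilde\Sigma K_l
\mathbf{y}$, and the marginal-epistasis test is the two-sided Wald test of
$\sigma^2_{gxg,t} = 0$.

Dense evaluation of the traces would need $O(N^2M)$ time and $O(N^2)$
memory. Instead, the trace terms between the two genotype-derived kernels
are sketched with $B$ Hutchinson probes
$v_b \sim \mathcal N(0, I_N)$:

$$\hat T_{kl} = \frac{1}{B\,M_kM_l}\sum_{b=1}^{B}
v_b^\top Z_kZ_k^\top Z_lZ_l^\top v_b ,$$

computed by streaming over column blocks of $Z_k$ — the fit touches only
$N\times B$ and $N\times b$ matrices, so memory is independent of $M$.
Everything that can be exact is exact: $\mathbf{q}$, the plug-in
$\mathrm{Cov}[\mathbf{q}]$, and every entry of $T$ involving the identity
kernel ($\mathrm{tr}(K_k) = \lVert Z_k\rVert_F^2/M_k$, accumulated during
the same pass). One probe set is shared by all components of a fit, so each
$Z_k^\top V$ product is computed once; a second cheap pass computes the
$w_k = K_k\mathbf{y}$ products for the covariance. `exact_moments_oracle()`
materializes everything densely and exists for testing only.

### Parameters that matter

* **B** (probe vectors, default 100): controls the Monte-Carlo variance of
  the off-diagonal $T$ entries, which falls as $1/B$. 100 probes give
  stable $-\log_{10}p$ across probe seeds (correlation > 0.95 in the test
  suite); raise B if two seeds disagree on a borderline call.
* **block size** (default 1024 SNPs): a pure memory/speed trade-off; results
  are bit-identical across block sizes.
* **condition guard** (`max_condition = 1e12`): an ill-conditioned $T$
  means two kernels are nearly collinear (for example, a "genome" scope
  interaction on a panel that is one LD block); the solve refuses rather
  than regularizes.
* **scope**: `genome` pairs the target with all retained SNPs; `local`
  restricts to the target's chromosome, `distal` to the other chromosomes.
  Local and distal columns partition the genome scope exactly.

## Phenotype pipeline and why the order is fixed

`fit_marginal_epistasis()` applies, in order: inverse rank-normal transform
(Blom offsets, $\Phi^{-1}((r - 3/8)/(N + 1/4))$, average ranks on ties),
covariate residualization (intercept always included; collinear columns
dropped with a warning), and a joint OLS regress-out of all standardized
SNPs in the target's LD block. The transform comes first so that every
downstream quantity — and therefore the reported p-value — is invariant to
any strictly monotone rescaling of the raw trait; the test suite asserts
bit-level agreement between fits of $y$, $\exp(y)$ and $y^3 + 5y$.

The LD-block regress-out matters when targets are selected from a GWAS:
selection enriches for additive signal in LD with the target, which leaks
into the interaction kernel and inflates the test. Regressing out the
block's additive effects and excluding the block from both $X$ and $E_t$
restores calibration; with no block map supplied, a $\pm$1 Mb window is
used. Covariates are residualized out of the phenotype only, not out of
each genotype column (the phenotype-side Frisch–Waugh approximation); the
exact joint projection is a known refinement we deliberately leave out, and
the calibration experiments quantify the consequences at desk scale.

## The synthetic-data generator

`simulate_genotypes()` draws hard-call dosages with frequencies uniform in
`maf_range`. `ld_mode = "blocky"` builds haplotypes by a first-order
copying process inside blocks of `block_snps` SNPs sharing a block
frequency: adjacent-SNP correlation is `adj_r` (default 0.6) and decays
geometrically, and the generating blocks double as the LD-block map for the
fits. This emulates the block structure of real LD well enough to exercise
target selection, pruning and block regress-out; it does *not* reproduce
coalescent LD tails, MAF-LD coupling, relatedness or population
stratification, so passing calibration here does not certify robustness to
population structure (PCs are consumed as ordinary covariates and their
computation is out of scope).

`simulate_phenotype()` implements
$y = X\beta + E_t\alpha_t + \epsilon$ with 10% of SNPs additive-causal and
10% (disjoint, outside the target's block) interaction-causal; additive
variance defaults to 0.3 (0.25 in the null-calibration runs), total
variance 1. Because standardized columns have unit sample variance, the
realized variance contributions center on the configured components; the
one approximation is that interaction product columns are not
re-standardized (their population variance is 1 for independent loci, and
slightly off within LD blocks).

Misspecification scenarios modify the generative process while the analyst
still fits the standard pipeline: a covariate entering as $w + 0.5w^2$ but
adjusted linearly; a hidden gene–environment product term (10% variance
share); scaled $t_3$ noise; covariate-dependent noise scale (slope 0.5); a
3× denser causal panel with only every third SNP observed; and additive
effect variance $\propto (f(1-f))^{1.25}$. These parameter values are this
package's fixed defaults (the corresponding published analyses do not print
theirs); they are deliberately not tuned.

## Experiments and what they showed

`run_calibration_experiment()` reproduces the null design end to end:
additive-only traits on a fixed blocky panel (N = 4,000, M = 2,000 in the
test suite), GWAS, LD pruning (window 500 SNPs, remove the later SNP of any
pair with $r^2 > 0.1$, shift by one), marginal-epistasis fits at the
selected targets. At this panel size no SNP reaches $5\times10^{-8}$ in a
GWAS, so target *selection* uses a desk-scale threshold of $5\times10^{-4}$
(a parameter; at biobank scale one would use $5\times10^{-8}$), while the
marginal-epistasis *discovery* threshold stays $5\times10^{-8}$. The suite
checks: rejection at $\alpha = 0.05$ inside its binomial CI, the
$\lambda_{gc}$ bootstrap CI covering 1, and zero discoveries.

`run_power_experiment()` (N = 4,000, M = 1,000, $\sigma^2_g = 0.3$, targets
rotating over SNPs near MAF 0.01/0.14/0.49) shows power > 0.9 at
$\alpha = 0.05$ for $\sigma^2_{gxg} = 0.05$, monotone power in
$\sigma^2_{gxg}$, and mean estimates within Monte-Carlo error of the truth.
The problem sizes are the package's desk-scale validation conditions;
genome-wide sample sizes shift the detectable $\sigma^2_{gxg}$ an order of
magnitude lower.

`run_misspec_experiment()` (N = 1,200, M = 500, 300 replicates per
scenario) stays within the binomial CI of the nominal level for five of the
six scenarios. The exception is the nonlinear-covariate scenario, which is
mildly anti-conservative (rejection ≈ 0.08–0.09 at $\alpha = 0.05$, null z-sd
≈ 1.15) under our default quadratic share. The mechanism is a genuine
limitation worth knowing about: the plug-in
$\mathrm{Cov}[\mathbf{q}] = 2\,\mathrm{tr}(\Sigma K_i \Sigma K_j)$ is the
*Gaussian* fourth-moment identity, and a quadratic covariate remnant leaves
a leptokurtic residual, so the sandwich SE is slightly too small. (The
heavy-tail scenario does not trigger this because the rank-normal transform
re-gaussianizes the trait margin.) A kurtosis-robust covariance of
$\mathbf{q}$ would remove the inflation at the cost of leaving the
published estimator; we report the behavior instead of changing either.

## Numerical choices and degenerate inputs

Population scaling (columns scaled to sum of squares $N$) makes
$\mathrm{tr}(K_1) = N$ exactly, which the tests use as an identity. Missing
genotypes are mean-imputed per SNP before centering, so they contribute
zeros to the standardized matrix. QC applies a fixed first-failing order —
missingness (> 1%), MAF (< 1%), HWE ($p < 10^{-7}$, 1-df chi-square without
continuity correction), region exclusion (MHC chr6:25–35 Mb) — so report
counts are reproducible; an all-filtered panel is an explicit error, as are
zero-variance columns reaching standardization, constant phenotypes
reaching the rank-normal transform, and LD blocks with as many SNPs as
samples reaching the regress-out. Probe draws, permutations and every
simulation consume isolated, label-offset RNG streams, so a fit never
perturbs the caller's RNG state and identical seeds give bit-identical
results.

## Known limitations

* Standard errors condition on the sketched $\hat T$; probe noise in $\hat
  T$ is not propagated into $\mathrm{Cov}[\tilde\sigma^2]$ (at $B = 100$
  this is far below the sampling noise).
* The Gaussian-moment sandwich can be slightly anti-conservative under
  strongly non-Gaussian residuals that survive covariate adjustment (see
  above).
* The reported SE shrinks like $1/N$ only in the small-signal regime where
  $\mathrm{Cov}[\mathbf{q}] \approx 2\sigma^4\mathrm{tr}(K^2)$; under a
  heritable architecture the signal terms decay more slowly (≈
  $N^{-1/2}$).
* Binary traits, REML/likelihood estimation, dosage genotypes, PLINK 2
  formats and higher-order interactions are out of scope; covariates are
  consumed, never computed.

## A worked example

```{r example, eval = FALSE}
src <- simulate_genotypes(2000, 800, ld_mode = "blocky", seed = 1)
sim <- simulate_phenotype(src, sim_config(sigma2_g = 0.3,
                                          sigma2_gxg = 0.1,
                                          target = 150L, seed = 2))
fit <- fit_marginal_epistasis(src, sim$y, target = 150L,
                              B = 100, seed = 3,
                              ld_blocks = ld_block_map(src))
fit
fit_marginal_epistasis(src, sim$y, target = 150L, B = 100, seed = 3,
                       ld_blocks = ld_block_map(src), permute = TRUE)
```

The permuted refit is the built-in negative control: a real signal
disappears when the interaction rows are shuffled against the phenotype.
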
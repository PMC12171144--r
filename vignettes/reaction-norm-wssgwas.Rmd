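---
title: "Reaction-norm single-step GWAS for genotype-by-environment interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-norm single-step GWAS for genotype-by-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgxe)
```

## The problem

Feed-efficiency traits in beef cattle — residual feed intake (RFI) and dry
matter intake (DMI), both in kg/day — are measured in feeding trials whose
management, diet and climate vary widely between farms and years. An
animal's genetic merit may therefore depend on the environment in which its
performance is expressed (genotype-by-environment interaction, G×E). This
package implements a two-step reaction-norm single-step GBLUP analysis of
such data, a weighted single-step GWAS (WssGWAS) on the fitted
intercept/slope genetic coefficients, and the downstream G×E summaries
(SNP-effect reaction norms, GEBV correlations across environments, top-sire
reranking), together with a simulator that generates data with exactly the
statistical structure the model assumes.

## The model

**Step 1 — environmental gradient.** Average daily gain (ADG) is modeled as
`y = Xβ + Zα + e` with contemporary group (CG: farm × year/season × sex
batch) and age as fixed effects and a pedigree-based animal effect,
`α ~ N(0, A σ²ₐ)`. The BLUE of each CG, standardized to mean 0 and SD 1
(sample SD) across CGs, is the environmental gradient (EG): a continuous
descriptor of environment quality derived from how well contemporaries
grew. The step-1 variance ratio uses an assumed heritability (default 0.3,
configurable) because the analysis only needs the fixed-effect solutions,
which are insensitive to moderate changes in the ratio.

**Step 2 — reaction norm.** Each trait is modeled as

y_ij = Xb + Σ_f ω_f φ_f(EG_j) + Σ_f a_fi φ_f(EG_j) + e_ij

with φ₀ = √(1/2), φ₁(x) = √(3/2)·x the normalized first-order Legendre
polynomials on the EG domain mapped to [−1, 1]. The per-animal coefficients
(a₀, a₁) = (intercept, slope) have covariance `H ⊗ K` where K is the 2×2
genetic covariance of intercept and slope and H combines pedigree and
genomic information through

H⁻¹ = A⁻¹ + [0 0; 0 G*⁻¹ − A₂₂⁻¹],

with G the VanRaden method-1 genomic relationship matrix and A₂₂ the
pedigree relationships among genotyped animals. Residual variances are
heterogeneous across discrete EG level classes (diagonal R).

A practical note on the fixed regression ω_f: because EG is a CG-level
covariate (all records in a CG share one gradient value), the covariables
φ_f(EG) are linear combinations of the CG dummies. The fixed regression is
therefore aliased with the CG effects whenever full CG dummies are fitted;
`solve_ssbrn()` detects this by pivoted QR on the fixed block, drops the
aliased columns and reports them. The fixed-effect *space* — and hence all
BLUPs — is identical under either parameterization, so nothing is lost.

**Variance components.** `gibbs_components()` runs a block Gibbs sampler:
all location parameters jointly from their multivariate-normal full
conditional (one sparse Cholesky factorization per cycle, symbolic
factorization cached and updated numerically), K from an inverse-Wishart
full conditional, and each residual-class variance from a scaled
inverse-chi-square full conditional. Priors are weakly informative and
configurable: `K ~ IW(ν = 4, S = 0.5·K_start)` and residuals
`~ scaled-inv-χ²(ν = 4, s² = R_start)`. The desk-scale default chain is
20,000 cycles / 4,000 burn-in / thinning 10; the full protocol of the
source analysis (500,000 / 50,000 / 10) is reached by configuration.
Convergence is screened with the Geweke diagnostic (`geweke_z()`,
spectral-density-at-zero variances from an AR fit; defaults first 10%
vs last 50% of the stored chain).

**WssGWAS.** GEBVs of genotyped animals are back-solved into SNP effects by
û = λ D Z'g (Z_g D Z'g λ)⁻¹ â_g with Z_g centered by 2p and
λ = 1/(2Σpᵢ(1−pᵢ)), independently for the intercept and the slope
solutions. Per-SNP weights dᵢ = ûᵢ²·2pᵢ(1−pᵢ) are normalized to keep
Σdᵢ·2pᵢ(1−pᵢ) constant, and the build-solve-backsolve loop is run for two
iterations (configurable; one iteration is the unweighted scan). Variance
is then partitioned into moving windows of 100 adjacent same-chromosome
SNPs; windows explaining ≥ 1% of the additive variance are reported after
greedy non-overlap deduplication (take the best window, discard everything
sharing a marker with it, repeat).

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| step-1 heritability | 0.3 | moderate value for growth traits; only CG BLUEs are consumed |
| EG level classes | 17 (or #CGs if fewer) | the motivating data showed 17 discrete levels; binning is by quantiles |
| G blending toward A₂₂ | 0.05, with tuning | guarantees an invertible G*; tuning matches mean diagonal/off-diagonal to A₂₂ first |
| missing-genotype imputation | 2p after QC | keeps centered dosage columns mean-zero |
| window size / step | 100 SNPs / 1 | the source protocol's window; "moving" read as step-1 sliding |
| relevance threshold | 1% | the source protocol's threshold |
| weight combination | mean of intercept and slope weight shares | one D must serve both coefficients in the weighted G; intercept-only and slope-only are provided |
| Gibbs chain | 20,000/4,000/10 | desk-scale; scaled down from 500,000/50,000/10 to fit test budgets |

## The window-variance denominator

The per-window percentage is Var(Σ_j Z_j û_j)/σ²ₐ × 100, computed across
genotyped animals, separately for intercept and slope effects. By default
σ²ₐ is the *marker-explained* additive variance — the variance of the
whole-genome aggregate Zû for the same coefficient — which is the
convention under which published window tables sum to meaningful totals
(tens of percent). The parametric alternative (the corresponding diagonal
of K) can be supplied explicitly, but BLUP shrinkage makes Var(Zû) a small
fraction of the parametric variance in any finite design, so with that
denominator virtually no window can reach a 1% threshold; the published
per-window values (1–7%) are only consistent with the marker-explained
total. This is the one place where we deviated from a literal reading of
the design notes, as a package-level design decision.

## What the simulator emulates — and what it does not

`sim_config()` + `simulate_pedigree()`/`simulate_genotypes()`/
`simulate_phenotypes()` generate:

* a multi-generation pedigree (random pairing within the previous
  generation, configurable family size), founders as an unrelated base;
* biallelic SNPs in linkage groups by gene dropping, founder frequencies
  uniform in `maf_range`, one uniformly-placed crossover per chromosome per
  transmitted gamete (configurable) — enough linkage realism for window
  tests without a genetic-map model;
* contemporary groups whose standard-normal environmental quality both
  shifts mean performance (scaled by `cg_effect_sd`) and is the gradient
  entering the reaction norm — this makes step-1 recovery well-posed, since
  the CG BLUEs estimate exactly the quantity that drives the genetic slope;
* intercept/slope genetic coefficients as QTL dosage effects plus a
  pedigree polygenic remainder, rescaled so their realized covariance
  matches `K_true` (QTL explain `qtl_prop`, default 50%); `qtl_on` and
  `qtl_equal_effects` give clean slope-only (or intercept-only)
  architectures with equal per-QTL variance contributions for power
  studies;
* heterogeneous residual variance by EG level (default rising from 0.6 to
  1.4 trait-units², mirroring the larger residual spread recorded in
  extreme environments);
* records for all non-founder animals, age ~ N(415, 116²) days.

Not emulated: ancestral linkage disequilibrium (founders are in linkage
equilibrium, so sample LD is purely familial and long-range), selection or
assortative mating, repeated records, realistic genetic maps, and
sequence-level variation. A green test therefore establishes that the
estimation machinery recovers the generative model's quantities under its
own assumptions — not that it is robust to every feature of field data.

## Numerical choices

* Sparse mixed-model equations are solved by CHOLMOD Cholesky
  factorizations (Matrix package); the Gibbs sampler draws the joint
  location block as θ = μ + P'L⁻ᵀz from the cached factorization.
* Aliased fixed effects are detected by pivoted QR with tolerance 1e-8 and
  dropped, keeping the first of any dependent set.
* Gradient values outside the Legendre domain are clamped with a warning
  (prediction use); a degenerate domain is an error.
* EG standardization uses the sample SD (n − 1).
* Zero SNP weights are floored at 1e-8 after normalization so D stays
  invertible.
* Monomorphic markers inside a genotyped subset are dropped by
  `run_wssgwas()` with a message (QC contracts assume polymorphic
  markers).
* Half-open interval semantics `[start, end)` are used internally for all
  window/feature overlap; BED enters natively, GFF3 is converted.
* Trailing windows shorter than the window size are reported but flagged
  and excluded from threshold selection.

## Design choices where the design was open

* **Discrete EG levels before binning**: exposed as `n_levels`
  (default 17) rather than fixed.
* **Sliding step and deduplication**: step-1 moving windows with greedy
  non-overlap selection of reported regions; both configurable.
* **One D for two coefficients**: the weighted G uses a single diagonal
  weight matrix; the default combines the intercept and slope weight
  *shares* by averaging, so a marker large for either coefficient is
  up-weighted, and neither scan dominates by scale.
* **GEBV correlations and sire lists**: computed over sires with at least
  `min_progeny` (default 5) offspring by default, whole-population option
  available; ranking direction is configurable per trait (lower is better
  for RFI).
* **Three reference environments**: low/medium/high default to the
  minimum, 0 and maximum of the standardized gradient.

## Known limitations

* Bi-trait fitting (a 4×4 K across two traits) is not implemented; each
  trait is analyzed univariately. The univariate model is the tested
  desk-scale configuration; nothing in the window or reporting machinery
  depends on it.
* Inbreeding in the polygenic simulator's Mendelian-sampling variances is
  ignored (generation counts are small); `build_A_inverse()` itself does
  account for inbreeding via the Meuwissen–Luo recursion.
* The Gibbs sampler assumes one record per animal; repeated-records and
  permanent-environment effects are out of scope.
* `build_A22()` materializes the full tabular A, which is quadratic in
  pedigree size — fine at desk scale, not for national evaluations.

## Detection-power expectations

With slope-only QTL of equal variance contribution (`qtl_on = "slope"`,
`qtl_equal_effects = TRUE`, 3 QTL explaining 90% of slope variance on a
6,000-marker genome, progeny-tested genotyped animals), the two-iteration
weighted scan flags at least one QTL-carrying slope window above the 1%
threshold while the same windows stay below 1% in the intercept scan in at
least 90% of seeded replicates. Detecting *every* simulated QTL is not
claimed — a QTL whose signal is split across window boundaries or diluted
by familial LD can stay below threshold, exactly as real scans report only
the windows that do exceed the threshold.
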
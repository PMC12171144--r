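# ssgxe — single-step reaction-norm GWAS for genotype-by-environment interaction

`ssgxe` is an R toolkit for mapping genomic regions whose effects on
feed-efficiency traits (residual feed intake, dry matter intake; kg/day)
change with environmental quality, for quantitative geneticists working
with livestock feeding-trial data. It implements:

1. **Environmental gradient (EG)** — an animal model for average daily
   gain yields contemporary-group (CG) BLUEs, standardized to mean 0 /
   SD 1: a continuous descriptor of how favorable each trial environment
   was.
2. **Reaction-norm single-step GBLUP** — a random-regression mixed model
   on the normalized first-order Legendre basis,

   *y* = Xb + Σ<sub>f</sub> ω<sub>f</sub>φ<sub>f</sub>(EG) +
   Σ<sub>f</sub> a<sub>fi</sub>φ<sub>f</sub>(EG) + e,
   (a₀, a₁) ~ N(0, **H** ⊗ **K**),

   with heterogeneous residual variances per EG level and
   **H**⁻¹ = **A**⁻¹ + [0 0; 0 **G**\*⁻¹ − **A₂₂**⁻¹] combining pedigree
   (Henderson/Meuwissen–Luo **A**⁻¹) and genomic (VanRaden method-1 **G**)
   relationships. Variance components come from a block Gibbs sampler
   (inverse-Wishart **K**, scaled inverse-χ² residuals, joint sparse draw
   of all location effects), screened with the Geweke diagnostic.
3. **WssGWAS** — GEBVs of genotyped animals are back-solved into SNP
   effects, û = λ**D**Z′(Z**D**Z′λ)⁻¹â, weighted by
   d<sub>i</sub> = û²<sub>i</sub>2p<sub>i</sub>(1−p<sub>i</sub>) over two
   iterations, and additive variance is partitioned into moving 100-SNP
   windows with a 1% relevance threshold — separately for the intercept
   (merit in the average environment) and the slope (environmental
   sensitivity).
4. **G×E reporting** — per-SNP reaction norms with crossing detection,
   GEBV Pearson correlations across gradient levels, and top-50-sire
   overlap between low/medium/high environments.
5. **Simulator** — pedigree + gene-dropped genotypes + reaction-norm
   phenotypes with configurable intercept/slope covariance `K_true`, QTL
   architecture and heterogeneous residuals, so the whole pipeline is
   testable without proprietary data.

## Worked example

Simulate a small herd with slope-only QTL, estimate the gradient, run the
two-iteration weighted scan, and summarize G×E:

```r
library(ssgxe)

sc <- sim_config(n_founders = 80, n_generations = 3, offspring_per_mating = 3,
                 n_chromosomes = 3, snps_per_chromosome = 200,
                 n_qtl = 6, qtl_on = "slope", qtl_equal_effects = TRUE,
                 qtl_prop = 0.8, K_true = matrix(c(0.3, 0, 0, 0.25), 2),
                 n_cg = 15, n_eg_levels = 5,
                 resid_var_by_level = seq(0.4, 0.6, length.out = 5), seed = 42)
ped  <- simulate_pedigree(sc)
geno <- simulate_genotypes(ped, sc)
sim  <- simulate_phenotypes(ped, geno, sc)

eg <- estimate_eg(sim$pheno, ped, n_levels = 5)
pheno <- sim$pheno
pheno$eg <- eg$record_eg; pheno$level <- eg$record_level
basis <- legendre_basis(min(pheno$eg), max(pheno$eg))

gg <- subset_genotypes(geno, animals = ped$animal[ped$generation >= 1])
gg <- qc_genotypes(gg, pedigree = ped)

res <- run_wssgwas(pheno, ped, gg, basis, sc$K_true, sc$resid_var_by_level,
                   n_iterations = 2)
win <- window_variance(res[[2]], gg, window_size = 50, step = 50)
sel <- select_windows(win, pct_col = "pct_slope", threshold_pct = 1)
sel$selected[, c("chrom", "start_bp", "end_bp", "pct_slope")]
#>   chrom start_bp  end_bp pct_slope
#> 1     3    50000 2500000  6.594392
#> 2     1  2600000 5100000  5.876470
#> 3     3  2550000 5050000  5.822843
#> ...
# selected 8 windows totalling 34.86% of slope variance

sol <- attr(res[[2]], "solution")
round(gebv_correlations(sol, c(basis$eg_min, 0, basis$eg_max)), 3)
#>           -2.578853 0.000000 1.739738
#> -2.578853     1.000    0.554   -0.157
#> 0.000000      0.554    1.000    0.735
#> 1.739738     -0.157    0.735    1.000
```

The top slope windows sit over the simulated QTL (e.g. the QTL at
1:3,100,000 falls in the selected window 1:2,600,000–5,100,000), and the
GEBV correlation between the extreme environments (−0.157 here, versus
0.55–0.74 for adjacent levels) shows the re-ranking that slope-only QTL
produce: selection decisions made in a poor environment would not carry
over to a rich one.

Published per-window percentages can be replayed through the same summary
machinery:

```r
sel <- select_windows(published_windows("rfi", "slope"), pct_col = "pct")
sel$summary
#> $n_windows [1] 11      $total_pct [1] 29.65
```

## Command-line pipeline

```sh
Rscript -e 'ssgxe::ssgxe_cli()' pipeline --config config.yaml --out-dir out/
```

Subcommands `simulate | qc | eg | fit | gwas | report | pipeline` read the
previous stage's TSV/VCF outputs from the output directory and log the
config hash and seed with every stage. See `?ssgxe_cli` for the
configuration keys.

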
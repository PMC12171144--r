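test_that("backsolve_snp_effects matches the ridge SNP-BLUP oracle", {
  w <- small_world(seed = 5)
  A_inv <- build_A_inverse(w$ped)
  sol <- suppressMessages(
    solve_ssbrn(w$pheno, w$ped, A_inv, w$basis, w$sc$K_true,
                w$sc$resid_var_by_level))
  p0 <- w$geno$founder_freq
  Z <- sweep(w$geno$dosage, 2, 2 * p0)
  lam <- 1 / (2 * sum(p0 * (1 - p0)))

  # zero GEBVs give zero effects (linearity)
  eff0 <- backsolve_snp_effects(matrix(0, nrow(Z), 2), w$geno, p = p0)
  expect_true(all(eff0$effects == 0))

  # unweighted: explicit dense oracle and the projection identity
  eff <- backsolve_snp_effects(sol$coeffs, w$geno, p = p0)
  u_or <- lam * t(Z) %*% solve(lam * Z %*% t(Z), sol$coeffs)
  expect_lt(max(abs(u_or - eff$effects)), 1e-8)
  expect_lt(max(abs(Z %*% eff$effects - sol$coeffs)), 1e-8)

  # weighted oracle
  set.seed(1)
  D <- runif(ncol(Z), 0.5, 2)
  effw <- backsolve_snp_effects(sol$coeffs, w$geno, D = D, p = p0)
  u_w <- lam * (D * t(Z)) %*% solve(lam * Z %*% (D * t(Z)), sol$coeffs)
  expect_lt(max(abs(u_w - effw$effects)), 1e-8)

  expect_error(backsolve_snp_effects(sol$coeffs[1:3, ], w$geno),
               "dimension mismatch")
  expect_error(backsolve_snp_effects(sol$coeffs, w$geno,
                                     D = rep(-1, ncol(Z))), "positive")
})

test_that("snp weights follow the heterozygosity-scaled square", {
  expect_equal(snp_weight(0.1, 0.5), 0.005)
  expect_equal(snp_weight(0, 0.3), 0)
  expect_equal(snp_weight(-0.1, 0.27), snp_weight(0.1, 0.27))
  expect_error(snp_weight(0.1, 0), "frequencies")
})

test_that("normalize_weights conserves the total genetic variance", {
  p <- c(0.1, 0.3, 0.5, 0.4)
  # uniform raw weights normalize to the identity
  expect_equal(normalize_weights(rep(0.37, 4), p), rep(1, 4))

  set.seed(3)
  d <- runif(50); pp <- runif(50, 0.05, 0.95)
  dn <- normalize_weights(d, pp)
  het <- 2 * pp * (1 - pp)
  expect_lt(abs(sum(dn * het) - sum(het)), 1e-10)

  # zero weight floored, D stays invertible
  dz <- normalize_weights(c(0, 1, 2), c(0.5, 0.5, 0.5))
  expect_gt(min(dz), 0)
  expect_equal(dz[1], 1e-8)

  expect_error(normalize_weights(c(0, 0), c(0.5, 0.5)), "all-zero")
})

test_that("run_wssgwas iterates weighting and degenerates correctly", {
  w <- small_world(seed = 19, n_founders = 40, n_generations = 3,
                   offspring_per_mating = 2, n_chromosomes = 2,
                   snps_per_chromosome = 150, n_qtl = 5, qtl_prop = 0.8,
                   n_cg = 10)
  gg <- subset_genotypes(w$geno,
                         animals = w$ped$animal[w$ped$generation >= 1])
  gg <- subset_genotypes(gg, markers = which(gg$p > 0 & gg$p < 1))
  res <- suppressMessages(
    run_wssgwas(w$pheno, w$ped, gg, w$basis, w$sc$K_true,
                w$sc$resid_var_by_level, n_iterations = 2))
  expect_length(res, 2)
  expect_equal(res[[1]]$iteration, 1L)
  expect_true(all(res[[1]]$D == 1))
  expect_false(all(res[[2]]$D == 1))

  # iteration 2 concentrates weight share on the true QTL
  qtl <- match(w$geno$map$id[w$truth$qtl_indices], gg$map$id)
  qtl <- qtl[!is.na(qtl)]
  expect_gt(length(qtl), 0)
  share <- function(eff) {
    d <- snp_weight(eff$effects[, 1], gg$p) + snp_weight(eff$effects[, 2], gg$p)
    sum(d[qtl]) / sum(d)
  }
  expect_gt(share(res[[2]]), share(res[[1]]))

  # effects stay bounded between iterations (null-stability guard)
  expect_lt(max(abs(res[[2]]$effects)), 10 * max(abs(res[[1]]$effects)))

  # one iteration reduces to the unweighted scan
  res1 <- suppressMessages(
    run_wssgwas(w$pheno, w$ped, gg, w$basis, w$sc$K_true,
                w$sc$resid_var_by_level, n_iterations = 1))
  expect_length(res1, 1)
  expect_equal(res1[[1]]$effects, res[[1]]$effects)
})

test_that("window_variance partitions variance by chromosome windows", {
  set.seed(6)
  # unlinked markers: founders-only world
  sc <- sim_config(n_founders = 300, n_generations = 1, n_chromosomes = 2,
                   snps_per_chromosome = 100, n_eg_levels = 2,
                   resid_var_by_level = c(1, 1), seed = 6)
  ped <- simulate_pedigree(sc)
  geno <- simulate_genotypes(ped, sc)
  m <- ncol(geno$dosage)
  eff <- structure(list(effects = cbind(intercept = numeric(m),
                                        slope = numeric(m)),
                        map = geno$map, p = geno$p, D = rep(1, m),
                        iteration = 1L), class = "snp_effect_set")

  # all effects zero -> every window 0%
  win0 <- window_variance(eff, geno, sigma_a2 = c(1, 1), window_size = 20)
  expect_true(all(win0$pct_intercept == 0) && all(win0$pct_slope == 0))
  expect_true(all(win0$end_idx - win0$start_idx < 20))
  expect_true(all(win0$chrom[win0$start_idx <= 100] == 1))

  # single nonzero marker: every window containing it shares one value,
  # all others are zero
  eff1 <- eff
  eff1$effects[57, "intercept"] <- 0.3
  win1 <- window_variance(eff1, geno, sigma_a2 = c(0.2, 0.2),
                          window_size = 20, step = 1)
  hit <- win1$start_idx <= 57 & win1$end_idx >= 57
  expect_true(all(win1$pct_intercept[!hit] == 0))
  expect_equal(length(unique(round(win1$pct_intercept[hit], 10))), 1L)
  expect_true(all(win1$pct_slope == 0))

  # linkage equilibrium: non-overlapping window percentages sum to ~100
  set.seed(6)
  u <- cbind(rnorm(m, 0, 0.02), rnorm(m, 0, 0.02))
  effr <- eff
  effr$effects <- u
  Z <- sweep(geno$dosage, 2, 2 * geno$p)
  tot <- c(var(as.vector(Z %*% u[, 1])), var(as.vector(Z %*% u[, 2])))
  winr <- window_variance(effr, geno, sigma_a2 = tot, window_size = 20,
                          step = 20)
  expect_equal(sum(winr$pct_intercept), 100, tolerance = 0.05)
  expect_equal(sum(winr$pct_slope), 100, tolerance = 0.05)

  # a chromosome shorter than the window is skipped with a warning
  g2 <- subset_genotypes(geno, markers = c(1:100, 101:110))
  eff2 <- eff
  eff2$effects <- eff$effects[1:110, ]
  eff2$map <- g2$map
  expect_warning(window_variance(eff2, g2, sigma_a2 = c(1, 1),
                                 window_size = 50), "fewer than")
})

test_that("select_windows applies greedy non-overlap selection", {
  # published worked example: all rows retained, total matches the print
  t3 <- published_windows("rfi", "intercept")
  sel <- select_windows(t3, pct_col = "pct", threshold_pct = 1)
  expect_equal(sel$summary$n_windows, 10L)
  expect_equal(sel$summary$total_pct, 20.63, tolerance = 1e-12)

  # below-threshold windows vanish
  low <- data.frame(chrom = 1, start_bp = c(1, 100), end_bp = c(50, 160),
                    pct = c(0.4, 0.9))
  sel0 <- select_windows(low, threshold_pct = 1)
  expect_equal(sel0$summary$n_windows, 0L)
  expect_equal(sel0$summary$total_pct, 0)

  # overlapping pair: only the larger survives
  ovl <- data.frame(chrom = 1, start_idx = c(10, 15), end_idx = c(20, 25),
                    start_bp = c(10, 15), end_bp = c(20, 25),
                    pct = c(2.0, 1.5))
  selo <- select_windows(ovl)
  expect_equal(selo$selected$pct, 2.0)

  # same span on different chromosomes never conflicts
  two <- data.frame(chrom = c(1, 2), start_idx = c(1, 1), end_idx = c(5, 5),
                    pct = c(2, 3))
  expect_equal(select_windows(two)$summary$n_windows, 2L)

  expect_error(select_windows(data.frame()), "empty")
})

test_that("annotate_windows matches a brute-force overlap oracle", {
  win <- data.frame(chrom = c("1", "1", "2"),
                    start_bp = c(100, 500, 100), end_bp = c(200, 600, 300))
  iv <- data.frame(chrom = c("1", "1", "2", "2"),
                   start = c(150, 200, 0, 290),
                   end = c(180, 250, 400, 310),
                   name = c("gA", "gB", "gC", "gD"))
  ann <- annotate_windows(win, iv)
  expect_equal(ann$features[[1]], "gA")       # gB touches only at end: out
  expect_equal(ann$features[[2]], character(0))
  expect_setequal(ann$features[[3]], c("gC", "gD"))

  # randomized toy vs quadratic oracle
  set.seed(4)
  wr <- data.frame(chrom = sample(1:3, 40, TRUE),
                   start_bp = sample(0:500, 40, TRUE))
  wr$end_bp <- wr$start_bp + sample(10:80, 40, TRUE)
  ir <- data.frame(chrom = sample(1:3, 60, TRUE),
                   start = sample(0:500, 60, TRUE))
  ir$end <- ir$start + sample(5:60, 60, TRUE)
  ir$name <- paste0("f", seq_len(60))
  got <- annotate_windows(wr, ir)$features
  for (i in seq_len(nrow(wr))) {
    exp_i <- ir$name[ir$chrom == wr$chrom[i] &
                     ir$start < wr$end_bp[i] & wr$start_bp[i] < ir$end]
    expect_setequal(got[[i]], exp_i)
  }

  expect_warning(
    annotate_windows(data.frame(chrom = "9", start_bp = 1, end_bp = 5),
                     iv), "absent")
})
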
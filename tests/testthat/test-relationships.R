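test_that("qc_genotypes applies each rule and reports counts", {
  # 4 animals x 10 SNPs, hand-enumerated; marker 3 missing in 3/4 animals
  # (marker call rate 0.25) while sample call rates stay at 0.9
  set.seed(1)
  dos <- matrix(rbinom(40, 2, 0.5), 4, 10)
  dos[, 4] <- 0  # monomorphic
  dos[1:3, 3] <- NA
  g <- toy_genotypes(dos)
  out <- qc_genotypes(g, min_call_rate = 0.9, min_maf = 0)
  rep <- qc_report(out)
  expect_equal(unname(rep["sample_call_rate_removed"]), 0L)
  expect_equal(unname(rep["marker_call_rate_removed"]), 1L)
  expect_false("m3" %in% out$map$id)

  # monomorphic marker (p = 0) removed at MAF 0.05
  out2 <- qc_genotypes(g, min_call_rate = 0, min_maf = 0.05)
  expect_false("m4" %in% out2$map$id)
  expect_gte(unname(qc_report(out2)["maf_removed"]), 1L)

  # Mendelian conflict: offspring 2 with both parents 0 at one marker
  ped <- data.frame(animal = 1:3, sire = c(NA, NA, 1), dam = c(NA, NA, 2))
  dosm <- rbind(c(0, 1), c(0, 1), c(2, 1))
  gm <- toy_genotypes(dosm)
  outm <- qc_genotypes(gm, pedigree = ped, min_call_rate = 0, min_maf = 0,
                       max_mendelian_conflict = 0.01)
  expect_equal(unname(qc_report(outm)["mendel_removed"]), 1L)
  expect_false("m1" %in% outm$map$id)

  # non-autosomal markers dropped
  gx <- toy_genotypes(rbind(c(0, 1), c(1, 2)), chrom = c("1", "X"))
  outx <- qc_genotypes(gx, min_call_rate = 0, min_maf = 0)
  expect_equal(unname(qc_report(outx)["non_autosomal_removed"]), 1L)

  # everything removed -> explicit error
  mono <- toy_genotypes(rbind(c(0, 0), c(0, 0)))
  expect_error(qc_genotypes(mono), "empty genotype set")

  # idempotence: same thresholds twice change nothing
  w <- small_world(seed = 9)
  q1 <- qc_genotypes(w$geno, pedigree = w$ped)
  q2 <- qc_genotypes(q1, pedigree = w$ped)
  expect_equal(q1$dosage, q2$dosage)
  expect_equal(sum(qc_report(q2)), 0L)

  # missing dosages imputed to 2p after QC
  gmiss <- toy_genotypes(rbind(c(0, 1), c(NA, 1), c(2, 0), c(2, 2)))
  qmiss <- qc_genotypes(gmiss, min_call_rate = 0.5, min_maf = 0)
  expect_equal(qmiss$dosage[2, 1], 2 * mean(c(0, 2, 2)) / 2)
})

test_that("build_A_inverse matches tabular-method oracle", {
  # two unrelated founders -> identity
  ped2 <- data.frame(animal = 1:2, sire = c(NA, NA), dam = c(NA, NA))
  expect_equal(as.matrix(build_A_inverse(ped2)), diag(2),
               ignore_attr = TRUE)

  # founders 1,2 and offspring 3 = 1 x 2: textbook 3x3 inverse
  ped3 <- data.frame(animal = 1:3, sire = c(NA, NA, 1), dam = c(NA, NA, 2))
  expect_equal(as.matrix(build_A_inverse(ped3)),
               rbind(c(1.5, 0.5, -1), c(0.5, 1.5, -1), c(-1, -1, 2)),
               ignore_attr = TRUE)

  # A^-1 A = I on random pedigrees (incl. inbreeding), tabular oracle
  for (seed in c(1, 2, 3)) {
    ped <- random_pedigree(50, seed)
    A <- build_A(ped)
    expect_lt(max(abs(as.matrix(build_A_inverse(ped) %*% A) - diag(50))),
              1e-10)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  # unsorted pedigree rejected
  bad <- data.frame(animal = 1:2, sire = c(2, NA), dam = c(NA, NA))
  expect_error(build_A_inverse(bad), "sorted")
})

test_that("inbreeding follows the classical recursion", {
  # offspring of full sibs: F = 0.25; next full-sib mating compounds it
  ped <- data.frame(animal = 1:6, sire = c(NA, NA, 1, 1, 3, 5),
                    dam = c(NA, NA, 2, 2, 4, 4))
  f <- inbreeding_ml(ped)
  expect_equal(unname(f), c(0, 0, 0, 0, 0.25, 0.375))
  expect_equal(unname(diag(build_A(ped))), 1 + unname(f))
})

test_that("build_A22 extracts numerator relationships of the genotyped", {
  ped2 <- data.frame(animal = 1:2, sire = c(NA, NA), dam = c(NA, NA))
  expect_equal(build_A22(ped2, 1:2), diag(2), ignore_attr = TRUE)

  ped4 <- data.frame(animal = 1:4, sire = c(NA, NA, 1, 1),
                     dam = c(NA, NA, 2, 2))
  A22 <- build_A22(ped4, c(3, 4))
  expect_equal(A22[1, 2], 0.5)

  ped <- random_pedigree(30, 4)
  idx <- c(5, 12, 18, 29, 30)
  expect_equal(build_A22(ped, idx), build_A(ped)[idx, idx])
  expect_error(build_A22(ped, c(1, 99)), "not all present")
})

test_that("build_G_vanraden matches its closed form and brute force", {
  g2 <- toy_genotypes(matrix(c(0, 2), ncol = 1))
  expect_equal(build_G_vanraden(g2), rbind(c(2, -2), c(-2, 2)),
               ignore_attr = TRUE)

  set.seed(8)
  dos <- matrix(rbinom(100, 2, 0.4), 5, 20)
  g <- toy_genotypes(dos)
  p <- g$p
  # brute-force double loop
  Z <- sweep(dos, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  Gb <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    Gb[i, j] <- sum(Z[i, ] * Z[j, ]) / denom
  expect_lt(max(abs(build_G_vanraden(g) - Gb)), 1e-12)

  # allele-swap invariance: x -> 2 - x with p -> 1 - p
  gs <- toy_genotypes(2 - dos)
  expect_equal(build_G_vanraden(gs, p = 1 - p), build_G_vanraden(g, p = p),
               ignore_attr = TRUE)

  expect_error(build_G_vanraden(toy_genotypes(matrix(0, 2, 2))),
               "monomorphic")

  # unrelated panel under HWE: mean diagonal near 1
  sc <- sim_config(n_founders = 500, n_generations = 1, n_chromosomes = 5,
                   snps_per_chromosome = 1000, n_eg_levels = 2,
                   resid_var_by_level = c(1, 1), seed = 15)
  ped <- simulate_pedigree(sc)
  geno <- simulate_genotypes(ped, sc)
  expect_lt(abs(mean(diag(build_G_vanraden(geno))) - 1), 0.05)
})

test_that("blend_tune_G guarantees invertibility and honors its contract", {
  set.seed(3)
  w <- small_world(seed = 3)
  gg <- subset_genotypes(w$geno, animals = w$ped$animal[w$ped$generation > 0])
  A22 <- build_A22(w$ped, gg$animal_ids)
  G <- build_G_vanraden(gg)

  expect_equal(blend_tune_G(G, A22, blend = 0, tune = FALSE), G)
  expect_error(blend_tune_G(G, A22, blend = 1), "blend")

  # rank-deficient G (observed frequencies): blending restores PD
  expect_lt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
            1e-8)
  Gs <- blend_tune_G(G, A22, blend = 0.05)
  expect_gt(min(eigen(Gs, symmetric = TRUE, only.values = TRUE)$values), 0)

  # tuning matches mean diagonal / off-diagonal to A22
  Gt <- blend_tune_G(G, A22, blend = 0, tune = TRUE)
  expect_equal(mean(diag(Gt)), mean(diag(A22)), tolerance = 1e-10)
  off <- function(M) (sum(M) - sum(diag(M))) / (length(M) - nrow(M))
  expect_equal(off(Gt), off(A22), tolerance = 1e-10)
})

test_that("build_H_inverse equals the dense-H oracle", {
  w <- small_world(seed = 6, n_founders = 20, n_generations = 2,
                   n_chromosomes = 2, snps_per_chromosome = 60)
  ped <- w$ped
  A_inv <- build_A_inverse(ped)

  # no genotyped animals -> H^-1 = A^-1 exactly
  H0 <- build_H_inverse(A_inv, matrix(0, 0, 0), matrix(0, 0, 0), integer(0))
  expect_equal(as.matrix(H0), as.matrix(A_inv), ignore_attr = TRUE)

  # G* = A22 -> correction vanishes
  idx <- which(ped$generation == max(ped$generation))[1:10]
  A22 <- build_A22(ped, ped$animal[idx])
  H1 <- build_H_inverse(A_inv, A22, A22, idx)
  expect_lt(max(abs(as.matrix(H1) - as.matrix(A_inv))), 1e-10)

  # dense oracle: invert H assembled from its closed form
  gg <- subset_genotypes(w$geno, animals = ped$animal[idx])
  G <- build_G_vanraden(gg, p = gg$founder_freq)
  Gs <- blend_tune_G(G, A22, blend = 0.05)
  Hinv <- build_H_inverse(A_inv, A22, Gs, idx)
  Hd <- dense_H_oracle(build_A(ped), Gs, idx)
  expect_lt(max(abs(as.matrix(Hinv) - solve(Hd))), 1e-8)

  # non-genotyped block of H^-1 equals A^-1's, element-wise
  nidx <- setdiff(seq_len(nrow(ped)), idx)
  expect_equal(as.matrix(Hinv)[nidx, nidx], as.matrix(A_inv)[nidx, nidx],
               ignore_attr = TRUE)
})
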
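# shared fixture builders (all data generated in code)

# small end-to-end world: pedigree + genotypes + phenotypes
small_world <- function(seed = 5, n_founders = 30, n_generations = 2,
                        offspring_per_mating = 2, n_chromosomes = 3,
                        snps_per_chromosome = 80, n_qtl = 5, n_cg = 8,
                        n_eg_levels = 3,
                        resid_var_by_level = c(0.6, 0.8, 1.0), ...) {
  sc <- sim_config(n_founders = n_founders, n_generations = n_generations,
                   offspring_per_mating = offspring_per_mating,
                   n_chromosomes = n_chromosomes,
                   snps_per_chromosome = snps_per_chromosome, n_qtl = n_qtl,
                   n_cg = n_cg, n_eg_levels = n_eg_levels,
                   resid_var_by_level = resid_var_by_level, seed = seed, ...)
  ped <- simulate_pedigree(sc)
  geno <- simulate_genotypes(ped, sc)
  sim <- simulate_phenotypes(ped, geno, sc)
  list(sc = sc, ped = ped, geno = geno, pheno = sim$pheno,
       eg_assign = sim$eg_assign, truth = sim$truth, basis = sim$basis)
}

# random valid pedigree of n animals (founder block + random matings)
random_pedigree <- function(n, seed, n_founders = max(4L, n %/% 5L)) {
  set.seed(seed)
  sire <- dam <- rep(NA_integer_, n)
  for (i in (n_founders + 1L):n) {
    sire[i] <- sample.int(i - 1L, 1L)
    dam[i] <- sample.int(i - 1L, 1L)
    if (dam[i] == sire[i]) dam[i] <- NA_integer_
  }
  data.frame(animal = seq_len(n), sire = sire, dam = dam)
}

# tiny genotype_set from an explicit dosage matrix
toy_genotypes <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  map <- data.frame(chrom = chrom %||% rep(1L, m),
                    pos = pos %||% (1000L * seq_len(m)),
                    id = paste0("m", seq_len(m)))
  rownames(dosage) <- as.character(seq_len(nrow(dosage)))
  colnames(dosage) <- map$id
  ssgxe:::new_genotype_set(seq_len(nrow(dosage)), map, dosage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense generalized-least-squares oracle for the reaction-norm model
dense_gls_oracle <- function(pheno, ped, basis, K, R_levels,
                             H_dense = NULL) {
  des <- ssgxe:::ssbrn_design(pheno, ped, basis, report_aliased = FALSE)
  X <- as.matrix(des$X)
  W <- as.matrix(des$W)
  H <- H_dense %||% build_A(ped)
  Kk <- kronecker(H, K)
  V <- W %*% Kk %*% t(W) + diag(R_levels[des$level])
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% pheno$y)
  u <- Kk %*% t(W) %*% Vi %*% (pheno$y - X %*% beta)
  list(fixed = as.vector(beta),
       coeffs = matrix(u, ncol = 2, byrow = TRUE))
}

# dense H matrix from its closed form given A and G* on the genotyped block
dense_H_oracle <- function(A, G_star, idx) {
  H <- A
  n <- nrow(A)
  nidx <- setdiff(seq_len(n), idx)
  A22 <- A[idx, idx, drop = FALSE]
  A22i <- solve(A22)
  if (length(nidx)) {
    A12 <- A[nidx, idx, drop = FALSE]
    H[nidx, idx] <- A12 %*% A22i %*% G_star
    H[idx, nidx] <- t(H[nidx, idx])
    H[nidx, nidx] <- A[nidx, nidx] +
      A12 %*% A22i %*% (G_star - A22) %*% A22i %*% t(A12)
  }
  H[idx, idx] <- G_star
  H
}

# minimal multivariate normal draw without extra dependencies
MASS_free_mvrnorm <- function(n, S) {
  L <- chol(S)
  matrix(rnorm(n * nrow(S)), n) %*% L
}
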
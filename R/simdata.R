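#' Simulation configuration
#'
#' Collects the generative quantities for the synthetic reaction-norm world:
#' a multi-generation pedigree with genotyped recent generations, biallelic
#' SNPs in linkage groups, contemporary groups (CG) whose mean performance
#' defines the environmental gradient (EG), additive intercept and slope
#' genetic effects with (co)variance `K_true`, and heterogeneous residual
#' variance across gradient levels.
#'
#' @param n_founders number of unrelated base animals (generation 0).
#' @param n_generations number of descendant generations to breed.
#' @param offspring_per_mating full-sib family size per mating.
#' @param n_chromosomes,snps_per_chromosome marker panel layout.
#' @param maf_range founder allele-frequency range, within (0, 0.5].
#' @param n_qtl number of causal markers.
#' @param K_true 2x2 genetic covariance of the (intercept, slope) random
#'   regression coefficients, trait units squared.
#' @param qtl_prop proportion of `K_true` explained by the QTL; the remainder
#'   is a pedigree polygenic term.
#' @param n_eg_levels number of discrete gradient levels (residual classes).
#' @param resid_var_by_level residual variance per EG level; defaults to a
#'   gradient increasing from 0.6 to 1.4, mirroring larger residual spread in
#'   extreme environments.
#' @param n_cg number of contemporary groups.
#' @param cg_effect_sd SD of the CG environmental-quality effect on the trait
#'   (trait units).
#' @param age_beta linear age effect, trait units per day.
#' @param crossovers_per_chr crossovers per chromosome per transmitted gamete.
#' @param qtl_on which coefficient(s) the QTL act on: "both", "intercept" or
#'   "slope" (the latter two zero out the other column of QTL effects, giving
#'   clean intercept-only/slope-only architectures for power studies).
#' @param qtl_equal_effects draw QTL allele-substitution effects with equal
#'   magnitude and random sign instead of Gaussian draws, so every QTL has
#'   the same configured effect size (power studies).
#' @param seed integer seed; all simulator output is reproducible given it.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 200L,
                       n_generations = 3L,
                       offspring_per_mating = 2L,
                       n_chromosomes = 5L,
                       snps_per_chromosome = 400L,
                       maf_range = c(0.05, 0.5),
                       n_qtl = 20L,
                       K_true = matrix(c(0.4, 0.1, 0.1, 0.2), 2, 2),
                       qtl_prop = 0.5,
                       n_eg_levels = 17L,
                       resid_var_by_level = NULL,
                       n_cg = 40L,
                       cg_effect_sd = 0.25,
                       age_beta = 0.001,
                       crossovers_per_chr = 1L,
                       qtl_on = c("both", "intercept", "slope"),
                       qtl_equal_effects = FALSE,
                       seed = 1L) {
  qtl_on <- match.arg(qtl_on)
  if (is.null(resid_var_by_level))
    resid_var_by_level <- seq(0.6, 1.4, length.out = n_eg_levels)
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    offspring_per_mating = as.integer(offspring_per_mating),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    maf_range = as.numeric(maf_range),
    n_qtl = as.integer(n_qtl),
    K_true = K_true,
    qtl_prop = qtl_prop,
    n_eg_levels = as.integer(n_eg_levels),
    resid_var_by_level = as.numeric(resid_var_by_level),
    n_cg = as.integer(n_cg),
    cg_effect_sd = cg_effect_sd,
    age_beta = age_beta,
    crossovers_per_chr = as.integer(crossovers_per_chr),
    qtl_on = qtl_on,
    qtl_equal_effects = isTRUE(qtl_equal_effects),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_founders", "n_generations", "offspring_per_mating",
              "n_chromosomes", "snps_per_chromosome", "n_eg_levels", "n_cg")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop(sprintf("'%s' must be a count >= 1", nm), call. = FALSE)
  if (cfg$n_qtl < 0L) stop("'n_qtl' must be >= 0", call. = FALSE)
  mr <- cfg$maf_range
  if (length(mr) != 2L || any(mr <= 0) || any(mr > 0.5) || mr[1] > mr[2])
    stop("'maf_range' must be within (0, 0.5] with min <= max", call. = FALSE)
  K <- cfg$K_true
  if (!is.matrix(K) || nrow(K) != 2L || ncol(K) != 2L ||
      max(abs(K - t(K))) > 1e-10)
    stop("'K_true' must be a symmetric 2x2 matrix", call. = FALSE)
  if (any(eigen(K, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    stop("'K_true' must be positive (semi-)definite", call. = FALSE)
  if (any(cfg$resid_var_by_level <= 0))
    stop("residual variances must all be > 0", call. = FALSE)
  if (length(cfg$resid_var_by_level) != cfg$n_eg_levels)
    stop("'resid_var_by_level' length must equal 'n_eg_levels'", call. = FALSE)
  if (cfg$qtl_prop < 0 || cfg$qtl_prop > 1)
    stop("'qtl_prop' must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents. Each later generation pairs
#' the previous generation's animals into sire x dam matings (random pairing,
#' disjoint parents within a generation) and produces
#' `offspring_per_mating` offspring per mating, so every parent appears
#' before its offspring in the returned table.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with columns `animal`, `sire`, `dam` (NA =
#'   unknown), `sex` ("M"/"F") and `generation`, in topological order.
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n0 <- config$n_founders
  if (config$n_generations >= 1L && n0 < 2L)
    stop("at least 2 founders are required to breed a generation",
         call. = FALSE)
  animal <- seq_len(n0)
  sire <- dam <- rep(NA_integer_, n0)
  sex <- sample(rep_len(c("M", "F"), n0))
  generation <- rep(0L, n0)
  prev <- animal
  prev_sex <- sex
  nxt <- n0 + 1L
  for (g in seq_len(config$n_generations - 1L)) {
    sires <- prev[prev_sex == "M"]
    dams <- prev[prev_sex == "F"]
    n_mat <- min(length(sires), length(dams))
    if (n_mat < 1L)
      stop(sprintf("generation %d has no available sire/dam pairs", g),
           call. = FALSE)
    sires <- sample(sires)[seq_len(n_mat)]
    dams <- sample(dams)[seq_len(n_mat)]
    n_off <- n_mat * config$offspring_per_mating
    off <- seq.int(nxt, length.out = n_off)
    animal <- c(animal, off)
    sire <- c(sire, rep(sires, each = config$offspring_per_mating))
    dam <- c(dam, rep(dams, each = config$offspring_per_mating))
    off_sex <- sample(rep_len(c("M", "F"), n_off))
    sex <- c(sex, off_sex)
    generation <- c(generation, rep(g, n_off))
    prev <- off
    prev_sex <- off_sex
    nxt <- nxt + n_off
  }
  data.frame(animal = animal, sire = sire, dam = dam, sex = sex,
             generation = generation)
}

# positions: evenly spaced, 50 kb apart, 1-based bp
default_marker_map <- function(n_chr, m_per_chr) {
  data.frame(
    chrom = rep(seq_len(n_chr), each = m_per_chr),
    pos = rep(50000L * seq_len(m_per_chr), times = n_chr),
    id = paste0("snp", seq_len(n_chr * m_per_chr))
  )
}

#' Simulate genotypes by gene dropping
#'
#' Founder haplotypes are drawn from per-locus allele frequencies sampled
#' uniformly within `maf_range`; descendants inherit one recombinant gamete
#' from each parent, with `crossovers_per_chr` uniformly placed crossovers
#' per chromosome (default 1), which preserves within-chromosome linkage.
#'
#' @param pedigree output of [simulate_pedigree()] (topologically ordered).
#' @param config the same [sim_config()].
#' @return a `genotype_set`: list with `animal_ids`, `map` (chrom, pos, id),
#'   dosage `matrix` coded 0/1/2 (counted allele = founder minor allele),
#'   `p` observed allele frequencies, and `founder_freq` the generative ones.
#' @export
simulate_genotypes <- function(pedigree, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- nrow(pedigree)
  n_chr <- config$n_chromosomes
  m_chr <- config$snps_per_chromosome
  m <- n_chr * m_chr
  map <- default_marker_map(n_chr, m_chr)
  freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  # two gamete matrices, animals x markers, alleles 0/1
  g1 <- matrix(0L, n, m)
  g2 <- matrix(0L, n, m)
  chr_index <- split(seq_len(m), map$chrom)
  founders <- which(is.na(pedigree$sire) & is.na(pedigree$dam))
  nf <- length(founders)
  g1[founders, ] <- matrix(stats::rbinom(nf * m, 1L, rep(freq, each = nf)),
                           nf, m)
  g2[founders, ] <- matrix(stats::rbinom(nf * m, 1L, rep(freq, each = nf)),
                           nf, m)
  make_gamete <- function(h1, h2) {
    out <- integer(m)
    for (idx in chr_index) {
      k <- length(idx)
      cuts <- sort(sample.int(k - 1L, min(config$crossovers_per_chr, k - 1L)))
      take <- integer(k)
      cur <- sample(c(0L, 1L), 1L)
      bounds <- c(0L, cuts, k)
      for (s in seq_len(length(bounds) - 1L)) {
        seg <- (bounds[s] + 1L):bounds[s + 1L]
        take[seg] <- cur
        cur <- 1L - cur
      }
      out[idx] <- ifelse(take == 0L, h1[idx], h2[idx])
    }
    out
  }
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]
    d <- pedigree$dam[i]
    if (is.na(s) && is.na(d)) next
    si <- match(s, pedigree$animal)
    di <- match(d, pedigree$animal)
    g1[i, ] <- make_gamete(g1[si, ], g2[si, ])
    g2[i, ] <- make_gamete(g1[di, ], g2[di, ])
  }
  dosage <- g1 + g2
  rownames(dosage) <- as.character(pedigree$animal)
  colnames(dosage) <- map$id
  new_genotype_set(pedigree$animal, map, dosage, founder_freq = freq)
}

new_genotype_set <- function(animal_ids, map, dosage, founder_freq = NULL) {
  stopifnot(nrow(dosage) == length(animal_ids), ncol(dosage) == nrow(map))
  p <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(animal_ids = animal_ids, map = map, dosage = dosage,
                 p = p, founder_freq = founder_freq),
            class = "genotype_set")
}

#' @exportS3Method
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d animals x %d markers on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' Subset a genotype set by animal or marker
#'
#' @param g a `genotype_set`.
#' @param animals animal ids to keep (default all).
#' @param markers marker column indices to keep (default all).
#' @export
subset_genotypes <- function(g, animals = NULL, markers = NULL) {
  rows <- if (is.null(animals)) seq_along(g$animal_ids) else
    match(animals, g$animal_ids)
  if (anyNA(rows)) stop("unknown animal id(s) in subset", call. = FALSE)
  cols <- if (is.null(markers)) seq_len(ncol(g$dosage)) else markers
  new_genotype_set(g$animal_ids[rows], g$map[cols, , drop = FALSE],
                   g$dosage[rows, cols, drop = FALSE],
                   founder_freq = g$founder_freq[cols])
}

#' Simulate reaction-norm phenotypes with known genetic architecture
#'
#' Each non-founder animal receives one record
#' \deqn{y = CG + age \cdot \beta_{age} + a_0\phi_0(EG) + a_1\phi_1(EG) + e}
#' where the (intercept, slope) coefficients `(a0, a1)` combine QTL dosage
#' effects with a pedigree polygenic term, scaled so their total covariance
#' approximates `K_true`; `e` has the residual variance of the record's EG
#' level class. Environmental quality is a CG-level standard normal value,
#' standardized over CGs; the same value shifts CG mean performance (scaled
#' by `cg_effect_sd`) and enters the reaction norm through the normalized
#' first-order Legendre basis on the observed gradient range.
#'
#' @param pedigree from [simulate_pedigree()].
#' @param genotypes from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `pheno` (animal, y, cg, age, eg, level), `eg_assign`
#'   (cg, eg, level), `truth` (qtl indices/effects, true coefficients, cg
#'   environment values) and `basis` used for generation.
#' @export
simulate_phenotypes <- function(pedigree, genotypes, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(pedigree)
  m <- ncol(genotypes$dosage)
  K <- config$K_true

  # --- QTL component -------------------------------------------------------
  qtl_idx <- sort(sample.int(m, config$n_qtl))
  a_qtl <- matrix(0, n, 2)
  eff <- matrix(0, config$n_qtl, 2)
  if (config$n_qtl > 0 && config$qtl_prop > 0) {
    eff <- if (config$qtl_equal_effects) {
      # equal expected variance contribution per QTL: beta ~ 1/sqrt(2pq)
      het <- 2 * genotypes$founder_freq[qtl_idx] *
        (1 - genotypes$founder_freq[qtl_idx])
      matrix(sample(c(-1, 1), 2L * config$n_qtl, replace = TRUE),
             ncol = 2) * (1 / sqrt(het)) %*% t(sqrt(diag(K)))
    } else mvrnorm_chol(config$n_qtl, K)
    if (config$qtl_on == "intercept") eff[, 2] <- 0
    if (config$qtl_on == "slope") eff[, 1] <- 0
    Zq <- scale(genotypes$dosage[, qtl_idx, drop = FALSE], scale = FALSE)
    raw <- Zq %*% eff
    target <- config$qtl_prop * K
    if (config$qtl_on == "intercept") target[2, ] <- target[, 2] <- 0
    if (config$qtl_on == "slope") target[1, ] <- target[, 1] <- 0
    M <- cov_match_transform(stats::cov(raw), target)
    a_qtl <- raw %*% t(M)
    eff <- eff %*% t(M)
  }

  # --- polygenic component (pedigree gene flow) ---------------------------
  poly_target <- (1 - config$qtl_prop) * K
  if (config$qtl_on == "intercept") poly_target[2, 2] <- K[2, 2]
  if (config$qtl_on == "slope") poly_target[1, 1] <- K[1, 1]
  if (config$qtl_on != "both") poly_target[1, 2] <- poly_target[2, 1] <- 0
  a_poly <- matrix(0, n, 2)
  if (any(diag(poly_target) > 0)) {
    Lp <- safe_chol(poly_target)
    idx <- match(pedigree$animal, pedigree$animal)
    for (i in seq_len(n)) {
      s <- match(pedigree$sire[i], pedigree$animal)
      d <- match(pedigree$dam[i], pedigree$animal)
      if (is.na(s) && is.na(d)) {
        a_poly[i, ] <- drop(t(Lp) %*% stats::rnorm(2))
      } else {
        pa <- 0.5 * ((if (is.na(s)) c(0, 0) else a_poly[s, ]) +
                     (if (is.na(d)) c(0, 0) else a_poly[d, ]))
        w <- 1 - 0.25 * ((!is.na(s)) + (!is.na(d)))  # Mendelian-sampling var
        a_poly[i, ] <- pa + sqrt(w) * drop(t(Lp) %*% stats::rnorm(2))
      }
    }
  }
  coeffs <- a_qtl + a_poly

  # --- environment ---------------------------------------------------------
  cg_env <- stats::rnorm(config$n_cg)
  cg_env <- (cg_env - mean(cg_env)) / stats::sd(cg_env)
  level <- as.integer(cut(cg_env, breaks = stats::quantile(
    cg_env, probs = seq(0, 1, length.out = config$n_eg_levels + 1L)),
    include.lowest = TRUE))
  basis <- legendre_basis(min(cg_env), max(cg_env))

  recorded <- which(pedigree$generation >= 1L | config$n_generations == 1L)
  nr <- length(recorded)
  cg <- sample.int(config$n_cg, nr, replace = TRUE)
  age <- round(stats::rnorm(nr, 415, 116))
  age <- pmax(age, 200)
  eg <- cg_env[cg]
  phi <- legendre_eval(basis, eg)
  e_sd <- sqrt(config$resid_var_by_level[level[cg]])
  y <- config$cg_effect_sd * cg_env[cg] + config$age_beta * age +
    rowSums(phi * coeffs[recorded, , drop = FALSE]) +
    stats::rnorm(nr, 0, e_sd)

  pheno <- data.frame(animal = pedigree$animal[recorded], y = y, cg = cg,
                      age = age, eg = eg, level = level[cg])
  eg_assign <- data.frame(cg = seq_len(config$n_cg), eg = cg_env,
                          level = level)
  truth <- list(qtl_indices = qtl_idx,
                qtl_intercept_effects = eff[, 1],
                qtl_slope_effects = eff[, 2],
                true_coeffs = coeffs,
                cg_effects = config$cg_effect_sd * cg_env,
                cg_env = cg_env)
  list(pheno = pheno, eg_assign = eg_assign, truth = truth, basis = basis)
}

# draw n rows from N(0, S); tolerates PSD S
mvrnorm_chol <- function(n, S) {
  L <- safe_chol(S)
  matrix(stats::rnorm(n * nrow(S)), n) %*% L
}

safe_chol <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  t(ev$vectors %*% (sqrt(ev$values) * t(ev$vectors)))
}

# M such that M %*% S %*% t(M) = target (both 2x2 PSD, possibly degenerate)
cov_match_transform <- function(S, target) {
  keep <- diag(target) > 0
  M <- matrix(0, 2, 2)
  if (!any(keep)) return(M)
  Ls <- chol(S[keep, keep, drop = FALSE] +
             diag(1e-12, sum(keep)))
  Lt <- safe_chol(target[keep, keep, drop = FALSE])
  M[keep, keep] <- t(Lt) %*% solve(t(Ls))
  M
}
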
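#' Validate and topologically check a pedigree table
#'
#' @param pedigree data.frame with columns `animal`, `sire`, `dam` (NA or 0
#'   meaning unknown).
#' @return the pedigree with parents recoded to NA where unknown, checked so
#'   that ids are unique and every known parent precedes its offspring.
#' @export
check_pedigree <- function(pedigree) {
  ped <- pedigree
  for (col in c("sire", "dam")) {
    v <- ped[[col]]
    v[!is.na(v) & v == 0] <- NA
    ped[[col]] <- v
  }
  if (anyDuplicated(ped$animal))
    stop("duplicated animal ids in pedigree", call. = FALSE)
  pos <- seq_len(nrow(ped))
  names(pos) <- as.character(ped$animal)
  for (col in c("sire", "dam")) {
    pp <- pos[as.character(ped[[col]])]
    known <- !is.na(ped[[col]])
    if (anyNA(pp[known]))
      stop(sprintf("unknown %s id(s) referenced in pedigree", col),
           call. = FALSE)
    if (any(pp[known] >= pos[known]))
      stop("pedigree is not topologically sorted (a parent follows its offspring)",
           call. = FALSE)
  }
  ped
}

ped_parent_index <- function(ped) {
  list(s = match(ped$sire, ped$animal), d = match(ped$dam, ped$animal))
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense recursive construction of A; quadratic in pedigree size, intended
#' for desk-scale pedigrees and as the oracle for [build_A_inverse()].
#'
#' @param pedigree a topologically sorted pedigree table.
#' @return dense symmetric matrix with dimnames = animal ids.
#' @export
build_A <- function(pedigree) {
  ped <- check_pedigree(pedigree)
  n <- nrow(ped)
  pi <- ped_parent_index(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- pi$s[i]; d <- pi$d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (is.na(s)) 0 else A[j, s]) +
                   (if (is.na(d)) 0 else A[j, d]))
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' @param pedigree a topologically sorted pedigree table.
#' @return numeric vector F (0 for non-inbred animals), named by animal id.
#' @export
inbreeding_ml <- function(pedigree) {
  ped <- check_pedigree(pedigree)
  n <- nrow(ped)
  pi <- ped_parent_index(ped)
  s <- pi$s; d <- pi$d
  f <- numeric(n)
  # L[i] holds contributions of ancestors to animal i (Meuwissen & Luo style
  # within-round ancestor accumulation)
  point <- integer(n)
  Fvec <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (is.na(si) || is.na(di)) { Fvec[i] <- 0; next }
    # accumulate path contributions by walking ancestor lists;
    # A_ii = sum_j L_j^2 D_j over i and its ancestors, F_i = A_ii - 1
    L <- numeric(n)
    L[i] <- 1
    AN <- i
    Fi <- -1
    while (length(AN) > 0) {
      j <- max(AN)
      AN <- AN[AN != j]
      sj <- s[j]; dj <- d[j]
      if (!is.na(sj)) {
        if (L[sj] == 0) AN <- c(AN, sj)
        L[sj] <- L[sj] + 0.5 * L[j]
      }
      if (!is.na(dj)) {
        if (L[dj] == 0) AN <- c(AN, dj)
        L[dj] <- L[dj] + 0.5 * L[j]
      }
      # Mendelian sampling variance of j
      fsj <- if (is.na(sj)) -1 else Fvec[sj]
      fdj <- if (is.na(dj)) -1 else Fvec[dj]
      Dj <- 0.5 - 0.25 * (fsj + fdj)
      Fi <- Fi + L[j]^2 * Dj
      L[j] <- 0
    }
    Fvec[i] <- Fi
  }
  names(Fvec) <- as.character(ped$animal)
  Fvec
}

#' Inverse numerator relationship matrix (Henderson's rules)
#'
#' Builds A-inverse directly from pedigree structure. With
#' `with_inbreeding = TRUE` (default) the Mendelian-sampling variances use
#' parental inbreeding from [inbreeding_ml()]; otherwise the classical
#' 1, 4/3, 2 increments apply.
#'
#' @param pedigree a topologically sorted pedigree table.
#' @param with_inbreeding account for inbreeding in the diagonal D.
#' @return sparse symmetric `Matrix::dsCMatrix`, dimnames = animal ids.
#' @export
build_A_inverse <- function(pedigree, with_inbreeding = TRUE) {
  ped <- check_pedigree(pedigree)
  n <- nrow(ped)
  pi <- ped_parent_index(ped)
  Fvec <- if (with_inbreeding) inbreeding_ml(ped) else numeric(n)
  ii <- jj <- integer(9L * n)
  xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    s <- pi$s[i]; d <- pi$d[i]
    fs <- if (is.na(s)) -1 else Fvec[s]
    fd <- if (is.na(d)) -1 else Fvec[d]
    di <- 1 / (0.5 - 0.25 * (fs + fd))
    add(i, i, di)
    par <- c(s, d)[!is.na(c(s, d))]
    for (p in par) {
      add(p, i, -0.5 * di)
      add(i, p, -0.5 * di)
      for (q in par)
        add(p, q, 0.25 * di)
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' Pedigree relationships among the genotyped animals (A22)
#'
#' @param pedigree a topologically sorted pedigree table.
#' @param genotyped ids of genotyped animals (subset of pedigree ids).
#' @return dense symmetric matrix in the order of `genotyped`.
#' @export
build_A22 <- function(pedigree, genotyped) {
  ped <- check_pedigree(pedigree)
  idx <- match(genotyped, ped$animal)
  if (anyNA(idx))
    stop("genotyped ids not all present in pedigree", call. = FALSE)
  A <- build_A(ped)
  A[idx, idx, drop = FALSE]
}

#' Genotype quality control
#'
#' Applies, in order: sample call-rate filter, marker call-rate filter,
#' minor-allele-frequency filter, Mendelian-conflict filter over genotyped
#' parent-offspring pairs (when a pedigree is supplied), and removal of
#' non-autosomal markers (map chromosome labels not coercible to an autosome
#' number). Remaining missing dosages are imputed to `2p` (observed post-QC
#' allele frequency), keeping the centered dosage matrix mean-zero.
#'
#' @param g a `genotype_set` (missing dosage = NA).
#' @param pedigree optional pedigree; Mendelian check skipped if absent.
#' @param min_call_rate minimum per-sample and per-marker call rate.
#' @param min_maf minimum minor allele frequency.
#' @param max_mendelian_conflict maximum tolerated parent-offspring opposing
#'   homozygote rate per marker.
#' @param autosomes_only drop markers with non-autosomal chromosome labels.
#' @return the filtered `genotype_set` with attribute `"qc_report"` (named
#'   counts of removals per rule), also accessible via [qc_report()].
#' @export
qc_genotypes <- function(g, pedigree = NULL, min_call_rate = 0.90,
                         min_maf = 0.05, max_mendelian_conflict = 0.01,
                         autosomes_only = TRUE) {
  dos <- g$dosage
  report <- c(sample_call_rate_removed = 0L, marker_call_rate_removed = 0L,
              maf_removed = 0L, mendel_removed = 0L,
              non_autosomal_removed = 0L)

  cr_sample <- rowMeans(!is.na(dos))
  keep_s <- cr_sample >= min_call_rate
  report["sample_call_rate_removed"] <- sum(!keep_s)
  dos <- dos[keep_s, , drop = FALSE]
  ids <- g$animal_ids[keep_s]

  keep <- rep(TRUE, ncol(dos))
  cr_marker <- colMeans(!is.na(dos))
  rm1 <- keep & cr_marker < min_call_rate
  report["marker_call_rate_removed"] <- sum(rm1)
  keep <- keep & !rm1

  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  rm2 <- keep & (is.na(maf) | maf < min_maf)
  report["maf_removed"] <- sum(rm2)
  keep <- keep & !rm2

  if (!is.null(pedigree)) {
    ped <- check_pedigree(pedigree)
    pairs <- rbind(
      data.frame(off = ped$animal, par = ped$sire),
      data.frame(off = ped$animal, par = ped$dam))
    pairs <- pairs[!is.na(pairs$par), , drop = FALSE]
    oi <- match(as.character(pairs$off), as.character(ids))
    pi_ <- match(as.character(pairs$par), as.character(ids))
    ok <- !is.na(oi) & !is.na(pi_)
    if (any(ok)) {
      O <- dos[oi[ok], , drop = FALSE]
      P <- dos[pi_[ok], , drop = FALSE]
      conflict <- (O == 0L & P == 2L) | (O == 2L & P == 0L)
      informative <- !is.na(O) & !is.na(P)
      rate <- colSums(conflict, na.rm = TRUE) / pmax(colSums(informative), 1L)
      rm3 <- keep & rate > max_mendelian_conflict
      report["mendel_removed"] <- sum(rm3)
      keep <- keep & !rm3
    }
  }

  if (autosomes_only) {
    chr_num <- suppressWarnings(as.numeric(gsub("^(chr|Chr|CHR)", "",
                                                as.character(g$map$chrom))))
    rm4 <- keep & is.na(chr_num)
    report["non_autosomal_removed"] <- sum(rm4)
    keep <- keep & !rm4
  }

  if (!any(keep))
    stop("empty genotype set: all markers removed by QC", call. = FALSE)
  dos <- dos[, keep, drop = FALSE]
  p <- colMeans(dos, na.rm = TRUE) / 2
  if (anyNA(dos)) {
    miss <- which(is.na(dos), arr.ind = TRUE)
    dos[miss] <- 2 * p[miss[, 2]]
  }
  out <- new_genotype_set(ids, g$map[keep, , drop = FALSE], dos,
                          founder_freq = g$founder_freq[keep])
  attr(out, "qc_report") <- report
  out
}

#' @rdname qc_genotypes
#' @export
qc_report <- function(g) attr(g, "qc_report")

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \eqn{G = (M - 2p)(M - 2p)' / (2\sum p_i(1 - p_i))} with M the 0/1/2
#' dosage matrix.
#'
#' @param g a `genotype_set` (QC already applied; markers polymorphic).
#' @param p optional supplied allele frequencies (defaults to observed).
#' @param weights optional positive per-marker weights (diagonal D of the
#'   weighted genomic relationship matrix \eqn{Z D Z' \lambda}).
#' @return dense symmetric matrix, dimnames = animal ids.
#' @export
build_G_vanraden <- function(g, p = NULL, weights = NULL) {
  if (is.null(p)) p <- g$p
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("zero denominator: all markers monomorphic", call. = FALSE)
  Z <- sweep(g$dosage, 2, 2 * p)
  G <- if (is.null(weights)) tcrossprod(Z) / denom else
    tcrossprod(sweep(Z, 2, weights, `*`), Z) / denom
  dimnames(G) <- list(g$animal_ids, g$animal_ids)
  G
}

#' Blend (and optionally tune) G toward A22
#'
#' Tuning rescales G so its mean diagonal and mean off-diagonal match those
#' of A22 (a*G + b); blending then takes
#' \eqn{G^* = (1-\beta) G + \beta A22}, which guarantees invertibility when
#' markers are fewer than genotyped animals.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationships of the genotyped animals.
#' @param blend blending fraction in \[0, 1).
#' @param tune logical; rescale before blending.
#' @return dense symmetric matrix G*.
#' @export
blend_tune_G <- function(G, A22, blend = 0.05, tune = TRUE) {
  if (!is.numeric(blend) || blend < 0 || blend >= 1)
    stop("'blend' must lie in [0, 1)", call. = FALSE)
  if (!all(dim(G) == dim(A22)))
    stop("G and A22 are not conformable", call. = FALSE)
  Gt <- G
  if (tune && nrow(G) > 1L) {
    md_g <- mean(diag(G)); mo_g <- (sum(G) - sum(diag(G))) / (length(G) - nrow(G))
    md_a <- mean(diag(A22)); mo_a <- (sum(A22) - sum(diag(A22))) / (length(A22) - nrow(A22))
    if (abs(md_g - mo_g) > 1e-12) {
      a <- (md_a - mo_a) / (md_g - mo_g)
      b <- md_a - a * md_g
      Gt <- a * G + b
    }
  }
  (1 - blend) * Gt + blend * A22
}

#' Combined pedigree-genomic inverse relationship matrix
#'
#' \deqn{H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1}
#' \end{bmatrix}}
#' with the correction applied only on the genotyped block.
#'
#' @param A_inv sparse inverse numerator relationship matrix (all animals).
#' @param A22 pedigree relationships among genotyped animals.
#' @param G_star (blended) genomic relationship matrix, same order as A22.
#' @param genotyped_index positions of the genotyped animals within the
#'   pedigree ordering of `A_inv`.
#' @return sparse symmetric `Matrix` H-inverse.
#' @export
build_H_inverse <- function(A_inv, A22, G_star, genotyped_index) {
  Hinv <- methods::as(A_inv, "CsparseMatrix")
  if (length(genotyped_index) == 0L) return(Matrix::forceSymmetric(Hinv))
  Gi <- tryCatch(solve(G_star), error = function(e)
    stop("G* is singular; consider blending toward A22", call. = FALSE))
  Ai <- tryCatch(solve(A22), error = function(e)
    stop("A22 is singular", call. = FALSE))
  corr <- Gi - Ai
  Hinv <- methods::as(Hinv, "generalMatrix")
  Hinv[genotyped_index, genotyped_index] <-
    Hinv[genotyped_index, genotyped_index] + corr
  Matrix::forceSymmetric(Matrix::drop0(Hinv))
}
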
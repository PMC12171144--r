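#' First-order normalized Legendre basis on a gradient domain
#'
#' The environmental gradient domain `(eg_min, eg_max)` is mapped linearly
#' to \[-1, 1\]; the normalized Legendre polynomials are
#' \eqn{\phi_0 = \sqrt{1/2}} and \eqn{\phi_1(x) = \sqrt{3/2}\, x}, orthonormal
#' on \[-1, 1\].
#'
#' @param eg_min,eg_max domain of the standardized gradient.
#' @param order polynomial order (only 0 and 1 supported; default 1).
#' @param normalized use the orthonormal scaling (default TRUE).
#' @return object of class `legendre_basis`.
#' @export
legendre_basis <- function(eg_min, eg_max, order = 1L, normalized = TRUE) {
  if (!is.finite(eg_min) || !is.finite(eg_max) || eg_min >= eg_max)
    stop("degenerate domain: eg_min must be < eg_max", call. = FALSE)
  if (order > 1L) stop("only order <= 1 is implemented", call. = FALSE)
  structure(list(order = as.integer(order), eg_min = eg_min, eg_max = eg_max,
                 normalized = normalized),
            class = "legendre_basis")
}

#' Evaluate the Legendre covariables at gradient values
#'
#' Values outside the basis domain are clamped to it with a warning
#' (prediction use).
#'
#' @param basis a [legendre_basis()].
#' @param eg numeric vector of gradient values.
#' @return matrix with `length(eg)` rows and `order + 1` columns.
#' @export
legendre_eval <- function(basis, eg) {
  if (any(eg < basis$eg_min - 1e-12 | eg > basis$eg_max + 1e-12))
    warning("gradient value(s) outside basis domain; clamped")
  eg <- pmin(pmax(eg, basis$eg_min), basis$eg_max)
  x <- -1 + 2 * (eg - basis$eg_min) / (basis$eg_max - basis$eg_min)
  k0 <- if (basis$normalized) sqrt(1 / 2) else 1
  k1 <- if (basis$normalized) sqrt(3 / 2) else 1
  out <- cbind(phi0 = rep(k0, length(x)))
  if (basis$order >= 1L) out <- cbind(out, phi1 = k1 * x)
  out
}

#' Environmental gradient from contemporary-group BLUEs
#'
#' Step 1 of the two-step reaction-norm analysis: fits the animal model
#' `y = CG + age + animal + e` for the gradient trait (average daily gain)
#' with pedigree covariance `A sigma_a^2`, extracts the CG BLUEs, and
#' standardizes them to mean 0, SD 1 (sample SD) over CGs. Each record is
#' assigned its CG's gradient value; discrete level classes for
#' heterogeneous residual variances are formed by quantile binning.
#'
#' @param pheno data.frame with `animal`, `y`, `cg`, `age`.
#' @param pedigree pedigree covering all phenotyped animals.
#' @param A_inv optional precomputed sparse A-inverse (else built here).
#' @param h2 assumed heritability of the gradient trait (variance ratio
#'   lambda = (1 - h2)/h2); default 0.3.
#' @param n_levels number of discrete EG level classes (default 17 or the
#'   number of CGs, whichever is smaller).
#' @return `eg_assignment`: list with `cg_table` (cg, blue, eg, level) and
#'   `record_eg`/`record_level` aligned to `pheno` rows.
#' @export
estimate_eg <- function(pheno, pedigree, A_inv = NULL, h2 = 0.3,
                        n_levels = NULL) {
  ped <- check_pedigree(pedigree)
  if (!all(as.character(pheno$animal) %in% as.character(ped$animal)))
    stop("phenotyped animals missing from pedigree", call. = FALSE)
  cgs <- sort(unique(pheno$cg))
  if (any(tabulate(match(pheno$cg, cgs)) == 0L))
    stop("contemporary group with zero records", call. = FALSE)
  if (is.null(A_inv)) A_inv <- build_A_inverse(ped)
  lambda <- (1 - h2) / h2

  n <- nrow(pheno)
  q <- nrow(ped)
  cg_idx <- match(pheno$cg, cgs)
  X <- Matrix::sparseMatrix(i = seq_len(n), j = cg_idx, x = 1,
                            dims = c(n, length(cgs)))
  X <- cbind(X, Matrix::Matrix(pheno$age - mean(pheno$age), ncol = 1))
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = match(as.character(pheno$animal),
                                      as.character(ped$animal)),
                            x = 1, dims = c(n, q))
  C <- rbind(cbind(Matrix::crossprod(X), Matrix::crossprod(X, Z)),
             cbind(Matrix::crossprod(Z, X),
                   Matrix::crossprod(Z) + lambda * A_inv))
  r <- c(as.vector(Matrix::crossprod(X, pheno$y)),
         as.vector(Matrix::crossprod(Z, pheno$y)))
  sol <- tryCatch(
    as.vector(Matrix::solve(Matrix::forceSymmetric(C), r)),
    error = function(e)
      stop("confounded CG/animal structure: the step-1 equations are singular",
           call. = FALSE))
  blue <- sol[seq_along(cgs)]
  eg <- (blue - mean(blue)) / stats::sd(blue)
  if (is.null(n_levels)) n_levels <- min(17L, length(cgs))
  level <- bin_levels(eg, n_levels)
  cg_table <- data.frame(cg = cgs, blue = blue, eg = eg, level = level)
  list(cg_table = cg_table,
       record_eg = eg[cg_idx],
       record_level = level[cg_idx])
}

bin_levels <- function(eg, n_levels) {
  if (n_levels >= length(unique(eg)))
    return(as.integer(factor(rank(eg, ties.method = "min"))))
  br <- unique(stats::quantile(eg, probs = seq(0, 1, length.out = n_levels + 1L)))
  as.integer(cut(eg, breaks = br, include.lowest = TRUE))
}

# --- mixed-model equation assembly for the single-step reaction norm -------

# Builds the pieces shared by solve_ssbrn() and gibbs_components().
# Returns design matrices, residual-level index and bookkeeping.
ssbrn_design <- function(pheno, pedigree, basis, report_aliased = TRUE) {
  ped <- check_pedigree(pedigree)
  n <- nrow(pheno)
  q <- nrow(ped)
  if (!all(c("eg", "level") %in% names(pheno)))
    stop("phenotypes must carry 'eg' and 'level' (run estimate_eg first)",
         call. = FALSE)
  phi <- legendre_eval(basis, pheno$eg)
  cgs <- sort(unique(pheno$cg))
  Xcg <- Matrix::sparseMatrix(i = seq_len(n), j = match(pheno$cg, cgs),
                              x = 1, dims = c(n, length(cgs)))
  Xother <- cbind(age = pheno$age - mean(pheno$age), phi)
  X <- cbind(Xcg, Matrix::Matrix(Xother, sparse = TRUE))
  colnames(X) <- c(paste0("cg", cgs), "age", colnames(phi))
  # drop aliased fixed columns (phi columns are CG-level covariates, hence
  # aliased with the CG dummies whenever full dummies are fitted)
  qrX <- qr(as.matrix(Matrix::crossprod(X)), tol = 1e-8)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  aliased <- colnames(X)[-keep]
  if (length(aliased) && report_aliased)
    message("dropping aliased fixed effect(s): ",
            paste(aliased, collapse = ", "))
  X <- X[, keep, drop = FALSE]

  ai <- match(as.character(pheno$animal), as.character(ped$animal))
  if (anyNA(ai)) stop("phenotyped animal missing from pedigree", call. = FALSE)
  # W: n x 2q, animal-major coefficient order (a_i0, a_i1)
  W <- Matrix::sparseMatrix(i = rep(seq_len(n), 2L),
                            j = c(2L * ai - 1L, 2L * ai),
                            x = c(phi[, 1], phi[, 2]),
                            dims = c(n, 2L * q))
  level <- as.integer(pheno$level)
  list(X = X, W = W, y = pheno$y, level = level,
       n_levels = max(level), animal_ids = ped$animal, n_fixed = ncol(X),
       fixed_names = colnames(X), aliased = aliased, q = q)
}

# Kronecker H^-1 (x) K^-1 for animal-major 2-coefficient ordering
kron_hinv_kinv <- function(H_inv, K_inv) {
  Matrix::forceSymmetric(
    methods::as(kronecker(methods::as(H_inv, "generalMatrix"), K_inv),
                "CsparseMatrix"))
}

assemble_mme <- function(des, H_inv, K, R_levels) {
  rinv <- 1 / R_levels[des$level]
  S <- cbind(des$X, des$W)
  Srw <- Matrix::Diagonal(x = rinv) %*% S   # row-scaled
  C <- Matrix::forceSymmetric(Matrix::crossprod(S, Srw))
  r <- as.vector(Matrix::crossprod(Srw, des$y))
  K_inv <- solve(K)
  prior <- kron_hinv_kinv(H_inv, K_inv)
  p <- des$n_fixed
  idx <- (p + 1L):(p + 2L * des$q)
  C <- methods::as(C, "generalMatrix")
  C[idx, idx] <- C[idx, idx] + prior
  list(C = Matrix::forceSymmetric(Matrix::drop0(C)), r = r)
}

#' Solve the single-step reaction-norm mixed-model equations
#'
#' Assembles and solves the sparse MME for the model
#' `y = CG + age + (fixed regression) + sum_f a_f phi_f(EG) + e` with random
#' per-animal (intercept, slope) coefficients of covariance `H (x) K` and
#' heterogeneous diagonal residual variance by EG level class. The fixed
#' regression on the covariables is aliased with the CG dummies whenever the
#' gradient is CG-level; aliased columns are dropped and reported.
#'
#' @param pheno data.frame with `animal`, `y`, `cg`, `age`, `eg`, `level`.
#' @param pedigree pedigree table (defines the order of `H_inv`).
#' @param H_inv sparse combined inverse relationship matrix (all animals).
#' @param basis a [legendre_basis()].
#' @param K 2x2 covariance of the random regression coefficients.
#' @param R_levels residual variance per EG level class.
#' @return `rn_solution`: list with `fixed` (named vector), `coeffs`
#'   (animals x 2 matrix of intercept/slope BLUPs), `K`, `R_levels`,
#'   `basis`, `aliased`, and the MME residual norm `mme_resid`.
#' @export
solve_ssbrn <- function(pheno, pedigree, H_inv, basis, K, R_levels) {
  if (any(eigen(K, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("K must be positive definite", call. = FALSE)
  if (max(as.integer(pheno$level)) > length(R_levels))
    stop("R_levels shorter than the number of EG level classes", call. = FALSE)
  des <- ssbrn_design(pheno, pedigree, basis)
  mme <- assemble_mme(des, H_inv, K, R_levels)
  sol <- as.vector(Matrix::solve(mme$C, mme$r))
  p <- des$n_fixed
  coeffs <- matrix(sol[-seq_len(p)], ncol = 2, byrow = TRUE,
                   dimnames = list(des$animal_ids, c("intercept", "slope")))
  fixed <- stats::setNames(sol[seq_len(p)], des$fixed_names)
  resid <- sqrt(sum(as.vector(mme$C %*% sol - mme$r)^2))
  structure(list(fixed = fixed, coeffs = coeffs, K = K,
                 R_levels = R_levels, basis = basis, aliased = des$aliased,
                 mme_resid = resid),
            class = "rn_solution")
}

#' @exportS3Method
print.rn_solution <- function(x, ...) {
  cat(sprintf("rn_solution: %d animals, %d fixed effects (%d aliased dropped)\n",
              nrow(x$coeffs), length(x$fixed), length(x$aliased)))
  cat("K:\n"); print(x$K)
  invisible(x)
}

#' Genomic breeding value at a gradient value
#'
#' \eqn{GEBV(EG) = a_0\phi_0(EG) + a_1\phi_1(EG)}.
#'
#' @param solution an `rn_solution`.
#' @param animals animal ids (default all).
#' @param eg gradient value(s).
#' @return matrix animals x length(eg) of breeding values.
#' @export
gebv_at <- function(solution, eg, animals = NULL) {
  co <- solution$coeffs
  if (!is.null(animals)) {
    idx <- match(as.character(animals), rownames(co))
    if (anyNA(idx)) stop("unknown animal id(s)", call. = FALSE)
    co <- co[idx, , drop = FALSE]
  }
  phi <- legendre_eval(solution$basis, eg)
  out <- co %*% t(phi)
  colnames(out) <- format(eg, trim = TRUE)
  out
}
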
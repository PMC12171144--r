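#' Gibbs sampling of reaction-norm variance components
#'
#' Block Gibbs sampler for the single-step reaction-norm model. Each cycle:
#' (1) all location parameters (fixed effects plus per-animal
#' intercept/slope coefficients) are drawn jointly from their multivariate
#' normal full conditional `N(C^-1 r, C^-1)` using a cached sparse Cholesky
#' factorization; (2) the 2x2 coefficient covariance `K` is drawn from its
#' inverse-Wishart full conditional; (3) each residual-class variance is
#' drawn from its scaled inverse chi-square full conditional. Priors are
#' weakly informative: `K ~ IW(nu0 = 4, S0 = 0.5 * K_start)` and
#' `sigma_l^2 ~ scaled-inv-chisq(nu = 4, s2 = R_start_l)`, both
#' configurable.
#'
#' @param pheno data.frame with `animal`, `y`, `cg`, `age`, `eg`, `level`.
#' @param pedigree pedigree table defining the order of `H_inv`.
#' @param H_inv sparse combined inverse relationship matrix.
#' @param basis a [legendre_basis()].
#' @param chain list with `n` (total cycles), `burn` (burn-in cycles) and
#'   `thin` (storage interval); desk-scale default 20000/4000/10. The
#'   full-scale protocol (500000/50000/10) is reached by passing it here.
#' @param start list with starting `K` (2x2) and `R_levels`.
#' @param priors list with `K_nu`, `K_S` (defaults 4 and `0.5 * start$K`),
#'   `R_nu`, `R_s2` (defaults 4 and `start$R_levels`).
#' @param seed integer seed; two runs with the same seed give identical
#'   chains.
#' @param keep_coeffs also return posterior-mean location solutions.
#' @return `gibbs_fit`: list with `K` and `R_levels` posterior means,
#'   `chain` (stored samples, columns K11, K12, K22, R1..RL), `coeffs`
#'   posterior-mean animal solutions, `settings`.
#' @export
gibbs_components <- function(pheno, pedigree, H_inv, basis,
                             chain = list(n = 20000L, burn = 4000L, thin = 10L),
                             start = NULL, priors = NULL, seed = 1L,
                             keep_coeffs = TRUE) {
  if (chain$n <= chain$burn)
    stop("chain length must exceed burn-in", call. = FALSE)
  des <- ssbrn_design(pheno, pedigree, basis)
  # residual classes: contiguous renumbering of the levels present in data
  lev_labels <- sort(unique(des$level))
  lev <- match(des$level, lev_labels)
  nlev <- length(lev_labels)
  if (is.null(start))
    start <- list(K = matrix(c(0.3, 0, 0, 0.15), 2), R_levels = rep(0.8, nlev))
  if (length(start$R_levels) < max(lev_labels))
    stop("start$R_levels shorter than number of EG level classes", call. = FALSE)
  if (is.null(priors)) priors <- list()
  K_nu <- priors$K_nu %||% 4
  K_S <- priors$K_S %||% (0.5 * start$K)
  R_nu <- priors$R_nu %||% 4
  R_s2 <- (priors$R_s2 %||% start$R_levels)[lev_labels]
  if (K_nu <= 3 || R_nu <= 2)
    stop("improper prior settings: K_nu must exceed dim + 1 and R_nu > 2",
         call. = FALSE)

  set.seed(seed)
  q <- des$q
  p <- des$n_fixed
  S <- cbind(des$X, des$W)
  y <- des$y
  lev_rows <- split(seq_along(y), lev)
  # per-level Gram pieces so C can be reassembled cheaply each cycle
  M_l <- lapply(lev_rows, function(rr)
    Matrix::forceSymmetric(Matrix::crossprod(S[rr, , drop = FALSE])))
  v_l <- lapply(lev_rows, function(rr)
    as.vector(Matrix::crossprod(S[rr, , drop = FALSE], y[rr])))
  n_l <- lengths(lev_rows)
  idx_rand <- (p + 1L):(p + 2L * q)

  Hg <- methods::as(H_inv, "generalMatrix")
  K <- start$K
  R <- start$R_levels[lev_labels]

  # --- precomputed triplet assembly of C (upper triangle) ------------------
  # data part: per-level Gram triplets tagged by level
  dimC <- p + 2L * q
  tri_u <- function(M) {
    Tm <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
    keep <- Tm@i <= Tm@j
    list(i = Tm@i[keep] + 1L, j = Tm@j[keep] + 1L, x = Tm@x[keep])
  }
  data_tri <- lapply(M_l, tri_u)
  di <- unlist(lapply(data_tri, `[[`, "i"))
  dj <- unlist(lapply(data_tri, `[[`, "j"))
  dx0 <- unlist(lapply(data_tri, `[[`, "x"))
  dtag <- rep.int(seq_len(nlev), vapply(data_tri, function(t)
    length(t$x), integer(1)))
  # prior part: kron(H^-1, K^-1) upper triangle from H^-1's upper triangle
  Ht <- tri_u(Matrix::forceSymmetric(Hg))
  off_diag <- Ht$i < Ht$j
  # off-diagonal H blocks contribute all four K^-1 cells; diagonal blocks
  # only the upper three
  mk_idx <- function(hi, hj, cells) {
    list(i = rep(2L * (hi - 1L), each = length(cells$a)) + cells$a + p,
         j = rep(2L * (hj - 1L), each = length(cells$b)) + cells$b + p,
         a = rep(cells$a, times = length(hi)),
         b = rep(cells$b, times = length(hi)),
         h = rep(0, length(hi) * length(cells$a)))
  }
  cells4 <- list(a = c(1L, 1L, 2L, 2L), b = c(1L, 2L, 1L, 2L))
  cells3 <- list(a = c(1L, 1L, 2L), b = c(1L, 2L, 2L))
  po <- mk_idx(Ht$i[off_diag], Ht$j[off_diag], cells4)
  po$h <- rep(Ht$x[off_diag], each = 4L)
  pd <- mk_idx(Ht$i[!off_diag], Ht$j[!off_diag], cells3)
  pd$h <- rep(Ht$x[!off_diag], each = 3L)
  pi_ <- c(po$i, pd$i)
  pj <- c(po$j, pd$j)
  pa <- c(po$a, pd$a)
  pb <- c(po$b, pd$b)
  ph <- c(po$h, pd$h)
  pcell <- (pa - 1L) * 2L + pb  # index into as.vector(K_inv) (column-major ok: symmetric)

  build_C <- function(K, R) {
    Kinv <- solve(K)
    x <- c(dx0 / R[dtag], ph * as.vector(Kinv)[pcell])
    Matrix::sparseMatrix(i = c(di, pi_), j = c(dj, pj), x = x,
                         dims = c(dimC, dimC), symmetric = TRUE)
  }
  C0 <- build_C(K, R)
  ch <- Matrix::Cholesky(C0, LDL = FALSE, perm = TRUE)
  dimC <- nrow(C0)

  n_store <- (chain$n - chain$burn) %/% chain$thin
  samp <- matrix(NA_real_, n_store, 3L + nlev)
  colnames(samp) <- c("K11", "K12", "K22", paste0("R", lev_labels))
  coeff_sum <- numeric(dimC)
  stored <- 0L

  for (it in seq_len(chain$n)) {
    C <- build_C(K, R)
    ch <- Matrix::.updateCHMfactor(ch, methods::as(C, "CsparseMatrix"), mult = 0)
    r <- v_l[[1]] * (1 / R[1])
    for (l in seq_len(nlev)[-1]) r <- r + v_l[[l]] * (1 / R[l])
    mu <- Matrix::solve(ch, r)
    z <- stats::rnorm(dimC)
    theta <- as.vector(mu + Matrix::solve(
      ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt"))

    # K | coefficients: inverse Wishart
    Tm <- matrix(theta[idx_rand], ncol = 2, byrow = TRUE)
    Sq <- as.matrix(crossprod(Tm, as.matrix(Hg %*% Tm)))
    K <- rinvwishart(K_nu + q, K_S + Sq)

    # residual variances | rest: scaled inverse chi-square per level
    e <- y - as.vector(S %*% theta)
    for (l in seq_len(nlev)) {
      sse <- sum(e[lev_rows[[l]]]^2)
      df <- R_nu + n_l[l]
      R[l] <- (R_nu * R_s2[l] + sse) / stats::rchisq(1L, df)
    }

    if (it > chain$burn && (it - chain$burn) %% chain$thin == 0L) {
      stored <- stored + 1L
      samp[stored, ] <- c(K[1, 1], K[1, 2], K[2, 2], R)
      coeff_sum <- coeff_sum + theta
    }
  }

  post <- colMeans(samp)
  K_hat <- matrix(c(post["K11"], post["K12"], post["K12"], post["K22"]), 2, 2,
                  dimnames = list(c("intercept", "slope"),
                                  c("intercept", "slope")))
  coeffs <- NULL
  if (keep_coeffs && stored > 0L) {
    th <- coeff_sum / stored
    coeffs <- matrix(th[idx_rand], ncol = 2, byrow = TRUE,
                     dimnames = list(des$animal_ids, c("intercept", "slope")))
  }
  structure(list(K = K_hat,
                 R_levels = unname(post[-(1:3)]),
                 chain = samp, coeffs = coeffs,
                 settings = list(chain = chain, priors = list(
                   K_nu = K_nu, K_S = K_S, R_nu = R_nu, R_s2 = R_s2),
                   seed = seed)),
            class = "gibbs_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw from inverse-Wishart(nu, S): X^-1 with X ~ Wishart(nu, S^-1)
rinvwishart <- function(nu, S) {
  W <- stats::rWishart(1L, nu, solve(S))[, , 1]
  solve(W)
}

#' Geweke convergence diagnostic
#'
#' Compares the means of the first and last segments of each stored chain,
#' \eqn{z = (\bar x_1 - \bar x_2) / \sqrt{s_1/n_1 + s_2/n_2}}, where the
#' segment variances are spectral-density-at-zero estimates (AR fit, as in
#' standard MCMC practice). A chain with (numerically) zero variance is
#' flagged and given z = 0.
#'
#' @param chain numeric vector or matrix of stored samples (columns =
#'   parameters).
#' @param first_frac,last_frac fractions of the chain used for the early and
#'   late segments (defaults 0.1 and 0.5).
#' @return data.frame with `parameter`, `z` and `degenerate` flag.
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  x <- as.matrix(chain)
  n <- nrow(x)
  if (n < 50L) stop("need at least 50 stored samples", call. = FALSE)
  n1 <- max(2L, floor(first_frac * n))
  n2 <- max(2L, floor(last_frac * n))
  res <- lapply(seq_len(ncol(x)), function(j) {
    a <- x[seq_len(n1), j]
    b <- x[(n - n2 + 1L):n, j]
    if (stats::var(x[, j]) < 1e-300 || (stats::var(a) == 0 && stats::var(b) == 0))
      return(c(z = 0, degenerate = 1))
    sv1 <- coda::spectrum0.ar(a)$spec
    sv2 <- coda::spectrum0.ar(b)$spec
    c(z = (mean(a) - mean(b)) / sqrt(sv1 / n1 + sv2 / n2), degenerate = 0)
  })
  res <- do.call(rbind, res)
  data.frame(parameter = colnames(x) %||% paste0("V", seq_len(ncol(x))),
             z = res[, "z"], degenerate = as.logical(res[, "degenerate"]))
}
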
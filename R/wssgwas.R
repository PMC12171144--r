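#' Back-solve genomic breeding values into SNP effects
#'
#' Implements \eqn{\hat u = \lambda D Z_g' (Z_g D Z_g' \lambda)^{-1} \hat
#' a_g}, applied independently to the intercept and slope solution vectors
#' of the genotyped animals. `Z_g` is the dosage matrix centered by `2p`;
#' \eqn{\lambda = 1/(2\sum p_i(1-p_i))} matches the scaling used to build
#' G. When the matrix inverted here is exactly the (unblended) G* used in
#' the mixed model, the re-prediction `Z_g uhat` reproduces `a_g`.
#'
#' @param a_g matrix (genotyped animals x 2) of intercept/slope BLUPs, rows
#'   ordered like `g$animal_ids`.
#' @param g the genotyped `genotype_set` (after QC).
#' @param D per-marker positive weights (default 1 = unweighted).
#' @param G_star optional relationship matrix to invert (e.g. the blended
#'   G* used in the MME); default `Z_g D Z_g' lambda` built here.
#' @param p allele frequencies used for centering and lambda (default the
#'   observed ones; note that with observed frequencies `Z_g Z_g'` is always
#'   singular because centered columns sum to zero, so either supply base
#'   frequencies, blend, or pass the G* used in the MME).
#' @param iteration bookkeeping label for the weighting round.
#' @return `snp_effect_set`: list with `effects` (markers x 2), `D`, `p`,
#'   `lambda`, `map`, `iteration`.
#' @export
backsolve_snp_effects <- function(a_g, g, D = NULL, G_star = NULL,
                                  p = NULL, iteration = 1L) {
  m <- ncol(g$dosage)
  if (is.null(D)) D <- rep(1, m)
  if (length(D) != m) stop("weight vector length mismatch", call. = FALSE)
  if (any(D <= 0)) stop("weights must be strictly positive", call. = FALSE)
  a_g <- as.matrix(a_g)
  if (nrow(a_g) != nrow(g$dosage))
    stop("dimension mismatch between solutions and genotypes", call. = FALSE)
  if (is.null(p)) p <- g$p
  lambda <- 1 / (2 * sum(p * (1 - p)))
  Z <- sweep(g$dosage, 2, 2 * p)
  if (is.null(G_star))
    G_star <- tcrossprod(sweep(Z, 2, D, `*`), Z) * lambda
  rhs <- tryCatch(solve(G_star, a_g), error = function(e)
    stop("singular Z_g D Z_g' lambda; consider blending toward A22",
         call. = FALSE))
  u <- lambda * D * crossprod(Z, rhs)
  colnames(u) <- c("intercept", "slope")[seq_len(ncol(u))]
  rownames(u) <- g$map$id
  structure(list(effects = u, D = D, p = p, lambda = lambda, map = g$map,
                 iteration = iteration),
            class = "snp_effect_set")
}

#' @exportS3Method
print.snp_effect_set <- function(x, ...) {
  cat(sprintf("snp_effect_set: %d markers, iteration %d\n",
              nrow(x$effects), x$iteration))
  invisible(x)
}

#' Per-SNP variance weight
#'
#' \eqn{d_i = \hat u_i^2 \, 2 p_i (1 - p_i)}.
#'
#' @param u SNP effect(s).
#' @param p allele frequency(ies) in (0, 1).
#' @return raw (unnormalized) weight(s).
#' @export
snp_weight <- function(u, p) {
  if (any(p <= 0 | p >= 1)) stop("allele frequencies must be in (0,1)",
                                 call. = FALSE)
  u^2 * 2 * p * (1 - p)
}

#' Normalize SNP weights to conserve total genetic variance
#'
#' Rescales the raw weights so that \eqn{\sum_i d_i 2 p_i (1 - p_i)} equals
#' its unweighted (D = I) value; zero raw weights are floored at a small
#' positive constant to keep D invertible.
#'
#' @param d raw weights (non-negative, at least one positive).
#' @param p allele frequencies.
#' @param floor value assigned to zero weights after scaling (default 1e-8).
#' @return normalized weight vector D.
#' @export
normalize_weights <- function(d, p, floor = 1e-8) {
  if (all(d <= 0)) stop("all-zero weights cannot be normalized", call. = FALSE)
  het <- 2 * p * (1 - p)
  d2 <- d * sum(het) / sum(d * het)
  d2[d2 < floor] <- floor
  d2
}

#' Weighted single-step reaction-norm GWAS
#'
#' Runs the iterative weighting loop: iteration 1 uses D = I to build the
#' (tuned/blended) genomic relationship, solve the reaction-norm MME via
#' H-inverse, and back-solve the genotyped animals' intercept/slope BLUPs
#' into SNP effects; iteration 2 (default, per the two-iteration protocol)
#' recomputes D from the iteration-1 effects, rebuilds the weighted G*, and
#' re-solves. `n_iterations = 1` reduces to the unweighted single-step GWAS.
#'
#' Weights are computed per coefficient and combined into the single D used
#' in the weighted G by `weight_combine`: mean of the two weight shares
#' (default), or intercept-only / slope-only.
#'
#' @param pheno phenotype table with `animal`, `y`, `cg`, `age`, `eg`,
#'   `level`.
#' @param pedigree pedigree table.
#' @param g genotyped `genotype_set` (QC applied); its animals must appear
#'   in the pedigree.
#' @param basis a [legendre_basis()].
#' @param K,R_levels variance components for the MME.
#' @param n_iterations number of weighting rounds (default 2).
#' @param blend,tune passed to [blend_tune_G()].
#' @param weight_combine "mean", "intercept" or "slope".
#' @param A_inv,A22 optional precomputed pedigree matrices.
#' @return list of `snp_effect_set` per iteration (attribute
#'   `"solution"` on each carries the fitted `rn_solution`).
#' @export
run_wssgwas <- function(pheno, pedigree, g, basis, K, R_levels,
                        n_iterations = 2L, blend = 0.05, tune = TRUE,
                        weight_combine = c("mean", "intercept", "slope"),
                        A_inv = NULL, A22 = NULL) {
  weight_combine <- match.arg(weight_combine)
  ped <- check_pedigree(pedigree)
  poly <- g$p > 0 & g$p < 1
  if (!all(poly)) {
    message(sum(!poly), " marker(s) monomorphic within the genotyped set; dropped")
    g <- subset_genotypes(g, markers = which(poly))
  }
  gen_idx <- match(as.character(g$animal_ids), as.character(ped$animal))
  if (anyNA(gen_idx))
    stop("stage relationships: genotyped animals missing from pedigree",
         call. = FALSE)
  if (is.null(A_inv)) A_inv <- build_A_inverse(ped)
  if (is.null(A22)) A22 <- build_A22(ped, g$animal_ids)

  m <- ncol(g$dosage)
  D <- rep(1, m)
  out <- vector("list", n_iterations)
  for (iter in seq_len(n_iterations)) {
    G <- build_G_vanraden(g, weights = D)
    G_star <- blend_tune_G(G, A22, blend = blend, tune = tune)
    H_inv <- build_H_inverse(A_inv, A22, G_star, gen_idx)
    sol <- solve_ssbrn(pheno, ped, H_inv, basis, K, R_levels)
    a_g <- sol$coeffs[gen_idx, , drop = FALSE]
    eff <- backsolve_snp_effects(a_g, g, D = D, G_star = G_star,
                                 iteration = iter)
    attr(eff, "solution") <- sol
    out[[iter]] <- eff
    if (iter < n_iterations) {
      d_int <- snp_weight(eff$effects[, 1], g$p)
      d_slo <- snp_weight(eff$effects[, 2], g$p)
      d_raw <- switch(weight_combine,
                      mean = (d_int / sum(d_int) + d_slo / sum(d_slo)) / 2,
                      intercept = d_int,
                      slope = d_slo)
      D <- normalize_weights(d_raw, g$p)
    }
  }
  out
}

#' Moving-window partition of additive genetic variance
#'
#' For each window of `window_size` adjacent same-chromosome SNPs (sliding
#' by `step`), computes the variance across genotyped animals of the
#' window's aggregate genotypic value \eqn{\sum_j Z_j \hat u_j} and
#' expresses it as a percentage of the additive genetic variance
#' `sigma_a2`, separately for intercept and slope effects. Windows never
#' cross chromosome boundaries; a trailing
#' shorter window at a chromosome end is reported but flagged incomplete.
#'
#' @param effects a `snp_effect_set`.
#' @param g the genotyped `genotype_set` (same markers).
#' @param sigma_a2 length-2 vector: the additive genetic variance used as
#'   denominator for the intercept and slope scans. Default (NULL) is the
#'   marker-explained additive variance, i.e. the variance across genotyped
#'   animals of the whole-genome aggregate \eqn{Z\hat u} per coefficient --
#'   the convention under which published window percentages sum to
#'   meaningful totals. Pass the K diagonal explicitly to express windows
#'   against the parametric genetic variance instead.
#' @param window_size number of SNPs per window (default 100).
#' @param step sliding step in SNPs (default 1).
#' @return data.frame with `chrom`, `start_idx`, `end_idx`, `start_bp`,
#'   `end_bp`, `n_snps`, `complete`, `pct_intercept`, `pct_slope`.
#' @export
window_variance <- function(effects, g, sigma_a2 = NULL, window_size = 100L,
                            step = 1L) {
  if (!identical(effects$map$id, g$map$id))
    stop("effects and genotype map are not aligned", call. = FALSE)
  Z <- sweep(g$dosage, 2, 2 * g$p)
  if (is.null(sigma_a2)) {
    agg <- Z %*% effects$effects
    sigma_a2 <- apply(agg, 2, stats::var)
    if (any(sigma_a2 == 0)) sigma_a2[sigma_a2 == 0] <- 1  # all-zero effects
  }
  map <- g$map
  res <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    k <- length(idx)
    if (k < window_size) {
      warning(sprintf("chromosome %s has fewer than %d markers; skipped",
                      chr, window_size))
      next
    }
    starts <- seq.int(1L, k, by = step)
    for (s in starts) {
      e <- min(s + window_size - 1L, k)
      cols <- idx[s:e]
      gi <- Z[, cols, drop = FALSE] %*% effects$effects[cols, 1]
      gs <- Z[, cols, drop = FALSE] %*% effects$effects[cols, 2]
      res[[length(res) + 1L]] <- data.frame(
        chrom = chr, start_idx = cols[1], end_idx = cols[length(cols)],
        start_bp = map$pos[cols[1]], end_bp = map$pos[cols[length(cols)]],
        n_snps = length(cols), complete = length(cols) == window_size,
        pct_intercept = 100 * stats::var(as.vector(gi)) / sigma_a2[1],
        pct_slope = 100 * stats::var(as.vector(gs)) / sigma_a2[2])
      if (e == k) break
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select relevant non-overlapping windows above a threshold
#'
#' Greedy deduplication of moving windows: repeatedly take the
#' highest-percentage remaining window, discard all windows sharing any
#' marker (or, when marker indices are absent, any base-pair overlap on the
#' same chromosome) with it, and keep those at or above `threshold_pct`.
#' Incomplete (short trailing) windows are excluded from selection.
#'
#' @param windows data.frame of windows; must carry `chrom` plus a
#'   percentage column and either `start_idx`/`end_idx` or
#'   `start_bp`/`end_bp`.
#' @param pct_col name of the percentage column (default "pct", falling
#'   back to "pct_slope" then "pct_intercept" if absent).
#' @param threshold_pct relevance threshold (default 1, i.e. windows
#'   explaining at least 1% of the additive genetic variance).
#' @return list with `selected` (ranked data.frame) and `summary`
#'   (`n_windows`, `total_pct`).
#' @export
select_windows <- function(windows, pct_col = NULL, threshold_pct = 1.0) {
  if (is.null(windows) || nrow(windows) == 0L)
    stop("empty window list", call. = FALSE)
  if (is.null(pct_col))
    pct_col <- intersect(c("pct", "pct_slope", "pct_intercept"),
                         names(windows))[1]
  if (is.na(pct_col) || !pct_col %in% names(windows))
    stop("no percentage column found", call. = FALSE)
  w <- windows
  if ("complete" %in% names(w)) w <- w[w$complete, , drop = FALSE]
  use_idx <- all(c("start_idx", "end_idx") %in% names(w))
  lo <- if (use_idx) w$start_idx else w$start_bp
  hi <- if (use_idx) w$end_idx else w$end_bp
  pct <- w[[pct_col]]
  avail <- rep(TRUE, nrow(w))
  picked <- integer(0)
  while (any(avail)) {
    i <- which(avail)[which.max(pct[avail])]
    picked <- c(picked, i)
    # indices are inclusive (sharing a marker = overlap); bp ranges are
    # half-open [start, end), so touching at a boundary is not overlap
    overlap <- if (use_idx)
      avail & w$chrom == w$chrom[i] & lo <= hi[i] & hi >= lo[i]
    else
      avail & w$chrom == w$chrom[i] & lo < hi[i] & hi > lo[i]
    avail[overlap] <- FALSE
  }
  sel <- w[picked, , drop = FALSE]
  sel <- sel[sel[[pct_col]] >= threshold_pct, , drop = FALSE]
  sel <- sel[order(-sel[[pct_col]]), , drop = FALSE]
  list(selected = sel,
       summary = list(n_windows = nrow(sel),
                      total_pct = sum(sel[[pct_col]])))
}

#' Annotate windows with overlapping features
#'
#' Half-open interval overlap of `[start_bp, end_bp)` windows against a
#' feature table (e.g. genes read by [read_intervals()]); a feature touching
#' a window only at its exact end coordinate does not overlap.
#'
#' @param windows data.frame with `chrom`, `start_bp`, `end_bp` (0-based
#'   half-open).
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `name`.
#' @return the windows with a `features` list-column of overlapping names.
#' @export
annotate_windows <- function(windows, intervals) {
  wc <- as.character(windows$chrom)
  ic <- as.character(intervals$chrom)
  unmatched <- setdiff(unique(wc), unique(ic))
  if (length(unmatched))
    warning("window chromosome(s) absent from intervals: ",
            paste(unmatched, collapse = ", "))
  # half-open [s, e) -> 1-based closed [s + 1, e]
  qr <- IRanges::IRanges(start = windows$start_bp + 1L,
                         end = windows$end_bp)
  sr <- IRanges::IRanges(start = intervals$start + 1L,
                         end = intervals$end)
  hits <- IRanges::findOverlaps(qr, sr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  same_chr <- wc[qh] == ic[sh]
  feats <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) feats[[i]] <- character(0)
  for (k in which(same_chr))
    feats[[qh[k]]] <- c(feats[[qh[k]]], as.character(intervals$name[sh[k]]))
  windows$features <- feats
  windows
}
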
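#' SNP-effect reaction norms across the gradient
#'
#' Evaluates each marker's effect \eqn{u(EG) = \hat u_0 \phi_0(EG) + \hat
#' u_1 \phi_1(EG)} on a gradient grid, flags sign changes within the range
#' (crossing reaction norms), and classifies markers as environmentally
#' "sensitive" or "stable" by the ratio of the effect range to the mean
#' absolute effect.
#'
#' @param effects a `snp_effect_set` with intercept and slope columns.
#' @param basis a [legendre_basis()].
#' @param eg_grid gradient values to evaluate (non-empty).
#' @param sensitivity_threshold ratio above which a marker is classed
#'   sensitive (default 1).
#' @return list with `values` (markers x grid matrix), `grid`, and a
#'   data.frame `norms` (`marker`, `sign_change`, `range`, `mean_abs`,
#'   `class`).
#' @export
snp_reaction_norms <- function(effects, basis, eg_grid,
                               sensitivity_threshold = 1) {
  if (length(eg_grid) == 0L) stop("empty gradient grid", call. = FALSE)
  phi <- legendre_eval(basis, eg_grid)
  vals <- effects$effects %*% t(phi)
  colnames(vals) <- format(eg_grid, trim = TRUE)
  rng <- apply(vals, 1, function(v) max(v) - min(v))
  mab <- rowMeans(abs(vals))
  sign_change <- apply(vals, 1, function(v) min(v) < 0 && max(v) > 0)
  cls <- ifelse(mab > 0 & rng / pmax(mab, .Machine$double.eps) >
                  sensitivity_threshold, "sensitive", "stable")
  list(values = vals, grid = eg_grid,
       norms = data.frame(marker = effects$map$id,
                          sign_change = sign_change,
                          range = rng, mean_abs = mab, class = cls))
}

#' GEBV correlations across gradient levels
#'
#' Evaluates every animal's (or a stated subset's) breeding value at each
#' gradient level and returns the pairwise Pearson correlation matrix; a
#' level with zero GEBV variance yields NA correlations with a warning.
#'
#' @param solution an `rn_solution` (or any object with `coeffs`, `basis`).
#' @param eg_levels gradient values (>= 2).
#' @param animals optional subset of animal ids.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
gebv_correlations <- function(solution, eg_levels, animals = NULL) {
  if (length(eg_levels) < 2L) stop("need at least 2 levels", call. = FALSE)
  gv <- gebv_at(solution, eg_levels, animals = animals)
  if (nrow(gv) < 2L) stop("need at least 2 animals", call. = FALSE)
  sds <- apply(gv, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance GEBV vector at some level(s); correlations NA")
  cc <- suppressWarnings(stats::cor(gv))
  diag(cc) <- 1
  dimnames(cc) <- list(colnames(gv), colnames(gv))
  cc
}

#' Top-sire overlap across environments
#'
#' Ranks eligible sires (>= `min_progeny` offspring in the pedigree) by
#' GEBV at a low, medium and high gradient value, takes the top `n_top` at
#' each, and reports the seven disjoint region counts of the three-set Venn
#' partition. For traits where lower values are better (residual feed
#' intake), set `lower_is_better = TRUE`.
#'
#' @param solution an `rn_solution`.
#' @param pedigree pedigree table (progeny counts from the sire column).
#' @param eg_low,eg_mid,eg_high the three gradient values (defaults min, 0,
#'   max of the basis domain).
#' @param n_top list size (default 50; reduced with a warning if fewer
#'   eligible sires).
#' @param min_progeny eligibility threshold (default 5).
#' @param lower_is_better ranking direction.
#' @return `sire_overlap`: list with the three top lists, `counts` (the 7
#'   disjoint regions: `common_all`, `low_only`, `mid_only`, `high_only`,
#'   `low_mid`, `low_high`, `mid_high`) and `union_size`.
#' @export
sire_overlap <- function(solution, pedigree, eg_low = NULL, eg_mid = 0,
                         eg_high = NULL, n_top = 50L, min_progeny = 5L,
                         lower_is_better = FALSE) {
  ped <- check_pedigree(pedigree)
  if (is.null(eg_low)) eg_low <- solution$basis$eg_min
  if (is.null(eg_high)) eg_high <- solution$basis$eg_max
  prog <- table(as.character(ped$sire[!is.na(ped$sire)]))
  eligible <- names(prog)[prog >= min_progeny]
  eligible <- intersect(eligible, rownames(solution$coeffs))
  if (length(eligible) == 0L) stop("no eligible sires", call. = FALSE)
  if (length(eligible) < n_top) {
    warning(sprintf("only %d eligible sires; reducing n_top from %d",
                    length(eligible), n_top))
    n_top <- length(eligible)
  }
  gv <- gebv_at(solution, c(eg_low, eg_mid, eg_high), animals = eligible)
  pick <- function(v) {
    o <- order(v, decreasing = !lower_is_better)
    eligible[o][seq_len(n_top)]
  }
  lists <- list(low = pick(gv[, 1]), mid = pick(gv[, 2]),
                high = pick(gv[, 3]))
  overlap_counts(lists$low, lists$mid, lists$high, n_top)
}

# three-set Venn partition; exported for direct use on hand-built lists
#' @rdname sire_overlap
#' @param low,mid,high explicit id lists (alternative entry point).
#' @param n_top expected list size.
#' @export
overlap_counts <- function(low, mid, high, n_top = length(low)) {
  in_l <- unique(low); in_m <- unique(mid); in_h <- unique(high)
  all3 <- intersect(intersect(in_l, in_m), in_h)
  lm <- setdiff(intersect(in_l, in_m), in_h)
  lh <- setdiff(intersect(in_l, in_h), in_m)
  mh <- setdiff(intersect(in_m, in_h), in_l)
  lo <- setdiff(in_l, union(in_m, in_h))
  mo <- setdiff(in_m, union(in_l, in_h))
  ho <- setdiff(in_h, union(in_l, in_m))
  counts <- c(common_all = length(all3), low_only = length(lo),
              mid_only = length(mo), high_only = length(ho),
              low_mid = length(lm), low_high = length(lh),
              mid_high = length(mh))
  structure(list(lists = list(low = in_l, mid = in_m, high = in_h),
                 counts = counts,
                 union_size = length(union(union(in_l, in_m), in_h)),
                 n_top = n_top),
            class = "sire_overlap")
}

#' @exportS3Method
print.sire_overlap <- function(x, ...) {
  cat(sprintf("sire_overlap (n_top = %d): %d sires common to all levels\n",
              x$n_top, x$counts["common_all"]))
  print(x$counts)
  invisible(x)
}

#' Manhattan-ready window table
#'
#' Adds a cumulative genome coordinate (chromosomes laid end to end in the
#' order given) so any plotting layer can draw the window-variance Manhattan
#' profile, with the 1% relevance threshold line.
#'
#' @param windows data.frame sorted by chromosome then position with
#'   `chrom`, `start_bp`, `end_bp` and percentage column(s).
#' @param threshold_pct threshold annotation carried in the output
#'   (default 1).
#' @return the input with `mid_bp`, `cum_bp` columns and attribute
#'   `"threshold_pct"`.
#' @export
manhattan_table <- function(windows, threshold_pct = 1.0) {
  w <- windows
  w$mid_bp <- (w$start_bp + w$end_bp) / 2
  offs <- 0
  w$cum_bp <- NA_real_
  for (chr in unique(w$chrom)) {
    rows <- w$chrom == chr
    w$cum_bp[rows] <- w$mid_bp[rows] + offs
    offs <- offs + max(w$end_bp[rows])
  }
  attr(w, "threshold_pct") <- threshold_pct
  w
}
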
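#' Published per-window variance tables (worked examples)
#'
#' Returns the per-window percentages of direct additive genetic variance
#' for the relevant genomic windows reported for the feed-efficiency
#' reaction-norm study (residual feed intake and dry matter intake, each
#' with intercept and slope scans), shipped as plain-text tables. Useful as
#' worked-example input to [select_windows()]: the ten intercept windows
#' for RFI total 20.63%, the eleven slope windows 29.65%, the twelve DMI
#' intercept windows 34.83% and the seventeen DMI slope windows 37.57%.
#'
#' @param trait "rfi" or "dmi".
#' @param coefficient "intercept" or "slope".
#' @return data.frame with `chrom`, `start_mb`, `end_mb`, `pct`, plus
#'   `start_bp`/`end_bp` convenience columns.
#' @export
published_windows <- function(trait = c("rfi", "dmi"),
                              coefficient = c("intercept", "slope")) {
  trait <- match.arg(trait)
  coefficient <- match.arg(coefficient)
  path <- system.file("extdata",
                      sprintf("windows_%s_%s.tsv", trait, coefficient),
                      package = "ssgxe", mustWork = TRUE)
  df <- utils::read.delim(path)
  df$start_bp <- df$start_mb * 1e6
  df$end_bp <- df$end_mb * 1e6
  df
}
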
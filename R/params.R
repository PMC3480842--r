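#' Detection parameters
#'
#' Bundles the seven tuning parameters of the Triform detection procedure.
#' All are fixed values chosen to reflect general properties of
#' transcription-factor ChIP-Seq data rather than fitted per data set.
#'
#' @param read_width Width `w` (bp) to which every read is extended, from its
#'   5' end in the read's own direction, before coverage is computed. Must be
#'   a positive integer. Default 100 bp, roughly half a sequenced fragment.
#' @param delta Flank spacing `delta` (bp) between the central location and
#'   the two flanking locations used by the form tests. Must exceed
#'   `read_width`; the default 150 bp is comparable to the DNA wrapped around
#'   one nucleosome.
#' @param min_p Upper-tail standard-normal probability defining the z cut-off;
#'   ignored when `min_z` is given directly. Default 0.1.
#' @param min_z z-value cut-off applied to every form and enrichment test
#'   (strictly: a location passes when z > `min_z`). Defaults to
#'   `min_z_from_p(min_p)`, about 1.2816 for `min_p = 0.1`.
#' @param min_n Minimum peak width in bp; a region is kept only when its
#'   width strictly exceeds `min_n`. Default 10 bp.
#' @param min_er_quantile Quantile of the enrichment ratios of significantly
#'   enriched Form-1 regions (per strand) used as the `min.er` cut-off.
#'   Default 3/8.
#' @param min_lag Minimum inter-strand lag in bp; a candidate peak pair is
#'   kept only when its estimated lag strictly exceeds `min_lag`. Default 10.
#' @param ratio Ratio `r` between control and ChIP library sizes. Usually left
#'   `NULL` and computed from the data by [call_peaks()]; set explicitly only
#'   for testing.
#'
#' @return An object of class `triform_params` (a named list).
#' @examples
#' triform_params()
#' triform_params(min_p = 0.05, min_lag = 20)
#' @export
triform_params <- function(read_width = 100L,
                           delta = 150L,
                           min_p = 0.1,
                           min_z = NULL,
                           min_n = 10L,
                           min_er_quantile = 3 / 8,
                           min_lag = 10L,
                           ratio = NULL) {
  read_width <- as.integer(read_width)
  delta <- as.integer(delta)
  min_n <- as.integer(min_n)
  min_lag <- as.integer(min_lag)
  if (length(read_width) != 1L || is.na(read_width) || read_width <= 0L) {
    stop("`read_width` must be a single positive integer", call. = FALSE)
  }
  if (length(delta) != 1L || is.na(delta) || delta <= read_width) {
    stop("`delta` must be a single integer greater than `read_width` (",
         read_width, ")", call. = FALSE)
  }
  if (is.null(min_z)) {
    min_z <- min_z_from_p(min_p)
  }
  if (!is.numeric(min_z) || length(min_z) != 1L || !is.finite(min_z)) {
    stop("`min_z` must be a single finite number", call. = FALSE)
  }
  if (is.na(min_n) || min_n < 1L) {
    stop("`min_n` must be at least 1", call. = FALSE)
  }
  if (is.na(min_lag) || min_lag < 0L) {
    stop("`min_lag` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(min_er_quantile) || length(min_er_quantile) != 1L ||
      is.na(min_er_quantile) ||
      min_er_quantile <= 0 || min_er_quantile >= 1) {
    stop("`min_er_quantile` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.null(ratio)) {
    if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
        ratio <= 0) {
      stop("`ratio` must be a single positive number", call. = FALSE)
    }
    ratio <- as.numeric(ratio)
  }
  structure(
    list(
      read_width = read_width,
      delta = delta,
      min_z = as.numeric(min_z),
      min_n = min_n,
      min_er_quantile = as.numeric(min_er_quantile),
      min_lag = min_lag,
      ratio = ratio
    ),
    class = "triform_params"
  )
}

#' @export
print.triform_params <- function(x, ...) {
  cat("Triform detection parameters\n")
  cat(sprintf("  read_width (w):      %d bp\n", x$read_width))
  cat(sprintf("  delta:               %d bp\n", x$delta))
  cat(sprintf("  min_z:               %.6g\n", x$min_z))
  cat(sprintf("  min_n:               %d bp\n", x$min_n))
  cat(sprintf("  min_er_quantile:     %.4g\n", x$min_er_quantile))
  cat(sprintf("  min_lag:             %d bp\n", x$min_lag))
  cat(sprintf("  ratio (r):           %s\n",
              if (is.null(x$ratio)) "computed from library sizes"
              else format(x$ratio)))
  invisible(x)
}

as_triform_params <- function(params) {
  if (inherits(params, "triform_params")) {
    return(params)
  }
  stop("`params` must be created with triform_params()", call. = FALSE)
}
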
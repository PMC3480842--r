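#' Extend reads to a fixed width from their 5' end
#'
#' Each read is replaced by an interval of width exactly `read_width`,
#' anchored at the read's 5' end and extended in the read's own direction: a
#' forward-strand read `[s, e]` becomes `[s, s + w - 1]` and a reverse-strand
#' read becomes `[e - w + 1, e]` (1-based inclusive). This emulates the
#' sequenced fragment reaching `w` bp inward from each sequenced end, which
#' is what draws the forward- and reverse-strand coverage profiles of a
#' binding site toward each other so that their peak regions can overlap.
#' Reverse-strand extensions may run below position 1 when no chromosome
#' sizes are supplied; such positions are dropped at track build. When
#' `chrom_sizes` is supplied, intervals are clamped to `[1, length]`.
#'
#' @param reads Tibble of reads (1-based inclusive, as from
#'   [read_bed_reads()]); the `strand` column decides the extension
#'   direction.
#' @param read_width Positive extension width `w` in bp.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return Tibble `chrom`, `start`, `end`, `strand` of extended intervals.
#' @examples
#' reads <- tibble::tibble(chrom = "chr1", start = 101L, end = 136L,
#'                         strand = "+")
#' extend_reads(reads, 100)   # 1-based [101, 200]
#' @export
extend_reads <- function(reads, read_width, chrom_sizes = NULL) {
  read_width <- as.integer(read_width)
  if (is.na(read_width) || read_width <= 0L) {
    stop("`read_width` must be a positive integer", call. = FALSE)
  }
  reads <- validate_reads(reads)
  fwd <- reads$strand == "+"
  start <- ifelse(fwd, reads$start, reads$end - read_width + 1L)
  out <- tibble::tibble(
    chrom = reads$chrom,
    start = as.integer(start),
    end = as.integer(start) + read_width - 1L,
    strand = reads$strand
  )
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(out$chrom), names(chrom_sizes))
    if (length(unknown)) {
      stop("chromosome(s) absent from chrom_sizes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    len <- unname(chrom_sizes[out$chrom])
    out$start <- pmax(out$start, 1L)
    out$end <- pmin(out$end, as.integer(len))
    out <- out[out$start <= out$end, , drop = FALSE]
  }
  out
}

#' Build a strand-specific coverage track
#'
#' Piles the `read_width` 5'-anchored extensions of all reads into a
#' run-length-encoded coverage vector: `counts[x]` is the number of extended
#' reads covering position x. Positions below 1 are dropped; with no
#' clipping the total coverage equals `n_reads * read_width`.
#'
#' @param reads Tibble of reads, all on one chromosome and strand.
#' @param read_width Extension width `w` in bp.
#' @param chrom,strand Track identity; inferred from the reads when `NULL`.
#' @param chrom_sizes Optional named chromosome lengths, used to clip
#'   extensions at chromosome ends.
#' @return A `coverage_track`: list with `chrom`, `strand`, `cov` (an
#'   [S4Vectors::Rle] of counts, position 1 onward) and `n_reads`.
#' @export
build_track <- function(reads, read_width, chrom = NULL, strand = NULL,
                        chrom_sizes = NULL) {
  reads <- validate_reads(reads)
  if (is.null(chrom)) chrom <- unique(reads$chrom)
  if (is.null(strand)) strand <- unique(reads$strand)
  if (length(chrom) > 1L || length(strand) > 1L) {
    stop("`reads` must all share one chromosome and strand; got ",
         paste(chrom, collapse = ","), " / ",
         paste(strand, collapse = ","), call. = FALSE)
  }
  if (length(chrom) == 0L) chrom <- NA_character_
  if (length(strand) == 0L) strand <- NA_character_
  ext <- extend_reads(reads, read_width, chrom_sizes)
  # drop the sub-1 portion of any extension positionwise
  start <- pmax(ext$start, 1L)
  keep <- start <= ext$end
  cov <- if (any(keep)) {
    IRanges::coverage(IRanges::IRanges(start = start[keep],
                                       end = ext$end[keep]))
  } else {
    S4Vectors::Rle(integer())
  }
  structure(
    list(chrom = chrom, strand = strand, cov = cov, n_reads = nrow(reads)),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s (%s): %d reads, support %d bp, total %d\n",
              x$chrom, x$strand, x$n_reads,
              sum(S4Vectors::runLength(x$cov)[S4Vectors::runValue(x$cov) > 0]),
              track_total(x)))
  invisible(x)
}

track_total <- function(track) {
  as.numeric(sum(as.numeric(S4Vectors::runValue(track$cov)) *
                   S4Vectors::runLength(track$cov)))
}

#' Coverage at given positions
#'
#' @param track A `coverage_track`.
#' @param x Integer position(s), 1-based.
#' @return Integer coverage count(s); 0 outside the stored support.
#' @export
coverage_at <- function(track, x) {
  rle_at(track$cov, x)
}

# vectorized point query on an Rle treated as starting at position 1,
# with 0 outside [1, length]
rle_at <- function(rle, x) {
  n <- length(rle)
  out <- numeric(length(x))
  inside <- !is.na(x) & x >= 1 & x <= n
  if (any(inside)) {
    run <- S4Vectors::findRun(as.integer(x[inside]), rle)
    out[inside] <- as.numeric(S4Vectors::runValue(rle))[run]
  }
  out
}

#' Control/ChIP library-size ratio
#'
#' The parameter `r`: the actual ratio between control and ChIP-Seq library
#' sizes (read counts).
#'
#' @param chip_reads,control_reads Positive read counts.
#' @return `control_reads / chip_reads`.
#' @export
library_size_ratio <- function(chip_reads, control_reads) {
  if (!is.numeric(chip_reads) || length(chip_reads) != 1L ||
      is.na(chip_reads) || chip_reads <= 0) {
    stop("ChIP library size must be a positive count", call. = FALSE)
  }
  if (!is.numeric(control_reads) || length(control_reads) != 1L ||
      is.na(control_reads) || control_reads <= 0) {
    stop("control library size must be a positive count", call. = FALSE)
  }
  control_reads / chip_reads
}

#' Optimal inter-strand lag by cross-correlation
#'
#' Finds the lag k in `[0, max_lag]` maximizing the raw sliding dot product
#' between the forward-strand coverage profile over
#' `[range_start, range_end]` and the reverse-strand profile shifted left by
#' k (forward position x is matched to reverse position x + k). A positive
#' lag therefore means the reverse profile lies downstream of the forward
#' profile, the direction implied by sequencing fragment ends. Ties break
#' toward the smallest lag. No mean-centering or normalization is applied:
#' the argmax is invariant to positive scaling, and centering can create
#' spurious optima on short sparse ranges.
#'
#' @param fwd,rev `coverage_track`s for the two strands.
#' @param range_start,range_end 1-based range over which to correlate.
#' @param max_lag Largest lag searched; defaults to the range width minus 1,
#'   capped at `cap` (fragment-shift lags beyond twice the flank spacing are
#'   not biologically meaningful).
#' @param cap Cap applied to the default `max_lag` (bp); default 300.
#' @return The optimal lag in bp.
#' @export
best_lag <- function(fwd, rev, range_start, range_end, max_lag = NULL,
                     cap = 300L) {
  if (range_start > range_end) {
    stop("`range_start` must be <= `range_end`", call. = FALSE)
  }
  width <- range_end - range_start + 1L
  if (is.null(max_lag)) {
    max_lag <- min(width - 1L, as.integer(cap))
  }
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("`max_lag` must be >= 0", call. = FALSE)
  f <- rle_at(fwd$cov, seq.int(range_start, range_end))
  g <- rle_at(rev$cov, seq.int(range_start, range_end + max_lag))
  if (all(f == 0)) {
    stop("undefined lag: forward profile is zero over the range",
         call. = FALSE)
  }
  if (all(g[seq_len(width)] == 0)) {
    stop("undefined lag: reverse profile is zero over the range",
         call. = FALSE)
  }
  cc <- vapply(0:max_lag, function(k) {
    sum(f * g[seq.int(1L + k, width + k)])
  }, numeric(1))
  (which.max(cc) - 1L)   # first maximum = smallest lag on ties
}
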
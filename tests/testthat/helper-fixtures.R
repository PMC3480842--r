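# shared fixtures, built in code

# reads of fixed length at given 1-based start positions
make_reads <- function(starts, strand = "+", chrom = "chr1", read_len = 36L) {
  tibble::tibble(
    chrom = chrom,
    start = as.integer(starts),
    end = as.integer(starts) + as.integer(read_len) - 1L,
    name = paste0("r", seq_along(starts)),
    score = 0,
    strand = strand
  )
}

# a coverage_track with an arbitrary coverage profile (position 1 onward)
track_from_profile <- function(profile, chrom = "chr1", strand = "+",
                               n_reads = 0L) {
  structure(
    list(chrom = chrom, strand = strand,
         cov = S4Vectors::Rle(as.integer(profile)), n_reads = n_reads),
    class = "coverage_track"
  )
}

# an all-zero track
empty_track <- function(chrom = "chr1", strand = "+") {
  track_from_profile(integer(), chrom, strand)
}

# brute-force coverage oracle: per-position membership count over extended
# intervals (independent of IRanges::coverage)
brute_coverage <- function(ext_start, ext_end, positions) {
  vapply(positions, function(x) {
    sum(ext_start <= x & x <= ext_end)
  }, numeric(1))
}

# brute-force lag oracle: independent dot-product scan over all lags
brute_lag <- function(f, g_extended, max_lag) {
  width <- length(f)
  cc <- vapply(0:max_lag, function(k) {
    sum(f * g_extended[seq.int(1L + k, width + k)])
  }, numeric(1))
  which.max(cc) - 1L
}

# reads whose extended coverage forms a flat plateau on both strands
plateau_reads <- function(start = 1001L, width = 500L, depth = 5L,
                          read_len = 36L, w = 100L) {
  step <- w
  starts <- rep(seq(start, start + width - 1L, by = step), each = depth)
  # reverse reads placed so their 5'-anchored extensions tile the same block
  rbind(make_reads(starts, "+", read_len = read_len),
        make_reads(starts + w - read_len, "-", read_len = read_len))
}

bed_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# region / peak rows for contract tests
region_row <- function(start, end, strand = "+", form = 1L, chrom = "chr1",
                       er = 10, z = 3) {
  tibble::tibble(
    chrom = chrom, strand = strand, form = form,
    start = as.integer(start), end = as.integer(end),
    center = (as.integer(start) + as.integer(end)) %/% 2L,
    summit = (as.integer(start) + as.integer(end)) %/% 2L,
    summit_z = z, er_center = er, nlp = nlp_from_z(z)
  )
}

peak_row <- function(start, end, form, nlp = 5, lag = 50L, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    peak_loc = (as.integer(start) + as.integer(end)) %/% 2L,
    peak_nlp = nlp, form = as.integer(form), lag = as.integer(lag),
    er = 10
  )
}

empty_peaks_tbl <- function() peak_row(1, 2, 1)[0, ]
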
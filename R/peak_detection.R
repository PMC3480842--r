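#' Form test statistic at a genomic location
#'
#' Evaluates the Hoel form statistic of the requested form at location x,
#' using the coverage values at x - delta, x and x + delta (0 outside the
#' stored support): Form 1 via [hoel_z1()], Form 2 via [hoel_z2()] (left
#' flank), Form 3 via [hoel_z3()] (right flank).
#'
#' @param track A `coverage_track`.
#' @param x Position(s), 1-based.
#' @param form 1, 2 or 3.
#' @param delta Flank spacing in bp (> 0).
#' @return z value(s).
#' @export
form_z <- function(track, x, form, delta) {
  stopifnot(delta > 0)
  ctr <- coverage_at(track, x)
  switch(as.character(form),
    "1" = hoel_z1(coverage_at(track, x - delta), ctr,
                  coverage_at(track, x + delta)),
    "2" = hoel_z2(coverage_at(track, x - delta), ctr),
    "3" = hoel_z3(ctr, coverage_at(track, x + delta)),
    stop("`form` must be 1, 2 or 3", call. = FALSE)
  )
}

# Rle of coverage padded/truncated to exactly n positions
padded_rle <- function(rle, n) {
  len <- length(rle)
  if (len >= n) {
    S4Vectors::window(rle, 1L, n)
  } else {
    c(rle, S4Vectors::Rle(0L, n - len))
  }
}

# C(x - delta) and C(x + delta) as Rles aligned with positions 1..n
shift_right <- function(rle, delta, n) {           # value at x is rle[x - delta]
  padded_rle(c(S4Vectors::Rle(0L, delta), rle), n)
}
shift_left <- function(rle, delta, n) {            # value at x is rle[x + delta]
  len <- length(rle)
  if (len <= delta) return(S4Vectors::Rle(0L, n))
  padded_rle(S4Vectors::window(rle, delta + 1L, len), n)
}

# maximal TRUE runs of a logical Rle -> tibble(start, end)
true_runs <- function(ok) {
  ends <- cumsum(S4Vectors::runLength(ok))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  val <- S4Vectors::runValue(ok)
  keep <- !is.na(val) & val
  tibble::tibble(start = starts[keep], end = ends[keep])
}

empty_regions <- function() {
  tibble::tibble(
    chrom = character(), strand = character(), form = integer(),
    start = integer(), end = integer(), center = integer(),
    summit = integer(), summit_z = numeric(), er_center = numeric(),
    nlp = numeric()
  )
}

#' Detect peak-like regions of one form on one strand
#'
#' Finds all maximal runs of consecutive positions whose form statistic and
#' enrichment statistic both strictly exceed `min_z`, and whose width
#' strictly exceeds `min_n` bp. The control track must be strand-matched to
#' the ChIP track (the enrichment test is defined per strand). Statistics are
#' computed by run-length arithmetic over the whole track, which is exact:
#' outside the coverage support every statistic is 0 and cannot pass the
#' strictly positive cut-off.
#'
#' For each surviving region the center `x0` (floor midpoint), the summit
#' (position of maximal form z, leftmost on ties), the summit z, the
#' enrichment ratio at `x0` and the NLP of the summit z are recorded.
#'
#' @param chip,control `coverage_track`s sharing chromosome and strand.
#' @param form 1, 2 or 3.
#' @param params [triform_params()] with a non-`NULL` `ratio`.
#' @return Tibble of region candidates (possibly empty) with columns
#'   `chrom`, `strand`, `form`, `start`, `end`, `center`, `summit`,
#'   `summit_z`, `er_center`, `nlp`.
#' @export
detect_form_regions <- function(chip, control, form, params) {
  params <- as_triform_params(params)
  r <- params$ratio
  if (is.null(r)) {
    stop("params$ratio must be set (see library_size_ratio())", call. = FALSE)
  }
  delta <- params$delta
  n <- max(length(chip$cov), length(control$cov)) + delta
  if (length(chip$cov) == 0L || track_total(chip) == 0) {
    return(empty_regions())
  }
  C <- padded_rle(chip$cov, n)
  B <- padded_rle(control$cov, n)
  zf <- switch(as.character(form),
    "1" = hoel_z1(shift_right(chip$cov, delta, n), C,
                  shift_left(chip$cov, delta, n)),
    "2" = hoel_z2(shift_right(chip$cov, delta, n), C),
    "3" = hoel_z3(C, shift_left(chip$cov, delta, n)),
    stop("`form` must be 1, 2 or 3", call. = FALSE)
  )
  z4 <- hoel_z4(C, B, r)
  ok <- (zf > params$min_z) & (z4 > params$min_z)
  runs <- true_runs(ok)
  runs <- runs[runs$end - runs$start + 1L > params$min_n, , drop = FALSE]
  if (nrow(runs) == 0L) {
    return(empty_regions())
  }
  center <- (runs$start + runs$end) %/% 2L
  summit <- integer(nrow(runs))
  summit_z <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    zv <- as.numeric(S4Vectors::window(zf, runs$start[i], runs$end[i]))
    j <- which.max(zv)
    summit[i] <- runs$start[i] + j - 1L
    summit_z[i] <- zv[j]
  }
  er_center <- enrichment_ratio(rle_at(chip$cov, center),
                                rle_at(control$cov, center), r)
  tibble::tibble(
    chrom = chip$chrom, strand = chip$strand, form = as.integer(form),
    start = runs$start, end = runs$end, center = center,
    summit = summit, summit_z = summit_z, er_center = er_center,
    nlp = nlp_from_z(summit_z)
  )
}

#' Per-strand min.er cut-off from Form-1 regions
#'
#' The enrichment-ratio cut-off is data-derived: for each strand it is the
#' `quantile` (default 3/8) empirical quantile, with the linear-interpolation
#' ("type 7") convention, of the center enrichment ratios of that strand's
#' significantly enriched Form-1 regions. A strand with no Form-1 regions
#' gets 0, making the filter vacuous there.
#'
#' @param form1_regions Tibble of Form-1 region candidates (both strands).
#' @param quantile Quantile in (0, 1).
#' @return Named numeric vector with entries `"+"` and `"-"`.
#' @export
compute_min_er <- function(form1_regions, quantile = 3 / 8) {
  stopifnot(quantile > 0, quantile < 1)
  out <- c("+" = 0, "-" = 0)
  for (s in c("+", "-")) {
    er <- form1_regions$er_center[form1_regions$strand == s]
    if (length(er) > 0L) {
      out[[s]] <- unname(stats::quantile(er, quantile, type = 7, names = FALSE))
    }
  }
  out
}

#' Apply the enrichment-ratio filter
#'
#' Keeps regions whose center enrichment ratio strictly exceeds their
#' strand's `min.er`.
#'
#' @param regions Tibble of region candidates (any forms, both strands).
#' @param min_er_by_strand Named vector as from [compute_min_er()].
#' @return Filtered tibble.
#' @export
apply_er_filter <- function(regions, min_er_by_strand) {
  if (nrow(regions) == 0L) return(regions)
  cut <- unname(min_er_by_strand[regions$strand])
  cut[is.na(cut)] <- 0
  regions[regions$er_center > cut, , drop = FALSE]
}

#' Apply the replicate-consistency filter
#'
#' With two or more ChIP replicates, a region is kept only when, in every
#' replicate and at every position of the region, both the form statistic and
#' the enrichment statistic (with that replicate's own library-size ratio
#' against the shared control) are strictly positive. With fewer than two
#' replicates the filter is the identity.
#'
#' @param regions Tibble of region candidates on one chromosome/strand.
#' @param replicate_tracks List of per-replicate `coverage_track`s matching
#'   the regions' chromosome and strand.
#' @param control `coverage_track` of the strand-matched control.
#' @param ratios Numeric vector of per-replicate control/ChIP library-size
#'   ratios, same length as `replicate_tracks`.
#' @param params [triform_params()].
#' @return Filtered tibble.
#' @export
apply_replicate_filter <- function(regions, replicate_tracks, control,
                                   ratios, params) {
  params <- as_triform_params(params)
  if (length(replicate_tracks) < 2L || nrow(regions) == 0L) {
    return(regions)
  }
  stopifnot(length(ratios) == length(replicate_tracks))
  delta <- params$delta
  keep <- rep(TRUE, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    x <- seq.int(regions$start[i], regions$end[i])
    form <- regions$form[i]
    for (k in seq_along(replicate_tracks)) {
      trk <- replicate_tracks[[k]]
      zf <- form_z(trk, x, form, delta)
      z4 <- hoel_z4(coverage_at(trk, x), coverage_at(control, x), ratios[k])
      if (any(zf <= 0) || any(z4 <= 0)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  regions[keep, , drop = FALSE]
}

#' Pair regions across strands
#'
#' A forward region and a reverse region (of the same form) are paired when
#' they overlap and each overlaps exactly one region of the opposite strand;
#' regions with zero or ambiguous (multiple) opposite-strand overlaps are
#' discarded. Pairing is evaluated per chromosome.
#'
#' @param fwd_regions,rev_regions Region tibbles for the two strands (one
#'   form).
#' @return Tibble of pairs with the forward region's columns prefixed `fwd_`
#'   and the reverse region's prefixed `rev_`, plus `chrom` and `form`.
#' @export
pair_strand_regions <- function(fwd_regions, rev_regions) {
  empty <- pair_skeleton()
  if (nrow(fwd_regions) == 0L || nrow(rev_regions) == 0L) {
    return(empty)
  }
  out <- list(empty)
  for (chr in intersect(unique(fwd_regions$chrom), unique(rev_regions$chrom))) {
    f <- fwd_regions[fwd_regions$chrom == chr, , drop = FALSE]
    r <- rev_regions[rev_regions$chrom == chr, , drop = FALSE]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(f$start, f$end),
      IRanges::IRanges(r$start, r$end)
    )
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    nf <- tabulate(q, nbins = nrow(f))
    nr <- tabulate(s, nbins = nrow(r))
    ok <- nf[q] == 1L & nr[s] == 1L
    if (!any(ok)) next
    fi <- f[q[ok], , drop = FALSE]
    ri <- r[s[ok], , drop = FALSE]
    out[[length(out) + 1L]] <- tibble::tibble(
      chrom = fi$chrom, form = fi$form,
      fwd_start = fi$start, fwd_end = fi$end, fwd_summit = fi$summit,
      fwd_summit_z = fi$summit_z, fwd_er = fi$er_center, fwd_nlp = fi$nlp,
      rev_start = ri$start, rev_end = ri$end, rev_summit = ri$summit,
      rev_summit_z = ri$summit_z, rev_er = ri$er_center, rev_nlp = ri$nlp
    )
  }
  dplyr::bind_rows(out)
}

pair_skeleton <- function() {
  tibble::tibble(
    chrom = character(), form = integer(),
    fwd_start = integer(), fwd_end = integer(), fwd_summit = integer(),
    fwd_summit_z = numeric(), fwd_er = numeric(), fwd_nlp = numeric(),
    rev_start = integer(), rev_end = integer(), rev_summit = integer(),
    rev_summit_z = numeric(), rev_er = numeric(), rev_nlp = numeric()
  )
}

#' Estimate and filter inter-strand lags for paired regions
#'
#' For every pair the lag is estimated with [best_lag()] over the range from
#' `fwd_start - delta` to `rev_end + delta` (the flank-extended span of the
#' pair), searching lags up to the range width minus one, capped at
#' `2 * delta`. Pairs whose lag strictly exceeds `min_lag` are kept; pairs
#' with an undefined lag (a strand profile that is zero over the range) are
#' dropped.
#'
#' @param pairs Tibble from [pair_strand_regions()], one chromosome.
#' @param fwd_track,rev_track `coverage_track`s for that chromosome.
#' @param params [triform_params()].
#' @return `pairs` with a `lag` column, filtered to `lag > min_lag`.
#' @export
lag_filter <- function(pairs, fwd_track, rev_track, params) {
  params <- as_triform_params(params)
  if (nrow(pairs) == 0L) {
    pairs$lag <- integer()
    return(pairs)
  }
  delta <- params$delta
  lag <- rep(NA_integer_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    rs <- max(1L, pairs$fwd_start[i] - delta)
    re <- pairs$rev_end[i] + delta
    lag[i] <- tryCatch(
      as.integer(best_lag(fwd_track, rev_track, rs, re,
                          max_lag = min(re - rs, 2L * delta))),
      error = function(e) NA_integer_
    )
  }
  pairs$lag <- lag
  pairs[!is.na(lag) & lag > params$min_lag, , drop = FALSE]
}

#' Score a paired region as a peak call
#'
#' The peak spans the union of the two strand regions; `peak_loc` is the
#' floor midpoint of that span. `peak_nlp` is the sum of the two strand NLPs
#' (each the NLP of the region's summit z), a Fisher combination of the two
#' strand tests: `2 * ln(10) * sum(NLP)` is the chi-squared statistic on 4
#' degrees of freedom for the combined null. The reported enrichment ratio is
#' the mean of the two center ratios.
#'
#' @param pairs Tibble from [lag_filter()] (must carry `lag`).
#' @return Tibble of peak calls: `chrom`, `start`, `end`, `peak_loc`,
#'   `peak_nlp`, `form`, `lag`, `er`.
#' @export
score_peaks <- function(pairs) {
  if (nrow(pairs) == 0L) return(empty_peaks())
  start <- pmin(pairs$fwd_start, pairs$rev_start)
  end <- pmax(pairs$fwd_end, pairs$rev_end)
  tibble::tibble(
    chrom = pairs$chrom,
    start = start,
    end = end,
    peak_loc = (start + end) %/% 2L,
    peak_nlp = pairs$fwd_nlp + pairs$rev_nlp,
    form = pairs$form,
    lag = as.integer(pairs$lag),
    er = (pairs$fwd_er + pairs$rev_er) / 2
  )
}

empty_peaks <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    peak_loc = integer(), peak_nlp = numeric(), form = integer(),
    lag = integer(), er = numeric()
  )
}

#' Resolve redundant and partial peak forms
#'
#' Applies the cross-form rules: (a) any Form-2 or Form-3 peak overlapping a
#' Form-1 peak is redundant and removed; (b) among the survivors, overlapping
#' Form-2 and Form-3 peaks are merged into a single Form-1 peak spanning
#' their union, scored by the sum of their NLPs, with the larger of the two
#' lags and the mean of their enrichment ratios (overlap groups larger than a
#' pair are merged the same way); (c) any residual same-chromosome overlap is
#' resolved by keeping the higher-NLP peak. The result is sorted by
#' decreasing `peak_nlp` (ties by chromosome and start) and is
#' non-overlapping within each chromosome.
#'
#' @param peaks1,peaks2,peaks3 Peak tibbles for Forms 1-3 (as from
#'   [score_peaks()]).
#' @return Final peak tibble.
#' @export
resolve_forms <- function(peaks1, peaks2, peaks3) {
  # (a) drop Form 2/3 peaks overlapping any Form 1 peak
  drop_overlapping <- function(p, ref) {
    if (nrow(p) == 0L || nrow(ref) == 0L) return(p)
    keep <- rep(TRUE, nrow(p))
    for (chr in unique(p$chrom)) {
      ri <- ref[ref$chrom == chr, , drop = FALSE]
      pi <- which(p$chrom == chr)
      if (nrow(ri) == 0L || length(pi) == 0L) next
      n_hit <- IRanges::countOverlaps(
        IRanges::IRanges(p$start[pi], p$end[pi]),
        IRanges::IRanges(ri$start, ri$end)
      )
      keep[pi[n_hit > 0L]] <- FALSE
    }
    p[keep, , drop = FALSE]
  }
  peaks2 <- drop_overlapping(peaks2, peaks1)
  peaks3 <- drop_overlapping(peaks3, peaks1)

  # (b) merge overlapping Form 2 + Form 3 groups into Form 1 peaks
  merged <- empty_peaks()
  if (nrow(peaks2) > 0L && nrow(peaks3) > 0L) {
    p23 <- dplyr::bind_rows(peaks2, peaks3)
    merged_idx <- logical(nrow(p23))
    out <- list()
    for (chr in unique(p23$chrom)) {
      idx <- which(p23$chrom == chr)
      has2 <- any(p23$form[idx] == 2L)
      has3 <- any(p23$form[idx] == 3L)
      if (!has2 || !has3) next
      ir <- IRanges::IRanges(p23$start[idx], p23$end[idx])
      grp <- S4Vectors::subjectHits(
        IRanges::findOverlaps(ir, IRanges::reduce(ir))
      )
      for (g in unique(grp)) {
        members <- idx[grp == g]
        if (length(unique(p23$form[members])) < 2L) next  # need both forms
        m <- p23[members, , drop = FALSE]
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = chr,
          start = min(m$start),
          end = max(m$end),
          peak_loc = (min(m$start) + max(m$end)) %/% 2L,
          peak_nlp = sum(m$peak_nlp),
          form = 1L,
          lag = max(m$lag),
          er = mean(m$er)
        )
        merged_idx[members] <- TRUE
      }
    }
    merged <- dplyr::bind_rows(out)
    p23 <- p23[!merged_idx, , drop = FALSE]
    peaks2 <- p23[p23$form == 2L, , drop = FALSE]
    peaks3 <- p23[p23$form == 3L, , drop = FALSE]
  }

  all_peaks <- sort_peaks(dplyr::bind_rows(peaks1, merged, peaks2, peaks3))

  # (c) greedy non-overlap enforcement, higher NLP first
  if (nrow(all_peaks) > 1L) {
    keep <- rep(TRUE, nrow(all_peaks))
    for (chr in unique(all_peaks$chrom)) {
      idx <- which(all_peaks$chrom == chr)
      taken_start <- integer(0)
      taken_end <- integer(0)
      for (i in idx) {
        if (length(taken_start) &&
            any(all_peaks$start[i] <= taken_end &
                all_peaks$end[i] >= taken_start)) {
          keep[i] <- FALSE
        } else {
          taken_start <- c(taken_start, all_peaks$start[i])
          taken_end <- c(taken_end, all_peaks$end[i])
        }
      }
    }
    all_peaks <- all_peaks[keep, , drop = FALSE]
  }
  all_peaks
}
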
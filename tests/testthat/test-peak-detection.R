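params_r1 <- function(...) triform_params(ratio = 1, ...)

test_that("form_z dispatches the right statistic at the right offsets", {
  expect_equal(form_z(empty_track(), c(10, 500), 1, 150), c(0, 0))

  spike <- track_from_profile(c(rep(0L, 499), 10L))   # count 10 at x = 500
  expect_equal(form_z(spike, 500, 1, 150), hoel_z1(0, 10, 0))
  expect_equal(form_z(spike, 500, 2, 150), hoel_z2(0, 10))
  expect_equal(form_z(spike, 500, 3, 150), hoel_z3(10, 0))
  # from the flank's point of view the spike sits at +delta
  expect_equal(form_z(spike, 350, 3, 150), hoel_z3(0, 10))

  flat <- track_from_profile(rep(4L, 1000))
  for (form in 1:3) {
    expect_equal(form_z(flat, 500, form, 150), 0)
  }
})

test_that("detect_form_regions finds a planted cluster and nothing else", {
  expect_equal(nrow(detect_form_regions(empty_track(), empty_track(), 1,
                                        params_r1())), 0L)

  # 10 stacked reads -> rectangular coverage 10 over [2001, 2100]
  chip <- build_track(make_reads(rep(2001L, 10)), 100)
  regions <- detect_form_regions(chip, empty_track(), 1, params_r1())
  expect_equal(nrow(regions), 1L)
  expect_true(regions$start <= 2050 && 2050 <= regions$end)
  expect_equal(regions$summit_z, hoel_z1(0, 10, 0))
  expect_equal(regions$er_center, 11)          # (1 + 10) / 1
  expect_equal(regions$form, 1L)
  expect_equal(regions$nlp, nlp_from_z(hoel_z1(0, 10, 0)))

  # the same region must agree with positionwise brute-force evaluation
  p <- params_r1()
  xs <- 1500:2600
  zf <- form_z(chip, xs, 1, p$delta)
  z4 <- hoel_z4(coverage_at(chip, xs), numeric(length(xs)), 1)
  ok <- zf > p$min_z & z4 > p$min_z
  expect_equal(range(xs[ok]), c(regions$start, regions$end))
})

test_that("a wide constant plateau yields no regions", {
  reads <- plateau_reads(width = 500L)
  chip <- build_track(reads[reads$strand == "+", ], 100)
  control <- chip
  for (form in 1:3) {
    expect_equal(nrow(detect_form_regions(chip, control, form, params_r1())),
                 0L)
  }
})

test_that("compute_min_er applies the interpolated quantile per strand", {
  regions <- tibble::tibble(
    chrom = "chr1", strand = "+", form = 1L, start = 1L, end = 20L,
    center = 10L, summit = 10L, summit_z = 2, er_center = c(1:8), nlp = 1
  )
  expect_equal(compute_min_er(regions, 3 / 8),
               c("+" = 3.625, "-" = 0))      # type-7 quantile of 1..8

  single <- regions[5, ]
  single$er_center <- 5
  expect_equal(compute_min_er(single, 3 / 8)[["+"]], 5)
  expect_equal(compute_min_er(single, 0.9)[["+"]], 5)

  expect_equal(compute_min_er(regions[0, ], 3 / 8), c("+" = 0, "-" = 0))
})

test_that("apply_er_filter keeps strictly greater enrichment only", {
  regions <- tibble::tibble(
    chrom = "chr1", strand = c("+", "+", "+"), form = 1L,
    start = c(1L, 100L, 200L), end = c(20L, 120L, 220L),
    center = c(10L, 110L, 210L), summit = c(10L, 110L, 210L),
    summit_z = 2, er_center = c(2, 3, 4), nlp = 1
  )
  expect_equal(apply_er_filter(regions, c("+" = 0, "-" = 0)), regions)
  kept <- apply_er_filter(regions, c("+" = 3, "-" = 0))
  expect_equal(kept$er_center, 4)            # er = 3 fails strict >
  expect_equal(nrow(apply_er_filter(regions[0, ], c("+" = 3, "-" = 0))), 0L)
})

test_that("replicate filter demands positive signal in every replicate", {
  chip <- build_track(make_reads(rep(2001L, 10)), 100)
  p <- params_r1()
  regions <- detect_form_regions(chip, empty_track(), 1, p)

  # fewer than two replicates: identity
  expect_equal(apply_replicate_filter(regions, list(chip), empty_track(),
                                      1, p), regions)
  # two supporting replicates keep the region
  expect_equal(nrow(apply_replicate_filter(regions, list(chip, chip),
                                           empty_track(), c(1, 1), p)), 1L)
  # a replicate with no coverage in the region kills it (z = 0 is not > 0)
  expect_equal(nrow(apply_replicate_filter(
    regions, list(chip, empty_track()), empty_track(), c(1, 1), p)), 0L)
})

test_that("strand pairing demands exactly one overlap on each side", {
  f <- region_row(100, 199)
  r1 <- region_row(150, 249, "-")
  expect_equal(nrow(pair_strand_regions(f, r1)), 1L)

  # one forward overlapping two reverse regions: ambiguous, nothing emitted
  r2 <- dplyr::bind_rows(r1, region_row(180, 230, "-"))
  expect_equal(nrow(pair_strand_regions(f, r2)), 0L)

  # disjoint regions pair nothing
  expect_equal(nrow(pair_strand_regions(f, region_row(500, 600, "-"))), 0L)

  # different chromosomes never pair
  expect_equal(nrow(pair_strand_regions(
    f, region_row(150, 249, "-", chrom = "chr2"))), 0L)
})

test_that("lag_filter keeps pairs with lag strictly above min_lag", {
  # forward cluster then reverse cluster shifted 80 bp downstream
  fwd <- build_track(make_reads(rep(1001L, 8)), 100)
  rev_prof <- track_from_profile(c(rep(0L, 1080), rep(8L, 100)),
                                 strand = "-")
  pairs <- pair_strand_regions(region_row(1001, 1100),
                               region_row(1081, 1180, "-"))
  kept <- lag_filter(pairs, fwd, rev_prof, triform_params())
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$lag, 80L)

  # coincident profiles: lag 0 fails min_lag = 10
  coincident <- lag_filter(pairs, fwd,
                           track_from_profile(c(rep(0L, 1000), rep(8L, 100)),
                                              strand = "-"),
                           triform_params())
  expect_equal(nrow(coincident), 0L)

  # a pair whose reverse profile is silent is dropped, not an error
  silent <- lag_filter(pairs, fwd, empty_track(strand = "-"),
                       triform_params())
  expect_equal(nrow(silent), 0L)

  empty <- lag_filter(pair_strand_regions(region_row(1, 2)[0, ],
                                          region_row(1, 2)[0, ]),
                      fwd, rev_prof, triform_params())
  expect_equal(nrow(empty), 0L)
})

test_that("score_peaks spans the union and sums strand NLPs", {
  z <- stats::qnorm(0.9)
  pairs <- pair_strand_regions(region_row(100, 199, z = z),
                               region_row(150, 249, "-", z = z))
  pairs$lag <- 80L
  peak <- score_peaks(pairs)
  expect_equal(c(peak$start, peak$end), c(100L, 249L))
  expect_equal(peak$peak_loc, 174L)
  expect_equal(peak$peak_nlp, 2)       # each strand NLP is exactly 1

  # swapping the strand roles leaves the call unchanged
  swapped <- pair_strand_regions(region_row(150, 249, z = z),
                                 region_row(100, 199, "-", z = z))
  swapped$lag <- 80L
  peak2 <- score_peaks(swapped)
  expect_equal(peak2[c("start", "end", "peak_loc", "peak_nlp")],
               peak[c("start", "end", "peak_loc", "peak_nlp")])
})

test_that("resolve_forms rejects redundant partial forms and merges pairs", {
  p1 <- peak_row(100, 300, 1)
  expect_equal(resolve_forms(p1, empty_peaks_tbl(), empty_peaks_tbl()), p1)

  # Form 2 overlapping a Form 1 peak is redundant
  out <- resolve_forms(p1, peak_row(250, 400, 2), empty_peaks_tbl())
  expect_equal(out, p1)

  # overlapping Form 2 + Form 3 (no Form 1 nearby) merge into Form 1
  merged <- resolve_forms(empty_peaks_tbl(),
                          peak_row(100, 200, 2, nlp = 3, lag = 40L),
                          peak_row(180, 300, 3, nlp = 4, lag = 60L))
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(100L, 300L))
  expect_equal(merged$peak_loc, 200L)
  expect_equal(merged$form, 1L)
  expect_equal(merged$peak_nlp, 7)     # sum of the two scores
  expect_equal(merged$lag, 60L)        # max of the two lags

  # residual overlaps resolved by NLP rank
  out2 <- resolve_forms(dplyr::bind_rows(peak_row(100, 300, 1, nlp = 9),
                                         peak_row(250, 450, 1, nlp = 4)),
                        empty_peaks_tbl(), empty_peaks_tbl())
  expect_equal(out2$peak_nlp, 9)
})

test_that("call_peaks end-to-end behaviour on edge inputs", {
  # a strong and a weaker binding site, each with shifted strand clusters
  reads <- make_reads(
    c(rep(5001L, 10), rep(5115L, 10), rep(9001L, 4), rep(9115L, 4)),
    c(rep("+", 10), rep("-", 10), rep("+", 4), rep("-", 4))
  )
  # control identical to ChIP: enrichment condition unsatisfiable
  none <- call_peaks(reads, reads)
  expect_equal(nrow(tidy(none)), 0L)

  # empty ChIP input
  expect_equal(nrow(tidy(call_peaks(make_reads(integer()),
                                    make_reads(integer())))), 0L)

  # with a sparse control, the strong site is called; the weak site's
  # enrichment ratio falls at/below the data-derived min.er cut-off
  ctrl <- make_reads(50000L)
  calls <- call_peaks(reads, ctrl, triform_params(ratio = 1))
  expect_equal(nrow(tidy(calls)), 1L)
  expect_equal(tidy(calls)$form, 1L)
  expect_true(abs(tidy(calls)$peak_loc - 5100L) < 30)
  expect_gt(tidy(calls)$lag, 10L)
})

test_that("a uniform plateau wider than 2*delta + min_n is rejected", {
  reads <- plateau_reads(width = 500L, depth = 5L)
  calls <- call_peaks(reads, reads)   # matched control, r = 1
  expect_equal(nrow(tidy(calls)), 0L)
  # even against a weak control: the interior is flat (z1 = 0) and the edge
  # ramps coincide across strands (lag 0), so nothing survives
  weak_ctrl <- make_reads(9000L)
  calls2 <- call_peaks(reads, weak_ctrl, triform_params(ratio = 1))
  expect_equal(nrow(tidy(calls2)), 0L)
})

test_that("peak calling is deterministic and strand-mirror symmetric", {
  sim <- simulate_chipseq(genome_length = 3e5, n_sites = 8, seed = 104)
  calls_a <- call_peaks(sim$chip, sim$control)
  calls_b <- call_peaks(sim$chip, sim$control)
  expect_identical(tidy(calls_a), tidy(calls_b))

  # mirror the genome: x -> L + 1 - x with strands swapped
  L <- sim$config$genome_length
  mirror <- function(reads) {
    tibble::tibble(
      chrom = reads$chrom,
      start = L + 1L - reads$end,
      end = L + 1L - reads$start,
      name = reads$name, score = reads$score,
      strand = ifelse(reads$strand == "+", "-", "+")
    )
  }
  mirrored <- call_peaks(mirror(sim$chip), mirror(sim$control))
  a <- dplyr::arrange(tidy(calls_a), start)
  b <- dplyr::arrange(tidy(mirrored), dplyr::desc(end))
  expect_equal(nrow(a), nrow(b))
  expect_equal(L + 1L - b$end, a$start)
  expect_equal(L + 1L - b$start, a$end)
  expect_equal(b$peak_nlp[order(L + 1L - b$end)], a$peak_nlp)
})

test_that("every reported peak's strand regions satisfy all conditions", {
  sim <- simulate_chipseq(genome_length = 5e5, n_sites = 12, seed = 7)
  calls <- call_peaks(sim$chip, sim$control)
  p <- calls$params
  pairs <- calls$regions
  expect_gt(nrow(pairs), 0L)

  fwd <- build_track(sim$chip[sim$chip$strand == "+", ], p$read_width,
                     "chr1", "+")
  rev <- build_track(sim$chip[sim$chip$strand == "-", ], p$read_width,
                     "chr1", "-")
  cfw <- build_track(sim$control[sim$control$strand == "+", ], p$read_width,
                     "chr1", "+")
  crv <- build_track(sim$control[sim$control$strand == "-", ], p$read_width,
                     "chr1", "-")

  audit_region <- function(trk, ctl, start, end, form) {
    xs <- start:end
    zf <- form_z(trk, xs, form, p$delta)
    z4 <- hoel_z4(coverage_at(trk, xs), coverage_at(ctl, xs), p$ratio)
    all(zf > p$min_z) && all(z4 > p$min_z) &&
      (end - start + 1L) > p$min_n
  }
  for (i in seq_len(nrow(pairs))) {
    expect_true(audit_region(fwd, cfw, pairs$fwd_start[i], pairs$fwd_end[i],
                             pairs$form[i]))
    expect_true(audit_region(rev, crv, pairs$rev_start[i], pairs$rev_end[i],
                             pairs$form[i]))
    expect_gt(pairs$fwd_er[i], calls$min_er[["+"]])
    expect_gt(pairs$rev_er[i], calls$min_er[["-"]])
    expect_gt(pairs$lag[i], p$min_lag)
  }
  # final peak list is non-overlapping per chromosome
  peaks <- dplyr::arrange(tidy(calls), chrom, start)
  if (nrow(peaks) > 1L) {
    same <- peaks$chrom[-1] == peaks$chrom[-nrow(peaks)]
    expect_true(all(peaks$start[-1][same] > peaks$end[-nrow(peaks)][same]))
  }
})

test_that("tightening any threshold never increases the peak count", {
  sim <- simulate_chipseq(genome_length = 5e5, n_sites = 12, seed = 31)
  base <- nrow(tidy(call_peaks(sim$chip, sim$control)))
  variants <- list(
    triform_params(min_z = min_z_from_p(0.05)),
    triform_params(min_n = 30),
    triform_params(min_lag = 60),
    triform_params(min_er_quantile = 0.7)
  )
  for (p in variants) {
    expect_lte(nrow(tidy(call_peaks(sim$chip, sim$control, p))), base)
  }
})
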
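#' Simulate a transcription-factor ChIP-Seq experiment
#'
#' Generates ChIP and control read sets with the structure the detection
#' procedure assumes: planted binding sites each producing a cluster of
#' forward-strand reads upstream and reverse-strand reads downstream of the
#' site (the fragment-end shift), over uniform Poisson background, with a
#' matched site-free control sample. Read centers around a site at position
#' p are drawn as `Normal(p - fragment_length/2 + read_length/2,
#' position_sd)` on the forward strand and the mirror image on the reverse
#' strand, so the expected offset between the two cluster centers is
#' `fragment_length - read_length`. Per-site, per-strand read counts are
#' Poisson with mean `reads_per_site * strength`. Background and control
#' reads are uniform with the stated per-bp, per-strand Poisson rates. Reads
#' extending past chromosome ends are truncated at emission. The whole
#' simulation is reproducible from `seed`.
#'
#' Planted sites are placed uniformly, at least `fragment_length +
#' 4 * position_sd` from either chromosome end and at least
#' `2 * fragment_length` apart, so each site is a distinct, resolvable
#' binding event.
#'
#' @param genome_length Length in bp of each simulated chromosome.
#' @param chroms Chromosome name(s). One chromosome by default.
#' @param n_sites Number of planted binding sites per chromosome (ignored
#'   when `site_positions` is given).
#' @param site_positions Optional explicit site positions: a tibble with
#'   columns `chrom` and `position` (and optionally `strength`).
#' @param fragment_length Mean sequenced-fragment length in bp; governs the
#'   strand shift. Must exceed `read_length`.
#' @param read_length Emitted read length in bp.
#' @param reads_per_site Mean read count per site per strand.
#' @param position_sd Standard deviation of read-center jitter in bp.
#' @param background_rate ChIP background rate, reads per bp per strand.
#' @param control_rate Control rate, reads per bp per strand.
#' @param strengths Optional per-site strength multipliers (recycled);
#'   default 1 for every site.
#' @param seed Integer seed; the simulation is a pure function of its
#'   arguments.
#' @return A `triform_sim` object: list with tibbles `chip`, `control` (read
#'   tables in the internal 1-based convention, ready for [call_peaks()] or
#'   [write_bed_reads()]), `truth` (`chrom`, `position`, `strength` = expected
#'   reads per strand) and `config`.
#' @examples
#' sim <- simulate_chipseq(genome_length = 1e5, n_sites = 3, seed = 1)
#' glance(sim)
#' @export
simulate_chipseq <- function(genome_length = 2e6,
                             chroms = "chr1",
                             n_sites = 50,
                             site_positions = NULL,
                             fragment_length = 200,
                             read_length = 36,
                             reads_per_site = 40,
                             position_sd = 20,
                             background_rate = 0.005,
                             control_rate = background_rate,
                             strengths = 1,
                             seed = 1) {
  stopifnot(genome_length > 0, fragment_length > read_length,
            read_length > 0, reads_per_site >= 0, position_sd >= 0,
            background_rate >= 0, control_rate >= 0, n_sites >= 0)
  genome_length <- as.integer(genome_length)
  config <- list(
    genome_length = genome_length, chroms = chroms, n_sites = n_sites,
    fragment_length = fragment_length, read_length = read_length,
    reads_per_site = reads_per_site, position_sd = position_sd,
    background_rate = background_rate, control_rate = control_rate,
    seed = seed
  )
  withr::with_seed(as.integer(seed), {
    truth_list <- list()
    chip_list <- list()
    ctrl_list <- list()
    for (chr in chroms) {
      if (is.null(site_positions)) {
        pos <- draw_site_positions(n_sites, genome_length, fragment_length,
                                   position_sd)
        stren <- rep_len(strengths, length(pos))
      } else {
        sub <- site_positions[site_positions$chrom == chr, , drop = FALSE]
        pos <- as.integer(sub$position)
        if (any(pos < 1L | pos > genome_length)) {
          stop("site position outside the genome on ", chr, call. = FALSE)
        }
        stren <- if ("strength" %in% names(sub)) sub$strength
                 else rep_len(strengths, length(pos))
      }
      truth_list[[chr]] <- tibble::tibble(
        chrom = chr, position = pos,
        strength = reads_per_site * stren
      )
      chip_list[[chr]] <- dplyr::bind_rows(
        emit_site_reads(chr, pos, stren, config),
        emit_uniform_reads(chr, background_rate, config, "bg")
      )
      ctrl_list[[chr]] <- emit_uniform_reads(chr, control_rate, config, "ctl")
    }
    chip <- finalize_reads(dplyr::bind_rows(chip_list), genome_length)
    control <- finalize_reads(dplyr::bind_rows(ctrl_list), genome_length)
    truth <- dplyr::bind_rows(truth_list)
  })
  structure(
    list(chip = chip, control = control, truth = truth, config = config),
    class = "triform_sim"
  )
}

# uniform site draw with edge margin and minimum spacing (rejection sampling)
draw_site_positions <- function(n_sites, genome_length, fragment_length,
                                position_sd) {
  if (n_sites == 0L) return(integer())
  margin <- ceiling(fragment_length + 4 * position_sd)
  min_gap <- 2 * fragment_length
  lo <- margin + 1L
  hi <- genome_length - margin
  if (hi - lo < (n_sites - 1) * min_gap) {
    stop("genome too short to place ", n_sites, " sites ", min_gap,
         " bp apart", call. = FALSE)
  }
  pos <- integer(0)
  tries <- 0L
  while (length(pos) < n_sites) {
    cand <- as.integer(floor(stats::runif(1, lo, hi + 1)))
    if (!length(pos) || min(abs(pos - cand)) >= min_gap) {
      pos <- c(pos, cand)
    }
    tries <- tries + 1L
    if (tries > 1000L * n_sites) {
      stop("failed to place sites; genome too crowded", call. = FALSE)
    }
  }
  sort(pos)
}

emit_site_reads <- function(chr, positions, strengths, cfg) {
  if (length(positions) == 0L) return(empty_reads())
  rl <- cfg$read_length
  fl <- cfg$fragment_length
  out <- list()
  for (i in seq_along(positions)) {
    p <- positions[i]
    for (s in c("+", "-")) {
      n <- stats::rpois(1, cfg$reads_per_site * strengths[i])
      if (n == 0L) next
      mu <- if (s == "+") p - fl / 2 + rl / 2 else p + fl / 2 - rl / 2
      centers <- round(stats::rnorm(n, mu, cfg$position_sd))
      start <- as.integer(centers - floor(rl / 2))
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chr, start = start, end = start + as.integer(rl) - 1L,
        name = sprintf("site%d_%s", i, s), score = 0, strand = s
      )
    }
  }
  dplyr::bind_rows(out)
}

emit_uniform_reads <- function(chr, rate, cfg, label) {
  if (rate == 0) return(empty_reads())
  out <- list()
  for (s in c("+", "-")) {
    n <- stats::rpois(1, rate * cfg$genome_length)
    if (n == 0L) next
    start <- as.integer(floor(stats::runif(n, 1, cfg$genome_length + 1)))
    out[[length(out) + 1L]] <- tibble::tibble(
      chrom = chr, start = start,
      end = start + as.integer(cfg$read_length) - 1L,
      name = sprintf("%s_%s%d", label, s, seq_len(n)), score = 0, strand = s
    )
  }
  dplyr::bind_rows(out)
}

# truncate at chromosome ends, drop degenerate reads, fix deterministic order
finalize_reads <- function(reads, genome_length) {
  if (nrow(reads) == 0L) return(empty_reads())
  reads$start <- pmax(reads$start, 1L)
  reads$end <- pmin(reads$end, genome_length)
  reads <- reads[reads$start <= reads$end, , drop = FALSE]
  dplyr::arrange(reads, .data$chrom, .data$strand, .data$start, .data$name)
}

#' @export
print.triform_sim <- function(x, ...) {
  cat(sprintf(
    "<triform_sim> %d site(s) on %s; %d ChIP / %d control reads (seed %s)\n",
    nrow(x$truth), paste(x$config$chroms, collapse = ","),
    nrow(x$chip), nrow(x$control), format(x$config$seed)))
  invisible(x)
}

#' Tidy a simulated experiment
#'
#' @param x A `triform_sim` object.
#' @param ... Unused.
#' @return The truth table: one row per planted site.
#' @export
tidy.triform_sim <- function(x, ...) {
  x$truth
}

#' One-row summary of a simulated experiment
#'
#' @param x A `triform_sim` object.
#' @param ... Unused.
#' @return One-row tibble of site and read counts plus the expected
#'   inter-strand lag `fragment_length - read_length`.
#' @export
glance.triform_sim <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$truth),
    n_chip_reads = nrow(x$chip),
    n_control_reads = nrow(x$control),
    genome_length = x$config$genome_length,
    expected_lag = x$config$fragment_length - x$config$read_length,
    seed = x$config$seed
  )
}

#' Plot simulated read-start density by strand
#'
#' Histogram of read start positions, colored by strand, with planted sites
#' marked; a quick visual check of the strand-shift structure.
#'
#' @param object A `triform_sim` object.
#' @param binwidth Histogram bin width in bp.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triform_sim <- function(object, binwidth = 50, ...) {
  ggplot2::ggplot(object$chip,
                  ggplot2::aes(x = .data$start, fill = .data$strand)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::geom_vline(data = object$truth,
                        ggplot2::aes(xintercept = .data$position),
                        linetype = "dotted", linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "read start (bp)", y = "reads") +
    ggplot2::theme_minimal()
}

#' Write simulated reads and truth to disk
#'
#' Writes `chip.bed`, `control.bed` and `truth.tsv` under `dir`.
#'
#' @param sim A `triform_sim` object.
#' @param dir Output directory (created if needed).
#' @return The three paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chip <- file.path(dir, "chip.bed")
  control <- file.path(dir, "control.bed")
  truth <- file.path(dir, "truth.tsv")
  write_bed_reads(sim$chip, chip)
  write_bed_reads(sim$control, control)
  utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(chip = chip, control = control, truth = truth))
}

#' Read a truth table written by [write_sim()]
#'
#' @param path Path to a `truth.tsv`.
#' @return Tibble `chrom`, `position`, `strength`.
#' @export
read_truth <- function(path) {
  tab <- utils::read.delim(path, header = TRUE,
                           colClasses = c("character", "integer", "numeric"))
  tibble::as_tibble(tab)
}

#' Evaluate peak calls against simulator ground truth
#'
#' Greedy one-to-one matching: peaks are taken in order of decreasing
#' `peak_nlp` and each is matched to the nearest still-unmatched true site
#' within `tol` bp of its `peak_loc`. Recall is the fraction of true sites
#' matched; the false-discovery proportion is the fraction of peaks left
#' unmatched (reported as 0, with `fdp_defined = FALSE`, when there are no
#' peaks).
#'
#' @param peaks Peak tibble (as from [call_peaks()]) or a `triform_calls`
#'   object.
#' @param truth Truth tibble (`chrom`, `position`).
#' @param tol Matching tolerance in bp (0 means exact).
#' @return A `triform_eval` object; see [tidy.triform_eval()] and
#'   [glance.triform_eval()].
#' @export
evaluate_calls <- function(peaks, truth, tol = 100) {
  stopifnot(tol >= 0)
  if (inherits(peaks, "triform_calls")) peaks <- peaks$peaks
  peaks <- sort_peaks(peaks)
  matched_site <- rep(NA_integer_, nrow(peaks))
  site_taken <- rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(peaks))) {
    cand <- which(!site_taken & truth$chrom == peaks$chrom[i])
    if (!length(cand)) next
    d <- abs(truth$position[cand] - peaks$peak_loc[i])
    j <- cand[which.min(d)]
    if (abs(truth$position[j] - peaks$peak_loc[i]) <= tol) {
      matched_site[i] <- j
      site_taken[j] <- TRUE
    }
  }
  matches <- tibble::tibble(
    chrom = peaks$chrom,
    peak_loc = peaks$peak_loc,
    peak_nlp = peaks$peak_nlp,
    site = ifelse(is.na(matched_site), NA_integer_,
                  truth$position[matched_site]),
    error = abs(peaks$peak_loc - truth$position[matched_site]),
    matched = !is.na(matched_site)
  )
  structure(
    list(matches = matches, n_truth = nrow(truth), tol = tol),
    class = "triform_eval"
  )
}

#' @export
print.triform_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<triform_eval> recall %.3f, FDP %.3f, median error %s bp (%d peaks vs %d sites, tol %g bp)\n",
    g$recall, g$fdp, format(g$median_error), g$n_peaks, g$n_truth, x$tol))
  invisible(x)
}

#' Per-peak matching detail
#'
#' @param x A `triform_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per peak: matched site, positional error and
#'   match status.
#' @export
tidy.triform_eval <- function(x, ...) {
  x$matches
}

#' One-row evaluation summary
#'
#' @param x A `triform_eval` object.
#' @param ... Unused.
#' @return One-row tibble: `recall`, `fdp`, `fdp_defined`, `median_error`,
#'   counts.
#' @export
glance.triform_eval <- function(x, ...) {
  m <- x$matches
  n_peaks <- nrow(m)
  n_matched <- sum(m$matched)
  tibble::tibble(
    recall = if (x$n_truth > 0) n_matched / x$n_truth else NA_real_,
    fdp = if (n_peaks > 0) (n_peaks - n_matched) / n_peaks else 0,
    fdp_defined = n_peaks > 0,
    median_error = if (n_matched > 0) {
      stats::median(m$error[m$matched])
    } else {
      NA_real_
    },
    n_peaks = n_peaks,
    n_matched = n_matched,
    n_truth = x$n_truth
  )
}
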
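#' Call transcription-factor binding peaks
#'
#' Runs the full detection procedure on ChIP and control reads: strand
#' extension and coverage, per-strand Form 1/2/3 region detection under the
#' form and enrichment z tests, the data-derived min.er enrichment-ratio
#' filter, optional replicate consistency, cross-strand pairing with the
#' inter-strand lag test, and resolution/merging of the three forms into a
#' final non-overlapping, NLP-ranked peak list.
#'
#' Replicates are pooled into a single sample for the main statistics; when
#' two or more replicates are supplied, the per-replicate sign filter is
#' additionally applied. The chromosome universe is taken from the data
#' unless `chrom_sizes` is supplied, in which case reads are clipped to the
#' stated lengths.
#'
#' @param chip A tibble of ChIP reads (as from [read_bed_reads()] or
#'   [simulate_chipseq()]), or a list of such tibbles, one per replicate.
#' @param control A tibble of control reads.
#' @param params [triform_params()]. A `NULL` `ratio` is replaced by the
#'   control/ChIP library-size ratio computed from the pooled data.
#' @param chrom_sizes Optional named chromosome lengths.
#' @return A `triform_calls` object: list with
#'   \describe{
#'     \item{peaks}{tibble of peak calls (`chrom`, `start`, `end`,
#'       `peak_loc`, `peak_nlp`, `form`, `lag`, `er`), sorted by decreasing
#'       `peak_nlp`}
#'     \item{params}{the parameters used, with `ratio` filled in}
#'     \item{min_er}{per-strand min.er cut-offs}
#'     \item{library_sizes}{read counts per replicate, pooled, and control}
#'     \item{stages}{tibble of candidate counts surviving each stage}
#'     \item{regions}{per-strand region candidates backing each final peak}
#'   }
#' @examples
#' sim <- simulate_chipseq(genome_length = 2e5, n_sites = 5, seed = 7)
#' calls <- call_peaks(sim$chip, sim$control)
#' tidy(calls)
#' glance(calls)
#' @export
call_peaks <- function(chip, control, params = triform_params(),
                       chrom_sizes = NULL) {
  params <- as_triform_params(params)
  if (is.data.frame(chip)) chip <- list(chip)
  if (!is.list(chip) || length(chip) == 0L) {
    stop("`chip` must be a read tibble or a non-empty list of them",
         call. = FALSE)
  }
  chip <- lapply(chip, validate_reads)
  control <- validate_reads(control)
  pooled <- dplyr::bind_rows(chip)

  rep_sizes <- vapply(chip, nrow, integer(1))
  lib <- list(replicates = rep_sizes, pooled = nrow(pooled),
              control = nrow(control))
  if (nrow(pooled) == 0L) {
    return(new_triform_calls(empty_peaks(), params, c("+" = 0, "-" = 0), lib,
                             stage_skeleton(), pair_skeleton()))
  }
  if (is.null(params$ratio)) {
    params$ratio <- library_size_ratio(nrow(pooled), max(nrow(control), 1L))
  }
  use_replicates <- length(chip) >= 2L
  rep_ratios <- if (use_replicates) {
    vapply(rep_sizes, function(nk) {
      library_size_ratio(nk, max(nrow(control), 1L))
    }, numeric(1))
  } else {
    numeric(0)
  }

  chroms <- if (!is.null(chrom_sizes)) {
    intersect(names(chrom_sizes), unique(c(pooled$chrom, control$chrom)))
  } else {
    sort(unique(c(pooled$chrom, control$chrom)))
  }
  strands <- c("+", "-")
  w <- params$read_width

  # pass 1: tracks and raw region detection everywhere
  tracks <- list()
  regions <- list()
  for (chr in chroms) {
    for (s in strands) {
      key <- paste0(chr, s)
      tracks[[key]] <- build_track(
        pooled[pooled$chrom == chr & pooled$strand == s, , drop = FALSE],
        w, chrom = chr, strand = s, chrom_sizes = chrom_sizes
      )
      tracks[[paste0("ctrl", key)]] <- build_track(
        control[control$chrom == chr & control$strand == s, , drop = FALSE],
        w, chrom = chr, strand = s, chrom_sizes = chrom_sizes
      )
      if (use_replicates) {
        for (k in seq_along(chip)) {
          rk <- chip[[k]]
          tracks[[paste0("rep", k, key)]] <- build_track(
            rk[rk$chrom == chr & rk$strand == s, , drop = FALSE],
            w, chrom = chr, strand = s, chrom_sizes = chrom_sizes
          )
        }
      }
      for (form in 1:3) {
        regions[[paste0(key, form)]] <- detect_form_regions(
          tracks[[key]], tracks[[paste0("ctrl", key)]], form, params
        )
      }
    }
  }
  regions <- dplyr::bind_rows(regions)
  n_detected <- nrow(regions)

  # pass 2: genome-wide per-strand min.er, then the downstream filters
  min_er <- compute_min_er(regions[regions$form == 1L, , drop = FALSE],
                           params$min_er_quantile)
  regions <- apply_er_filter(regions, min_er)
  n_er <- nrow(regions)

  if (use_replicates && nrow(regions) > 0L) {
    kept <- list()
    for (chr in chroms) {
      for (s in strands) {
        key <- paste0(chr, s)
        sub <- regions[regions$chrom == chr & regions$strand == s, ,
                       drop = FALSE]
        if (nrow(sub) == 0L) next
        rep_trks <- lapply(seq_along(chip), function(k) {
          tracks[[paste0("rep", k, key)]]
        })
        kept[[key]] <- apply_replicate_filter(
          sub, rep_trks, tracks[[paste0("ctrl", key)]], rep_ratios, params
        )
      }
    }
    regions <- dplyr::bind_rows(kept)
    if (nrow(regions) == 0L) regions <- empty_regions()
  }
  n_rep <- nrow(regions)

  all_pairs <- list(pair_skeleton())
  for (chr in chroms) {
    for (form in 1:3) {
      f <- regions[regions$chrom == chr & regions$strand == "+" &
                     regions$form == form, , drop = FALSE]
      r <- regions[regions$chrom == chr & regions$strand == "-" &
                     regions$form == form, , drop = FALSE]
      pairs <- pair_strand_regions(f, r)
      if (nrow(pairs) > 0L) {
        all_pairs[[length(all_pairs) + 1L]] <- pairs
      }
    }
  }
  pairs <- dplyr::bind_rows(all_pairs)
  n_paired <- nrow(pairs)

  lagged <- list()
  for (chr in unique(pairs$chrom)) {
    sub <- pairs[pairs$chrom == chr, , drop = FALSE]
    lagged[[chr]] <- lag_filter(sub, tracks[[paste0(chr, "+")]],
                                tracks[[paste0(chr, "-")]], params)
  }
  pairs <- if (length(lagged)) dplyr::bind_rows(lagged) else {
    p <- pair_skeleton()
    p$lag <- integer()
    p
  }
  n_lag <- nrow(pairs)

  peaks_by_form <- lapply(1:3, function(form) {
    score_peaks(pairs[pairs$form == form, , drop = FALSE])
  })
  peaks <- resolve_forms(peaks_by_form[[1L]], peaks_by_form[[2L]],
                         peaks_by_form[[3L]])
  stages <- tibble::tibble(
    stage = c("detected", "er_filter", "replicate_filter", "paired",
              "lag_filter", "final"),
    n = c(n_detected, n_er, n_rep, n_paired, n_lag, nrow(peaks))
  )
  new_triform_calls(peaks, params, min_er, lib, stages, pairs)
}

stage_skeleton <- function() {
  tibble::tibble(
    stage = c("detected", "er_filter", "replicate_filter", "paired",
              "lag_filter", "final"),
    n = rep(0L, 6L)
  )
}

new_triform_calls <- function(peaks, params, min_er, library_sizes, stages,
                              pairs) {
  structure(
    list(peaks = peaks, params = params, min_er = min_er,
         library_sizes = library_sizes, stages = stages, regions = pairs),
    class = "triform_calls"
  )
}

#' Call peaks directly from BED files
#'
#' Thin wrapper around [call_peaks()] that reads one or more ChIP replicate
#' BED files and a control BED file.
#'
#' @param chip_files Character vector of ChIP BED paths (one per replicate).
#' @param control_file Control BED path.
#' @inheritParams call_peaks
#' @param chrom_sizes_file Optional chromosome-sizes file path.
#' @return A `triform_calls` object.
#' @export
call_peaks_files <- function(chip_files, control_file,
                             params = triform_params(),
                             chrom_sizes_file = NULL) {
  chip <- lapply(chip_files, read_bed_reads)
  control <- read_bed_reads(control_file)
  sizes <- if (!is.null(chrom_sizes_file)) {
    read_chrom_sizes(chrom_sizes_file)
  }
  call_peaks(chip, control, params, sizes)
}

#' @export
print.triform_calls <- function(x, ...) {
  cat(sprintf("<triform_calls> %d peak(s); r = %.4g; min.er [+] %.4g [-] %.4g\n",
              nrow(x$peaks), x$params$ratio %||% NA_real_,
              x$min_er[["+"]], x$min_er[["-"]]))
  print(x$peaks, n = 10)
  invisible(x)
}

#' Tidy a peak-call result
#'
#' @param x A `triform_calls` object.
#' @param ... Unused.
#' @return The peak tibble, one row per peak, sorted by decreasing
#'   `peak_nlp`.
#' @export
tidy.triform_calls <- function(x, ...) {
  x$peaks
}

#' One-row summary of a peak-call result
#'
#' @param x A `triform_calls` object.
#' @param ... Unused.
#' @return A one-row tibble: peak count, peaks per form, library sizes, the
#'   library ratio and the per-strand min.er cut-offs.
#' @export
glance.triform_calls <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x$peaks),
    n_form1 = sum(x$peaks$form == 1L),
    n_form2 = sum(x$peaks$form == 2L),
    n_form3 = sum(x$peaks$form == 3L),
    n_chip_reads = x$library_sizes$pooled,
    n_control_reads = x$library_sizes$control,
    n_replicates = length(x$library_sizes$replicates),
    ratio = x$params$ratio %||% NA_real_,
    min_er_fwd = x$min_er[["+"]],
    min_er_rev = x$min_er[["-"]],
    min_z = x$params$min_z
  )
}

#' Plot called peaks along the genome
#'
#' A lollipop plot of peak significance (`PEAK.NLP`) against genomic
#' position, faceted by chromosome and colored by peak form.
#'
#' @param object A `triform_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triform_calls <- function(object, ...) {
  peaks <- object$peaks
  ggplot2::ggplot(peaks,
                  ggplot2::aes(x = .data$peak_loc, y = .data$peak_nlp,
                               color = factor(.data$form))) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$peak_loc, yend = 0),
                          linewidth = 0.3) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "PEAK.NLP", color = "form") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
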
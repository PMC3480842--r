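#' Read aligned reads from a BED6 file
#'
#' Parses a BED file of aligned sequencing reads. Input coordinates follow the
#' BED standard (0-based, half-open); they are converted exactly once, here,
#' to the 1-based inclusive convention used everywhere inside the package.
#' Columns beyond the sixth are ignored so BED6+ exports are tolerated;
#' `track`, `browser` and `#` lines are skipped.
#'
#' @param path Path to a BED file with at least 6 tab-separated columns.
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive),
#'   `name`, `score`, `strand` ("+" or "-"), ordered by chromosome, strand
#'   and start position. An empty file yields a zero-row tibble.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t136\tr1\t0\t+", bed)
#' read_bed_reads(bed)
#' @export
read_bed_reads <- function(path) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_reads())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- line_no[which(nf < 6L)[1L]]
    stop("BED parse error at line ", bad,
         ": fewer than 6 tab-separated fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  name <- vapply(fields, `[[`, "", 4L)
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  strand <- vapply(fields, `[[`, "", 6L)

  bad_coord <- is.na(start0) | is.na(end0)
  if (any(bad_coord)) {
    stop("BED parse error at line ", line_no[which(bad_coord)[1L]],
         ": non-integer coordinates", call. = FALSE)
  }
  bad_order <- start0 >= end0
  if (any(bad_order)) {
    stop("BED parse error at line ", line_no[which(bad_order)[1L]],
         ": start must be < end", call. = FALSE)
  }
  bad_strand <- !strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("BED parse error at line ", line_no[which(bad_strand)[1L]],
         ": strand must be '+' or '-'", call. = FALSE)
  }
  tibble::tibble(
    chrom = chrom,
    start = start0 + 1L,   # to 1-based inclusive
    end = end0,
    name = name,
    score = ifelse(is.na(score), 0, score),
    strand = strand
  ) |>
    dplyr::arrange(.data$chrom, .data$strand, .data$start)
}

empty_reads <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character()
  )
}

#' Write aligned reads to a BED6 file
#'
#' Inverse of [read_bed_reads()]: converts the internal 1-based inclusive
#' coordinates back to BED's 0-based half-open convention.
#'
#' @param reads Tibble of reads as returned by [read_bed_reads()] or
#'   [simulate_chipseq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_reads <- function(reads, path) {
  reads <- validate_reads(reads)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   reads$chrom, reads$start - 1L, reads$end,
                   if (nrow(reads)) reads$name else character(),
                   format_num(reads$score), reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome-sizes file
#'
#' @param path Two-column whitespace-separated text: chromosome name and
#'   length in bp.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) {
    stop("chromosome-sizes file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.table(path, header = FALSE, col.names = c("chrom", "len"),
                           colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$chrom)) {
    stop("duplicate chromosome name in ", path, ": ",
         tab$chrom[duplicated(tab$chrom)][1L], call. = FALSE)
  }
  if (any(!is.finite(tab$len)) || any(tab$len <= 0) ||
      any(tab$len != round(tab$len))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  stats::setNames(as.integer(tab$len), tab$chrom)
}

peak_table_cols <- c("CHR", "START", "END", "PEAK.LOC", "PEAK.NLP",
                     "FORM", "LAG", "ER")

#' Write peak calls
#'
#' Writes a peak list either as the tab-delimited peak table (columns
#' `CHR START END PEAK.LOC PEAK.NLP FORM LAG ER`, 1-based inclusive
#' coordinates) or as BED (0-based half-open, `PEAK.NLP` in the score column,
#' the form label as the name). Peaks are sorted by decreasing `PEAK.NLP`
#' before writing, ties broken by chromosome and start.
#'
#' @param peaks Tibble of peak calls as produced by [call_peaks()] /
#'   [tidy()][tidy.triform_calls].
#' @param path Output path.
#' @param format `"table"` (default) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("table", "bed")) {
  format <- match.arg(format)
  peaks <- sort_peaks(peaks)
  if (format == "table") {
    header <- paste(peak_table_cols, collapse = "\t")
    lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%d\t%d\t%s",
                     peaks$chrom, peaks$start, peaks$end, peaks$peak_loc,
                     format_num(peaks$peak_nlp), peaks$form, peaks$lag,
                     format_num(peaks$er))
    writeLines(c(header, lines), path)
  } else {
    lines <- sprintf("%s\t%d\t%d\tform_%d\t%s\t.",
                     peaks$chrom, peaks$start - 1L, peaks$end, peaks$form,
                     format_num(peaks$peak_nlp))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a peak table written by [write_peaks()]
#'
#' @param path Path to a peak table in `"table"` format.
#' @return Tibble with the same columns [call_peaks()] produces.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) {
    stop("peak table not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = c(
                             CHR = "character", START = "integer",
                             END = "integer", `PEAK.LOC` = "integer",
                             `PEAK.NLP` = "numeric", FORM = "integer",
                             LAG = "integer", ER = "numeric"
                           ))
  if (!identical(names(tab), peak_table_cols)) {
    stop("not a triformr peak table: ", path, call. = FALSE)
  }
  tibble::tibble(
    chrom = tab$CHR, start = tab$START, end = tab$END,
    peak_loc = tab$`PEAK.LOC`, peak_nlp = tab$`PEAK.NLP`,
    form = tab$FORM, lag = tab$LAG, er = tab$ER
  )
}

sort_peaks <- function(peaks) {
  dplyr::arrange(peaks, dplyr::desc(.data$peak_nlp), .data$chrom, .data$start)
}

# fixed-notation numeric formatting with enough digits for round trips
format_num <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  trimws(out)
}

validate_reads <- function(reads) {
  required <- c("chrom", "start", "end", "strand")
  if (!is.data.frame(reads) || !all(required %in% names(reads))) {
    stop("`reads` must be a data frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (!"name" %in% names(reads)) reads$name <- paste0("r", seq_len(nrow(reads)))
  if (!"score" %in% names(reads)) reads$score <- 0
  if (nrow(reads) > 0L) {
    if (any(reads$start > reads$end)) {
      stop("read intervals must satisfy start <= end (1-based inclusive)",
           call. = FALSE)
    }
    if (any(!reads$strand %in% c("+", "-"))) {
      stop("read strand must be '+' or '-'", call. = FALSE)
    }
  }
  tibble::as_tibble(reads)
}
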
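#' Genome specification
#'
#' An ordered table of chromosomes with physical (Mb) and genetic (cM)
#' lengths. All physical coordinates in the package are 0-based, half-open
#' and expressed in Mb.
#'
#' @param chrom chromosome identifiers (coerced to character).
#' @param length_mb physical length of each chromosome in Mb.
#' @param length_cm genetic length of each chromosome in cM (optional,
#'   `NA` allowed; genetic coordinates are reporting metadata only).
#' @return A `genome_spec` data.frame with columns `chrom`, `length_mb`,
#'   `length_cm`.
#' @examples
#' genome_spec(1:2, c(90, 50), c(135, 139))
#' @export
genome_spec <- function(chrom, length_mb, length_cm = NA_real_) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("duplicated chromosome ids")
  if (any(!is.finite(length_mb)) || any(length_mb <= 0))
    stop("chromosome physical lengths must be positive")
  if (!all(is.na(length_cm)) && any(length_cm <= 0, na.rm = TRUE))
    stop("chromosome genetic lengths must be positive")
  g <- data.frame(chrom = chrom, length_mb = as.numeric(length_mb),
                  length_cm = as.numeric(rep_len(length_cm, length(chrom))))
  class(g) <- c("genome_spec", "data.frame")
  g
}

#' Default tomato genome specification
#'
#' Twelve chromosomes with physical lengths close to the SL2.40 tomato
#' assembly and nominal genetic lengths. Used as the default genome for the
#' trial simulator; any `genome_spec` can be substituted.
#'
#' @return A `genome_spec` with 12 chromosomes (~768 Mb total).
#' @export
default_genome <- function() {
  genome_spec(
    chrom = as.character(1:12),
    length_mb = c(90.3, 49.9, 64.8, 64.1, 65.2, 46.0,
                  65.3, 63.0, 67.7, 64.8, 53.4, 65.5),
    length_cm = c(135, 139, 124, 135, 90, 100, 100, 95, 105, 115, 93, 133)
  )
}

#' Introgression-line library
#'
#' Container for a genomic library of introgression lines: a genome
#' specification, one or more lines each carrying homozygous donor-genome
#' segments, and a designated control (the recurrent parent, which carries
#' no donor segments).
#'
#' @param genome a [genome_spec()].
#' @param segments data.frame with columns `line`, `chrom`, `start_mb`,
#'   `end_mb` and optionally `start_cm`, `end_cm` (one row per donor
#'   segment; 0-based half-open Mb).
#' @param control identifier of the recurrent parent (must not appear in
#'   `segments$line`).
#' @return An object of class `il_library`.
#' @export
il_library <- function(genome, segments, control = "MM") {
  stopifnot(inherits(genome, "genome_spec"))
  need <- c("line", "chrom", "start_mb", "end_mb")
  if (!all(need %in% names(segments)))
    stop("segments must have columns ", paste(need, collapse = ", "))
  segments$line <- as.character(segments$line)
  segments$chrom <- as.character(segments$chrom)
  if (!"start_cm" %in% names(segments)) segments$start_cm <- NA_real_
  if (!"end_cm" %in% names(segments)) segments$end_cm <- NA_real_
  segments <- segments[, c(need, "start_cm", "end_cm")]

  if (control %in% segments$line)
    stop("control '", control, "' must carry no donor segments")
  if (nrow(segments) == 0L) stop("library has no introgression segments")
  bad <- !segments$chrom %in% genome$chrom
  if (any(bad))
    stop("unknown chromosome id(s): ",
         paste(unique(segments$chrom[bad]), collapse = ", "))
  if (any(!is.finite(segments$start_mb)) || any(!is.finite(segments$end_mb)))
    stop("non-finite segment coordinates")
  if (any(segments$end_mb <= segments$start_mb))
    stop("segment with end <= start")
  if (any(segments$start_mb < 0))
    stop("segment with negative start")
  len <- genome$length_mb[match(segments$chrom, genome$chrom)]
  over <- segments$end_mb > len + 1e-9
  if (any(over))
    stop("segment beyond chromosome end for line(s): ",
         paste(unique(segments$line[over]), collapse = ", "))
  # within-line, within-chromosome overlap
  key <- split(seq_len(nrow(segments)),
               paste(segments$line, segments$chrom, sep = "\r"))
  for (idx in key) {
    if (length(idx) < 2L) next
    s <- segments[idx, ]
    s <- s[order(s$start_mb), ]
    if (any(s$start_mb[-1L] < s$end_mb[-nrow(s)] - 1e-12))
      stop("overlapping segments within line '", s$line[1L],
           "' on chromosome ", s$chrom[1L])
  }
  ord <- order(match(segments$chrom, genome$chrom), segments$start_mb,
               segments$line)
  segments <- segments[ord, ]
  rownames(segments) <- NULL
  structure(list(genome = genome, segments = segments, control = control),
            class = "il_library")
}

#' @export
print.il_library <- function(x, ...) {
  cat("Introgression-line library\n")
  cat("  genome:", nrow(x$genome), "chromosomes,",
      format(sum(x$genome$length_mb)), "Mb\n")
  cat("  lines:", length(il_lines(x)), " control:", x$control, "\n")
  cat("  segments:", nrow(x$segments), "\n")
  invisible(x)
}

#' Line identifiers of a library
#' @param library an [il_library()].
#' @return Character vector of IL identifiers (control excluded).
#' @export
il_lines <- function(library) unique(library$segments$line)

#' Donor segments of one line on one chromosome
#'
#' @param library an [il_library()].
#' @param line_id line identifier (the control is valid and yields an
#'   empty result, as it carries no donor segments).
#' @param chrom chromosome identifier.
#' @return data.frame of segments sorted by start (possibly 0 rows).
#' @export
introgression_intervals <- function(library, line_id, chrom) {
  stopifnot(inherits(library, "il_library"))
  chrom <- as.character(chrom)
  if (!chrom %in% library$genome$chrom)
    stop("unknown chromosome id: ", chrom)
  if (identical(line_id, library$control))
    return(library$segments[0, ])
  if (!line_id %in% library$segments$line)
    stop("unknown line id: ", line_id)
  s <- library$segments[library$segments$line == line_id &
                          library$segments$chrom == chrom, , drop = FALSE]
  s <- s[order(s$start_mb), ]
  rownames(s) <- NULL
  s
}

# merged interval set (iv) of a line on a chromosome
line_iv <- function(library, line_id, chrom) {
  s <- introgression_intervals(library, line_id, chrom)
  iv(s$start_mb, s$end_mb)
}

#' Coverage statistics of an IL library
#'
#' Per-line donor-genome fraction, union coverage of the whole library and
#' segment-length statistics; the figures used to characterize a genomic
#' library of introgression lines (e.g. mean introgression size, percent of
#' the donor genome represented).
#'
#' @param library an [il_library()].
#' @return A `coverage_summary` list with elements `per_line` (data.frame
#'   `line`, `donor_mb`, `pct`), `union_pct`, `segment_mb` (named vector
#'   mean/min/max) and `genome_mb`.
#' @export
coverage_summary <- function(library) {
  stopifnot(inherits(library, "il_library"))
  if (nrow(library$segments) == 0L) stop("empty library")
  total <- sum(library$genome$length_mb)
  seg <- library$segments
  seg$len <- seg$end_mb - seg$start_mb
  donor <- tapply(seg$len, seg$line, sum)
  per_line <- data.frame(line = names(donor),
                         donor_mb = as.numeric(donor),
                         pct = 100 * as.numeric(donor) / total)
  rownames(per_line) <- NULL
  union_mb <- sum(vapply(split(seg, seg$chrom), function(s)
    iv_length(iv(s$start_mb, s$end_mb)), numeric(1)))
  out <- list(per_line = per_line,
              union_pct = 100 * union_mb / total,
              segment_mb = c(mean = mean(seg$len), min = min(seg$len),
                             max = max(seg$len)),
              genome_mb = total)
  class(out) <- "coverage_summary"
  out
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("Library coverage: union %.1f%% of %.0f Mb\n",
              x$union_pct, x$genome_mb))
  cat(sprintf("  per-line donor fraction: mean %.2f%% (range %.2f-%.2f%%)\n",
              mean(x$per_line$pct), min(x$per_line$pct), max(x$per_line$pct)))
  cat(sprintf("  segment length (Mb): mean %.1f, range %.1f-%.1f\n",
              x$segment_mb["mean"], x$segment_mb["min"], x$segment_mb["max"]))
  invisible(x)
}
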
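# I/O for introgression maps and genome files.
#
# Map format: BED-like, tab-separated, 0-based half-open, columns
# chrom / start / end / line id. Coordinates are base pairs unless the
# first line declares "#units=mb". Genome file: two tab-separated columns
# (chromosome, length), same unit convention. An optional cM companion CSV
# (line, chrom, start_cm, end_cm) attaches genetic coordinates to segments
# in file order within each (line, chromosome).

read_units <- function(path, default = "bp") {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*units\\s*=", first)) {
    u <- tolower(sub("^#\\s*units\\s*=\\s*", "", first))
    u <- trimws(u)
    if (!u %in% c("bp", "mb")) stop("unknown units declaration: ", u)
    u
  } else default
}

to_mb <- function(x, units) if (units == "bp") x / 1e6 else x

#' Read an introgression map
#'
#' Loads a BED-like introgression map plus a chromosome-length file into a
#' validated [il_library()]. A leading `#units=mb` (or `bp`, the default)
#' line in either file declares the coordinate unit; internally everything
#' is normalized to Mb, 0-based half-open. Heterozygous segment codes are
#' not representable: every segment is a homozygous donor region.
#'
#' @param map_path BED-like file: chrom, start, end, line id.
#' @param genome_path two-column chromosome/length file.
#' @param cm_path optional CSV `line,chrom,start_cm,end_cm` with genetic
#'   coordinates, matched to segments by order within (line, chromosome).
#' @param control recurrent-parent identifier (carries no segments).
#' @return An [il_library()].
#' @export
load_introgression_map <- function(map_path, genome_path, cm_path = NULL,
                                   control = "MM") {
  gu <- read_units(genome_path)
  g <- utils::read.table(genome_path, sep = "\t", comment.char = "#",
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  genome <- genome_spec(g$chrom, to_mb(g$length, gu))

  mu <- read_units(map_path)
  m <- utils::read.table(map_path, sep = "\t", comment.char = "#",
                         col.names = c("chrom", "start", "end", "line"),
                         colClasses = c("character", "numeric", "numeric",
                                        "character"))
  seg <- data.frame(line = m$line, chrom = m$chrom,
                    start_mb = to_mb(m$start, mu),
                    end_mb = to_mb(m$end, mu))
  if (!is.null(cm_path)) {
    cm <- utils::read.csv(cm_path, colClasses = c(line = "character",
                                                  chrom = "character"))
    need <- c("line", "chrom", "start_cm", "end_cm")
    if (!all(need %in% names(cm)))
      stop("cM companion file must have columns ", paste(need, collapse = ", "))
    seg$.ord <- stats::ave(seq_len(nrow(seg)),
                           paste(seg$line, seg$chrom), FUN = seq_along)
    cm$.ord <- stats::ave(seq_len(nrow(cm)),
                          paste(cm$line, cm$chrom), FUN = seq_along)
    i <- match(paste(seg$line, seg$chrom, seg$.ord),
               paste(cm$line, cm$chrom, cm$.ord))
    seg$start_cm <- cm$start_cm[i]
    seg$end_cm <- cm$end_cm[i]
    seg$.ord <- NULL
  }
  il_library(genome, seg, control = control)
}

#' Write an introgression map
#'
#' Inverse of [load_introgression_map()]. With `units = "mb"` coordinates
#' are written at full double precision and a load/write round trip is
#' bit-exact; with `units = "bp"` (the BED convention) coordinates are
#' rounded to integer base pairs.
#'
#' @param library an [il_library()].
#' @param map_path,genome_path output paths (`genome_path = NULL` skips the
#'   genome file).
#' @param cm_path optional output path for the genetic-coordinate companion
#'   CSV (written only for segments that carry cM coordinates).
#' @param units `"bp"` (default, integer base pairs) or `"mb"`.
#' @return `map_path`, invisibly.
#' @export
write_introgression_map <- function(library, map_path, genome_path = NULL,
                                    cm_path = NULL, units = c("bp", "mb")) {
  stopifnot(inherits(library, "il_library"))
  units <- match.arg(units)
  fmt <- function(x) {
    if (units == "bp") sprintf("%.0f", round(x * 1e6))
    else sprintf("%.17g", x)
  }
  s <- library$segments
  lines_out <- c(paste0("#units=", units),
                 paste(s$chrom, fmt(s$start_mb), fmt(s$end_mb), s$line,
                       sep = "\t"))
  writeLines(lines_out, map_path)
  if (!is.null(genome_path)) {
    g <- library$genome
    writeLines(c(paste0("#units=", units),
                 paste(g$chrom, fmt(g$length_mb), sep = "\t")), genome_path)
  }
  if (!is.null(cm_path)) {
    keep <- !is.na(s$start_cm) & !is.na(s$end_cm)
    utils::write.csv(
      data.frame(line = s$line, chrom = s$chrom,
                 start_cm = s$start_cm, end_cm = s$end_cm)[keep, ],
      cm_path, row.names = FALSE, quote = FALSE)
  }
  invisible(map_path)
}
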
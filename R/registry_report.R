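# QTL registry I/O and summaries. The package ships a curated registry
# (inst/extdata/qtl_registry_to937.csv) transcribing the published QTL
# summary of the TO-937 x Moneymaker introgression-line library, plus the
# curated descriptive (categorical) loci of that collection.

qtl_name_re <- "^(.*?)([0-9]+)\\.([0-9]+)$"

parse_interval <- function(x) {
  # accepts "57-75", "57–75" (en dash), "57—75" (em dash)
  parts <- strsplit(trimws(x), "\\s*[-–—]\\s*")
  t(vapply(parts, function(p) {
    if (length(p) != 2L) return(c(NA_real_, NA_real_))
    suppressWarnings(as.numeric(p))
  }, numeric(2)))
}

#' Load a QTL registry
#'
#' Reads a registry CSV with columns `trait`, `qtl`, `chr`, `cm_interval`,
#' `mb_interval`, `n_locations`, `pct_diff` (intervals as `start-end`
#' strings; hyphen, en dash and em dash all accepted) and optional
#' descriptive-locus records from a companion CSV. QTL names must match
#' `<prefix><chromosome>.<serial>` with the chromosome digits agreeing
#' with the `chr` column; malformed rows are errors naming the row.
#' Rows on the same chromosome with identical physical but different
#' genetic intervals are internally suspect and produce a warning, not an
#' error (published tables are transcribed verbatim).
#'
#' @param path registry CSV.
#' @param descriptive_path optional CSV of descriptive loci
#'   (`name,trait_class,chr,lines,description`).
#' @param provenance free-text provenance note carried on the object.
#' @return A `qtl_registry` list: `records` (data.frame with numeric
#'   `cm_start`, `cm_end`, `mb_start`, `mb_end`), `descriptive`,
#'   `provenance`.
#' @export
load_registry <- function(path, descriptive_path = NULL,
                          provenance = NULL) {
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("trait", "qtl", "chr", "cm_interval", "mb_interval",
            "n_locations", "pct_diff")
  if (!all(need %in% names(d)))
    stop("registry must have columns ", paste(need, collapse = ", "))
  if (nrow(d) > 0L) {
    m <- regmatches(d$qtl, regexec(qtl_name_re, d$qtl))
    bad <- which(vapply(m, length, integer(1)) != 4L)
    if (length(bad) > 0L)
      stop("malformed QTL name at row ", bad[1L], ": '", d$qtl[bad[1L]], "'")
    name_chr <- vapply(m, `[`, character(1), 3L)
    mism <- which(name_chr != d$chr)
    if (length(mism) > 0L)
      stop("QTL name/chromosome mismatch at row ", mism[1L], ": '",
           d$qtl[mism[1L]], "' on chr ", d$chr[mism[1L]])
    if (anyDuplicated(d$qtl))
      stop("duplicate QTL name(s): ",
           paste(unique(d$qtl[duplicated(d$qtl)]), collapse = ", "))
    cm <- parse_interval(d$cm_interval)
    mb <- parse_interval(d$mb_interval)
    if (anyNA(mb))
      stop("malformed physical interval at row ", which(is.na(mb[, 1]))[1L])
    if (anyNA(cm))
      stop("malformed genetic interval at row ", which(is.na(cm[, 1]))[1L])
    rec <- data.frame(trait = d$trait, qtl = d$qtl, chr = d$chr,
                      cm_start = cm[, 1], cm_end = cm[, 2],
                      mb_start = mb[, 1], mb_end = mb[, 2],
                      n_locations = as.integer(d$n_locations),
                      pct_diff = as.numeric(d$pct_diff))
    # suspect rows: same physical interval on a chromosome, different cM
    key <- paste(rec$chr, rec$mb_start, rec$mb_end)
    for (k in unique(key[duplicated(key)])) {
      rows <- rec[key == k, ]
      if (length(unique(paste(rows$cm_start, rows$cm_end))) > 1L)
        warning("registry rows ", paste(rows$qtl, collapse = ", "),
                " share a physical interval but disagree on the genetic ",
                "interval (transcribed verbatim)", call. = FALSE)
    }
  } else {
    rec <- data.frame(trait = character(), qtl = character(),
                      chr = character(), cm_start = numeric(),
                      cm_end = numeric(), mb_start = numeric(),
                      mb_end = numeric(), n_locations = integer(),
                      pct_diff = numeric())
  }
  desc <- NULL
  if (!is.null(descriptive_path)) {
    desc <- utils::read.csv(descriptive_path, colClasses = "character")
    m <- regmatches(desc$name, regexec(qtl_name_re, desc$name))
    if (any(vapply(m, length, integer(1)) != 4L))
      stop("malformed descriptive locus name")
    if (any(vapply(m, `[`, character(1), 3L) != desc$chr))
      stop("descriptive locus name/chromosome mismatch")
  }
  out <- list(records = rec, descriptive = desc,
              provenance = provenance %||% attr(d, "provenance"))
  class(out) <- "qtl_registry"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a QTL registry
#'
#' Inverse of [load_registry()]; intervals are serialized as
#' `start-end` strings with full precision.
#'
#' @param registry a `qtl_registry`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  r <- registry$records
  num <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))
  out <- data.frame(trait = r$trait, qtl = r$qtl, chr = r$chr,
                    cm_interval = paste0(num(r$cm_start), "-", num(r$cm_end)),
                    mb_interval = paste0(num(r$mb_start), "-", num(r$mb_end)),
                    n_locations = r$n_locations, pct_diff = r$pct_diff)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged curated QTL registry
#'
#' Loads the registry distributed with the package: the QTLs detected in
#' the TO-937 (donor) x Moneymaker (recurrent) IL library, transcribed
#' verbatim from the published summary (33 QTLs across 11 chromosomes;
#' descriptive loci for vigor, anthocyanin, trichomes, earliness and
#' green shoulder carried separately). Known internal inconsistencies of
#' the published table are preserved and flagged by warnings.
#'
#' @return A `qtl_registry`.
#' @export
packaged_registry <- function() {
  load_registry(
    system.file("extdata", "qtl_registry_to937.csv", package = "ilqtl",
                mustWork = TRUE),
    descriptive_path = system.file("extdata", "descriptive_loci_to937.csv",
                                   package = "ilqtl", mustWork = TRUE),
    provenance = paste("Transcribed from the published QTL summary of the",
                       "S. pimpinellifolium TO-937 x Moneymaker IL library"))
}

#' QTL counts per chromosome
#'
#' Counts QTL records (descriptive loci excluded) per chromosome,
#' including zero entries for chromosomes with no QTL.
#'
#' @param registry a `qtl_registry`.
#' @param genome a [genome_spec()] supplying the full chromosome set
#'   (default: the 12-chromosome tomato genome).
#' @return Named integer vector over all chromosomes.
#' @export
count_by_chromosome <- function(registry, genome = default_genome()) {
  counts <- stats::setNames(integer(nrow(genome)), genome$chrom)
  t <- base::table(registry$records$chr)
  counts[names(t)] <- as.integer(t)
  counts
}

#' QTL counts per trait
#'
#' @param registry a `qtl_registry`.
#' @return Named integer vector (traits present in the registry).
#' @export
count_by_trait <- function(registry) {
  t <- base::table(registry$records$trait)
  stats::setNames(as.integer(t), names(t))
}

#' Export a registry (or QTL records) to BED
#'
#' BED6: base-pair coordinates (Mb x 1e6, 0-based half-open), QTL name in
#' column 4, score 0, strand ".". Rows without a physical interval are
#' skipped with a warning.
#'
#' @param registry a `qtl_registry` or a [qtl_table()] data.frame with
#'   columns `chrom`/`chr`, `mb_start`, `mb_end`, `qtl`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_bed <- function(registry, path) {
  r <- if (inherits(registry, "qtl_registry")) registry$records
       else as.data.frame(registry)
  if (!"chr" %in% names(r) && "chrom" %in% names(r)) r$chr <- r$chrom
  miss <- is.na(r$mb_start) | is.na(r$mb_end)
  if (any(miss)) {
    warning("skipping ", sum(miss), " record(s) without physical interval")
    r <- r[!miss, ]
  }
  lines_out <- sprintf("%s\t%.0f\t%.0f\t%s\t0\t.",
                       r$chr, round(r$mb_start * 1e6),
                       round(r$mb_end * 1e6), r$qtl)
  writeLines(lines_out, path)
  invisible(path)
}

#' Registry summary
#'
#' Per-chromosome and per-trait QTL counts plus totals, printed as a
#' human-readable report.
#'
#' @param object a `qtl_registry`.
#' @param genome a [genome_spec()] for the chromosome set.
#' @param ... unused.
#' @return Invisibly, a list with `total`, `by_chromosome`, `by_trait`,
#'   `n_descriptive`.
#' @export
summary.qtl_registry <- function(object, genome = default_genome(), ...) {
  bc <- count_by_chromosome(object, genome)
  bt <- count_by_trait(object)
  res <- list(total = nrow(object$records), by_chromosome = bc,
              by_trait = bt,
              n_descriptive = if (is.null(object$descriptive)) 0L
                              else nrow(object$descriptive))
  cat("QTL registry:", res$total, "QTLs")
  if (res$n_descriptive > 0)
    cat(" (+", res$n_descriptive, "descriptive loci)")
  cat("\n  by chromosome: ",
      paste(names(bc), bc, sep = ":", collapse = " "), "\n", sep = "")
  cat("  by trait: ",
      paste(names(bt), bt, sep = ":", collapse = " "), "\n", sep = "")
  invisible(res)
}
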
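#' Trait catalog
#'
#' The fruit-quality trait set used throughout the package: size (fruit
#' weight FW in g, diameter FD and length FL in cm), shape indices (FS,
#' CIR, PSH, dimensionless), organoleptic traits (SSC in degrees Brix, PH,
#' TA in percent citric acid) and CIELab color variables (L*, a*, b*,
#' chroma C*, hue angle H in degrees) measured externally (EC_) and
#' internally (IC_). `family` groups the color variables under EC/IC for
#' QTL reporting; `qtl_prefix` is the lowercase stem used in QTL names
#' (e.g. `fw`, `ec_a`, `ic_L`).
#'
#' @return data.frame with columns `code`, `name`, `units`, `category`,
#'   `family`, `qtl_prefix`.
#' @export
trait_catalog <- function() {
  base <- data.frame(
    code = c("FW", "FD", "FL", "FS", "CIR", "PSH", "SSC", "PH", "TA"),
    name = c("Fruit weight", "Fruit diameter", "Fruit length",
             "Fruit shape index", "Circular shape", "Shoulder height",
             "Soluble solid content", "pH", "Titratable acidity"),
    units = c("g", "cm", "cm", "", "", "", "°Brix", "", "% citric acid"),
    category = c("size", "size", "size", "shape", "shape", "shape",
                 "organoleptic", "organoleptic", "organoleptic"))
  base$family <- base$code
  base$qtl_prefix <- tolower(base$code)
  comp <- c("L", "a", "b", "C", "H")
  cu <- c("", "", "", "", "degrees")
  col <- do.call(rbind, lapply(c("EC", "IC"), function(fam) {
    data.frame(code = paste0(fam, "_", comp),
               name = paste(ifelse(fam == "EC", "External", "Internal"),
                            "color", comp),
               units = cu,
               category = ifelse(fam == "EC", "external_color",
                                 "internal_color"),
               family = fam,
               qtl_prefix = paste0(tolower(fam), "_", comp))
  }))
  rbind(base, col)
}

#' Chroma from CIELab a*, b*
#'
#' Color saturation \eqn{C^* = \sqrt{a^{*2} + b^{*2}}}.
#'
#' @param a_star,b_star CIELab chromaticity coordinates (finite numerics,
#'   vectorized).
#' @return Non-negative chroma values.
#' @examples chroma(3, 4) # 5
#' @export
chroma <- function(a_star, b_star) {
  if (any(!is.finite(a_star)) || any(!is.finite(b_star)))
    stop("chroma: non-finite input")
  sqrt(a_star^2 + b_star^2)
}

#' Hue angle from CIELab a*, b*
#'
#' Hue angle in degrees, \eqn{H = (180/\pi)\,\arccos(a^*/C^*)}, defined for
#' positive b* only (the arccos form cannot distinguish the lower half of
#' the a*-b* plane). Result lies in (0, 180).
#'
#' @inheritParams chroma
#' @return Hue angle in degrees.
#' @examples hue_angle(0, 1) # 90
#' @export
hue_angle <- function(a_star, b_star) {
  if (any(!is.finite(a_star)) || any(!is.finite(b_star)))
    stop("hue_angle: non-finite input")
  if (any(b_star <= 0))
    stop("hue_angle is defined for positive b* only")
  cc <- chroma(a_star, b_star)
  if (any(cc == 0)) stop("hue_angle undefined at (0, 0)")
  (180 / pi) * acos(a_star / cc)
}

#' Aggregate fruit-level measurements to a plot value
#'
#' The per-plot value of a fruit trait is the unweighted arithmetic mean of
#' the sampled fruits (typically four per plot), with the sample size
#' recorded.
#'
#' @param fruit_values numeric vector of fruit-level measurements.
#' @return list with `value` (mean, `NA` for empty input) and `n`
#'   (number of fruits averaged).
#' @export
aggregate_fruit_sample <- function(fruit_values) {
  fruit_values <- fruit_values[!is.na(fruit_values)]
  if (length(fruit_values) == 0L)
    return(list(value = NA_real_, n = 0L))
  if (any(!is.finite(fruit_values)))
    stop("non-finite fruit values")
  list(value = mean(fruit_values), n = length(fruit_values))
}

#' Phenotype table
#'
#' Long-format plot-level phenotype observations keyed by
#' (line, location, block, trait), with design metadata. At most one record
#' per key; the control must be observed in every location. Values may be
#' `NA` (explicitly missing); missing plots are never imputed.
#'
#' @param records data.frame with columns `line`, `location`, `block`,
#'   `trait`, `value` and optionally `n_sampled`.
#' @param control recurrent-parent identifier.
#' @param blocks number of blocks per location.
#' @param control_reps control replicates per block.
#' @return A `phenotype_table` data.frame.
#' @export
phenotype_table <- function(records, control = "MM", blocks = 8L,
                            control_reps = 6L) {
  need <- c("line", "location", "block", "trait", "value")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (!"n_sampled" %in% names(records)) records$n_sampled <- NA_integer_
  keep <- c(need, "n_sampled", intersect("rep", names(records)))
  records <- records[, keep]
  records$line <- as.character(records$line)
  records$location <- as.character(records$location)
  records$trait <- as.character(records$trait)
  records$value <- as.numeric(records$value)
  if (any(is.infinite(records$value)))
    stop("values must be finite or NA")
  # replicate index: multiple control plots per block are distinct records,
  # so the uniqueness key includes a within-key replicate counter supplied
  # via the `rep` column when present
  if (!"rep" %in% names(records)) {
    key <- paste(records$line, records$location, records$block,
                 records$trait, sep = "\r")
    records$rep <- stats::ave(seq_along(key), key, FUN = seq_along)
  }
  if (anyDuplicated(paste(records$line, records$location, records$block,
                          records$trait, records$rep, sep = "\r")))
    stop("duplicate (line, location, block, trait, rep) records")
  if (any(records$block > blocks) || any(records$block < 1))
    stop("block id outside 1..", blocks)
  for (loc in unique(records$location)) {
    if (!control %in% records$line[records$location == loc])
      stop("control '", control, "' absent from location ", loc)
  }
  attr(records, "control") <- control
  attr(records, "blocks") <- blocks
  attr(records, "control_reps") <- control_reps
  class(records) <- c("phenotype_table", "data.frame")
  records
}

#' Read / write a phenotype table
#'
#' CSV, long format, header `line,location,block,trait,value,n_sampled`;
#' missing values are empty fields.
#'
#' @param path CSV path.
#' @param ... passed to [phenotype_table()] (`control`, `blocks`, ...).
#' @return A `phenotype_table`.
#' @export
read_phenotypes <- function(path, ...) {
  d <- utils::read.csv(path, colClasses = c(line = "character",
                                            location = "character",
                                            trait = "character"))
  phenotype_table(d, ...)
}

#' @rdname read_phenotypes
#' @param table a `phenotype_table`.
#' @export
write_phenotypes <- function(table, path) {
  out <- as.data.frame(table)[, c("line", "location", "block", "trait",
                                  "value", "n_sampled")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Derive chroma and hue-angle records from a*, b* records
#'
#' For each color family present (external `EC_`, internal `IC_`), pairs
#' the a* and b* records per (line, location, block, replicate) and adds
#' (or replaces) the corresponding `C` and `H` records. Hue is undefined
#' for b* <= 0: those plots get a missing `H` and their count is attached
#' as attribute `n_hue_undefined`. The operation is idempotent.
#'
#' @param table a [phenotype_table()].
#' @return The table with derived `*_C` and `*_H` records.
#' @export
derive_color_traits <- function(table) {
  stopifnot(inherits(table, "phenotype_table"))
  att <- attributes(table)
  d <- as.data.frame(table)
  n_undef <- 0L
  for (fam in c("EC", "IC")) {
    a_code <- paste0(fam, "_a"); b_code <- paste0(fam, "_b")
    a <- d[d$trait == a_code, ]
    b <- d[d$trait == b_code, ]
    if (nrow(a) == 0L && nrow(b) == 0L) next
    ka <- paste(a$line, a$location, a$block, a$rep, sep = "\r")
    kb <- paste(b$line, b$location, b$block, b$rep, sep = "\r")
    if (!all(ka %in% kb))
      stop(fam, ": a* present without paired b* for key(s): ",
           paste(utils::head(gsub("\r", "/", setdiff(ka, kb)), 5L),
                 collapse = "; "))
    i <- match(ka, kb)
    av <- a$value
    bv <- b$value[i]
    cv <- ifelse(is.na(av) | is.na(bv), NA_real_, sqrt(av^2 + bv^2))
    ok_h <- !is.na(av) & !is.na(bv) & bv > 0 & cv > 0
    hv <- rep(NA_real_, length(av))
    hv[ok_h] <- (180 / pi) * acos(av[ok_h] / cv[ok_h])
    n_undef <- n_undef + sum(!is.na(av) & !is.na(bv) & bv <= 0)
    derived <- rbind(
      data.frame(line = a$line, location = a$location, block = a$block,
                 trait = paste0(fam, "_C"), value = cv,
                 n_sampled = a$n_sampled, rep = a$rep),
      data.frame(line = a$line, location = a$location, block = a$block,
                 trait = paste0(fam, "_H"), value = hv,
                 n_sampled = a$n_sampled, rep = a$rep))
    # replace any existing derived records (idempotence)
    d <- d[!d$trait %in% c(paste0(fam, "_C"), paste0(fam, "_H")), ]
    d <- rbind(d, derived)
  }
  rownames(d) <- NULL
  out <- phenotype_table(d, control = att$control, blocks = att$blocks,
                         control_reps = att$control_reps)
  attr(out, "n_hue_undefined") <- n_undef
  out
}
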
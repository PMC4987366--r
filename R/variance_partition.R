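#' Two-way ANOVA variance partitioning
#'
#' Fits `value ~ genotype + location + genotype:location` on plot-level
#' data for one trait and expresses each effect's sum of squares as a
#' percentage of the total (effects + residual), with F-test significance
#' flags at 0.05 and 0.01. For unbalanced data (the control is replicated
#' more than the ILs) Type III (marginal) sums of squares are used, with
#' sum-to-zero contrasts; percentages are taken over the sum of all effect
#' SS plus the residual SS so that they add to 100. The choice of SS type
#' is recorded in the result.
#'
#' @param table a [phenotype_table()].
#' @param trait trait code.
#' @return An `effect_table` data.frame (one row) with the percentage and
#'   p-value of each effect.
#' @export
partition_variance <- function(table, trait) {
  stopifnot(inherits(table, "phenotype_table"))
  d <- as.data.frame(table)
  d <- d[d$trait == trait & !is.na(d$value), ]
  if (nrow(d) == 0L) stop("no observations for trait ", trait)
  if (length(unique(d$location)) < 2L)
    stop("trait observed in a single location; use heritability() ",
         "for a one-way analysis")
  if (length(unique(d$line)) < 2L) stop("need >= 2 genotypes")
  d$genotype <- factor(d$line)
  d$loc <- factor(d$location)
  cell_n <- base::table(d$genotype, d$loc)
  interaction_ok <- all(cell_n >= 1L) && any(cell_n >= 2L)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fm <- stats::lm(value ~ genotype * loc, data = d)
  # car refuses saturated (zero-residual) fits; on balanced data the
  # sequential decomposition coincides with the marginal one, so fall back
  a3 <- tryCatch(car::Anova(fm, type = 3, singular.ok = TRUE),
                 error = function(e) suppressWarnings(stats::anova(fm)))
  pick <- function(term) {
    i <- match(term, rownames(a3))
    c(ss = a3[i, "Sum Sq"], p = a3[i, "Pr(>F)"])
  }
  g <- pick("genotype"); l <- pick("loc"); gl <- pick("genotype:loc")
  res <- a3["Residuals", "Sum Sq"]
  if (!interaction_ok || is.na(gl["ss"])) {
    gl <- c(ss = NA_real_, p = NA_real_)
  }
  tot <- sum(c(g["ss"], l["ss"], gl["ss"], res), na.rm = TRUE)
  pct <- function(x) if (tot > 0) 100 * unname(x["ss"]) / tot else 0
  pval <- function(x) unname(x["p"])
  out <- data.frame(
    trait = trait,
    pct_genotype = pct(g), pct_location = pct(l), pct_interaction = pct(gl),
    ss_genotype = unname(g["ss"]), ss_location = unname(l["ss"]),
    ss_interaction = unname(gl["ss"]), ss_residual = res,
    p_genotype = pval(g), p_location = pval(l), p_interaction = pval(gl),
    sig05_genotype = isTRUE(pval(g) < 0.05),
    sig05_location = isTRUE(pval(l) < 0.05),
    sig05_interaction = isTRUE(pval(gl) < 0.05),
    sig01_genotype = isTRUE(pval(g) < 0.01),
    sig01_location = isTRUE(pval(l) < 0.01),
    sig01_interaction = isTRUE(pval(gl) < 0.01))
  # constant response: lm leaves effect SS at numerical zero but p is NaN
  if (tot <= .Machine$double.eps * max(1, sum(d$value^2))) {
    out[, c("pct_genotype", "pct_location", "pct_interaction")] <- 0
    out[, grep("^sig", names(out))] <- FALSE
  }
  if (!interaction_ok) attr(out, "interaction_inestimable") <- TRUE
  attr(out, "ss_type") <- "III"
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Broad-sense heritability within one location
#'
#' One-way ANOVA among genotypes in one location. The genetic variance is
#' the method-of-moments estimator
#' \eqn{V_g = \max(0, (MS_G - MS_e)/n_0)} with Searle's effective
#' replicate number \eqn{n_0 = (N - \sum n_i^2/N)/(a-1)} for unbalanced
#' data, the total variance \eqn{V_t = V_g + MS_e}, and
#' \eqn{h^2 = V_g/V_t}. Optionally a block covariate is absorbed before
#' the genotype ANOVA (`block_adjust = TRUE`; default off, the plain
#' one-way analysis).
#'
#' @param table a [phenotype_table()].
#' @param trait trait code.
#' @param location location id.
#' @param block_adjust absorb block effects before estimating.
#' @return A `heritability` data.frame (one row): `trait`, `location`,
#'   `h2`, `Vg`, `Vt`, `ms_genotype`, `ms_error`, `n0`.
#' @export
heritability <- function(table, trait, location, block_adjust = FALSE) {
  stopifnot(inherits(table, "phenotype_table"))
  d <- as.data.frame(table)
  d <- d[d$trait == trait & d$location == location & !is.na(d$value), ]
  if (nrow(d) == 0L) stop("no observations for ", trait, " in ", location)
  d$genotype <- factor(d$line)
  a <- nlevels(d$genotype)
  if (a < 2L) stop("need >= 2 genotypes in location ", location)
  n_i <- as.numeric(base::table(d$genotype))
  N <- nrow(d)
  if (N - a < 1L)
    stop("no within-genotype replication in location ", location)
  fm <- if (block_adjust)
    stats::lm(value ~ factor(block) + genotype, data = d)
  else stats::lm(value ~ genotype, data = d)
  an <- suppressWarnings(stats::anova(fm))  # perfect fits are legitimate here
  ms_g <- an["genotype", "Mean Sq"]
  ms_e <- an["Residuals", "Mean Sq"]
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  vg <- max(0, (ms_g - ms_e) / n0)
  vt <- vg + ms_e
  h2 <- if (vt > 0) vg / vt else 0
  out <- data.frame(trait = trait, location = location, h2 = h2,
                    Vg = vg, Vt = vt, ms_genotype = ms_g, ms_error = ms_e,
                    n0 = n0)
  class(out) <- c("heritability", "data.frame")
  out
}

#' Pairwise trait correlations within one location
#'
#' Pearson correlations among traits computed on genotype means within the
#' location (pairwise-complete), with the number of complete genotype
#' pairs recorded for every trait pair. Constant traits yield `NA`
#' correlations; pairs with fewer complete genotypes than `min_pairs` are
#' set to `NA`.
#'
#' @param table a [phenotype_table()].
#' @param location location id.
#' @param traits trait codes (default: all traits present).
#' @param min_pairs minimum complete pairs for a correlation (default 3).
#' @return A `trait_correlations` list: `location`, `r` (correlation
#'   matrix), `n` (pair counts).
#' @export
trait_correlations <- function(table, location, traits = NULL,
                               min_pairs = 3L) {
  stopifnot(inherits(table, "phenotype_table"))
  d <- as.data.frame(table)
  d <- d[d$location == location & !is.na(d$value), ]
  if (is.null(traits)) traits <- sort(unique(d$trait))
  d <- d[d$trait %in% traits, ]
  gm <- stats::aggregate(value ~ line + trait, data = d, FUN = mean)
  wide <- stats::reshape(gm, idvar = "line", timevar = "trait",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^value\\.", "", colnames(m))
  m <- m[, intersect(traits, colnames(m)), drop = FALSE]
  n <- crossprod(!is.na(m))
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r[n < min_pairs] <- NA_real_
  diag(r)[diag(n) >= 1] <- 1
  out <- list(location = location, r = r, n = n)
  class(out) <- "trait_correlations"
  out
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat("Trait correlations (genotype means), location", x$location, "\n")
  print(round(x$r, 2))
  invisible(x)
}
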
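# RCBD model fitting per location and Dunnett many-to-one screening of
# every IL against the recurrent parent.

# run expr with a locally-seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Fit the per-location RCBD model for one trait
#'
#' Least-squares fit of `value ~ block + genotype` (block adjustment can be
#' disabled) on plot-level data in one location, with the control as the
#' reference genotype. Returns adjusted (least-squares) genotype means, the
#' IL-minus-control differences with their standard errors, the residual
#' degrees of freedom, and the correlation matrix of the comparison
#' statistics implied by the (possibly unbalanced) replication — the
#' inputs that [dunnett_compare()] needs.
#'
#' @param table a [phenotype_table()].
#' @param trait trait code.
#' @param location location id.
#' @param block_adjust include the block factor (default TRUE).
#' @return A `location_fit` list: `location`, `trait`, `control`,
#'   `means` (named, adjusted), `diff`, `se`, `pct_diff`, `df`, `corr`,
#'   `low_replication` (lines with < 2 plots).
#' @export
fit_location_model <- function(table, trait, location, block_adjust = TRUE) {
  stopifnot(inherits(table, "phenotype_table"))
  control <- attr(table, "control")
  d <- as.data.frame(table)
  d <- d[d$trait == trait & d$location == location & !is.na(d$value), ]
  if (!control %in% d$line)
    stop("control '", control, "' has no data for ", trait, " in ", location)
  others <- setdiff(unique(d$line), control)
  if (length(others) == 0L)
    stop("no IL data for ", trait, " in ", location)
  d$genotype <- stats::relevel(factor(d$line), ref = control)
  d$blk <- factor(d$block)
  fm <- if (block_adjust && nlevels(d$blk) > 1L)
    stats::lm(value ~ blk + genotype, data = d)
  else stats::lm(value ~ genotype, data = d)
  cf <- stats::coef(fm)
  gi <- grep("^genotype", names(cf))
  if (any(is.na(cf[gi])))
    stop("aliased genotype effects (insufficient data) in ", location)
  V <- stats::vcov(fm)[gi, gi, drop = FALSE]
  diffs <- cf[gi]
  lines_ord <- sub("^genotype", "", names(cf)[gi])
  names(diffs) <- lines_ord
  se <- stats::setNames(sqrt(diag(V)), lines_ord)
  corr <- stats::cov2cor(V)
  dimnames(corr) <- list(lines_ord, lines_ord)
  # adjusted control mean: average prediction over blocks
  blocks <- levels(d$blk)
  nd <- data.frame(blk = factor(blocks, levels = blocks),
                   genotype = factor(control, levels = levels(d$genotype)))
  ctrl_mean <- if (block_adjust && nlevels(d$blk) > 1L)
    mean(stats::predict(fm, newdata = nd)) else unname(cf[1L])
  means <- c(ctrl_mean, ctrl_mean + diffs)
  names(means) <- c(control, lines_ord)
  nobs <- base::table(d$line)
  low <- names(nobs)[nobs < 2L]
  out <- list(location = location, trait = trait, control = control,
              means = means, diff = diffs, se = se,
              pct_diff = 100 * diffs / ctrl_mean,
              df = fm$df.residual, corr = corr,
              low_replication = setdiff(low, control))
  class(out) <- "location_fit"
  out
}

#' @export
print.location_fit <- function(x, ...) {
  cat(sprintf("RCBD fit: %s at %s — %d comparisons vs %s, df = %d\n",
              x$trait, x$location, length(x$diff), x$control, x$df))
  invisible(x)
}

# Two-sided many-to-one adjusted p-values: P(max_j |T_j| >= |t_i|) under
# the maximum-modulus multivariate t with the fit's correlation matrix.
# Evaluated by the deterministic (seeded) quasi-Monte-Carlo integrator of
# mvtnorm; k = 1 reduces exactly to the ordinary two-sided t p-value.
dunnett_p_adjust <- function(tstat, df, corr, abseps = 5e-4,
                             mc_seed = 190443L) {
  k <- length(tstat)
  if (k == 1L) return(2 * stats::pt(-abs(tstat), df))
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev))
    stop("comparison correlation matrix is not positive semi-definite")
  p <- vapply(abs(tstat), function(a) {
    pr <- with_local_seed(mc_seed, mvtnorm::pmvt(
      lower = rep(-a, k), upper = rep(a, k), df = as.integer(round(df)),
      corr = corr,
      algorithm = mvtnorm::GenzBretz(abseps = abseps, maxpts = 50000L)))
    min(max(1 - as.numeric(pr), 0), 1)
  }, numeric(1))
  # enforce monotonicity in |t| (QMC noise could break it marginally)
  ord <- order(abs(tstat), decreasing = TRUE)
  p[ord] <- cummax(p[ord])
  p
}

#' Equicoordinate Dunnett critical value
#'
#' The two-sided critical constant c solving
#' \eqn{P(\max_j |T_j| \le c) = 1 - \alpha} for the fit's comparison
#' correlation matrix and residual df. A comparison is significant under
#' [dunnett_compare()] exactly when its |t| exceeds this constant, which
#' makes the critical value the cheap route for large simulation studies
#' on a fixed design.
#'
#' @param fit a [fit_location_model()] result (or a list with `corr`, `df`).
#' @param alpha family-wise error rate.
#' @param mc_seed seed for the quasi-Monte-Carlo integrator.
#' @return The critical constant (scalar).
#' @export
dunnett_critical <- function(fit, alpha = 0.05, mc_seed = 190443L) {
  k <- nrow(fit$corr)
  if (is.null(k) || k == 1L)
    return(stats::qt(1 - alpha / 2, fit$df))
  q <- with_local_seed(mc_seed, mvtnorm::qmvt(
    1 - alpha, tail = "both.tails", df = as.integer(round(fit$df)),
    corr = fit$corr,
    algorithm = mvtnorm::GenzBretz(abseps = 1e-4, maxpts = 100000L)))
  as.numeric(q$quantile)
}

#' Dunnett many-to-one comparison of ILs against the control
#'
#' Computes two-sided Dunnett-adjusted p-values for every IL-vs-control
#' difference in a [fit_location_model()] result and flags significance at
#' `alpha`. Adjusted p-values are monotone non-increasing in |t|, bounded
#' below by the unadjusted t-test p-value and above by the Bonferroni
#' bound. The quasi-Monte-Carlo seed is fixed and recorded in the output
#' attributes so p-values are reproducible to the integrator tolerance.
#'
#' @param fit a [fit_location_model()] result.
#' @param alpha significance level (default 0.05).
#' @param abseps absolute tolerance of the multivariate-t integral.
#' @param mc_seed integrator seed (recorded in output).
#' @return A `comparison_results` data.frame: `line`, `location`, `trait`,
#'   `diff`, `pct_diff`, `t`, `p_adj`, `significant`.
#' @export
dunnett_compare <- function(fit, alpha = 0.05, abseps = 5e-4,
                            mc_seed = 190443L) {
  stopifnot(inherits(fit, "location_fit"))
  if (fit$df < 1L) stop("residual df < 1")
  tstat <- fit$diff / fit$se
  p <- dunnett_p_adjust(tstat, fit$df, fit$corr, abseps = abseps,
                        mc_seed = mc_seed)
  out <- data.frame(line = names(fit$diff), location = fit$location,
                    trait = fit$trait, diff = unname(fit$diff),
                    pct_diff = unname(fit$pct_diff), t = unname(tstat),
                    p_adj = p, significant = p < alpha)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "mc_seed") <- mc_seed
  attr(out, "abseps") <- abseps
  class(out) <- c("comparison_results", "data.frame")
  out
}

#' Cross-location consistency filter
#'
#' Keeps (line, trait) combinations that are significant in at least
#' `min_locations` locations and (by default) with the same sign of effect
#' in all qualifying locations; the screening rule that turns per-location
#' Dunnett results into QTL candidates.
#'
#' @param results one or more `comparison_results` (rbind-ed across
#'   locations and traits).
#' @param min_locations minimum number of significant locations (default 2).
#' @param require_same_sign demand a common effect direction among the
#'   significant locations (default TRUE).
#' @return A `candidate_effects` data.frame: `line`, `trait`, `locations`
#'   (semicolon-joined), `n_locations`, `sign`, `mean_pct_diff` (mean over
#'   qualifying locations).
#' @export
consistency_filter <- function(results, min_locations = 2L,
                               require_same_sign = TRUE) {
  res <- as.data.frame(results)
  empty <- data.frame(line = character(), trait = character(),
                      locations = character(), n_locations = integer(),
                      sign = integer(), mean_pct_diff = numeric())
  class(empty) <- c("candidate_effects", "data.frame")
  if (nrow(res) == 0L) return(empty)
  sig <- res[res$significant, ]
  if (nrow(sig) == 0L) return(empty)
  parts <- split(sig, paste(sig$line, sig$trait, sep = "\r"))
  rows <- lapply(parts, function(s) {
    s <- s[!duplicated(s$location), ]
    s <- s[order(s$location), ]
    if (require_same_sign) {
      sgn <- sign(s$diff)
      dominant <- if (all(sgn > 0)) 1L else if (all(sgn < 0)) -1L else NA
      if (is.na(dominant)) return(NULL)
    }
    if (nrow(s) < min_locations) return(NULL)
    data.frame(line = s$line[1L], trait = s$trait[1L],
               locations = paste(s$location, collapse = ";"),
               n_locations = nrow(s),
               sign = as.integer(sign(mean(s$diff))),
               mean_pct_diff = mean(s$pct_diff))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$trait, out$line), ]
  rownames(out) <- NULL
  class(out) <- c("candidate_effects", "data.frame")
  out
}
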
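# Multi-environment IL trial simulator: the statistical structure the
# analysis assumes (additive planted QTL effects on the control mean,
# Gaussian location, block, GxL and residual components, RCBD replication
# with an over-replicated control), so every pipeline stage is testable
# without external data.

#' Default simulated trait definitions
#'
#' Trait means and variance components used by [simulation_config()]:
#' fruit weight (control mean 98.2 g) and soluble solid content (4.48
#' degrees Brix), with location / block / genotype-by-location / residual
#' variances chosen so the relative magnitudes of the non-genetic
#' variance shares resemble a Mediterranean multi-location tomato trial
#' (location and residual dominating, interaction small).
#'
#' @return data.frame `trait`, `mean`, `var_location`, `var_block`,
#'   `var_gxl`, `var_resid`.
#' @export
default_sim_traits <- function() {
  data.frame(
    trait = c("FW", "SSC"),
    mean = c(98.2, 4.48),
    var_location = c(67, 0.04),
    var_block = c(16, 0.02),
    var_gxl = c(18, 0.04),
    var_resid = c(144, 0.2))
}

#' Simulation configuration
#'
#' All parameters of the library and trial generator. Defaults emulate the
#' reference design: a 54-line library on a 12-chromosome genome, 3
#' locations, 8 blocks per location, 1 IL replicate and 6 control
#' replicates per block, with block 8 pooled over three plants.
#'
#' @param genome a [genome_spec()].
#' @param n_lines number of ILs.
#' @param seg_len_mean,seg_len_sd,seg_len_min truncated-normal segment
#'   length parameters (Mb).
#' @param overlap_frac minimum overlap between consecutive segments on a
#'   chromosome, as a fraction of the mean inter-segment spacing.
#' @param coverage_floor minimum library union coverage (%) the generator
#'   must achieve (error if infeasible).
#' @param locations location identifiers.
#' @param blocks blocks per location.
#' @param il_reps,control_reps replicates per block for ILs / control.
#' @param control control (recurrent parent) identifier.
#' @param traits trait definition data.frame (see [default_sim_traits()]).
#' @param planted_qtls data.frame `trait`, `chrom`, `pos_mb`, `effect_pct`
#'   (additive effect as percent of the control mean); `NULL` for none.
#' @param pooled_block index of the block simulated as a pooled mean of
#'   three plants (`NA` to disable).
#' @param missing data.frame `line`, `location` of cells to drop (emulates
#'   lines that fail in a location); `NULL` for none.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(genome = default_genome(), n_lines = 54L,
                              seg_len_mean = 25, seg_len_sd = 8,
                              seg_len_min = 0.7, overlap_frac = 0.25,
                              coverage_floor = 98, locations = paste0("LOC", 1:3),
                              blocks = 8L, il_reps = 1L, control_reps = 6L,
                              control = "MM", traits = default_sim_traits(),
                              planted_qtls = NULL, pooled_block = 8L,
                              missing = NULL, seed = 1L) {
  stopifnot(inherits(genome, "genome_spec"), n_lines >= 0,
            all(traits$var_location >= 0), all(traits$var_block >= 0),
            all(traits$var_gxl >= 0), all(traits$var_resid >= 0))
  if (!is.null(planted_qtls)) {
    planted_qtls$chrom <- as.character(planted_qtls$chrom)
    i <- match(planted_qtls$chrom, genome$chrom)
    if (anyNA(i)) stop("planted QTL on unknown chromosome")
    if (any(planted_qtls$pos_mb < 0 |
              planted_qtls$pos_mb > genome$length_mb[i]))
      stop("planted QTL position outside chromosome")
    if (!all(planted_qtls$trait %in% traits$trait))
      stop("planted QTL for trait without simulation parameters")
    planted_qtls$qtl_id <- seq_len(nrow(planted_qtls))
  }
  cfg <- list(genome = genome, n_lines = as.integer(n_lines),
              seg_len_mean = seg_len_mean, seg_len_sd = seg_len_sd,
              seg_len_min = seg_len_min, overlap_frac = overlap_frac,
              coverage_floor = coverage_floor, locations = locations,
              blocks = as.integer(blocks), il_reps = as.integer(il_reps),
              control_reps = as.integer(control_reps), control = control,
              traits = traits, planted_qtls = planted_qtls,
              pooled_block = pooled_block, missing = missing,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# truncated-normal draw by rejection (vectorized enough for our sizes)
rtnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1L
  }
  pmin(pmax(x, lo), hi)
}

#' Simulate an IL library
#'
#' Tiles each chromosome with donor segments: per-chromosome line counts
#' are allocated proportionally to physical length (largest remainder);
#' segment lengths are truncated-normal draws, inflated when necessary to
#' at least `(1 + overlap_frac)` times the inter-segment spacing so that
#' consecutive segments overlap and the library union covers each
#' chromosome end to end. Line ids follow `SP_<chrom>-<serial>` with
#' serials ordered by position. Genetic (cM) coordinates are attached by
#' linear interpolation of the chromosome's genetic length. Deterministic
#' under a fixed config seed.
#'
#' @param config a [simulation_config()].
#' @return List with `library` (an [il_library()]) and `truth` (a
#'   `trial_truth` list: `planted` data.frame and `carriers` data.frame
#'   mapping lines to the planted QTLs inside their segments).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$coverage_floor > 100)
    stop("infeasible coverage floor: ", config$coverage_floor, "%")
  if (config$n_lines < 1L)
    stop("config has no ILs (n_lines = ", config$n_lines, ")")
  if (config$n_lines < nrow(config$genome) && config$coverage_floor > 0)
    stop("infeasible coverage floor: fewer lines than chromosomes")
  g <- config$genome
  # largest-remainder allocation proportional to physical length
  share <- config$n_lines * g$length_mb / sum(g$length_mb)
  n_c <- floor(share)
  n_c <- n_c + ifelse(rank(-(share - n_c), ties.method = "first") <=
                        config$n_lines - sum(n_c), 1L, 0L)
  n_c <- pmax(n_c, 1L)
  while (sum(n_c) > config$n_lines) {    # pmax may have over-allocated
    i <- which.max(ifelse(n_c > 1L, n_c - share, -Inf))
    n_c[i] <- n_c[i] - 1L
  }
  segs <- NULL
  with_local_seed(config$seed, {
    for (ci in seq_len(nrow(g))) {
      L <- g$length_mb[ci]
      n <- n_c[ci]
      step <- L / n
      len <- rtnorm(n, config$seg_len_mean, config$seg_len_sd,
                    config$seg_len_min, L)
      len <- pmax(len, pmin(step * (1 + config$overlap_frac), L))
      anchor <- (seq_len(n) - 0.5) * step
      start <- pmax(0, anchor - len / 2)
      end <- pmin(L, anchor + len / 2)
      # keep the ends anchored so the chromosome is covered edge to edge
      start[1L] <- 0
      end[n] <- L
      segs <- rbind(segs, data.frame(
        line = sprintf("SP_%s-%d", g$chrom[ci], seq_len(n)),
        chrom = g$chrom[ci], start_mb = start, end_mb = end))
    }
  })
  # linear Mb -> cM interpolation per chromosome
  i <- match(segs$chrom, g$chrom)
  scale_cm <- g$length_cm[i] / g$length_mb[i]
  segs$start_cm <- segs$start_mb * scale_cm
  segs$end_cm <- segs$end_mb * scale_cm
  lib <- il_library(g, segs, control = config$control)
  cov <- coverage_summary(lib)
  if (cov$union_pct < config$coverage_floor)
    stop(sprintf("infeasible coverage floor: achieved %.1f%% < %.1f%%",
                 cov$union_pct, config$coverage_floor))
  truth <- trial_truth(lib, config)
  list(library = lib, truth = truth)
}

# planted-QTL ground truth: which lines carry which planted QTLs
trial_truth <- function(library, config) {
  planted <- config$planted_qtls
  carriers <- data.frame(line = character(), qtl_id = integer(),
                         trait = character(), effect_pct = numeric())
  if (!is.null(planted) && nrow(planted) > 0L) {
    s <- library$segments
    rows <- lapply(seq_len(nrow(planted)), function(q) {
      hit <- s$chrom == planted$chrom[q] &
        s$start_mb <= planted$pos_mb[q] & planted$pos_mb[q] < s$end_mb
      if (!any(hit)) return(NULL)
      data.frame(line = unique(s$line[hit]), qtl_id = planted$qtl_id[q],
                 trait = planted$trait[q],
                 effect_pct = planted$effect_pct[q])
    })
    carriers <- do.call(rbind, c(rows, list(carriers)))
  }
  out <- list(planted = planted, carriers = carriers)
  class(out) <- "trial_truth"
  out
}

#' Simulate a multi-location RCBD phenotype trial
#'
#' Draws plot values
#' \eqn{y = \mu_t (1 + \sum \mathrm{effects}/100) + L_j + B_{k(j)} +
#' (GL)_{ij} + \epsilon} with independent Gaussian components per trait.
#' The control carries no planted effects and is replicated
#' `control_reps` times per block; ILs `il_reps` times. The pooled block
#' (if configured) is drawn as the mean of three independent plant
#' residuals. Cells listed in `config$missing` are omitted. Deterministic
#' under the config seed (a stage seed derived from it).
#'
#' @param library an [il_library()] (from [simulate_library()]).
#' @param truth the matching `trial_truth`.
#' @param config the [simulation_config()].
#' @return A [phenotype_table()] with attribute `expected` (per
#'   line/location/trait expected value including the drawn location and
#'   GxL effects) and attribute `seed`.
#' @export
simulate_trial <- function(library, truth, config) {
  stopifnot(inherits(library, "il_library"), inherits(truth, "trial_truth"),
            inherits(config, "simulation_config"))
  lines <- c(config$control, il_lines(library))
  n_loc <- length(config$locations)
  tr <- config$traits
  if (nrow(tr) == 0L) stop("no traits configured")
  # genetic expectation per line x trait
  gmult <- matrix(1, nrow = length(lines), ncol = nrow(tr),
                  dimnames = list(lines, tr$trait))
  if (nrow(truth$carriers) > 0L) {
    for (r in seq_len(nrow(truth$carriers))) {
      cr <- truth$carriers[r, ]
      gmult[cr$line, cr$trait] <- gmult[cr$line, cr$trait] +
        cr$effect_pct / 100
    }
  }
  trial_seed <- (config$seed + 1000003L) %% .Machine$integer.max
  recs <- NULL
  expected <- NULL
  with_local_seed(trial_seed, {
    for (ti in seq_len(nrow(tr))) {
      mu <- tr$mean[ti]
      L_j <- stats::rnorm(n_loc, 0, sqrt(tr$var_location[ti]))
      B_jk <- matrix(stats::rnorm(n_loc * config$blocks, 0,
                                  sqrt(tr$var_block[ti])),
                     n_loc, config$blocks)
      GL <- matrix(stats::rnorm(length(lines) * n_loc, 0,
                                sqrt(tr$var_gxl[ti])),
                   length(lines), n_loc, dimnames = list(lines, NULL))
      for (j in seq_len(n_loc)) {
        loc <- config$locations[j]
        for (li in seq_along(lines)) {
          ln <- lines[li]
          if (!is.null(config$missing) && ln != config$control &&
              any(config$missing$line == ln &
                    config$missing$location == loc)) next
          reps <- if (ln == config$control) config$control_reps
                  else config$il_reps
          cell_mu <- mu * gmult[li, ti] + L_j[j] + GL[li, j]
          expected <- rbind(expected, data.frame(
            line = ln, location = loc, trait = tr$trait[ti],
            expected = cell_mu))
          for (b in seq_len(config$blocks)) {
            n_draw <- if (!is.na(config$pooled_block) &&
                            b == config$pooled_block) 3L else 1L
            eps <- vapply(seq_len(reps), function(r)
              mean(stats::rnorm(n_draw, 0, sqrt(tr$var_resid[ti]))),
              numeric(1))
            recs <- rbind(recs, data.frame(
              line = ln, location = loc, block = b, trait = tr$trait[ti],
              value = cell_mu + B_jk[j, b] + eps,
              n_sampled = if (n_draw == 3L) 3L else 4L))
          }
        }
      }
    }
  })
  out <- phenotype_table(recs, control = config$control,
                         blocks = config$blocks,
                         control_reps = config$control_reps)
  attr(out, "expected") <- expected
  attr(out, "seed") <- trial_seed
  out
}

#' Score QTL recovery against the planted truth
#'
#' A planted QTL is recovered when some same-trait QTL record on its
#' chromosome has a physical interval containing the planted position
#' (`matching_rule = "contains"`; `"chromosome"` relaxes matching to the
#' chromosome, with localization then scored separately). Records matching
#' no planted QTL are false discoveries.
#'
#' @param qtl_records list of `qtl_record` objects (or a [qtl_table()]
#'   data.frame).
#' @param truth a `trial_truth`.
#' @param matching_rule `"contains"` or `"chromosome"`.
#' @return A `recovery_report` list: `power`, `n_false`,
#'   `localization_rate`, `per_qtl` data.frame (recovered flag, matched
#'   record, effect-estimate error reported minus planted percent).
#' @export
evaluate_recovery <- function(qtl_records, truth,
                              matching_rule = c("contains", "chromosome")) {
  matching_rule <- match.arg(matching_rule)
  stopifnot(inherits(truth, "trial_truth"))
  tab <- if (is.data.frame(qtl_records)) qtl_records else
    qtl_table(qtl_records)
  planted <- truth$planted
  if (is.null(planted) || nrow(planted) == 0L) {
    out <- list(power = NA_real_, n_false = nrow(tab),
                localization_rate = NA_real_,
                per_qtl = data.frame())
    class(out) <- "recovery_report"
    return(out)
  }
  matched_rec <- rep(FALSE, nrow(tab))
  per <- do.call(rbind, lapply(seq_len(nrow(planted)), function(q) {
    same <- tab$trait == planted$trait[q] & tab$chrom == planted$chrom[q]
    inside <- same & tab$mb_start <= planted$pos_mb[q] &
      planted$pos_mb[q] < tab$mb_end
    hit <- if (matching_rule == "contains") inside else same
    rec <- which(hit)[1L]
    if (!is.na(rec)) matched_rec[which(hit)] <<- TRUE
    data.frame(qtl_id = planted$qtl_id[q], trait = planted$trait[q],
               chrom = planted$chrom[q], pos_mb = planted$pos_mb[q],
               effect_pct = planted$effect_pct[q],
               recovered = !is.na(rec),
               localized = any(inside),
               matched = if (!is.na(rec)) tab$qtl[rec] else NA_character_,
               effect_error = if (!is.na(rec))
                 tab$pct_diff[rec] - planted$effect_pct[q] else NA_real_)
  }))
  out <- list(power = mean(per$recovered),
              n_false = sum(!matched_rec),
              localization_rate = if (any(per$recovered))
                mean(per$localized[per$recovered]) else NA_real_,
              per_qtl = per)
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("QTL recovery: power %.2f, %d false discoveries",
              x$power, x$n_false))
  if (!is.na(x$localization_rate))
    cat(sprintf(", localization %.2f", x$localization_rate))
  cat("\n")
  invisible(x)
}
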
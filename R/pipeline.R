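# End-to-end runs tying the stages together, with file outputs and a
# run-metadata record. These functions are the programmatic interface; the
# thin command-line front-end at inst/exec/ilqtl maps subcommands
# simulate/analyze/report onto them.

stage_msg <- function(verbose, ...) if (verbose) message("[ilqtl] ", ...)

file_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  stats::setNames(as.character(tools::md5sum(paths)), basename(paths))
}

write_run_metadata <- function(out_dir, params, inputs = character()) {
  meta <- list(
    package = "ilqtl",
    version = as.character(utils::packageVersion("ilqtl")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    parameters = params,
    input_checksums = as.list(file_checksums(inputs)))
  yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yaml"))
}

#' Read a simulation/run configuration from YAML
#'
#' Recognized keys mirror the arguments of [simulation_config()] (genome
#' given as lists `chrom`, `length_mb`, `length_cm`; traits and
#' planted_qtls as lists of records). Unknown keys are an error.
#'
#' @param path YAML file.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$genome))
    y$genome <- genome_spec(y$genome$chrom, y$genome$length_mb,
                            y$genome$length_cm %||% NA_real_)
  for (k in c("traits", "planted_qtls", "missing"))
    if (!is.null(y[[k]]) && !is.data.frame(y[[k]]))
      y[[k]] <- do.call(rbind, lapply(y[[k]], as.data.frame))
  do.call(simulation_config, y)
}

#' Simulate a library and trial to files
#'
#' Writes the introgression map (BED, bp), genome file, cM companion,
#' phenotype CSV, planted-truth CSV and a run-metadata YAML into
#' `out_dir`. Outputs re-validate on load and are byte-identical under a
#' repeated run with the same config.
#'
#' @param config a [simulation_config()] (or path to a YAML config).
#' @param out_dir output directory (created if needed).
#' @param verbose log each stage.
#' @return Invisibly, a list with the simulated `library`, `truth`,
#'   `phenotypes` and the written `paths`.
#' @export
run_simulate <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_lines < 1L) stop("config has no ILs; nothing to simulate")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_msg(verbose, "simulate_library (", config$n_lines, " lines, seed ",
            config$seed, ")")
  sim <- simulate_library(config)
  stage_msg(verbose, "simulate_trial (", length(config$locations),
            " locations x ", config$blocks, " blocks)")
  phen <- simulate_trial(sim$library, sim$truth, config)
  paths <- list(
    map = file.path(out_dir, "introgression_map.bed"),
    genome = file.path(out_dir, "genome.txt"),
    cm = file.path(out_dir, "introgression_map_cm.csv"),
    phenotypes = file.path(out_dir, "phenotypes.csv"),
    truth = file.path(out_dir, "planted_qtls.csv"))
  write_introgression_map(sim$library, paths$map, paths$genome, paths$cm)
  write_phenotypes(phen, paths$phenotypes)
  planted <- sim$truth$planted
  if (is.null(planted))
    planted <- data.frame(trait = character(), chrom = character(),
                          pos_mb = numeric(), effect_pct = numeric(),
                          qtl_id = integer())
  utils::write.csv(planted, paths$truth, row.names = FALSE, quote = FALSE)
  write_run_metadata(out_dir, params = list(
    subcommand = "simulate", seed = config$seed, n_lines = config$n_lines,
    locations = config$locations, blocks = config$blocks,
    il_reps = config$il_reps, control_reps = config$control_reps))
  stage_msg(verbose, "wrote ", length(paths), " artifacts to ", out_dir)
  invisible(list(library = sim$library, truth = sim$truth,
                 phenotypes = phen, paths = paths))
}

#' Run the full QTL-detection analysis
#'
#' Executes the pipeline on a phenotype table and introgression library:
#' color-trait derivation, two-way variance partitioning, per-location
#' heritability and trait correlations, per-location RCBD fits with
#' Dunnett screening against the control, the cross-location consistency
#' filter, overlap grouping with IL-vs-IL contrasts, and merge-or-split
#' QTL resolution with naming. With `out_dir` set, every intermediate
#' table is written (screen, candidates, effects, heritability,
#' correlations, QTL CSV and BED) along with run metadata.
#'
#' @param phenotypes a [phenotype_table()] or path to a phenotype CSV.
#' @param library an [il_library()] or path to a BED-like map (then
#'   `genome` must be the genome file path).
#' @param genome genome file path when `library` is a path.
#' @param cm_path optional cM companion path when `library` is a path.
#' @param alpha Dunnett / contrast significance level.
#' @param min_locations consistency filter threshold.
#' @param same_sign require a common effect sign across locations.
#' @param block_adjust adjust for blocks in the per-location fits.
#' @param traits traits to screen (default: all in the table).
#' @param out_dir optional output directory.
#' @param mc_seed seed of the multivariate-t integrator (recorded).
#' @param verbose log each stage.
#' @return A list: `effects`, `heritability`, `correlations`, `screen`,
#'   `candidates`, `qtls` (named `qtl_record` list), `qtl_table`.
#' @export
run_analyze <- function(phenotypes, library, genome = NULL, cm_path = NULL,
                        alpha = 0.05, min_locations = 2L, same_sign = TRUE,
                        block_adjust = TRUE, traits = NULL, out_dir = NULL,
                        mc_seed = 190443L, verbose = TRUE) {
  stopifnot(alpha > 0, alpha < 1, min_locations >= 1L)
  inputs <- character(0)
  if (is.character(phenotypes)) {
    inputs <- c(inputs, phenotypes)
    phenotypes <- read_phenotypes(phenotypes)
  }
  if (is.character(library)) {
    if (is.null(genome))
      stop("genome file path required when library is given as a path")
    inputs <- c(inputs, library, genome)
    library <- load_introgression_map(library, genome, cm_path = cm_path)
  }
  stopifnot(inherits(phenotypes, "phenotype_table"),
            inherits(library, "il_library"))

  stage_msg(verbose, "derive_color_traits")
  phenotypes <- derive_color_traits(phenotypes)
  d <- as.data.frame(phenotypes)
  if (is.null(traits)) traits <- sort(unique(d$trait))
  locations <- sort(unique(d$location))

  stage_msg(verbose, "partition_variance (", length(traits), " traits)")
  effects <- NULL
  for (tr in traits) {
    ef <- tryCatch(partition_variance(phenotypes, tr),
                   error = function(e) NULL)
    effects <- rbind(effects, ef)
  }

  stage_msg(verbose, "heritability and trait_correlations per location")
  herit <- NULL
  for (tr in traits) for (loc in locations) {
    h <- tryCatch(heritability(phenotypes, tr, loc),
                  error = function(e) NULL)
    herit <- rbind(herit, h)
  }
  correlations <- lapply(locations, function(loc)
    trait_correlations(phenotypes, loc, traits = traits))
  names(correlations) <- locations

  stage_msg(verbose, "dunnett_compare per trait x location (alpha = ",
            alpha, ")")
  screen <- NULL
  for (tr in traits) for (loc in locations) {
    fit <- tryCatch(
      fit_location_model(phenotypes, tr, loc, block_adjust = block_adjust),
      error = function(e) NULL)
    if (is.null(fit)) next
    screen <- rbind(screen, dunnett_compare(fit, alpha = alpha,
                                            mc_seed = mc_seed))
  }
  if (is.null(screen)) stop("dunnett_screen: no trait/location could be fit")

  stage_msg(verbose, "consistency_filter (min_locations = ", min_locations,
            ", same_sign = ", same_sign, ")")
  candidates <- consistency_filter(screen, min_locations = min_locations,
                                   require_same_sign = same_sign)

  stage_msg(verbose, "build_overlap_groups (", nrow(candidates),
            " candidates)")
  groups <- build_overlap_groups(candidates, library)

  stage_msg(verbose, "contrast_test + resolve_qtls (", length(groups),
            " groups)")
  records <- list()
  for (g in groups) {
    contrasts <- list()
    k <- nrow(g$members)
    if (k > 1L) for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (!g$overlap[i, j]) next
      la <- g$members$line[i]; lb <- g$members$line[j]
      shared_q <- intersect(
        strsplit(g$members$locations[i], ";", fixed = TRUE)[[1L]],
        strsplit(g$members$locations[j], ";", fixed = TRUE)[[1L]])
      ct <- contrast_test(phenotypes, g$trait, la, lb,
                          locations = if (length(shared_q) > 0) shared_q,
                          alpha = alpha, block_adjust = block_adjust)
      contrasts[[length(contrasts) + 1L]] <- ct
    }
    records <- c(records,
                 resolve_qtls(g, contrasts, library, alpha = alpha))
  }
  records <- name_qtls(records)
  qtab <- qtl_table(records)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(x, f) if (!is.null(x))
      utils::write.csv(as.data.frame(x), file.path(out_dir, f),
                       row.names = FALSE)
    wcsv(effects, "effects.csv")
    wcsv(herit, "heritability.csv")
    for (loc in locations)
      utils::write.csv(correlations[[loc]]$r,
                       file.path(out_dir, paste0("correlations_", loc,
                                                 ".csv")))
    wcsv(screen, "screen.csv")
    wcsv(candidates, "candidates.csv")
    wcsv(qtab, "qtls.csv")
    if (nrow(qtab) > 0L)
      export_bed(qtab, file.path(out_dir, "qtls.bed"))
    write_run_metadata(out_dir, params = list(
      subcommand = "analyze", alpha = alpha, min_locations = min_locations,
      same_sign = same_sign, block_adjust = block_adjust,
      mc_seed = mc_seed, ss_type = "III"), inputs = inputs)
    stage_msg(verbose, "wrote analysis tables to ", out_dir)
  }
  list(effects = effects, heritability = herit,
       correlations = correlations, screen = screen,
       candidates = candidates, qtls = records, qtl_table = qtab)
}

#' Summarize a QTL registry to files
#'
#' Loads a registry CSV, prints/returns per-chromosome and per-trait
#' counts and writes the BED export plus a plain-text summary when
#' `out_dir` is given.
#'
#' @param registry_path registry CSV (see [load_registry()]), or a
#'   `qtl_registry` object.
#' @param out_dir optional output directory.
#' @param genome a [genome_spec()] for the chromosome set.
#' @param verbose log stages.
#' @return Invisibly, the summary list of [summary.qtl_registry()].
#' @export
run_report <- function(registry_path, out_dir = NULL,
                       genome = default_genome(), verbose = TRUE) {
  stage_msg(verbose, "load_registry")
  reg <- if (inherits(registry_path, "qtl_registry")) registry_path
         else load_registry(registry_path)
  stage_msg(verbose, "summarize (", nrow(reg$records), " QTLs)")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    export_bed(reg, file.path(out_dir, "registry.bed"))
    sink(file.path(out_dir, "registry_summary.txt"))
    res <- summary(reg, genome = genome)
    sink()
    write_run_metadata(out_dir, params = list(subcommand = "report"),
                       inputs = if (is.character(registry_path))
                         registry_path else character())
    stage_msg(verbose, "wrote registry report to ", out_dir)
  } else {
    res <- summary(reg, genome = genome)
  }
  invisible(res)
}
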
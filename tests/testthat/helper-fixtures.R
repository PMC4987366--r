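# Fixture builders shared across test files. Everything is generated in
# code; no binary or downloaded data.

# tiny two-chromosome genome
tiny_genome <- function() genome_spec(c("1", "2"), c(100, 80), c(120, 90))

# library with hand-placed segments for overlap-logic tests
tiny_library <- function() {
  il_library(tiny_genome(), data.frame(
    line = c("SP_1-1", "SP_1-2", "SP_2-1", "SP_2-2", "SP_2-3"),
    chrom = c("1", "1", "2", "2", "2"),
    start_mb = c(0, 45, 0, 30, 55),
    end_mb = c(50, 100, 40, 60, 80)))
}

# balanced single-location RCBD phenotype table with specified genotype
# effects, block effects and residual sd (control = "MM")
rcbd_table <- function(effects = c(MM = 0, A = 0, B = 0), blocks = 4L,
                       block_eff = rep(0, blocks), sd = 0, reps = 1L,
                       location = "L1", trait = "FW", mu = 50,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  recs <- expand.grid(line = names(effects), block = seq_len(blocks),
                      rep = seq_len(reps), stringsAsFactors = FALSE)
  recs$location <- location
  recs$trait <- trait
  recs$value <- mu + effects[recs$line] + block_eff[recs$block] +
    rnorm(nrow(recs), 0, sd)
  recs$rep <- NULL
  phenotype_table(recs, control = "MM", blocks = blocks)
}

# multi-location table: list of per-location effect vectors
multiloc_table <- function(effects_by_loc, blocks = 4L, sd = 0, mu = 50,
                           trait = "FW", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tabs <- lapply(names(effects_by_loc), function(loc)
    as.data.frame(rcbd_table(effects_by_loc[[loc]], blocks = blocks,
                             sd = sd, mu = mu, location = loc,
                             trait = trait)))
  phenotype_table(do.call(rbind, tabs), control = "MM", blocks = blocks)
}

# 1-kb bitmap union oracle for coverage (coordinates must be multiples of
# 1e-3 Mb); independent of the interval algebra under test
bitmap_union_mb <- function(library) {
  total <- 0
  for (ci in seq_len(nrow(library$genome))) {
    ch <- library$genome$chrom[ci]
    nbins <- round(library$genome$length_mb[ci] * 1000)
    bits <- logical(nbins)
    s <- library$segments[library$segments$chrom == ch, ]
    for (i in seq_len(nrow(s))) {
      a <- round(s$start_mb[i] * 1000) + 1L
      b <- round(s$end_mb[i] * 1000)
      if (b >= a) bits[a:b] <- TRUE
    }
    total <- total + sum(bits) / 1000
  }
  total
}

# connected components by boolean matrix powers (independent of the BFS
# used in the package)
components_matrix_power <- function(adj) {
  k <- nrow(adj)
  reach <- adj | diag(k) == 1
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  match(apply(reach, 1, paste, collapse = ""),
        unique(apply(reach, 1, paste, collapse = "")))
}

# global-null single-location dataset of the reference design:
# n_il ILs x 1 rep/block, control x 6 reps/block, 8 blocks
null_location_table <- function(seed, n_il = 54L, blocks = 8L,
                                control_reps = 6L, sd = 1) {
  set.seed(seed)
  ils <- sprintf("IL%02d", seq_len(n_il))
  recs <- rbind(
    expand.grid(line = ils, block = seq_len(blocks), rep = 1L,
                stringsAsFactors = FALSE),
    expand.grid(line = "MM", block = seq_len(blocks),
                rep = seq_len(control_reps), stringsAsFactors = FALSE))
  blk_eff <- rnorm(blocks, 0, 0.5)
  recs$location <- "L1"
  recs$trait <- "FW"
  recs$value <- 10 + blk_eff[recs$block] + rnorm(nrow(recs), 0, sd)
  recs$rep <- NULL
  phenotype_table(recs, control = "MM", blocks = blocks)
}
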
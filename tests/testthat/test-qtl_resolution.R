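# Overlap grouping, contrasts and the merge-or-split resolution rule.

mk_cand <- function(lines, trait = "FW", pct = -20, locs = "L1;L2") {
  data.frame(line = lines, trait = trait, locations = locs,
             n_locations = 2L, sign = as.integer(sign(pct)),
             mean_pct_diff = pct)
}

# contrast stub for resolution tests (the rule consumes only the flag)
mk_contrast <- function(a, b, significant, trait = "FW") {
  structure(list(line_a = a, line_b = b, trait = trait,
                 p = if (significant) 0.001 else 0.8,
                 significant = significant),
            class = "contrast_result")
}

test_that("candidates split into per-(trait, chromosome) groups", {
  lib <- tiny_library()
  # same trait, disjoint chromosomes -> two singleton groups
  g <- build_overlap_groups(mk_cand(c("SP_1-1", "SP_2-1")), lib)
  expect_length(g, 2L)
  expect_equal(vapply(g, function(x) nrow(x$members), integer(1)), c(1L, 1L))
  # overlapping on one chromosome -> one group with overlap matrix TRUE
  g2 <- build_overlap_groups(mk_cand(c("SP_2-1", "SP_2-2")), lib)
  expect_length(g2, 1L)
  expect_true(g2[[1]]$overlap["SP_2-1", "SP_2-2"])
  # non-overlapping same-chromosome members share a group, overlap FALSE
  g3 <- build_overlap_groups(mk_cand(c("SP_2-1", "SP_2-3")), lib)
  expect_false(g3[[1]]$overlap["SP_2-1", "SP_2-3"])
  expect_error(build_overlap_groups(mk_cand("SP_9-9"), lib), "absent")
})

test_that("a line with segments on two chromosomes joins both groups,
           flagged ambiguous", {
  lib <- il_library(tiny_genome(), data.frame(
    line = c("SP_1-1", "SP_1-1", "SP_2-9"),
    chrom = c("1", "2", "2"),
    start_mb = c(0, 0, 30), end_mb = c(50, 20, 60)))
  g <- build_overlap_groups(mk_cand("SP_1-1"), lib)
  expect_length(g, 2L)
  expect_true(all(vapply(g, function(x) x$members$ambiguous[1], logical(1))))
})

test_that("contrast test: identical lines give p near 1, separated lines
           are detected", {
  # identical simulated effects, zero noise: difference exactly 0
  tab <- multiloc_table(list(L1 = c(MM = 0, A = 5, B = 5, C = 0),
                             L2 = c(MM = 0, A = 5, B = 5, C = 0)),
                        blocks = 4, sd = 1, seed = 42)
  ct <- contrast_test(tab, "FW", "A", "B")
  expect_gt(ct$p, 0.05)
  expect_equal(ct$locations, c("L1", "L2"))
  # zero-noise identical effects: estimate exactly 0
  tab0 <- multiloc_table(list(L1 = c(MM = 0, A = 5, B = 5, C = 1)),
                         blocks = 4, sd = 0)
  ct0 <- suppressWarnings(contrast_test(tab0, "FW", "A", "B"))
  expect_equal(ct0$estimate, 0)
  expect_error(contrast_test(tab, "FW", "A", "B", locations = "L9"),
               "shared location")
})

test_that("contrasts separate planted effects 4 SE apart with power > 95%", {
  # one location, 8 blocks; effect gap tuned to ~4 SE of the A-B contrast
  sd_e <- 1
  se_ab <- sd_e * sqrt(2 / 8)       # balanced contrast SE
  gap <- 4 * se_ab
  hits <- 0L
  n_trials <- 300L
  for (i in seq_len(n_trials)) {
    tab <- rcbd_table(c(MM = 0, A = 0, B = gap), blocks = 8, sd = sd_e,
                      seed = 9000 + i)
    ct <- contrast_test(tab, "FW", "A", "B")
    hits <- hits + ct$significant
  }
  expect_gt(hits / n_trials, 0.95)
})

test_that("singleton and pairwise resolution follow the merge/split rule", {
  lib <- tiny_library()
  g1g <- genome_spec("7", 80, 100)
  lib7 <- il_library(g1g, data.frame(
    line = c("SP_7-1", "SP_7-2"), chrom = "7",
    start_mb = c(60, 40), end_mb = c(64, 50)))
  # singleton: QTL spans the line's introgression
  g <- build_overlap_groups(mk_cand("SP_7-1"), lib7)
  r <- resolve_qtls(g[[1]], list(), lib7)
  expect_length(r, 1L)
  expect_equal(c(r[[1]]$mb_start, r[[1]]$mb_end), c(60, 64))

  # overlapping pair [38,44) + [40,50), contrast NOT significant:
  # one QTL at the intersection [40,44)
  libp <- il_library(g1g, data.frame(
    line = c("A", "B"), chrom = "7", start_mb = c(38, 40),
    end_mb = c(44, 50)))
  gp <- build_overlap_groups(mk_cand(c("A", "B")), libp)
  rm_ <- resolve_qtls(gp[[1]], list(mk_contrast("A", "B", FALSE)), libp)
  expect_length(rm_, 1L)
  expect_equal(c(rm_[[1]]$mb_start, rm_[[1]]$mb_end), c(40, 44))
  expect_setequal(rm_[[1]]$lines, c("A", "B"))

  # same geometry, significant contrast: two QTLs flanking the overlap
  rs <- resolve_qtls(gp[[1]], list(mk_contrast("A", "B", TRUE)), libp)
  expect_length(rs, 2L)
  ints <- lapply(rs, function(r) c(r$mb_start, r$mb_end))
  expect_equal(ints[[1]], c(38, 40))
  expect_equal(ints[[2]], c(44, 50))

  # missing contrast for an overlapping pair is an error naming the pair
  expect_error(resolve_qtls(gp[[1]], list(), libp), "A / B")
})

test_that("split that would empty an interval keeps the introgression,
           flagged", {
  # B nested inside A: A minus overlap is non-empty, B minus overlap empty
  g1g <- genome_spec("1", 100, 100)
  lib <- il_library(g1g, data.frame(
    line = c("A", "B"), chrom = "1", start_mb = c(10, 20),
    end_mb = c(60, 40)))
  g <- build_overlap_groups(mk_cand(c("A", "B")), lib)
  r <- resolve_qtls(g[[1]], list(mk_contrast("A", "B", TRUE)), lib)
  expect_length(r, 2L)
  flags <- lapply(r, `[[`, "flags")
  expect_true(any(vapply(flags, function(f)
    "split_would_empty_interval" %in% f, logical(1))))
})

test_that("component partition matches the matrix-power oracle on random
           overlap/contrast patterns up to 5 members", {
  set.seed(314)
  g1g <- genome_spec("1", 1000, 100)
  for (case in 1:250) {
    k <- sample(2:5, 1)
    starts <- runif(k, 0, 900)
    ends <- starts + runif(k, 10, 120)
    lines <- sprintf("L%d", seq_len(k))
    lib <- il_library(g1g, data.frame(line = lines, chrom = "1",
                                      start_mb = starts,
                                      end_mb = pmin(ends, 1000)))
    g <- build_overlap_groups(mk_cand(lines), lib)[[1]]
    # random contrast significance for overlapping pairs
    contrasts <- list()
    sig <- matrix(FALSE, k, k)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (!g$overlap[i, j]) next
      s <- runif(1) < 0.5
      sig[i, j] <- sig[j, i] <- s
      contrasts[[length(contrasts) + 1L]] <-
        mk_contrast(g$members$line[i], g$members$line[j], s)
    }
    recs <- resolve_qtls(g, contrasts, lib)
    # oracle partition: edges = overlap & !significant, components via
    # boolean matrix powers
    adj <- g$overlap & !sig
    diag(adj) <- TRUE
    oracle <- components_matrix_power(adj)
    # compare partitions via supporting-line sets
    got <- lapply(recs, function(r) sort(r$lines))
    want <- lapply(split(g$members$line, oracle), sort)
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
    # hard invariant: interval within union of supporting introgressions
    for (r in recs) {
      sup <- Reduce(ilqtl:::iv_union,
                    lapply(r$lines, ilqtl:::line_iv, library = lib,
                           chrom = "1"))
      expect_true(ilqtl:::iv_contains(sup, r$interval))
    }
  }
})

test_that("resolution is invariant under member order", {
  g1g <- genome_spec("1", 200, 100)
  lib <- il_library(g1g, data.frame(
    line = c("A", "B", "C"), chrom = "1",
    start_mb = c(0, 30, 80), end_mb = c(40, 90, 140)))
  cands <- mk_cand(c("A", "B", "C"))
  cons <- list(mk_contrast("A", "B", FALSE), mk_contrast("B", "C", TRUE))
  g1 <- build_overlap_groups(cands, lib)[[1]]
  g2 <- build_overlap_groups(cands[c(3, 1, 2), ], lib)[[1]]
  r1 <- qtl_table(name_qtls(resolve_qtls(g1, cons, lib)))
  r2 <- qtl_table(name_qtls(resolve_qtls(g2, cons, lib)))
  expect_equal(r1[order(r1$qtl), ], r2[order(r2$qtl), ],
               ignore_attr = TRUE)
})

test_that("QTL names follow <prefix><chrom>.<serial> ordered by position", {
  mk_rec <- function(trait, chrom, s, e, lines = "X") {
    structure(list(name = NA_character_, trait = trait, chrom = chrom,
                   interval = ilqtl:::iv(s, e), mb_start = s, mb_end = e,
                   cm_start = NA_real_, cm_end = NA_real_,
                   n_locations = 2L, pct_diff = -20, lines = lines,
                   flags = character()), class = "qtl_record")
  }
  recs <- list(mk_rec("FW", "1", 78, 90), mk_rec("FW", "1", 74, 78),
               mk_rec("SSC", "9", 4, 57))
  named <- name_qtls(recs)
  tab <- qtl_table(named)
  expect_equal(tab$qtl[tab$mb_start == 74], "fw1.1")
  expect_equal(tab$qtl[tab$mb_start == 78], "fw1.2")
  expect_equal(tab$qtl[tab$trait == "SSC"], "ssc9.1")
  # permuting input order gives identical names
  named2 <- name_qtls(recs[c(3, 1, 2)])
  expect_equal(qtl_table(named2)$qtl, tab$qtl)
  # color-family prefixes keep the component case
  r_ic <- name_qtls(list(mk_rec("IC_L", "5", 0, 0.5)))
  expect_equal(r_ic[[1]]$name, "ic_L5.1")
  expect_error(name_qtls(list(mk_rec("FW", "1", 74, 78),
                              mk_rec("FW", "1", 74, 78))), "duplicate")
})

test_that("effect summaries average the qualifying locations", {
  scr <- data.frame(line = "A", trait = "FW",
                    location = c("L1", "L2", "L3"),
                    diff = -1, pct_diff = c(-20, -30, -25),
                    t = -3, p_adj = 0.01, significant = TRUE)
  cand <- consistency_filter(scr)
  expect_equal(effect_summary(cand[1, ], scr), -25)
  scr2 <- scr[1:2, ]; scr2$pct_diff <- c(-25, -25)
  cand2 <- consistency_filter(scr2)
  expect_equal(effect_summary(cand2[1, ], scr2), -25)
})
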
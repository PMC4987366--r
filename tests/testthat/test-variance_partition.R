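# Two-way variance partitioning, heritability and trait correlations.

test_that("constant data gives zero effect percentages and no significance", {
  tab <- multiloc_table(list(L1 = c(MM = 0, A = 0), L2 = c(MM = 0, A = 0)),
                        blocks = 3)
  ef <- partition_variance(tab, "FW")
  expect_equal(ef$pct_genotype, 0)
  expect_equal(ef$pct_location, 0)
  expect_equal(ef$pct_interaction, 0)
  expect_false(any(unlist(ef[grep("^sig", names(ef))])))
})

test_that("pure additive genotype shift gives 100% genotype effect", {
  tab <- multiloc_table(list(L1 = c(MM = 0, A = 10), L2 = c(MM = 0, A = 10)),
                        blocks = 3)
  ef <- partition_variance(tab, "FW")
  expect_equal(ef$pct_genotype, 100, tolerance = 1e-9)
  expect_equal(ef$pct_location, 0, tolerance = 1e-9)
  expect_equal(ef$pct_interaction, 0, tolerance = 1e-9)
})

test_that("balanced SS decomposition is exact and relabeling-invariant", {
  set.seed(31)
  g <- rep(sprintf("G%d", 1:6), each = 2 * 10)
  l <- rep(rep(c("L1", "L2"), each = 10), 6)
  recs <- data.frame(line = ifelse(g == "G1", "MM", g), location = l,
                     block = rep(1:10, 12), trait = "FW",
                     value = rnorm(120) + as.integer(factor(g)) +
                       2 * (l == "L2"))
  tab <- phenotype_table(recs, blocks = 10)
  ef <- partition_variance(tab, "FW")
  total_ss <- sum((recs$value - mean(recs$value))^2)
  expect_equal(ef$ss_genotype + ef$ss_location + ef$ss_interaction +
                 ef$ss_residual, total_ss, tolerance = 1e-8)
  expect_equal(ef$pct_genotype + ef$pct_location + ef$pct_interaction,
               100 * (1 - ef$ss_residual / total_ss), tolerance = 1e-8)
  # relabeling genotypes and locations leaves percentages unchanged
  rl <- recs
  rl$line <- chartr("GM", "HX", rl$line)   # MM -> XX etc.
  rl$location <- paste0("Z", rl$location)
  tab2 <- phenotype_table(rl, control = "XX", blocks = 10)
  ef2 <- partition_variance(tab2, "FW")
  expect_equal(ef2$pct_genotype, ef$pct_genotype, tolerance = 1e-9)
  expect_equal(ef2$pct_location, ef$pct_location, tolerance = 1e-9)
  expect_equal(ef2$pct_interaction, ef$pct_interaction, tolerance = 1e-9)
})

test_that("SS percentages recover planted variance-component structure", {
  # (s2G, s2L, s2GL, s2e) = (4, 2, 1, 1): with many replicates the SS
  # shares approach the expected mean squares' shares; checked against an
  # independent explicit design-matrix projection computation
  set.seed(77)
  ng <- 8; nl <- 3; nr <- 40
  g_eff <- rnorm(ng, 0, 2); l_eff <- rnorm(nl, 0, sqrt(2))
  gl_eff <- matrix(rnorm(ng * nl, 0, 1), ng, nl)
  d <- expand.grid(gi = 1:ng, li = 1:nl, r = 1:nr)
  d$value <- g_eff[d$gi] + l_eff[d$li] + gl_eff[cbind(d$gi, d$li)] +
    rnorm(nrow(d))
  recs <- data.frame(line = ifelse(d$gi == 1, "MM", sprintf("G%d", d$gi)),
                     location = sprintf("L%d", d$li),
                     block = d$r, trait = "FW", value = d$value)
  tab <- phenotype_table(recs, blocks = nr)
  ef <- partition_variance(tab, "FW")
  # independent oracle: sequential projections (balanced => type III ==
  # type I), built from raw design matrices and lm only via lsfit-free
  # algebra
  X0 <- matrix(1, nrow(d), 1)
  Xg <- model.matrix(~ 0 + factor(gi), d)
  Xl <- model.matrix(~ 0 + factor(li), d)
  Xgl <- model.matrix(~ 0 + factor(gi):factor(li), d)
  proj <- function(X) X %*% solve(crossprod(X), t(X))
  P0 <- proj(X0); Pg <- proj(cbind(Xg)); Pl <- proj(cbind(Xl))
  Pgl <- proj(Xgl)
  y <- d$value
  ss_g <- drop(t(y) %*% (Pg - P0) %*% y)
  ss_l <- drop(t(y) %*% (Pl - P0) %*% y)
  ss_gl <- drop(t(y) %*% (Pgl - Pg - Pl + P0) %*% y)
  ss_e <- drop(t(y) %*% (diag(nrow(d)) - Pgl) %*% y)
  tot <- ss_g + ss_l + ss_gl + ss_e
  expect_equal(ef$pct_genotype, 100 * ss_g / tot, tolerance = 1e-6)
  expect_equal(ef$pct_location, 100 * ss_l / tot, tolerance = 1e-6)
  expect_equal(ef$pct_interaction, 100 * ss_gl / tot, tolerance = 1e-6)
  expect_true(ef$sig05_genotype && ef$sig05_location)
})

test_that("single location or single genotype is rejected", {
  tab <- rcbd_table(c(MM = 0, A = 1), blocks = 3)
  expect_error(partition_variance(tab, "FW"), "single location")
})

test_that("heritability handles degenerate spreads and truncation", {
  # zero between-genotype spread (pure noise): Vg truncated near 0
  set.seed(8)
  recs <- data.frame(line = rep(c("MM", "A", "B", "C"), each = 10),
                     location = "L1", block = rep(1:10, 4), trait = "FW",
                     value = rep(c(5, 5, 5, 5), each = 10))
  h <- heritability(phenotype_table(recs, blocks = 10), "FW", "L1")
  expect_equal(h$h2, 0)
  expect_equal(h$Vg, 0)
  # two genotypes, means 0 and 10, zero residual variance: h2 -> 1
  recs2 <- data.frame(line = rep(c("MM", "A"), each = 4), location = "L1",
                      block = rep(1:4, 2), trait = "FW",
                      value = rep(c(0, 10), each = 4))
  h2 <- heritability(phenotype_table(recs2, blocks = 4), "FW", "L1")
  expect_equal(h2$h2, 1)
  # no replication: error
  recs3 <- data.frame(line = c("MM", "A"), location = "L1", block = 1,
                      trait = "FW", value = c(0, 1))
  expect_error(heritability(phenotype_table(recs3), "FW", "L1"),
               "replication")
})

test_that("heritability estimator recovers a true h2 of 0.5", {
  # 50 genotypes x 8 reps, s2g = s2e = 1 => h2 = 0.5; mean over 200
  # trials within +/- 0.05 of truth
  set.seed(123)
  est <- replicate(200, {
    g <- rnorm(50)
    d <- data.frame(line = rep(c("MM", sprintf("G%d", 1:49)), each = 8),
                    location = "L1", block = rep(1:8, 50), trait = "FW",
                    value = rep(g, each = 8) + rnorm(400))
    heritability(phenotype_table(d, blocks = 8), "FW", "L1")$h2
  })
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("heritability is invariant under affine trait transforms", {
  set.seed(9)
  d <- data.frame(line = rep(c("MM", "A", "B"), each = 6),
                  location = "L1", block = rep(1:6, 3), trait = "FW",
                  value = rnorm(18) + rep(c(0, 1, 2), each = 6))
  h1 <- heritability(phenotype_table(d, blocks = 6), "FW", "L1")$h2
  d$value <- -3.7 * d$value + 100
  h2 <- heritability(phenotype_table(d, blocks = 6), "FW", "L1")$h2
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("trait correlations hit exact and planted values", {
  set.seed(55)
  lines <- c("MM", sprintf("G%d", 1:53))
  base <- rnorm(54, 10, 2)
  recs <- rbind(
    data.frame(line = lines, location = "L1", block = 1, trait = "T1",
               value = base),
    data.frame(line = lines, location = "L1", block = 1, trait = "T2",
               value = base),               # duplicate trait: r = 1
    data.frame(line = lines, location = "L1", block = 1, trait = "T3",
               value = -base))              # negation: r = -1
  tc <- trait_correlations(phenotype_table(recs), "L1")
  expect_equal(tc$r["T1", "T2"], 1)
  expect_equal(tc$r["T1", "T3"], -1)
  expect_true(isSymmetric(tc$r))
  expect_equal(unname(diag(tc$r)), rep(1, 3))

  # planted r = 0.6 between FW and FD across 54 genotype means
  set.seed(56)
  z1 <- rnorm(54); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(54)
  recs2 <- rbind(
    data.frame(line = lines, location = "L1", block = 1, trait = "FW",
               value = z1),
    data.frame(line = lines, location = "L1", block = 1, trait = "FD",
               value = z2))
  tc2 <- trait_correlations(phenotype_table(recs2), "L1")
  ci <- stats::cor.test(z1, z2)$conf.int
  expect_true(tc2$r["FW", "FD"] >= ci[1] && tc2$r["FW", "FD"] <= ci[2])
  expect_equal(unname(tc2$n["FW", "FD"]), 54)
  # constant trait: correlation undefined
  recs3 <- rbind(recs2, data.frame(line = lines, location = "L1",
                                   block = 1, trait = "K", value = 1))
  tc3 <- trait_correlations(phenotype_table(recs3), "L1")
  expect_true(is.na(tc3$r["K", "FW"]))
})
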
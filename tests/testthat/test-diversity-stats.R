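test_that("Gini closed forms and error contracts", {
  expect_equal(giniIndex(c(1, 1, 1, 1)), 0)
  expect_equal(giniIndex(c(0, 0, 0, 1)), 0.75)         # (n-1)/n, n = 4
  expect_equal(giniIndex(c(1, 2, 3, 4)), 0.25)         # double-sum value
  expect_equal(giniIndex(c(99, 1)), 0.49)
  expect_error(giniIndex(c(0, 0, 0)), "all-zero")
  expect_error(giniIndex(c(-1, 2)), "non-negative")
  expect_equal(giniIndex(c(99, 1), bias_correction = TRUE), 0.98)
})

test_that("Gini matches the double-sum oracle and its invariances", {
  withr::with_seed(7, {
    for (i in 1:50) {
      x <- rpois(sample(2:40, 1), 3) + runif(1)
      expect_equal(giniIndex(x), oracleGini(x), tolerance = 1e-12)
      expect_equal(giniIndex(17.3 * x), giniIndex(x), tolerance = 1e-12)
      expect_equal(giniIndex(sample(x)), giniIndex(x), tolerance = 1e-12)
      expect_lte(giniIndex(x), (length(x) - 1) / length(x) + 1e-12)
      expect_gte(giniIndex(x), 0 - 1e-12)
    }
  })
})

test_that("per-stratum Gini applies the 15-cell cutoff and pools all cells", {
  mkcalls <- function(n, stratum, pair) data.frame(
    cell_id = paste0(stratum, seq_len(n)), ab_type = "ab_single_pair",
    pair_id = pair, gd_type = "gd_unknown", gd_pair_id = NA,
    label = stratum)
  calls <- rbind(
    mkcalls(14, "small", "TRAV4|TRBV19"),                 # under cutoff
    mkcalls(20, "even", rep(paste0("TRAV", 1:20 %% 4, "|TRBV19"), 5)),
    mkcalls(100, "skew", c(rep("TRAV4|TRBV19", 99), "TRAV2|TRBV30")))
  rep <- giniByStratum(calls, min_cells = 15)
  g <- stats::setNames(rep$gini, rep$stratum)
  expect_true(is.na(g[["small"]]))
  expect_equal(g[["even"]], 0)
  expect_equal(g[["skew"]], 0.49)                        # [99, 1]
  expect_true("All T cells" %in% rep$stratum)
  expect_false(is.na(g[["All T cells"]]))
  # uniform 20 pairs x 5 cells -> 0
  uni <- mkcalls(100, "u", rep(sprintf("TRAV%02d|TRBV19", 1:20), each = 5))
  expect_equal(giniByStratum(uni)$gini[1], 0)
})

test_that("gene-count mode measures TRV transcript inequality", {
  p <- toyPanel()
  m <- matrix(0L, 3, 20, dimnames = list(
    c("TRAV1-1", "TRBV19", "TRAC"), sprintf("c%02d", 1:20)))
  m["TRAV1-1", ] <- 3L                     # even across V genes
  m["TRBV19", ] <- 3L
  m["TRAC", ] <- 2L                        # C gene: excluded from the vector
  x <- toyExperiment(m)
  calls <- data.frame(cell_id = colnames(m), ab_type = "ab_unknown",
                      pair_id = NA, gd_type = "gd_unknown", gd_pair_id = NA)
  rep <- giniByStratum(calls, mode = "gene_counts", min_cells = 15,
                       x = x, panel = p)
  expect_equal(rep$gini[rep$stratum == "All T cells"], 0)
  m2 <- m; m2["TRBV19", ] <- 0L
  m2["TRBV19", 1] <- 5L                    # beta mass collapses to 5 counts
  rep2 <- giniByStratum(calls, mode = "gene_counts", min_cells = 15,
                        x = toyExperiment(m2), panel = p)
  expect_gt(rep2$gini[rep2$stratum == "All T cells"], 0)
})

test_that("abundance Jaccard: closed forms, symmetry, binary reduction", {
  expect_equal(jaccardAbundance(c(p = 2, q = 1), c(p = 1, r = 1)), 0.25)
  a <- c(x = 3, y = 2, z = 1)
  expect_equal(jaccardAbundance(a, a), 1)
  expect_equal(jaccardAbundance(a, c(w = 5)), 0)
  expect_equal(jaccardAbundance(a, c(w = 5)),
               jaccardAbundance(c(w = 5), a))
  expect_error(jaccardAbundance(c(p = 0), c(q = 0)), "non-empty")
  # equals binary Jaccard on 0/1 vectors
  withr::with_seed(14, {
    for (i in 1:20) {
      u <- stats::setNames(rbinom(10, 1, 0.5), letters[1:10])
      v <- stats::setNames(rbinom(10, 1, 0.5), letters[1:10])
      if (sum(u) + sum(v) == 0) next
      bin <- sum(u & v) / sum(u | v)
      expect_equal(jaccardAbundance(u, v), bin)
      expect_equal(jaccardAbundance(u, v), jaccardAbundance(v, u))
    }
  })
  # monotone non-increasing as disjoint mass is added to one side
  j0 <- jaccardAbundance(a, a)
  j1 <- jaccardAbundance(a, c(a, new1 = 2))
  j2 <- jaccardAbundance(a, c(a, new1 = 2, new2 = 4))
  expect_true(j0 >= j1 && j1 >= j2)
})

test_that("Chao variant matches vegan and stays in [0, 1]", {
  a <- c(p = 10, q = 5, r = 1)
  b <- c(p = 8, q = 1, s = 2)
  j <- jaccardAbundance(a, b, method = "chao")
  expect_gte(j, 0); expect_lte(j, 1)
  items <- union(names(a), names(b))
  av <- stats::setNames(numeric(length(items)), items); bv <- av
  av[names(a)] <- a; bv[names(b)] <- b
  expect_equal(j, 1 - as.numeric(vegan::vegdist(rbind(av, bv),
                                                method = "chao")))
})

test_that("venn summary mirrors shared/only splits", {
  v <- vennSummary(c(p = 2, q = 1), c(p = 1, r = 1))
  expect_equal(v$n_baseline_only, 1L)
  expect_equal(v$n_shared, 1L)
  expect_equal(v$n_ontreat_only, 1L)
  expect_equal(v$jaccard_abd, 0.25)
})

test_that("paired Gini t-test matches manual computation and degeneracy", {
  r <- pairedGiniTest(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(c(r$t, r$p), c(0, 1))
  # constant non-zero differences: undefined statistic, flagged
  d <- pairedGiniTest(c(0.5, 0.6, 0.7), c(0.3, 0.4, 0.5))
  expect_true(d$degenerate)
  expect_true(is.na(d$p))
  # textbook evaluation: diffs 0.2, 0.15, 0.3
  b <- c(0.5, 0.6, 0.7); o <- c(0.3, 0.45, 0.4)
  diffs <- b - o
  t_manual <- mean(diffs) / (sd(diffs) / sqrt(3))
  p_manual <- 2 * pt(-abs(t_manual), df = 2)
  got <- pairedGiniTest(b, o)
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$p, p_manual, tolerance = 1e-12)
  expect_equal(got$n, 3L)
})

test_that("estimated Gini converges to the planted distribution's Gini", {
  # geometric clone-size distribution; the smallest clone stays above the
  # 3-cells-per-gene detection limit at this depth
  fracs <- 0.5^(1:8)
  fracs <- fracs / sum(fracs)
  alphas <- vFamilyGroups(defaultPanel(), "TRAV")[1:8]
  clones <- data.frame(pair_id = paste0(alphas, "|TRBV19"),
                       fraction = fracs, host_cell_type = "t_cell",
                       spatial_mode = "uniform")
  cfg <- syntheticConfig(
    seed = 19, n_cells = 4000L, tissue_size = c(8000, 8000),
    cell_types = data.frame(name = "t_cell", proportion = 1,
                            spatial_mode = "uniform", t_cell = TRUE),
    clones = clones)
  tt <- generateTissue(cfg)
  calls <- callClonotypes(filterMatrix(tt$experiment), cfg@panel)
  ab <- pairAbundances(calls)
  est <- giniIndex(ab$n_cells)
  # planted abundance vector has one entry per clone
  expect_equal(est, giniIndex(fracs), tolerance = 0.02)
})
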
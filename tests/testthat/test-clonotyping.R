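test_that("seven-way rule table matches the brute-force oracle on [0,6]^2", {
  grid <- expand.grid(a = 0:6, b = 0:6)
  got <- as.character(classifyAB(grid$a, grid$b))
  oracle <- mapply(oracleClassifyAB, grid$a, grid$b)
  expect_equal(got, unname(oracle))
  # spot values fixed by the rule list
  expect_equal(as.character(classifyAB(1, 1)), "ab_single_pair")
  expect_equal(as.character(classifyAB(0, 0)), "ab_unknown")
  expect_equal(as.character(classifyAB(3, 1)), "ab_unknown")
  expect_error(classifyAB(-1, 0), ">= 0")
})

test_that("the seven classes are exhaustive, exclusive and all reachable", {
  grid <- expand.grid(a = 0:6, b = 0:6)
  got <- classifyAB(grid$a, grid$b)
  expect_false(anyNA(got))                       # total function
  expect_setequal(levels(got),
                  c("orphan_alpha", "orphan_beta", "ab_single_pair",
                    "ab_multi_chain", "extra_alpha", "extra_beta",
                    "ab_unknown"))
  expect_true(all(table(got) > 0))               # every class reachable
})

test_that("clonotype calls count distinct V groups and format pairs", {
  p <- toyPanel()
  m <- matrix(0L, 8, 4,
              dimnames = list(c("TRAV29/DV5", "TRAV1-1", "TRAV2", "TRBV30",
                                "TRBV19", "TRAC", "TRGV2", "TRDV1"),
                              c("pair", "extra_a", "none", "gd")))
  m["TRAV29/DV5", "pair"] <- 2L; m["TRBV30", "pair"] <- 1L
  m["TRAV1-1", "extra_a"] <- 1L; m["TRAV2", "extra_a"] <- 1L
  m["TRBV30", "extra_a"] <- 1L
  m["TRAC", "none"] <- 5L
  m["TRGV2", "gd"] <- 1L; m["TRDV1", "gd"] <- 2L
  calls <- callClonotypes(toyExperiment(m), p)
  rownames(calls) <- calls$cell_id
  expect_equal(as.character(calls["pair", "ab_type"]), "ab_single_pair")
  expect_equal(calls["pair", "pair_id"], "TRAV29/DV5|TRBV30")
  expect_equal(as.character(calls["extra_a", "ab_type"]), "extra_alpha")
  expect_true(is.na(calls["extra_a", "pair_id"]))
  expect_equal(as.character(calls["none", "ab_type"]), "ab_unknown")
  expect_equal(calls["none", c("n_alpha", "n_beta")],
               data.frame(n_alpha = 0L, n_beta = 0L, row.names = "none"))
  expect_equal(as.character(calls["gd", "gd_type"]), "gd_single_pair")
  expect_equal(calls["gd", "gd_pair_id"], "TRGV2|TRDV1")
})

test_that("dual TRAV/DV policy moves dual genes between chains", {
  p <- toyPanel()
  m <- matrix(0L, 2, 1, dimnames = list(c("TRAV29/DV5", "TRBV30"), "c1"))
  m[, 1] <- c(2L, 1L)
  x <- toyExperiment(m)
  a <- callClonotypes(x, p, dual_policy = "alpha_only")
  expect_equal(a$pair_id, "TRAV29/DV5|TRBV30")
  expect_equal(c(a$n_alpha, a$n_delta), c(1L, 0L))
  d <- callClonotypes(x, p, dual_policy = "delta_only")
  expect_equal(c(d$n_alpha, d$n_delta), c(0L, 1L))
  expect_equal(as.character(d$ab_type), "orphan_beta")
  b <- callClonotypes(x, p, dual_policy = "both")
  expect_equal(c(b$n_alpha, b$n_delta), c(1L, 1L))
})

test_that("grouped genes count once and non-panel genes warn", {
  p <- toyPanel()
  m <- matrix(0L, 4, 1,
              dimnames = list(c("TRBC1", "TRBC2", "TRBV99", "TRAV1-1"), "c1"))
  m[, 1] <- c(1L, 1L, 3L, 1L)
  expect_warning(calls <- callClonotypes(toyExperiment(m), p), "TRBV99")
  # C genes never enter classification; one alpha V detected
  expect_equal(calls$n_alpha, 1L)
  expect_equal(as.character(calls$ab_type), "orphan_alpha")
})

test_that("calls are invariant to cell order", {
  cfg <- syntheticConfig(seed = 21, n_cells = 300L,
                         tissue_size = c(2000, 2000))
  tt <- generateTissue(cfg)
  x <- filterMatrix(tt$experiment)
  calls <- callClonotypes(x, cfg@panel)
  perm <- withr::with_seed(1, sample(ncol(x)))
  calls2 <- callClonotypes(x[, perm], cfg@panel)
  rownames(calls) <- calls$cell_id
  rownames(calls2) <- calls2$cell_id
  calls2 <- calls2[rownames(calls), ]
  expect_equal(calls2$pair_id, calls$pair_id)
  expect_equal(as.character(calls2$ab_type), as.character(calls$ab_type))
})

test_that("pair abundances count, rank and normalise per stratum", {
  calls <- data.frame(
    cell_id = sprintf("c%02d", 1:12),
    ab_type = c(rep("ab_single_pair", 10), "ab_unknown", "extra_alpha"),
    pair_id = c(rep("TRAV4|TRBV20-1", 6), rep("TRAV2|TRBV19", 3),
                "TRAV2|TRBV30", NA, NA),
    gd_type = "gd_unknown", gd_pair_id = NA)
  ab <- pairAbundances(calls)
  expect_equal(ab$pair_id[1], "TRAV4|TRBV20-1")
  expect_equal(ab$n_cells, c(6L, 3L, 1L))
  expect_equal(sum(ab$fraction), 1)
  s <- pairSummary(ab)
  expect_equal(s$n_unique_pairs, 3L)
  expect_equal(s$dominant_fraction, 0.6)
  # all same pair -> dominant fraction 1
  one <- calls[1:6, ]
  expect_equal(pairSummary(pairAbundances(one))$dominant_fraction, 1)
  # zero single-pair cells -> empty table
  none <- calls[11:12, ]
  expect_equal(nrow(pairAbundances(none)), 0L)
})

test_that("top baseline pairs are tracked into the on-treatment repertoire", {
  mk <- function(pairs, n) data.frame(stratum = "all", pair_id = pairs,
                                      n_cells = n, fraction = n / sum(n))
  base <- mk(c("p1", "p2", "p3", "p4", "p5"), c(9, 7, 5, 2, 1))
  on <- mk(c("p2", "p3", "p9", "p8"), c(4, 3, 2, 1))
  tab <- topPairPersistence(base, on, k = 3)
  expect_equal(tab$present, c(FALSE, TRUE, TRUE))
  expect_false(attr(tab, "shortfall"))
  # disjoint and identical repertoires
  expect_true(all(!topPairPersistence(base, mk("q", 1), 3)$present))
  expect_true(all(topPairPersistence(base, base, 3)$present))
  # k beyond available pairs flags a shortfall
  short <- topPairPersistence(mk(c("p1", "p2"), c(2, 1)), on, k = 3)
  expect_equal(nrow(short), 2L)
  expect_true(attr(short, "shortfall"))
})

test_that("planted pairs are recovered exactly without noise and degrade with it", {
  base <- syntheticConfig(seed = 13, n_cells = 500L,
                          tissue_size = c(2500, 2500),
                          expression = list(v_mean = 5),
                          noise = list(stray_rate = 0, dropout = 0))
  tt <- generateTissue(base)
  # cells-only filter: the gene-detection filter legitimately removes rare
  # background V genes, which is not the property under test here
  calls <- callClonotypes(filterMatrix(tt$experiment,
                                       filterParams(5, 3, 0)), base@panel)
  truth <- tt$truth$cells
  truth_pair <- stats::setNames(truth$true_pair, truth$cell_id)
  tcells <- calls$cell_id[!is.na(truth_pair[calls$cell_id])]
  expect_true(all(calls$ab_type[calls$cell_id %in% tcells] ==
                    "ab_single_pair"))
  expect_equal(calls$pair_id[match(tcells, calls$cell_id)],
               unname(truth_pair[tcells]))

  recovery <- vapply(c(0, 0.5, 2), function(rate) {
    cfg <- syntheticConfig(seed = 13, n_cells = 500L,
                           tissue_size = c(2500, 2500),
                           expression = list(v_mean = 5),
                           noise = list(stray_rate = rate, dropout = 0))
    tt <- generateTissue(cfg)
    calls <- callClonotypes(filterMatrix(tt$experiment,
                                         filterParams(5, 3, 0)), cfg@panel)
    truth <- stats::setNames(tt$truth$cells$true_pair, tt$truth$cells$cell_id)
    hit <- calls$pair_id == unname(truth[calls$cell_id])
    sum(hit, na.rm = TRUE) / sum(!is.na(truth[calls$cell_id]))
  }, numeric(1))
  expect_equal(recovery[1], 1)
  expect_true(recovery[3] <= recovery[2] + 1e-9 &&
                recovery[2] <= recovery[1] + 1e-9)
})
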
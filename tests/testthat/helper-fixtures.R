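# shared fixtures and independent oracles (brute force / direct enumeration)

toyPanel <- function() {
  TCRPanel(data.frame(
    group_name = c("TRAV1-1", "TRAV2", "TRAV29/DV5", "TRBV19", "TRBV30",
                   "TRGV2", "TRDV1", "TRAJ9", "TRBJ1-1", "TRAC",
                   "TRBC1/2", "TRBC1/2"),
    member_gene = c("TRAV1-1", "TRAV2", "TRAV29/DV5", "TRBV19", "TRBV30",
                    "TRGV2", "TRDV1", "TRAJ9", "TRBJ1-1", "TRAC",
                    "TRBC1", "TRBC2")))
}

# small cell matrix from a dense gene x cell count table
toyExperiment <- function(counts, x = NULL, y = NULL, labels = NULL) {
  nc <- ncol(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%02d", seq_len(nc))
  if (is.null(x)) x <- seq_len(nc) * 100
  if (is.null(y)) y <- rep(0, nc)
  TCRExperiment(counts,
                data.frame(centroid_x = x, centroid_y = y),
                labels = labels)
}

# independent rule-table oracle for the seven-way ab classification
oracleClassifyAB <- function(a, b) {
  if (a == 0 && b == 1) "orphan_beta"
  else if (a == 1 && b == 0) "orphan_alpha"
  else if (a == 1 && b == 1) "ab_single_pair"
  else if (a == 2 && b == 2) "ab_multi_chain"
  else if (a == 2 && (b == 0 || b == 1)) "extra_alpha"
  else if ((a == 0 || a == 1) && b == 2) "extra_beta"
  else "ab_unknown"
}

# independent recount oracle for the cell->gene single-pass filter
oracleFilter <- function(m, min_counts, min_genes, min_cells) {
  m <- as.matrix(m)
  cell_ok <- colSums(m) >= min_counts & colSums(m > 0) >= min_genes
  m2 <- m[, cell_ok, drop = FALSE]
  gene_ok <- rowSums(m2 > 0) >= min_cells
  m2[gene_ok, , drop = FALSE]
}

# regex + counting oracle for the padlock composition criteria
oracleComposition <- function(seq30, gc_min = 0.40, gc_max = 0.60,
                              max_run = 3L) {
  gc <- nchar(gsub("[AT]", "", seq30)) / nchar(seq30)
  run_bad <- grepl("AAAA|CCCC|GGGG|TTTT", seq30)
  pos16 <- substr(seq30, 16, 16) %in% c("G", "C")
  gc >= gc_min & gc <= gc_max & !run_bad & pos16
}

# exhaustive pairwise gapless-alignment oracle for the cross-reactivity
# screen: candidate pair flagged iff some shift has >= seed_len consecutive
# matches and matches/k >= min_identity
oracleCrossReactive <- function(seqs, genes, min_identity = 0.80,
                                seed_len = 12L) {
  k <- nchar(seqs[1])
  chm <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  flags <- replicate(n, character(), simplify = FALSE)
  max_shift <- floor(k * (1 - min_identity))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (genes[i] == genes[j]) next
    hit <- FALSE
    for (sh in -max_shift:max_shift) {
      i1 <- max(1, 1 - sh):min(k, k - sh)
      eq <- chm[i, i1] == chm[j, i1 + sh]
      if (sum(eq) / k < min_identity) next
      r <- rle(eq)
      if (any(r$values & r$lengths >= seed_len)) { hit <- TRUE; break }
    }
    if (hit) {
      flags[[i]] <- union(flags[[i]], genes[j])
      flags[[j]] <- union(flags[[j]], genes[i])
    }
  }
  flags
}

# nearest-center brute force oracle for hexagon assignment
oracleHexAssign <- function(x, y, params) {
  s <- params$grid_size / sqrt(3)
  if (params$orientation == "flat") {
    qmax <- ceiling(max(abs(x - params$origin[1])) / (1.5 * s)) + 2
    rmax <- ceiling(max(abs(y - params$origin[2])) / (sqrt(3) * s)) + qmax + 2
  } else stop("oracle covers flat orientation")
  grid <- expand.grid(q = -qmax:qmax, r = -rmax:rmax)
  ctr <- hexCenter(grid$q, grid$r, params)
  out <- matrix(NA_integer_, length(x), 2)
  for (i in seq_along(x)) {
    d2 <- (ctr$x - x[i])^2 + (ctr$y - y[i])^2
    j <- which.min(d2)
    out[i, ] <- c(grid$q[j], grid$r[j])
  }
  data.frame(q = out[, 1], r = out[, 2])
}

# O(n^2) brute-force fixed-radius graph oracle
oracleGraphEdges <- function(x, y, radius) {
  n <- length(x)
  out <- list()
  for (i in seq_len(n - 1)) {
    d <- sqrt((x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2)
    hit <- which(d <= radius)
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(from = i, to = i + hit,
                                           dist = d[hit])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(from = integer(), to = integer(), dist = numeric())
}

# direct double-sum evaluation of the Gini coefficient
oracleGini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

cliScript <- function() {
  p <- system.file("cli", "spatial-tcr.R", package = "spatialTCR")
  stopifnot(nzchar(p))
  p
}

runCLI <- function(...) {
  out <- system2("Rscript", c(cliScript(), ...), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  stopifnot(is.null(status) || status == 0)
  invisible(out)
}
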
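#' Configure a synthetic tissue
#'
#' Builds a validated \linkS4class{SimConfig}. The defaults emulate a
#' tumour biopsy: ~1600 cells on a 5000 x 5000 px section (about five cells
#' per 300-px hexagon), cancer cells and T cells clustered in shared tumour
#' nests, stromal and B cells scattered, one dominant planted TCRVb/Va clone
#' at 12.2\% of single-pair T cells seated next to the tumour nests, low
#' per-cell transcript counts, mild segmentation-spillover noise and
#' transcript dropout.
#'
#' @param seed integer seed; fully determines the tissue.
#' @param tissue_size numeric length-2, pixels.
#' @param n_cells number of cells.
#' @param cell_types data.frame (name, proportion, spatial_mode, t_cell);
#'   \code{spatial_mode} one of uniform/blob/ring; blob types share tumour
#'   nest centers; \code{t_cell} marks the types that express TCR pairs
#'   (derived from the name when absent).
#' @param clones data.frame (pair_id, fraction, host_cell_type,
#'   spatial_mode); \code{fraction} is the target share of the host type's
#'   single-pair cells; blob-mode clones occupy host cells nearest the first
#'   tumour nest.
#' @param panel a \linkS4class{TCRPanel}.
#' @param expression Poisson means: \code{v_mean} (V segments; realised as
#'   1 + Poisson(mean - 1) so both chains are present before noise),
#'   \code{j_mean}, \code{c_mean}, \code{phenotype_mean}.
#' @param noise list: \code{stray_rate} (expected misassigned transcripts per
#'   cell, reassigned to a random neighbouring cell), \code{dropout}
#'   (per-transcript loss probability).
#' @param cell_radius sd (px) of transcript placement around the centroid.
#' @param timepoints optional list(retention_prob, new_clone_rate) enabling
#'   \code{\link{generateTimepointPair}}.
#' @return a \linkS4class{SimConfig}.
#' @export
syntheticConfig <- function(seed = 1L,
                            tissue_size = c(5000, 5000),
                            n_cells = 1600L,
                            cell_types = NULL,
                            clones = NULL,
                            panel = defaultPanel(),
                            expression = list(),
                            noise = list(),
                            cell_radius = 15,
                            timepoints = NULL) {
  if (is.null(cell_types))
    cell_types <- data.frame(
      name = c("cancer", "t_cell", "stromal", "b_cell"),
      proportion = c(0.35, 0.30, 0.25, 0.10),
      spatial_mode = c("blob", "blob", "uniform", "uniform"))
  if (is.null(cell_types$t_cell))
    cell_types$t_cell <- grepl("t_cell", cell_types$name)
  if (is.null(clones))
    clones <- data.frame(pair_id = "TRAV29/DV5|TRBV30", fraction = 0.122,
                         host_cell_type = "t_cell", spatial_mode = "blob")
  expr <- utils::modifyList(list(v_mean = 3, j_mean = 1, c_mean = 3,
                                 phenotype_mean = 6), expression)
  nz <- utils::modifyList(list(stray_rate = 0.1, dropout = 0.05), noise)
  methods::new("SimConfig", seed = as.integer(seed),
               tissue_size = as.numeric(tissue_size),
               n_cells = as.integer(n_cells), cell_types = cell_types,
               clones = clones, panel = panel, expression = expr, noise = nz,
               cell_radius = as.numeric(cell_radius),
               timepoints = if (is.null(timepoints)) list() else timepoints)
}

.samplePositions <- function(mode, n, size, centers) {
  if (n == 0L) return(cbind(x = numeric(), y = numeric()))
  if (mode == "uniform") {
    cbind(x = stats::runif(n, 0, size[1]), y = stats::runif(n, 0, size[2]))
  } else if (mode == "blob") {
    ci <- sample(nrow(centers), n, replace = TRUE)
    sd <- min(size) / 10
    cbind(x = pmin(pmax(centers[ci, 1] + stats::rnorm(n, 0, sd), 0), size[1]),
          y = pmin(pmax(centers[ci, 2] + stats::rnorm(n, 0, sd), 0), size[2]))
  } else if (mode == "ring") {
    th <- stats::runif(n, 0, 2 * pi)
    rr <- stats::runif(n, 0.30, 0.45) * min(size)
    cbind(x = size[1] / 2 + rr * cos(th), y = size[2] / 2 + rr * sin(th))
  } else stop("unknown spatial_mode: ", mode)
}

#' Generate a synthetic tissue with known clonal ground truth
#'
#' Places cells of the configured types, plants TCRVb/Va clones at their
#' target fractions among the host T cells (remaining T cells draw a random
#' background pair from the panel's TRAV x TRBV groups), draws per-segment
#' transcript counts (V as 1 + Poisson so both chains of a pair are present
#' before noise; J/C and phenotype genes Poisson), scatters transcripts as a
#' Gaussian around each centroid, then applies per-transcript dropout and
#' neighbour-swap stray misassignment. All randomness is driven by the
#' config seed.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with \code{transcripts} (data.frame: x, y, gene, cell_id,
#'   quality), \code{experiment} (a \linkS4class{TCRExperiment} built from
#'   the transcripts, labelled with true cell types), and \code{truth}
#'   (cells with true type/pair, clone table with realised cell numbers,
#'   tumour nest centers, per-transcript true source cell).
#' @export
generateTissue <- function(cfg) {
  methods::validObject(cfg)
  withSeed(cfg@seed, .generateTissueImpl(cfg))
}

.generateTissueImpl <- function(cfg) {
  size <- cfg@tissue_size
  ct <- cfg@cell_types
  n_type <- floor(cfg@n_cells * ct$proportion)
  n_type[1] <- n_type[1] + cfg@n_cells - sum(n_type)
  centers <- cbind(stats::runif(2, 0.25 * size[1], 0.75 * size[1]),
                   stats::runif(2, 0.25 * size[2], 0.75 * size[2]))
  pos <- do.call(rbind, lapply(seq_len(nrow(ct)), function(i)
    .samplePositions(ct$spatial_mode[i], n_type[i], size, centers)))
  type <- rep(ct$name, n_type)
  n <- nrow(pos)
  cell_id <- sprintf("cell_%05d", seq_len(n))

  # plant clones among host T cells; the rest draw background pairs
  true_pair <- rep(NA_character_, n)
  clone_of <- rep(NA_character_, n)
  cl <- cfg@clones
  alpha_pool <- vFamilyGroups(cfg@panel, "TRAV")
  beta_pool <- vFamilyGroups(cfg@panel, "TRBV")
  if (nrow(cl)) {
    comp <- strsplit(cl$pair_id, "|", fixed = TRUE)
    ok <- vapply(comp, `[`, character(1), 1L) %in% alpha_pool &
      vapply(comp, `[`, character(1), 2L) %in% beta_pool
    if (!all(ok))
      stop("clone pair components must be panel TRAV/TRBV group names: ",
           paste(cl$pair_id[!ok], collapse = ", "))
  }
  for (host in unique(ct$name[ct$t_cell])) {
    host_idx <- which(type == host)
    free <- host_idx
    hcl <- cl[cl$host_cell_type == host, , drop = FALSE]
    for (ci in seq_len(nrow(hcl))) {
      n_c <- round(hcl$fraction[ci] * length(host_idx))
      n_c <- min(n_c, length(free))
      take <- if (hcl$spatial_mode[ci] == "blob") {
        d <- sqrt((pos[free, 1] - centers[1, 1])^2 +
                    (pos[free, 2] - centers[1, 2])^2)
        free[order(d)[seq_len(n_c)]]
      } else {
        sample(free, n_c)
      }
      true_pair[take] <- hcl$pair_id[ci]
      clone_of[take] <- hcl$pair_id[ci]
      free <- setdiff(free, take)
    }
    if (length(free)) {
      true_pair[free] <- paste0(sample(alpha_pool, length(free), TRUE), "|",
                                sample(beta_pool, length(free), TRUE))
    }
  }

  # per-cell (gene, count) draws
  ex <- cfg@expression
  gi <- groupInfo(cfg@panel)
  aj_pool <- gi$group_name[gi$chain == "alpha" & gi$segment == "J"]
  bj_pool <- gi$group_name[gi$chain == "beta" & gi$segment == "J"]
  ac <- gi$group_name[gi$chain == "alpha" & gi$segment == "C"]
  bc <- gi$group_name[gi$chain == "beta" & gi$segment == "C"]
  markers <- c(cancer = "EPCAM", t_cell = "CD3E", stromal = "COL1A1",
               b_cell = "MS4A1")
  marker_of <- function(tp) ifelse(tp %in% names(markers), markers[tp],
                                   paste0("MARKER_", toupper(tp)))
  rtpois <- function(m, mu) 1L + stats::rpois(m, max(mu - 1, 0))

  recs <- list(
    data.frame(ci = seq_len(n), gene = unname(marker_of(type)),
               cnt = stats::rpois(n, ex$phenotype_mean)),
    data.frame(ci = seq_len(n), gene = "ACTB", cnt = stats::rpois(n, 3)),
    data.frame(ci = seq_len(n), gene = "B2M", cnt = stats::rpois(n, 3)))
  tcell <- which(!is.na(true_pair))
  if (length(tcell)) {
    parts <- strsplit(true_pair[tcell], "|", fixed = TRUE)
    a_gene <- vapply(parts, `[`, character(1), 1L)
    b_gene <- vapply(parts, `[`, character(1), 2L)
    m <- length(tcell)
    recs <- c(recs, list(
      data.frame(ci = tcell, gene = a_gene, cnt = rtpois(m, ex$v_mean)),
      data.frame(ci = tcell, gene = b_gene, cnt = rtpois(m, ex$v_mean)),
      data.frame(ci = tcell, gene = sample(aj_pool, m, TRUE),
                 cnt = stats::rpois(m, ex$j_mean)),
      data.frame(ci = tcell, gene = sample(bj_pool, m, TRUE),
                 cnt = stats::rpois(m, ex$j_mean)),
      data.frame(ci = tcell, gene = rep(ac[1], m),
                 cnt = stats::rpois(m, ex$c_mean)),
      data.frame(ci = tcell, gene = rep(bc[1], m),
                 cnt = stats::rpois(m, ex$c_mean))))
  }
  recs <- do.call(rbind, recs)
  recs <- recs[recs$cnt > 0, , drop = FALSE]

  tx_cell <- rep(recs$ci, recs$cnt)
  tx_gene <- rep(recs$gene, recs$cnt)
  ntx <- length(tx_cell)
  tx_x <- pos[tx_cell, 1] + stats::rnorm(ntx, 0, cfg@cell_radius)
  tx_y <- pos[tx_cell, 2] + stats::rnorm(ntx, 0, cfg@cell_radius)

  # dropout
  keep <- stats::runif(ntx) >= cfg@noise$dropout
  tx_cell <- tx_cell[keep]; tx_gene <- tx_gene[keep]
  tx_x <- tx_x[keep]; tx_y <- tx_y[keep]
  ntx <- length(tx_cell)

  # stray misassignment: swap cell_id to a random neighbouring cell
  true_cell <- tx_cell
  n_stray <- min(ntx, stats::rpois(1, cfg@noise$stray_rate * n))
  if (n_stray > 0) {
    nb <- buildGraph(data.frame(cell_id = cell_id, x = pos[, 1],
                                y = pos[, 2]),
                     radius = 6 * cfg@cell_radius)
    e <- graphEdges(nb)
    if (nrow(e)) {
      adj <- split(c(e$to, e$from), c(e$from, e$to))
      stray_idx <- sample(ntx, n_stray)
      for (si in stray_idx) {
        nbrs <- adj[[as.character(tx_cell[si])]]
        if (!is.null(nbrs))
          tx_cell[si] <- nbrs[sample.int(length(nbrs), 1L)]
      }
    }
  }

  transcripts <- data.frame(x = tx_x, y = tx_y, gene = tx_gene,
                            cell_id = cell_id[tx_cell], quality = 20)
  tce <- buildCellMatrix(transcripts)
  lab <- stats::setNames(type, cell_id)
  cellLabels(tce) <- unname(lab[colnames(tce)])

  realised <- if (nrow(cl)) {
    data.frame(pair_id = cl$pair_id, host_cell_type = cl$host_cell_type,
               target_fraction = cl$fraction,
               n_cells = vapply(cl$pair_id, function(p)
                 sum(clone_of == p, na.rm = TRUE), integer(1)))
  } else data.frame(pair_id = character(), host_cell_type = character(),
                    target_fraction = numeric(), n_cells = integer())
  truth <- list(
    cells = data.frame(cell_id = cell_id, x = pos[, 1], y = pos[, 2],
                       type = type, true_pair = true_pair),
    clones = realised,
    centers = centers,
    transcript_true_cell = cell_id[true_cell])
  list(transcripts = transcripts, experiment = tce, truth = truth)
}

#' Generate linked baseline / on-treatment tissues
#'
#' Evolves the configured clone set between two time points: each baseline
#' clone is retained with probability \code{retention_prob}; lost clonal
#' mass is redistributed to \code{Poisson(new_clone_rate)} new clones with
#' fresh pair identities. Both tissues are generated with seeds derived from
#' the config seed; the ground-truth abundance-based Jaccard between the
#' planted repertoires is returned alongside.
#'
#' @param cfg a \linkS4class{SimConfig} with \code{timepoints} set
#'   (\code{retention_prob}, \code{new_clone_rate}).
#' @return list(baseline, ontreat, truth) where baseline/ontreat are
#'   \code{\link{generateTissue}} results and truth carries the on-treatment
#'   clone table and \code{true_jabd}.
#' @export
generateTimepointPair <- function(cfg) {
  stopIfNot(length(cfg@timepoints) > 0,
            "cfg@timepoints must set retention_prob and new_clone_rate")
  tp <- cfg@timepoints
  base_cl <- cfg@clones
  evolved <- withSeed(cfg@seed + 190001L, {
    kept <- stats::runif(nrow(base_cl)) < tp$retention_prob
    lost_mass <- sum(base_cl$fraction[!kept])
    n_new <- stats::rpois(1, tp$new_clone_rate)
    new_cl <- NULL
    if (n_new > 0 && lost_mass > 0) {
      a <- sample(vFamilyGroups(cfg@panel, "TRAV"), n_new, TRUE)
      b <- sample(vFamilyGroups(cfg@panel, "TRBV"), n_new, TRUE)
      new_pairs <- setdiff(paste0(a, "|", b), base_cl$pair_id)
      if (length(new_pairs))
        new_cl <- data.frame(pair_id = new_pairs,
                             fraction = lost_mass / length(new_pairs),
                             host_cell_type = base_cl$host_cell_type[1],
                             spatial_mode = "uniform")
    }
    rbind(base_cl[kept, , drop = FALSE], new_cl)
  })
  baseline <- generateTissue(cfg)
  cfg_on <- cfg
  cfg_on@clones <- evolved
  cfg_on@seed <- cfg@seed + 97L
  ontreat <- generateTissue(cfg_on)
  av <- stats::setNames(base_cl$fraction, base_cl$pair_id)
  bv <- if (nrow(evolved)) stats::setNames(evolved$fraction,
                                           evolved$pair_id) else numeric()
  true_jabd <- if (length(bv)) jaccardAbundance(av, bv) else 0
  list(baseline = baseline, ontreat = ontreat,
       truth = list(ontreat_clones = evolved, true_jabd = true_jabd))
}

#' Generate a star-phylogeny gene family
#'
#' Simulates a family of highly similar gene sequences: one random ancestor
#' and per-gene independent point mutations at \code{mutation_rate} per
#' site. Pairwise identity decreases (in expectation) with the rate. Gene
#' names are IMGT-style (\code{TRBV901}, ...) so the family can feed the
#' probe-design pipeline directly.
#'
#' @param n_genes number of family members.
#' @param length sequence length (>= 30).
#' @param mutation_rate per-site mutation probability.
#' @param seed integer seed.
#' @param prefix name prefix (default \code{"TRBV9"}).
#' @return named \code{Biostrings::DNAStringSet}.
#' @export
generateGeneFamily <- function(n_genes, length = 200L, mutation_rate = 0.05,
                               seed = 1L, prefix = "TRBV9") {
  stopIfNot(length >= 30L, "family sequences must be at least 30 nt")
  withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, length, replace = TRUE)
    seqs <- vapply(seq_len(n_genes), function(i) {
      s <- anc
      mut <- stats::runif(length) < mutation_rate
      if (any(mut))
        s[mut] <- vapply(s[mut], function(b)
          sample(setdiff(bases, b), 1L), character(1))
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0(prefix, "0", seq_len(n_genes))
    Biostrings::DNAStringSet(seqs)
  })
}
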
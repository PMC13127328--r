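AB_TYPES <- c("orphan_alpha", "orphan_beta", "ab_single_pair",
              "ab_multi_chain", "extra_alpha", "extra_beta", "ab_unknown")
GD_TYPES <- c("orphan_gamma", "orphan_delta", "gd_single_pair",
              "gd_multi_chain", "extra_gamma", "extra_delta", "gd_unknown")

# the seven-way rule table shared by the alpha/beta and gamma/delta
# classifications; n1 = first chain (alpha or gamma), n2 = second (beta/delta)
.classifyPair <- function(n1, n2, types) {
  stopIfNot(length(n1) == length(n2), "chain counts must have equal length")
  stopIfNot(all(n1 >= 0) && all(n2 >= 0), "chain gene counts must be >= 0")
  out <- rep(types[7L], length(n1))                 # *_unknown
  out[n1 == 1L & n2 == 0L] <- types[1L]             # orphan first chain
  out[n1 == 0L & n2 == 1L] <- types[2L]             # orphan second chain
  out[n1 == 1L & n2 == 1L] <- types[3L]             # single pair
  out[n1 == 2L & n2 == 2L] <- types[4L]             # multi chain
  out[n1 == 2L & n2 <= 1L] <- types[5L]             # extra first chain
  out[n1 <= 1L & n2 == 2L] <- types[6L]             # extra second chain
  factor(out, levels = types)
}

#' Classify a cell's alpha/beta V-gene detection pattern
#'
#' The seven-way rule table at the heart of single-cell TCR clonotype
#' calling. Inputs are the numbers of distinct detected alpha and beta V
#' genes in one cell (presence, not transcript counts):
#' \itemize{
#'   \item \code{orphan_beta}: 0 alpha, 1 beta
#'   \item \code{orphan_alpha}: 1 alpha, 0 beta
#'   \item \code{ab_single_pair}: 1 alpha, 1 beta (a putative clonotype)
#'   \item \code{ab_multi_chain}: 2 alpha, 2 beta
#'   \item \code{extra_alpha}: 2 alpha, 0 or 1 beta
#'   \item \code{extra_beta}: 0 or 1 alpha, 2 beta
#'   \item \code{ab_unknown}: every remaining case
#' }
#' The same table applied to gamma/delta counts yields the gd types.
#'
#' @param n_alpha,n_beta non-negative integer vectors.
#' @return factor with the seven ab levels.
#' @examples
#' classifyAB(1, 1)   # ab_single_pair
#' classifyAB(3, 1)   # ab_unknown
#' @export
classifyAB <- function(n_alpha, n_beta) .classifyPair(n_alpha, n_beta, AB_TYPES)

#' @rdname classifyAB
#' @param n_gamma,n_delta non-negative integer vectors.
#' @export
classifyGD <- function(n_gamma, n_delta) .classifyPair(n_gamma, n_delta, GD_TYPES)

#' Call per-cell TCR clonotype types and V-gene pairs
#'
#' Iterates all cells of a (pre-filtered) cell matrix, counts distinct
#' detected V-gene groups per chain, classifies the alpha/beta and
#' gamma/delta patterns with the seven-way rule table, and for
#' \code{ab_single_pair} (resp. \code{gd_single_pair}) cells records the pair
#' identity \code{"TRAVx|TRBVy"} with the alpha (gamma) gene first. Only V
#' genes enter classification; J and C genes are evidence/QC only. Grouped
#' genes count as one gene. Matrix genes absent from the panel are ignored
#' with a warning (they are typically phenotype genes).
#'
#' @param x a \linkS4class{TCRExperiment}, already filtered with
#'   \code{\link{filterMatrix}}.
#' @param panel a \linkS4class{TCRPanel}.
#' @param dual_policy how dual \code{"TRAVx/DVy"} genes are counted:
#'   \code{"alpha_only"} (default; they contribute to alpha and not delta),
#'   \code{"delta_only"}, or \code{"both"}.
#' @return data.frame with one row per cell: \code{cell_id}, \code{n_alpha},
#'   \code{n_beta}, \code{n_gamma}, \code{n_delta}, \code{ab_type},
#'   \code{gd_type}, \code{pair_id}, \code{gd_pair_id}, and \code{label} when
#'   the experiment carries cell labels.
#' @export
callClonotypes <- function(x, panel,
                           dual_policy = c("alpha_only", "delta_only", "both")) {
  dual_policy <- match.arg(dual_policy)
  m <- SummarizedExperiment::assay(x, "counts")
  map <- geneToGroup(panel)
  known <- rownames(m) %in% names(map)
  if (any(!known)) {
    unk <- rownames(m)[!known]
    tcr_like <- grepl("^TR[ABGD]", unk)
    if (any(tcr_like))
      warning("ignoring gene(s) absent from panel: ",
              paste(utils::head(unk[tcr_like], 5), collapse = ", "))
  }
  gi <- groupInfo(panel)
  vgrp <- gi[gi$segment == "V", , drop = FALSE]
  grp_of_row <- unname(map[rownames(m)])
  v_rows <- which(!is.na(grp_of_row) & grp_of_row %in% vgrp$group_name)

  # per cell, the set of detected V groups, via sparse triplets
  trip <- Matrix::summary(methods::as(m[v_rows, , drop = FALSE],
                                      "TsparseMatrix"))
  trip <- trip[trip$x > 0, , drop = FALSE]
  grp <- grp_of_row[v_rows][trip$i]
  info <- vgrp[match(grp, vgrp$group_name), ]
  counts_alpha <- info$chain == "alpha" & !info$dual_alpha_delta
  counts_delta <- info$chain == "delta"
  if (dual_policy %in% c("alpha_only", "both"))
    counts_alpha <- counts_alpha | info$dual_alpha_delta
  if (dual_policy %in% c("delta_only", "both"))
    counts_delta <- counts_delta | info$dual_alpha_delta

  cells <- colnames(m)
  nc <- length(cells)
  dedup <- !duplicated(paste(trip$j, grp))
  j <- trip$j[dedup]; grp_d <- grp[dedup]
  alpha_d <- counts_alpha[dedup]; delta_d <- counts_delta[dedup]
  beta_d <- info$chain[dedup] == "beta"
  gamma_d <- info$chain[dedup] == "gamma"

  tallies <- function(sel) tabulate(j[sel], nbins = nc)
  n_alpha <- tallies(alpha_d); n_beta <- tallies(beta_d)
  n_gamma <- tallies(gamma_d); n_delta <- tallies(delta_d)

  ab <- classifyAB(n_alpha, n_beta)
  gd <- classifyGD(n_gamma, n_delta)

  pairOf <- function(type, single, first_sel, second_sel) {
    out <- rep(NA_character_, nc)
    idx <- which(type == single)
    if (length(idx)) {
      first <- stats::setNames(rep(NA_character_, nc), NULL)
      second <- first
      f <- j[first_sel]; first[f] <- grp_d[first_sel]
      s <- j[second_sel]; second[s] <- grp_d[second_sel]
      out[idx] <- paste0(first[idx], "|", second[idx])
    }
    out
  }
  # for single-pair cells there is exactly one gene per chain, so the last
  # write per cell is the unique one
  pair_id <- pairOf(ab, "ab_single_pair", alpha_d, beta_d)
  gd_pair_id <- pairOf(gd, "gd_single_pair", gamma_d, delta_d)

  res <- data.frame(cell_id = cells, n_alpha = n_alpha, n_beta = n_beta,
                    n_gamma = n_gamma, n_delta = n_delta,
                    ab_type = ab, gd_type = gd,
                    pair_id = pair_id, gd_pair_id = gd_pair_id)
  lb <- cellLabels(x)
  if (!is.null(lb)) res$label <- unname(lb[cells])
  res
}

#' Pair abundance tables
#'
#' Counts cells per TCRVb/Va pair among \code{ab_single_pair} (or
#' \code{gd_single_pair}) cells, globally or within strata (e.g. T-cell
#' subsets). Fractions are relative to the single-pair cells of the stratum.
#' Rows are ordered by descending cell count, ties broken by pair id
#' (lexicographic).
#'
#' @param calls data.frame from \code{\link{callClonotypes}}.
#' @param strata optional named character vector mapping cell_id to stratum;
#'   when NULL a single \code{"all"} stratum is used, or the calls'
#'   \code{label} column when present and \code{use_labels = TRUE}.
#' @param chain \code{"ab"} (default) or \code{"gd"}.
#' @param use_labels use \code{calls$label} as strata when no \code{strata}
#'   map is given.
#' @return data.frame with \code{stratum}, \code{pair_id}, \code{n_cells},
#'   \code{fraction}.
#' @export
pairAbundances <- function(calls, strata = NULL, chain = c("ab", "gd"),
                           use_labels = FALSE) {
  chain <- match.arg(chain)
  type_col <- if (chain == "ab") "ab_type" else "gd_type"
  pair_col <- if (chain == "ab") "pair_id" else "gd_pair_id"
  single <- paste0(chain, "_single_pair")
  st <- if (!is.null(strata)) unname(strata[calls$cell_id])
  else if (use_labels && "label" %in% names(calls)) calls$label
  else rep("all", nrow(calls))
  keep <- calls[[type_col]] == single & !is.na(st)
  d <- data.frame(stratum = st[keep], pair_id = calls[[pair_col]][keep])
  if (nrow(d) == 0L)
    return(data.frame(stratum = character(), pair_id = character(),
                      n_cells = integer(), fraction = numeric()))
  agg <- stats::aggregate(list(n_cells = rep(1L, nrow(d))),
                          by = d[, c("stratum", "pair_id")], FUN = sum)
  agg <- do.call(rbind, lapply(split(agg, agg$stratum), function(s) {
    s$fraction <- s$n_cells / sum(s$n_cells)
    s[order(-s$n_cells, s$pair_id), ]
  }))
  rownames(agg) <- NULL
  agg[, c("stratum", "pair_id", "n_cells", "fraction")]
}

#' Per-stratum repertoire summary
#'
#' @param abund output of \code{\link{pairAbundances}}.
#' @return data.frame per stratum: \code{n_unique_pairs}, \code{n_cells},
#'   \code{dominant_pair}, \code{dominant_fraction}.
#' @export
pairSummary <- function(abund) {
  if (nrow(abund) == 0L)
    return(data.frame(stratum = character(), n_unique_pairs = integer(),
                      n_cells = integer(), dominant_pair = character(),
                      dominant_fraction = numeric()))
  out <- do.call(rbind, lapply(split(abund, abund$stratum), function(s) {
    s <- s[order(-s$n_cells, s$pair_id), ]
    data.frame(stratum = s$stratum[1], n_unique_pairs = nrow(s),
               n_cells = sum(s$n_cells), dominant_pair = s$pair_id[1],
               dominant_fraction = s$fraction[1])
  }))
  rownames(out) <- NULL
  out
}

#' Persistence of top baseline pairs at a later time point
#'
#' For the \code{k} most abundant pairs of the baseline repertoire, reports
#' whether each is present in the on-treatment repertoire, mirroring
#' longitudinal top-clone tracking.
#'
#' @param baseline,ontreat \code{\link{pairAbundances}} outputs computed on
#'   the same stratum definition (a single stratum each).
#' @param k number of top baseline pairs to track (default 3).
#' @return data.frame \code{pair_id}, \code{rank}, \code{present}; attribute
#'   \code{shortfall} is TRUE when fewer than \code{k} baseline pairs exist.
#' @export
topPairPersistence <- function(baseline, ontreat, k = 3L) {
  b <- baseline[order(-baseline$n_cells, baseline$pair_id), ]
  top <- utils::head(b, k)
  out <- data.frame(pair_id = top$pair_id, rank = seq_len(nrow(top)),
                    present = top$pair_id %in% ontreat$pair_id)
  attr(out, "shortfall") <- nrow(b) < k
  out
}
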
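#' Gini index of an abundance vector
#'
#' Population form of the Gini coefficient,
#' \deqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x),}
#' computed via the sorted-rank identity. 0 means a perfectly even
#' repertoire; values approach 1 when one clone dominates. Bounded above by
#' \eqn{(n-1)/n}. Scale- and permutation-invariant. No small-sample
#' correction is applied unless \code{bias_correction = TRUE} (factor
#' \eqn{n/(n-1)}).
#'
#' @param x non-negative numeric vector with positive sum.
#' @param bias_correction apply the \eqn{n/(n-1)} correction.
#' @return Gini index in \eqn{[0, 1)}.
#' @examples
#' giniIndex(c(1, 1, 1, 1))  # 0
#' giniIndex(c(0, 0, 0, 1))  # 0.75
#' @export
giniIndex <- function(x, bias_correction = FALSE) {
  stopIfNot(is.numeric(x) && length(x) >= 1L, "x must be a numeric vector")
  stopIfNot(all(x >= 0), "abundances must be non-negative")
  stopIfNot(sum(x) > 0, "Gini is undefined for an all-zero vector")
  n <- length(x)
  xs <- sort(x)
  g <- sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(xs))
  if (bias_correction) g <- g * n / (n - 1)
  g
}

#' Per-stratum Gini index with a cell cutoff
#'
#' Computes the Gini index of clonal abundances within each stratum (T-cell
#' subset, cluster, ...). Two abundance definitions are supported:
#' \code{"pair_counts"} (default) uses cells per TCRVb/Va pair among the
#' stratum's \code{ab_single_pair} cells; \code{"gene_counts"} uses total
#' transcript counts per TRV gene group within the stratum (requires
#' \code{x} and \code{panel}). Strata with fewer contributing cells than
#' \code{min_cells} are reported as NA (default cutoff 15 cells). A pooled
#' stratum over all cells is always included.
#'
#' @param calls \code{\link{callClonotypes}} output.
#' @param strata optional named character vector cell_id -> stratum; defaults
#'   to the calls' \code{label} column when present, else one global stratum.
#' @param mode \code{"pair_counts"} or \code{"gene_counts"}.
#' @param min_cells cell cutoff below which Gini is masked.
#' @param x,panel required for \code{mode = "gene_counts"}: the
#'   \linkS4class{TCRExperiment} and its \linkS4class{TCRPanel}.
#' @param pooled_label name of the pooled stratum (default "All T cells").
#' @return data.frame with \code{stratum}, \code{n_cells}, \code{gini}.
#' @export
giniByStratum <- function(calls, strata = NULL,
                          mode = c("pair_counts", "gene_counts"),
                          min_cells = 15L, x = NULL, panel = NULL,
                          pooled_label = "All T cells") {
  mode <- match.arg(mode)
  st <- if (!is.null(strata)) unname(strata[calls$cell_id])
  else if ("label" %in% names(calls)) calls$label
  else rep("all", nrow(calls))
  strat_list <- c(stats::setNames(split(seq_len(nrow(calls)), st),
                                  sort(unique(st))),
                  stats::setNames(list(seq_len(nrow(calls))), pooled_label))
  rows <- lapply(names(strat_list), function(s) {
    idx <- strat_list[[s]]
    if (mode == "pair_counts") {
      sp <- calls$ab_type[idx] == "ab_single_pair"
      n_cells <- sum(sp)
      abund <- if (n_cells) as.numeric(table(calls$pair_id[idx][sp])) else numeric()
    } else {
      stopIfNot(!is.null(x) && !is.null(panel),
                "gene_counts mode requires x and panel")
      m <- SummarizedExperiment::assay(x, "counts")
      cells <- intersect(calls$cell_id[idx], colnames(m))
      n_cells <- length(cells)
      map <- geneToGroup(panel)
      gi <- groupInfo(panel)
      v_groups <- gi$group_name[gi$segment == "V"]
      rows_v <- which(!is.na(map[rownames(m)]) &
                        unname(map[rownames(m)]) %in% v_groups)
      sub <- m[rows_v, cells, drop = FALSE]
      grp <- unname(map[rownames(sub)])
      abund <- as.numeric(tapply(Matrix::rowSums(sub), grp, sum))
      abund <- abund[!is.na(abund)]
    }
    g <- if (n_cells >= min_cells && length(abund) && sum(abund) > 0)
      giniIndex(abund) else NA_real_
    data.frame(stratum = s, n_cells = n_cells, gini = g)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Abundance-based Jaccard similarity
#'
#' Overlap of two repertoires weighting shared clonotypes by abundance. The
#' default is the Ruzicka (min/max) form
#' \deqn{J_{abd} = \sum_p \min(a_p, b_p) / \sum_p \max(a_p, b_p)}
#' over the union of items, which reduces to the binary Jaccard index on
#' presence/absence vectors. \code{method = "chao"} instead uses the Chao
#' abundance-based Jaccard estimator (via \code{vegan}), which corrects for
#' unseen shared species.
#'
#' @param a,b named non-negative numeric vectors (item -> count); names are
#'   matched over their union.
#' @param method \code{"ruzicka"} (default) or \code{"chao"}.
#' @return similarity in \eqn{[0, 1]}.
#' @examples
#' jaccardAbundance(c(p = 2, q = 1), c(p = 1, r = 1))  # 0.25
#' @export
jaccardAbundance <- function(a, b, method = c("ruzicka", "chao")) {
  method <- match.arg(method)
  stopIfNot(all(a >= 0) && all(b >= 0), "abundances must be non-negative")
  stopIfNot(sum(a) > 0 || sum(b) > 0,
            "at least one repertoire must be non-empty")
  items <- union(names(a), names(b))
  av <- stats::setNames(rep(0, length(items)), items)
  bv <- av
  av[names(a)] <- a; bv[names(b)] <- b
  if (method == "ruzicka") {
    sum(pmin(av, bv)) / sum(pmax(av, bv))
  } else {
    d <- vegan::vegdist(rbind(av, bv), method = "chao")
    1 - as.numeric(d)
  }
}

#' Venn-style repertoire overlap summary
#'
#' @param a,b named abundance vectors (baseline, on-treatment).
#' @return one-row data.frame: \code{n_baseline_only}, \code{n_shared},
#'   \code{n_ontreat_only}, \code{jaccard_abd}.
#' @export
vennSummary <- function(a, b) {
  sa <- names(a)[a > 0]; sb <- names(b)[b > 0]
  data.frame(n_baseline_only = length(setdiff(sa, sb)),
             n_shared = length(intersect(sa, sb)),
             n_ontreat_only = length(setdiff(sb, sa)),
             jaccard_abd = jaccardAbundance(a, b))
}

#' Paired two-tailed t-test on Gini indices
#'
#' Compares per-stratum Gini indices between two time points with a paired
#' two-tailed Student t-test. When every difference is zero the result is
#' t = 0, p = 1; when the differences are constant but non-zero (zero
#' variance) the statistic is undefined and the result is flagged degenerate.
#'
#' @param baseline,ontreat equal-length numeric vectors (NA pairs dropped).
#' @return list with \code{t}, \code{p}, \code{n}, \code{degenerate}.
#' @export
pairedGiniTest <- function(baseline, ontreat) {
  stopIfNot(length(baseline) == length(ontreat),
            "paired vectors must have equal length")
  ok <- !is.na(baseline) & !is.na(ontreat)
  b <- baseline[ok]; o <- ontreat[ok]
  n <- length(b)
  stopIfNot(n >= 2L, "need at least two complete pairs")
  d <- b - o
  if (max(abs(d)) < 1e-12)
    return(list(t = 0, p = 1, n = n, degenerate = FALSE))
  tt <- tryCatch(stats::t.test(b, o, paired = TRUE), error = function(e) NULL)
  if (is.null(tt))   # zero variance of non-zero differences
    return(list(t = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  list(t = unname(tt$statistic), p = tt$p.value, n = n, degenerate = FALSE)
}
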
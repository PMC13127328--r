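#' Build a fixed-radius spatial neighbour graph
#'
#' Connects every pair of cells whose centroids lie within \code{radius}
#' pixels of each other (boundary inclusive). The default 125 px corresponds
#' to roughly a two-cell diameter at typical imaging resolution. A uniform
#' grid-bucket index accelerates the search; the result equals the brute
#' force all-pairs graph.
#'
#' @param cells a \linkS4class{TCRExperiment} (centroids used) or a
#'   data.frame with columns \code{cell_id}, \code{x}, \code{y}.
#' @param radius neighbour radius in pixels.
#' @return a \linkS4class{SpatialGraph}.
#' @export
buildGraph <- function(cells, radius = 125) {
  if (methods::is(cells, "TCRExperiment")) cells <- cellCentroids(cells)
  stopIfNot(nrow(cells) >= 1L, "at least one cell is required")
  n <- nrow(cells)
  x <- cells$x; y <- cells$y
  gx <- floor(x / radius); gy <- floor(y / radius)
  dt <- data.table::data.table(i = seq_len(n), gx = gx, gy = gy)
  offs <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  pieces <- vector("list", nrow(offs))
  data.table::setkey(dt, gx, gy)
  for (k in seq_len(nrow(offs))) {
    right <- data.table::copy(dt)
    right[, `:=`(gx = gx - offs[k, 1L], gy = gy - offs[k, 2L])]
    hit <- dt[right, on = c("gx", "gy"), nomatch = NULL,
              allow.cartesian = TRUE]
    a <- hit$i; b <- hit$i.i
    keep <- if (k == 1L) a < b else rep(TRUE, length(a))
    pieces[[k]] <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  }
  pr <- do.call(rbind, pieces)
  if (is.null(pr) || nrow(pr) == 0L) {
    edges <- data.frame(from = integer(), to = integer(), dist = numeric())
  } else {
    d <- sqrt((x[pr[, 1]] - x[pr[, 2]])^2 + (y[pr[, 1]] - y[pr[, 2]])^2)
    keep <- d <= radius
    edges <- data.frame(from = pr[keep, 1], to = pr[keep, 2], dist = d[keep])
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  methods::new("SpatialGraph",
               nodes = data.frame(cell_id = as.character(cells$cell_id),
                                  x = x, y = y),
               edges = edges, radius = radius)
}

#' @rdname SpatialGraph-accessors
#' @param x a \linkS4class{SpatialGraph}.
#' @export
setMethod("graphNodes", "SpatialGraph", function(x) x@nodes)

#' @rdname SpatialGraph-accessors
#' @export
setMethod("graphEdges", "SpatialGraph", function(x) x@edges)

setMethod("show", "SpatialGraph", function(object) {
  cat("SpatialGraph:", nrow(object@nodes), "nodes,", nrow(object@edges),
      "edges (radius", object@radius, "px)\n")
})

#' Permutation-based neighbourhood enrichment
#'
#' Counts, for every unordered pair of categories, the number of graph edges
#' whose endpoints carry those categories, and compares each count with its
#' permutation null: node labels are randomly permuted (graph fixed, label
#' multiset preserved exactly) \code{n_perms} times and
#' \code{z = (observed - mean_perm) / sd_perm}. Positive z means the two
#' categories neighbour each other more often than label-shuffled chance.
#'
#' @param g a \linkS4class{SpatialGraph}.
#' @param labels character/factor vector of categories, either named by
#'   cell_id or aligned with \code{graphNodes(g)}.
#' @param n_perms number of permutations (default 1000).
#' @param seed integer seed; the same seed, graph and labels give a
#'   bit-identical result.
#' @return an \linkS4class{EnrichmentResult}.
#' @export
enrichment <- function(g, labels, n_perms = 1000L, seed = 1L) {
  nodes <- graphNodes(g)
  if (!is.null(names(labels))) labels <- labels[nodes$cell_id]
  stopIfNot(length(labels) == nrow(nodes),
            "labels must cover every node of the graph")
  stopIfNot(!anyNA(labels), "every node must be labelled")
  labels <- as.character(labels)
  cats <- sort(unique(labels))
  stopIfNot(length(cats) >= 2L, "at least two categories are required")
  K <- length(cats)
  lab_i <- match(labels, cats)
  e <- graphEdges(g)
  pairKey <- function(li) {
    a <- li[e$from]; b <- li[e$to]
    (pmin(a, b) - 1L) * K + pmax(a, b)
  }
  tallyKey <- function(li) tabulate(pairKey(li), nbins = K * K)
  obs <- tallyKey(lab_i)
  # the permutation stream acts on nodes in cell-id order, so the result is
  # bit-identical however the input rows were ordered
  canon <- order(nodes$cell_id)
  lab_canon <- lab_i[canon]
  inv <- integer(length(canon)); inv[canon] <- seq_along(canon)
  sum1 <- numeric(K * K); sum2 <- numeric(K * K)
  withSeed(seed, {
    for (p in seq_len(n_perms)) {
      perm <- sample(lab_canon)[inv]
      cnt <- tallyKey(perm)
      sum1 <- sum1 + cnt
      sum2 <- sum2 + cnt * cnt
    }
  })
  mu <- sum1 / n_perms
  va <- (sum2 - n_perms * mu * mu) / (n_perms - 1)
  sd <- sqrt(pmax(va, 0))
  z <- ifelse(sd > 0, (obs - mu) / sd, NA_real_)
  toMat <- function(v) {
    m <- matrix(0, K, K, dimnames = list(cats, cats))
    full <- matrix(v, K, K, byrow = TRUE)  # key = (min-1)*K + max
    for (a in seq_len(K)) for (b in a:K) {
      m[a, b] <- full[a, b]
      m[b, a] <- full[a, b]
    }
    m
  }
  methods::new("EnrichmentResult", labels = cats,
               observed = toMat(obs), z = toMat(z),
               nPerms = as.integer(n_perms), seed = as.integer(seed))
}

#' @rdname EnrichmentResult-accessors
#' @param x an \linkS4class{EnrichmentResult}.
#' @export
setMethod("zMatrix", "EnrichmentResult", function(x) x@z)

#' @rdname EnrichmentResult-accessors
#' @export
setMethod("observedCounts", "EnrichmentResult", function(x) x@observed)

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult:", length(object@labels), "categories,",
      object@nPerms, "permutations (seed", object@seed, ")\n")
  print(round(object@z, 2))
})

#' Neighbourhood enrichment of clonotype pairs versus cell types
#'
#' Relabels \code{ab_single_pair} cells of pairs carried by more than
#' \code{min_cells} cells with their pair identity, keeps the cell-type label
#' for every other cell, and runs \code{\link{enrichment}}. This asks which
#' cell populations each sufficiently abundant TCRVb/Va clone preferentially
#' neighbours (e.g. cancer subtypes). An optional \code{radius} rebuilds the
#' graph, e.g. 312.5 px for a five-cell radius under the convention that
#' 125 px is a two-cell diameter.
#'
#' @param g a \linkS4class{SpatialGraph} over the cells in \code{calls}.
#' @param calls \code{\link{callClonotypes}} output restricted to one stratum.
#' @param cell_labels named character vector cell_id -> cell-type label used
#'   for cells not relabelled by a pair.
#' @param min_cells pairs with more than this many cells are kept (default 5,
#'   strict).
#' @param radius optional radius override; graph is rebuilt when given.
#' @param n_perms,seed passed to \code{\link{enrichment}}.
#' @return an \linkS4class{EnrichmentResult}, or NULL (with a warning) when
#'   no pair exceeds the threshold.
#' @export
pairProximity <- function(g, calls, cell_labels, min_cells = 5L,
                          radius = NULL, n_perms = 1000L, seed = 1L) {
  if (!is.null(radius)) {
    nodes <- graphNodes(g)
    g <- buildGraph(nodes, radius = radius)
  }
  ab <- pairAbundances(calls)
  keep_pairs <- ab$pair_id[ab$n_cells > min_cells]
  if (length(keep_pairs) == 0L) {
    warning("no TCRVb/Va pair carried by more than ", min_cells, " cells")
    return(NULL)
  }
  lab <- cell_labels[graphNodes(g)$cell_id]
  pair_of <- stats::setNames(calls$pair_id, calls$cell_id)
  po <- pair_of[graphNodes(g)$cell_id]
  hit <- !is.na(po) & po %in% keep_pairs
  lab[hit] <- po[hit]
  enrichment(g, stats::setNames(unname(lab), graphNodes(g)$cell_id),
             n_perms = n_perms, seed = seed)
}
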
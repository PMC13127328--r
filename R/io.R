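#' Read a decoded transcript table
#'
#' Reads Xenium-style per-transcript exports from CSV/TSV or parquet and
#' normalises the column dialect: \code{x_location}/\code{y_location} map to
#' \code{x}/\code{y}, \code{feature_name} to \code{gene}, \code{qv} to
#' \code{quality}. Unassigned-cell markers (\code{"-1"}, \code{"UNASSIGNED"},
#' \code{"0"}, empty string) are normalised to \code{NA}.
#'
#' @param path path to a \code{.csv}/\code{.tsv}(\code{.gz}) or
#'   \code{.parquet} file with columns x, y, gene, cell_id and optional
#'   quality (under either dialect).
#' @return data.frame with columns \code{x}, \code{y}, \code{gene},
#'   \code{cell_id}, \code{quality} (NA when absent), in file order.
#' @export
readTranscripts <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("reading parquet requires the 'arrow' package")
    tab <- as.data.frame(arrow::read_parquet(path))
  } else {
    tab <- data.table::fread(path, data.table = FALSE)
  }
  dialect <- c(x_location = "x", y_location = "y", feature_name = "gene",
               qv = "quality")
  hit <- names(tab) %in% names(dialect)
  names(tab)[hit] <- dialect[names(tab)[hit]]
  need <- c("x", "y", "gene", "cell_id")
  if (!all(need %in% names(tab)))
    stop("transcript table is missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "),
         "; found: ", paste(names(tab), collapse = ", "))
  if (!"quality" %in% names(tab)) tab$quality <- NA_real_
  tab$cell_id <- as.character(tab$cell_id)
  tab$cell_id[tab$cell_id %in% c("-1", "UNASSIGNED", "0", "") |
                is.na(tab$cell_id)] <- NA_character_
  stopIfNot(all(is.finite(tab$x)) && all(is.finite(tab$y)),
            "transcript coordinates must be finite")
  stopIfNot(all(nzchar(tab$gene)), "gene names must be non-empty")
  tab[, c("x", "y", "gene", "cell_id", "quality")]
}

#' @rdname readTranscripts
#' @param transcripts transcript data.frame as returned by
#'   \code{readTranscripts}.
#' @param path output path (\code{.csv} or \code{.parquet}).
#' @export
writeTranscripts <- function(transcripts, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("writing parquet requires the 'arrow' package")
    arrow::write_parquet(transcripts, path)
  } else {
    data.table::fwrite(transcripts, path)
  }
  invisible(path)
}

#' Build a cell-by-gene matrix from transcripts
#'
#' Aggregates assigned transcripts into a sparse gene-by-cell count matrix;
#' cell centroids are the mean coordinates of each cell's contributing
#' transcripts. Unassigned transcripts (NA \code{cell_id}) and transcripts
#' below \code{min_quality} are excluded; their counts are recorded in
#' \code{metadata(x)$n_unassigned} and \code{$n_low_quality}. Transcripts
#' with missing quality always pass the quality gate.
#'
#' @param transcripts data.frame as from \code{\link{readTranscripts}}.
#' @param min_quality minimum decoding quality; default 0 (no cutoff).
#' @return a \linkS4class{TCRExperiment}.
#' @export
buildCellMatrix <- function(transcripts, min_quality = 0) {
  tx <- transcripts
  n_unassigned <- sum(is.na(tx$cell_id))
  qual_ok <- is.na(tx$quality) | tx$quality >= min_quality
  n_lowq <- sum(!qual_ok & !is.na(tx$cell_id))
  keep <- !is.na(tx$cell_id) & qual_ok
  tx <- tx[keep, , drop = FALSE]
  if (nrow(tx) == 0L) {
    counts <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                   x = integer(), dims = c(0L, 0L))
    tce <- methods::new("TCRExperiment", SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(centroid_x = numeric(),
                                     centroid_y = numeric())))
    metadata(tce)$n_unassigned <- n_unassigned
    metadata(tce)$n_low_quality <- n_lowq
    return(tce)
  }
  cells <- sort(unique(tx$cell_id))
  genes <- sort(unique(tx$gene))
  ci <- match(tx$cell_id, cells)
  gi <- match(tx$gene, genes)
  counts <- Matrix::sparseMatrix(i = gi, j = ci, x = rep(1L, nrow(tx)),
                                 dims = c(length(genes), length(cells)),
                                 dimnames = list(genes, cells))
  cx <- as.numeric(tapply(tx$x, factor(tx$cell_id, levels = cells), mean))
  cy <- as.numeric(tapply(tx$y, factor(tx$cell_id, levels = cells), mean))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(centroid_x = cx, centroid_y = cy,
                                   row.names = cells))
  tce <- methods::new("TCRExperiment", sce)
  metadata(tce)$n_unassigned <- n_unassigned
  metadata(tce)$n_low_quality <- n_lowq
  tce
}

#' Construct a TCRExperiment directly
#'
#' @param counts gene-by-cell matrix (dense or sparse), with dimnames.
#' @param centroids data.frame/matrix with columns \code{centroid_x},
#'   \code{centroid_y}, one row per cell in column order of \code{counts}.
#' @param labels optional character vector of cell-type labels.
#' @return a \linkS4class{TCRExperiment}.
#' @export
TCRExperiment <- function(counts, centroids, labels = NULL) {
  counts <- if (methods::is(counts, "Matrix")) {
    methods::as(counts, "CsparseMatrix")
  } else {
    methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                "CsparseMatrix")
  }
  cd <- S4Vectors::DataFrame(centroid_x = centroids[, "centroid_x"],
                             centroid_y = centroids[, "centroid_y"],
                             row.names = colnames(counts))
  if (!is.null(labels)) cd$label <- labels
  methods::new("TCRExperiment", SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd))
}

#' Accessors for TCRExperiment
#'
#' @param x a \linkS4class{TCRExperiment}.
#' @param value replacement cell labels (character, one per cell).
#' @return \code{cellCentroids}: data.frame of per-cell centroids;
#'   \code{cellLabels}: character vector of labels or NULL.
#' @name TCRExperiment-accessors
NULL

#' @rdname TCRExperiment-accessors
#' @export
setMethod("cellCentroids", "TCRExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(cell_id = colnames(x), x = cd$centroid_x, y = cd$centroid_y)
})

#' @rdname TCRExperiment-accessors
#' @export
setMethod("cellLabels", "TCRExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("label" %in% names(cd)) stats::setNames(cd$label, colnames(x)) else NULL
})

#' @rdname TCRExperiment-accessors
#' @export
setMethod("cellLabels<-", "TCRExperiment", function(x, value) {
  SummarizedExperiment::colData(x)$label <- value
  methods::validObject(x)
  x
})

setMethod("show", "TCRExperiment", function(object) {
  cat("TCRExperiment:", nrow(object), "genes x", ncol(object), "cells\n")
  lb <- cellLabels(object)
  if (!is.null(lb))
    cat("  labels:", paste(utils::head(sort(unique(lb)), 6), collapse = ", "),
        if (length(unique(lb)) > 6) "...\n" else "\n")
  md <- metadata(object)
  if (!is.null(md$n_unassigned))
    cat("  dropped transcripts: unassigned", md$n_unassigned,
        "| low quality", md$n_low_quality %||% 0L, "\n")
})

#' Cell and gene quality filtering
#'
#' \code{filterParams} bundles the minimum-expression thresholds; the
#' defaults keep cells with at least 5 transcripts over at least 3 genes and
#' genes detected in at least 3 of the passing cells. \code{filterMatrix}
#' applies them in a single pass, cells first, then genes over the surviving
#' cells (no iteration to a fixpoint).
#'
#' @param min_counts_per_cell minimum total transcripts per cell.
#' @param min_genes_per_cell minimum distinct detected genes per cell.
#' @param min_cells_per_gene minimum passing cells a gene is detected in.
#' @return \code{filterParams}: a named list of validated thresholds.
#' @export
filterParams <- function(min_counts_per_cell = 5L, min_genes_per_cell = 3L,
                         min_cells_per_gene = 3L) {
  p <- list(min_counts_per_cell = as.integer(min_counts_per_cell),
            min_genes_per_cell = as.integer(min_genes_per_cell),
            min_cells_per_gene = as.integer(min_cells_per_gene))
  stopIfNot(all(unlist(p) >= 0L), "filter thresholds must be >= 0")
  p
}

#' @rdname filterParams
#' @param x a \linkS4class{TCRExperiment}.
#' @param params thresholds from \code{filterParams()}.
#' @param genes optional character vector restricting which genes count
#'   towards the per-cell totals (e.g. TCR genes only); filtering decisions
#'   for cells are then based on those genes alone.
#' @return \code{filterMatrix}: the filtered \linkS4class{TCRExperiment}.
#' @export
filterMatrix <- function(x, params = filterParams(), genes = NULL) {
  m <- SummarizedExperiment::assay(x, "counts")
  mm <- if (is.null(genes)) m else m[rownames(m) %in% genes, , drop = FALSE]
  cell_ok <- Matrix::colSums(mm) >= params$min_counts_per_cell &
    Matrix::colSums(mm > 0) >= params$min_genes_per_cell
  x2 <- x[, cell_ok]
  m2 <- SummarizedExperiment::assay(x2, "counts")
  gene_ok <- Matrix::rowSums(m2 > 0) >= params$min_cells_per_gene
  x2[gene_ok, ]
}

#' Read / write a cell matrix as MatrixMarket + sidecar TSVs
#'
#' Writes \code{matrix.mtx} (genes x cells), \code{genes.tsv} and
#' \code{cells.tsv} (cell_id, centroid_x, centroid_y and label when present)
#' into a directory; counts round-trip exactly.
#'
#' @param x a \linkS4class{TCRExperiment}.
#' @param dir directory path (created if needed).
#' @export
writeCellMatrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(x, "counts")
  Matrix::writeMM(methods::as(m, "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene = rownames(m)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cd <- cellCentroids(x)
  names(cd) <- c("cell_id", "centroid_x", "centroid_y")
  lb <- cellLabels(x)
  if (!is.null(lb)) cd$label <- unname(lb)
  utils::write.table(cd, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname writeCellMatrix
#' @export
readCellMatrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  genes <- data.table::fread(file.path(dir, "genes.tsv"),
                             data.table = FALSE)$gene
  cells <- data.table::fread(file.path(dir, "cells.tsv"), data.table = FALSE,
                             colClasses = list(character = "cell_id"))
  dimnames(m) <- list(genes, cells$cell_id)
  TCRExperiment(m, cells, labels = cells$label)
}
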
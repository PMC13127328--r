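#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' TCR probe panel definition
#'
#' A \code{TCRPanel} holds the gene content of a targeted TCR probe panel:
#' every panel gene (IMGT-style name), its chain (alpha/beta/gamma/delta) and
#' segment (V/J/C) class, and the grouping of genes that share a probe because
#' no compliant 30-mer can discriminate them. Grouped genes are analysed as a
#' single unit named by \code{group_name} everywhere downstream; counts for a
#' group are never split back to members.
#'
#' @slot groups data.frame with columns \code{group_name}, \code{member_gene},
#'   \code{chain}, \code{segment}, \code{dual_alpha_delta}. Every member gene
#'   appears in exactly one group; all members of a group share chain and
#'   segment; singleton groups are named after their only member.
#' @slot version character scalar, free-form panel version tag.
#' @slot coverage data.frame with columns \code{chain}, \code{segment},
#'   \code{n_targeted}, \code{n_known}: genes targeted by the panel relative
#'   to the number of known genes of that class.
#' @export
setClass("TCRPanel",
  slots = c(groups = "data.frame", version = "character",
            coverage = "data.frame"))

setValidity("TCRPanel", function(object) {
  g <- object@groups
  need <- c("group_name", "member_gene", "chain", "segment", "dual_alpha_delta")
  if (!all(need %in% names(g)))
    return(paste("groups must have columns:", paste(need, collapse = ", ")))
  if (nrow(g) == 0L) return(TRUE)
  if (anyDuplicated(g$member_gene))
    return(paste("gene assigned to more than one group:",
                 paste(unique(g$member_gene[duplicated(g$member_gene)]),
                       collapse = ", ")))
  bad <- vapply(split(g, g$group_name), function(d) {
    length(unique(d$chain)) > 1L || length(unique(d$segment)) > 1L
  }, logical(1))
  if (any(bad))
    return(paste("mixed chain/segment within group:",
                 paste(names(bad)[bad], collapse = ", ")))
  sing <- vapply(split(g$member_gene, g$group_name), length, integer(1)) == 1L
  mism <- vapply(split(g, g$group_name), function(d)
    nrow(d) == 1L && d$group_name != d$member_gene, logical(1))
  if (any(mism))
    return(paste("singleton group not named after its member:",
                 paste(names(mism)[mism], collapse = ", ")))
  TRUE
})

#' Cell-by-gene experiment for spatial TCR analysis
#'
#' Thin extension of \linkS4class{SingleCellExperiment} that guarantees a
#' \code{counts} assay of non-negative values and per-cell spatial centroids
#' (\code{centroid_x}, \code{centroid_y}, in pixels) in \code{colData}. An
#' optional \code{label} column carries cell-type annotations. Genes are rows,
#' cells are columns, following Bioconductor convention.
#'
#' @export
setClass("TCRExperiment", contains = "SingleCellExperiment")

setValidity("TCRExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("a 'counts' assay is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("centroid_x", "centroid_y") %in% names(cd)))
    return("colData must contain centroid_x and centroid_y")
  if (ncol(object) > 0L) {
    m <- SummarizedExperiment::assay(object, "counts")
    if (min(m) < 0) return("counts must be non-negative")
  }
  if (anyDuplicated(colnames(object))) return("cell ids must be unique")
  TRUE
})

#' Probe design report
#'
#' Result of \code{\link{designPanel}}: per-gene survivor counts along the
#' filter chain (enumeration, cross-reactivity screen, composition filter,
#' transcriptome screen), the selected probe targets, the inferred gene
#' groups, and the genes for which no compliant target exists.
#'
#' @slot perGene data.frame of per-gene candidate counts along the chain.
#' @slot targets data.frame of selected 30-mer targets.
#' @slot groups data.frame (group_name, member_gene) of inferred gene groups.
#' @slot untargetable character vector of genes with no surviving candidate.
#' @slot params list of design parameters used.
#' @export
setClass("DesignReport",
  slots = c(perGene = "data.frame", targets = "data.frame",
            groups = "data.frame", untargetable = "character",
            params = "list"))

setValidity("DesignReport", function(object) {
  pg <- object@perGene
  if (nrow(pg)) {
    ok <- with(pg, n_candidates >= n_after_uniqueness &
                 n_after_uniqueness >= n_after_composition &
                 n_after_composition >= n_after_transcriptome)
    if (!all(ok)) return("filter-chain counts must be non-increasing")
  }
  TRUE
})

#' Fixed-radius spatial neighbour graph
#'
#' Undirected graph over cell centroids with an edge between every pair of
#' cells at Euclidean distance less than or equal to \code{radius} (boundary
#' inclusive). Edges store node indices \code{from < to} and the distance.
#'
#' @slot nodes data.frame with columns \code{cell_id}, \code{x}, \code{y}.
#' @slot edges data.frame with columns \code{from}, \code{to} (integer row
#'   indices into \code{nodes}) and \code{dist}.
#' @slot radius numeric scalar, pixels.
#' @export
setClass("SpatialGraph",
  slots = c(nodes = "data.frame", edges = "data.frame", radius = "numeric"))

setValidity("SpatialGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$from >= e$to)) return("edges must satisfy from < to (no self-edges)")
    if (any(e$dist > object@radius + 1e-9)) return("edge beyond radius")
  }
  TRUE
})

#' Neighbourhood enrichment result
#'
#' Observed label-pair edge counts on a spatial graph, together with
#' permutation z-scores: \code{z[a,b] = (observed - mean_perm) / sd_perm}
#' under random relabelling of nodes (graph fixed, label multiset preserved).
#' Entries with zero permutation spread are \code{NA}.
#'
#' @slot labels character vector of category names.
#' @slot observed symmetric integer matrix of observed edge counts.
#' @slot z symmetric numeric matrix of permutation z-scores.
#' @slot nPerms integer, number of permutations.
#' @slot seed integer seed used for the permutation stream.
#' @export
setClass("EnrichmentResult",
  slots = c(labels = "character", observed = "matrix", z = "matrix",
            nPerms = "integer", seed = "integer"))

setValidity("EnrichmentResult", function(object) {
  if (!isTRUE(all.equal(object@observed, t(object@observed))))
    return("observed matrix must be symmetric")
  TRUE
})

#' Synthetic tissue configuration
#'
#' Seeded configuration for \code{\link{generateTissue}}. The defaults emulate
#' a tumour biopsy profiled with a targeted in situ TCR panel: spatially
#' clustered cancer cells, T cells enriched around the tumour nests, one
#' dominant planted TCRVb/Va clone, low per-cell transcript counts, and
#' segmentation-spillover stray transcripts.
#'
#' @slot seed integer; fully determines the generated tissue.
#' @slot tissue_size numeric length-2, tissue extent in pixels.
#' @slot n_cells integer, number of cells.
#' @slot cell_types data.frame (name, proportion, spatial_mode).
#' @slot clones data.frame (pair_id, fraction, host_cell_type, spatial_mode).
#' @slot panel TCRPanel used for gene identities.
#' @slot expression named list of Poisson means (v_mean, j_mean, c_mean,
#'   phenotype_mean).
#' @slot noise named list (stray_rate, dropout).
#' @slot cell_radius numeric, Gaussian sd (pixels) of transcript placement.
#' @slot timepoints list or empty list; when set, fields retention_prob and
#'   new_clone_rate drive \code{\link{generateTimepointPair}}.
#' @export
setClass("SimConfig",
  slots = c(seed = "integer", tissue_size = "numeric", n_cells = "integer",
            cell_types = "data.frame", clones = "data.frame",
            panel = "TCRPanel", expression = "list", noise = "list",
            cell_radius = "numeric", timepoints = "list"))

setValidity("SimConfig", function(object) {
  ct <- object@cell_types
  if (abs(sum(ct$proportion) - 1) > 1e-6)
    return("cell-type proportions must sum to 1")
  cl <- object@clones
  if (nrow(cl)) {
    if (any(cl$fraction < 0 | cl$fraction > 1))
      return("clone fractions must lie in [0, 1]")
    tot <- tapply(cl$fraction, cl$host_cell_type, sum)
    if (any(tot > 1 + 1e-9))
      return("clone fractions within a host cell type exceed 1")
    if (!all(cl$host_cell_type %in% ct$name))
      return("clone host_cell_type not among cell types")
  }
  if (any(object@tissue_size <= 0)) return("tissue_size must be positive")
  TRUE
})
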
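#' Parse IMGT-style TCR gene names
#'
#' Classifies gene names such as \code{"TRBV20-1"}, \code{"TRAV29/DV5"} or
#' \code{"TRAC"} into chain (alpha/beta/gamma/delta) and segment (V/J/C).
#' Names carrying the \code{"/DV"} infix are dual alpha/delta variable genes;
#' they are classified \code{chain = "alpha"} with \code{dual_alpha_delta =
#' TRUE}, and downstream modules decide how to count them (see
#' \code{\link{callClonotypes}}). Parsing is case-insensitive and idempotent;
#' returned names are uppercased.
#'
#' @param name character vector of gene names.
#' @return data.frame with columns \code{name}, \code{chain}, \code{segment},
#'   \code{dual_alpha_delta}.
#' @examples
#' parseGeneName(c("TRBV20-1", "TRAV29/DV5", "TRAC"))
#' @export
parseGeneName <- function(name) {
  stopIfNot(is.character(name) && length(name) > 0L && all(nzchar(name)),
            "gene names must be non-empty strings")
  nm <- toupper(trimws(name))
  m <- regmatches(nm, regexec("^TR([ABGD])([VJC])", nm))
  ok <- lengths(m) == 3L
  if (!all(ok))
    stop("cannot parse TCR gene name(s): ",
         paste(unique(name[!ok]), collapse = ", "), call. = FALSE)
  chain_code <- vapply(m, `[`, character(1), 2L)
  seg <- vapply(m, `[`, character(1), 3L)
  chain <- c(A = "alpha", B = "beta", G = "gamma", D = "delta")[chain_code]
  data.frame(name = nm, chain = unname(chain), segment = seg,
             dual_alpha_delta = grepl("/DV", nm, fixed = TRUE))
}

#' Construct a TCRPanel
#'
#' @param groups data.frame with columns \code{group_name} and
#'   \code{member_gene}; \code{chain}/\code{segment}/\code{dual_alpha_delta}
#'   are derived from the member names when absent.
#' @param version panel version string.
#' @param known_genes optional character vector of all known genes per class;
#'   used to compute coverage denominators. When \code{NULL}, coverage
#'   denominators equal the targeted counts.
#' @return a \linkS4class{TCRPanel}.
#' @export
TCRPanel <- function(groups, version = "1", known_genes = NULL) {
  groups <- as.data.frame(groups)
  if (nrow(groups)) {
    parsed <- parseGeneName(groups$member_gene)
    groups$member_gene <- parsed$name
    groups$group_name <- toupper(trimws(groups$group_name))
    if (!is.null(groups$chain) &&
        !identical(tolower(groups$chain), parsed$chain))
      stop("declared chain column disagrees with parsed gene names")
    groups$chain <- parsed$chain
    groups$segment <- parsed$segment
    groups$dual_alpha_delta <- parsed$dual_alpha_delta
  } else {
    groups <- data.frame(group_name = character(), member_gene = character(),
                         chain = character(), segment = character(),
                         dual_alpha_delta = logical())
  }
  cov <- .panelCoverage(groups, known_genes)
  methods::new("TCRPanel", groups = groups, version = as.character(version),
               coverage = cov)
}

.panelCoverage <- function(groups, known_genes = NULL) {
  classes <- expand.grid(
    chain = c("alpha", "beta", "gamma", "delta"),
    segment = c("V", "J", "C"), stringsAsFactors = FALSE)
  kn <- if (!is.null(known_genes) && length(known_genes)) {
    parseGeneName(known_genes)
  } else NULL
  cov <- classes
  cov$n_targeted <- mapply(function(ch, sg)
    sum(groups$chain == ch & groups$segment == sg), classes$chain,
    classes$segment)
  cov$n_known <- if (is.null(kn)) cov$n_targeted else
    mapply(function(ch, sg) sum(kn$chain == ch & kn$segment == sg),
           classes$chain, classes$segment)
  cov$n_known <- pmax(cov$n_known, cov$n_targeted)
  cov[cov$n_targeted > 0 | cov$n_known > 0, , drop = FALSE]
}

#' Read / write panel definition tables
#'
#' The on-disk format is a CSV/TSV with header
#' \code{group_name,member_gene[,chain,segment]}; chain and segment are
#' derived by parsing when absent. Each member gene may appear in exactly one
#' group and groups must be homogeneous in chain and segment.
#'
#' @param path file path.
#' @param known_genes optional character vector for coverage denominators.
#' @param version panel version string.
#' @return \code{loadPanel}: a \linkS4class{TCRPanel}.
#' @export
loadPanel <- function(path, known_genes = NULL, version = "1") {
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = "character")
  need <- c("group_name", "member_gene")
  if (!all(need %in% names(tab)))
    stop("panel file must have columns group_name, member_gene; found: ",
         paste(names(tab), collapse = ", "))
  TCRPanel(tab[, intersect(names(tab), c(need, "chain", "segment"))],
           version = version, known_genes = known_genes)
}

#' @rdname loadPanel
#' @param panel a \linkS4class{TCRPanel}.
#' @export
writePanel <- function(panel, path) {
  g <- panelGroups(panel)
  utils::write.csv(g[, c("group_name", "member_gene", "chain", "segment")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default reconstructed TCR panel
#'
#' A best-effort reconstruction of a 98-gene TCR V/J/C probe panel with
#' IMGT-style names and a few grouped genes (for example the two beta
#' constant genes targeted by one shared probe). The exact gene grouping of
#' any published panel depends on the IMGT database snapshot used at design
#' time; this table is synthetic in that sense and shipped at
#' \code{inst/extdata/default_panel_synthetic.csv} purely so that every
#' analysis stage can run out of the box.
#'
#' @return a \linkS4class{TCRPanel}.
#' @export
defaultPanel <- function() {
  loadPanel(system.file("extdata", "default_panel_synthetic.csv",
                        package = "spatialTCR"),
            version = "synthetic-default")
}

#' Accessors for TCRPanel
#'
#' @param x a \linkS4class{TCRPanel}.
#' @return \code{panelGroups}: the group table; \code{panelGenes}: all member
#'   genes; \code{panelCoverage}: coverage table; \code{geneToGroup}: named
#'   character vector mapping member genes and group names to group names.
#' @name TCRPanel-accessors
NULL

#' @rdname TCRPanel-accessors
#' @export
setMethod("panelGroups", "TCRPanel", function(x) x@groups)

#' @rdname TCRPanel-accessors
#' @export
setMethod("panelGenes", "TCRPanel", function(x) x@groups$member_gene)

#' @rdname TCRPanel-accessors
#' @export
setMethod("panelCoverage", "TCRPanel", function(x) x@coverage)

#' @rdname TCRPanel-accessors
#' @export
setMethod("panelVersion", "TCRPanel", function(x) x@version)

#' @rdname TCRPanel-accessors
#' @export
setMethod("geneToGroup", "TCRPanel", function(x) {
  g <- x@groups
  map <- stats::setNames(g$group_name, g$member_gene)
  c(map, stats::setNames(unique(g$group_name), unique(g$group_name)))
})

# group-level metadata: one row per group with chain/segment/dual flag
groupInfo <- function(panel) {
  g <- panelGroups(panel)
  if (!nrow(g))
    return(data.frame(group_name = character(), chain = character(),
                      segment = character(), dual_alpha_delta = logical()))
  agg <- do.call(rbind, lapply(split(g, g$group_name), function(d)
    data.frame(group_name = d$group_name[1], chain = d$chain[1],
               segment = d$segment[1],
               dual_alpha_delta = any(d$dual_alpha_delta))))
  rownames(agg) <- NULL
  agg
}

#' V-gene groups of one family
#'
#' Returns the panel's V-gene group names belonging to one variable-gene
#' family. Dual alpha/delta (\code{"TRAV..../DV.."}) genes belong to the TRAV
#' family and are excluded from TRDV, mirroring the clonotyping default.
#'
#' @param panel a \linkS4class{TCRPanel}.
#' @param family one of \code{"TRAV"}, \code{"TRBV"}, \code{"TRGV"},
#'   \code{"TRDV"}.
#' @return character vector of group names.
#' @export
vFamilyGroups <- function(panel,
                          family = c("TRBV", "TRAV", "TRGV", "TRDV")) {
  family <- match.arg(family)
  gi <- groupInfo(panel)
  chain <- c(TRAV = "alpha", TRBV = "beta", TRGV = "gamma",
             TRDV = "delta")[family]
  keep <- gi$segment == "V" & gi$chain == chain
  if (family == "TRDV") keep <- keep & !gi$dual_alpha_delta
  gi$group_name[keep]
}

setMethod("show", "TCRPanel", function(object) {
  g <- object@groups
  cat("TCRPanel (version ", object@version, "): ",
      length(unique(g$group_name)), " groups / ", nrow(g), " genes\n",
      sep = "")
  if (nrow(object@coverage)) {
    cov <- object@coverage
    cat("  coverage:",
        paste0(substr(cov$chain, 1, 1), cov$segment, " ", cov$n_targeted,
               "/", cov$n_known, collapse = ", "), "\n")
  }
})
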
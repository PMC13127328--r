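#' Hexagonal grid parameters
#'
#' \code{grid_size} is the hexagon width measured flat-to-flat, in pixels
#' (default 300, roughly five cells at typical tissue cell density). The
#' default orientation is flat-top; both orientation and origin are
#' parameters. \code{min_counts} is the per-bin V-gene count below which the
#' diversity statistic is masked (default 10), so that sparse bins do not
#' falsely indicate low diversity.
#'
#' @param grid_size hexagon flat-to-flat width, pixels.
#' @param orientation \code{"flat"} or \code{"pointy"}.
#' @param origin length-2 numeric, grid origin in pixels.
#' @param min_counts masking threshold for diversity bins.
#' @return named list of validated parameters.
#' @export
hexGridParams <- function(grid_size = 300, orientation = c("flat", "pointy"),
                          origin = c(0, 0), min_counts = 10L) {
  stopIfNot(grid_size > 0, "grid_size must be positive")
  list(grid_size = grid_size, orientation = match.arg(orientation),
       origin = as.numeric(origin), min_counts = as.integer(min_counts),
       size = grid_size / sqrt(3))   # circumradius implied by flat-to-flat
}

#' Assign points to hexagons (axial coordinates)
#'
#' Standard axial-coordinate assignment with cube rounding for boundary
#' points: each point maps to the hexagon whose center is nearest.
#'
#' @param x,y numeric vectors of pixel coordinates.
#' @param params from \code{\link{hexGridParams}}.
#' @return data.frame with integer columns \code{q}, \code{r}.
#' @export
hexAssign <- function(x, y, params = hexGridParams()) {
  stopIfNot(all(is.finite(x)) && all(is.finite(y)), "coordinates must be finite")
  px <- x - params$origin[1]; py <- y - params$origin[2]
  s <- params$size
  if (params$orientation == "flat") {
    qf <- (2 / 3) * px / s
    rf <- (-px / 3 + sqrt(3) / 3 * py) / s
  } else {
    qf <- (sqrt(3) / 3 * px - py / 3) / s
    rf <- (2 / 3) * py / s
  }
  .cubeRound(qf, rf)
}

.cubeRound <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_y <- !fix_x & dy > dz
  fix_z <- !fix_x & !fix_y
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  ry[fix_y] <- -rx[fix_y] - rz[fix_y]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  data.frame(q = as.integer(rx), r = as.integer(rz))
}

#' Hexagon centers from axial coordinates
#'
#' @param q,r integer axial coordinates.
#' @param params from \code{\link{hexGridParams}}.
#' @return data.frame with \code{x}, \code{y} pixel coordinates.
#' @export
hexCenter <- function(q, r, params = hexGridParams()) {
  s <- params$size
  if (params$orientation == "flat") {
    x <- s * 1.5 * q
    y <- s * (sqrt(3) / 2 * q + sqrt(3) * r)
  } else {
    x <- s * (sqrt(3) * q + sqrt(3) / 2 * r)
    y <- s * 1.5 * r
  }
  data.frame(x = x + params$origin[1], y = y + params$origin[2])
}

#' Hexagon-binned TCR transcript density
#'
#' Bins TCR-panel transcripts into hexagons and reports the total TCR
#' transcript count per occupied hexagon (per-transcript counting; counts are
#' conserved exactly).
#'
#' @param transcripts transcript data.frame (\code{\link{readTranscripts}}).
#' @param panel a \linkS4class{TCRPanel}; transcripts whose gene is a panel
#'   member or group name count as TCR transcripts.
#' @param params from \code{\link{hexGridParams}}.
#' @return data.frame per occupied bin: \code{q}, \code{r}, \code{center_x},
#'   \code{center_y}, \code{total_tcr_counts}.
#' @export
binDensity <- function(transcripts, panel, params = hexGridParams()) {
  tcr <- transcripts$gene %in% names(geneToGroup(panel))
  tx <- transcripts[tcr, , drop = FALSE]
  if (nrow(tx) == 0L)
    return(data.frame(q = integer(), r = integer(), center_x = numeric(),
                      center_y = numeric(), total_tcr_counts = integer()))
  ax <- hexAssign(tx$x, tx$y, params)
  key <- paste(ax$q, ax$r)
  tab <- table(key)
  uq <- ax[!duplicated(key), , drop = FALSE]
  uq <- uq[match(names(tab), paste(uq$q, uq$r)), ]
  ctr <- hexCenter(uq$q, uq$r, params)
  out <- data.frame(q = uq$q, r = uq$r, center_x = ctr$x, center_y = ctr$y,
                    total_tcr_counts = as.integer(tab))
  out[order(out$q, out$r), ]
}

#' Hexagon-binned V-gene diversity (max fraction per bin)
#'
#' For one V-gene family (TRBV, TRAV, TRGV or TRDV; dual TRAV/DV genes belong
#' to the TRAV family), computes per-hexagon per-gene transcript counts and
#' the max-fraction statistic: the share of the most expressed V gene among
#' all family counts in the bin. Bins with fewer than \code{min_counts}
#' family transcripts are retained but masked (NA statistics) so density and
#' diversity maps share geometry. A max fraction of 0.5 or more flags low
#' local diversity.
#'
#' @param transcripts transcript data.frame.
#' @param panel a \linkS4class{TCRPanel}.
#' @param v_family \code{"TRBV"} (default), \code{"TRAV"}, \code{"TRGV"} or
#'   \code{"TRDV"}.
#' @param params from \code{\link{hexGridParams}}.
#' @return data.frame per occupied bin: axial coords, center, \code{total},
#'   \code{max_fraction}, \code{dominant_gene}, \code{low_diversity} (NA when
#'   masked), and a list column \code{per_gene_counts} of named integer
#'   vectors.
#' @export
binDiversity <- function(transcripts, panel,
                         v_family = c("TRBV", "TRAV", "TRGV", "TRDV"),
                         params = hexGridParams()) {
  v_family <- match.arg(v_family)
  fam_groups <- vFamilyGroups(panel, v_family)
  map <- geneToGroup(panel)
  grp <- unname(map[transcripts$gene])
  keep <- !is.na(grp) & grp %in% fam_groups
  tx <- transcripts[keep, , drop = FALSE]
  grp <- grp[keep]
  if (nrow(tx) == 0L)
    return(data.frame(q = integer(), r = integer(), center_x = numeric(),
                      center_y = numeric(), total = integer(),
                      max_fraction = numeric(), dominant_gene = character(),
                      low_diversity = logical()))
  ax <- hexAssign(tx$x, tx$y, params)
  key <- paste(ax$q, ax$r)
  split_grp <- split(grp, key)
  uq <- ax[!duplicated(key), , drop = FALSE]
  uq <- uq[match(names(split_grp), paste(uq$q, uq$r)), ]
  ctr <- hexCenter(uq$q, uq$r, params)
  per_gene <- lapply(split_grp, function(g) {
    t <- table(g)
    stats::setNames(as.integer(t), names(t))
  })
  total <- vapply(per_gene, sum, integer(1))
  masked <- total < params$min_counts
  maxf <- rep(NA_real_, length(total))
  dom <- rep(NA_character_, length(total))
  idx <- which(!masked)
  maxf[idx] <- vapply(per_gene[idx], function(p) max(p) / sum(p), numeric(1))
  dom[idx] <- vapply(per_gene[idx], function(p)
    sort(names(p)[p == max(p)])[1], character(1))
  low <- ifelse(masked, NA, maxf >= 0.5)
  out <- data.frame(q = uq$q, r = uq$r, center_x = ctr$x, center_y = ctr$y,
                    total = unname(total), max_fraction = maxf,
                    dominant_gene = dom, low_diversity = low)
  out$per_gene_counts <- unname(per_gene)
  out[order(out$q, out$r), ]
}
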
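#' Voronoi tessellation areas and Delaunay adjacency of a planar point set
#'
#' Computes the Delaunay triangulation of the (deduplicated) points and, for
#' every point, the area of its Voronoi cell. Points whose Voronoi cell is
#' unbounded (points on or adjacent to the convex hull) get area `Inf`.
#'
#' @param x,y Point coordinates in nm.
#' @return A list with `area` (numeric, per input point) and `edges`
#'   (two-column integer matrix of Delaunay-adjacent input indices).
#' @export
voronoi_tessellation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  key <- paste(x, y)
  rep_idx <- match(key, key)            # representative for exact duplicates
  uniq <- which(rep_idx == seq_along(x))
  if (length(uniq) < 3) stop("need at least 3 distinct points for tessellation")
  info <- delaunay_info_cpp(x[uniq], y[uniq])
  area <- info$area[match(rep_idx, uniq)]
  edges <- matrix(uniq[info$edges], ncol = 2)
  list(area = area, edges = edges)
}

#' Segment localizations into cells by Voronoi density
#'
#' Clusters a localization point cloud into per-cell groups following the
#' standard Voronoi-density segmentation of SMLM data: a point is *dense* if
#' its Voronoi cell area is below `voronoi_density_factor` times the median
#' (finite) cell area; cluster cores are the connected components of the
#' Delaunay adjacency restricted to dense points; components smaller than
#' `min_cluster_size` are discarded. Cores are then expanded to their own
#' fringe (hull and sliver cells, whose Voronoi areas are uninformative):
#' an unassigned point joins a cluster when it is connected to it by a
#' Delaunay edge no longer than `expansion_edge_factor` times the typical
#' dense spacing `sqrt(median area)` (majority vote over such neighbours,
#' lowest cluster id on ties), iterated to a fixpoint. Low-density
#' background sits many typical spacings away from any cluster, is never
#' reached, and stays unassigned.
#'
#' @param records Tibble with columns `x`, `y` (nm).
#' @param voronoi_density_factor Density threshold relative to the median
#'   Voronoi area (default 2).
#' @param min_cluster_size Minimum number of localizations per cell
#'   (default 300).
#' @param expansion_edge_factor Maximum Delaunay edge length used during
#'   cluster expansion, in units of the typical dense point spacing
#'   `sqrt(median Voronoi area)` (default 3).
#' @return The input tibble with integer columns `record` (original row) and
#'   `cell` (1, 2, ... by decreasing size; `NA` for unassigned background).
#' @export
cluster_cells <- function(records, voronoi_density_factor = 2,
                          min_cluster_size = 300, expansion_edge_factor = 3) {
  stopifnot(all(c("x", "y") %in% names(records)))
  records <- tibble::as_tibble(records)
  if (!"record" %in% names(records)) records$record <- seq_len(nrow(records))
  n <- nrow(records)
  records$cell <- NA_integer_
  if (n < 3 || length(unique(paste(records$x, records$y))) < 3) {
    warning("too few distinct points for Voronoi tessellation; no clusters returned")
    return(records)
  }

  vt <- voronoi_tessellation(records$x, records$y)
  med <- median(vt$area[is.finite(vt$area)])
  dense <- is.finite(vt$area) & vt$area < voronoi_density_factor * med

  keep <- dense[vt$edges[, 1]] & dense[vt$edges[, 2]]
  g <- igraph::graph_from_edgelist(vt$edges[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  comp[!dense] <- NA_integer_

  sizes <- table(comp)
  good <- as.integer(names(sizes)[sizes >= min_cluster_size])
  if (length(good) == 0) return(records)

  # deterministic ids: by decreasing core size, ties by smallest record index
  first_rec <- vapply(good, function(k) min(records$record[which(comp == k)]), numeric(1))
  good <- good[order(-as.integer(sizes[as.character(good)]), first_rec)]
  cell <- rep(NA_integer_, n)
  for (i in seq_along(good)) cell[which(comp == good[i])] <- i

  # expand cores over their fringe along short Delaunay edges
  # (synchronous rounds to a fixpoint)
  elen <- sqrt((records$x[vt$edges[, 1]] - records$x[vt$edges[, 2]])^2 +
                 (records$y[vt$edges[, 1]] - records$y[vt$edges[, 2]])^2)
  short <- elen <= expansion_edge_factor * sqrt(med)
  nb_from <- c(vt$edges[short, 1], vt$edges[short, 2])
  nb_to <- c(vt$edges[short, 2], vt$edges[short, 1])
  repeat {
    adj_cell <- cell[nb_to]
    sel <- !is.na(adj_cell) & is.na(cell[nb_from])
    if (!any(sel)) break
    votes <- tapply(adj_cell[sel], nb_from[sel], function(v) {
      tab <- sort(table(v), decreasing = TRUE)
      min(as.integer(names(tab)[tab == tab[1]]))
    })
    cell[as.integer(names(votes))] <- as.integer(votes)
  }
  records$cell <- cell
  records
}

#' Rotate a cell cluster onto its principal axis
#'
#' Rotates a localization cluster so that the first eigenvector of the point
#' cloud covariance matrix (the cell's long axis) lies along the first
#' coordinate. The transform is a proper rotation about the cluster centroid;
#' the axial orientation sign is fixed so that the skewness of the axial
#' coordinate is non-negative. The axial extent is the 0.5th-99.5th
#' percentile range of the axial coordinate, robust to stray background
#' points.
#'
#' @param records Tibble with `x`, `y` (nm) and optionally `frame`,
#'   `intensity`, `record`.
#' @param id Optional cluster label to carry along.
#' @return An object of class `smdm_cell`: `localizations` (tibble in the
#'   rotated frame, `x` = axial), `transform` (list with `center` and 2x2
#'   `rotation`, mapping raw coordinates via `(p - center) %*% rotation`),
#'   `axial_extent` (nm), `id`.
#' @export
rotate_cluster <- function(records, id = NULL) {
  stopifnot(all(c("x", "y") %in% names(records)))
  records <- tibble::as_tibble(records)
  if (!"record" %in% names(records)) records$record <- seq_len(nrow(records))
  if (nrow(records) < 3) stop("need at least 3 points to determine a long axis")
  P <- cbind(records$x, records$y)
  ctr <- colMeans(P)
  S <- stats::cov(P)
  ev <- eigen(S, symmetric = TRUE)
  if (!(ev$values[1] > 0)) stop("degenerate point cloud: coincident points")
  if (ev$values[2] <= ev$values[1] * 1e-12) {
    stop("degenerate point cloud: collinear points, cannot determine a rotation")
  }
  V <- ev$vectors                       # columns: major, minor axis
  if (det(V) < 0) V[, 2] <- -V[, 2]     # proper rotation
  rot <- sweep(P, 2, ctr) %*% V
  sk <- skewness(rot[, 1])
  if (!is.na(sk) && sk < 0) {
    V <- -V                             # 180 degree turn keeps det = +1
    rot <- -rot
  }
  out <- records
  out$x <- rot[, 1]
  out$y <- rot[, 2]
  extent <- unname(quantile(out$x, c(0.005, 0.995), names = FALSE))
  structure(list(localizations = out,
                 transform = list(center = ctr, rotation = V),
                 axial_extent = extent, id = id),
            class = "smdm_cell")
}

skewness <- function(z) {
  s <- sd(z)
  if (!(s > 0)) return(NA_real_)
  mean((z - mean(z))^3) / s^3
}

#' @export
print.smdm_cell <- function(x, ...) {
  cat(sprintf("<smdm_cell%s> %d localizations, axial extent [%.0f, %.0f] nm\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              nrow(x$localizations), x$axial_extent[1], x$axial_extent[2]))
  invisible(x)
}

#' Split a dividing-cell cluster at its axial density minimum
#'
#' Daughter cells that are still joined cluster as one; this operation splits
#' such a cluster perpendicular to the long axis at the minimum of the
#' (kernel-smoothed) axial localization density within the central 50% of the
#' axial extent. If no clear interior minimum exists (axially uniform
#' density) the split is refused.
#'
#' @param cell An [rotate_cluster()] result.
#' @param min_depth The density at the cut must be below `min_depth` times
#'   the smaller of the two flanking density maxima (default 0.9).
#' @return A list with the two daughter `smdm_cell` objects (`cells`, each
#'   re-rotated onto its own axis) and the cut position `cut_nm` (in the
#'   parent's rotated frame).
#' @export
split_dividing_cluster <- function(cell, min_depth = 0.9) {
  stopifnot(inherits(cell, "smdm_cell"))
  ax <- cell$localizations$x
  lo <- cell$axial_extent[1]; hi <- cell$axial_extent[2]
  den <- density(ax, from = lo, to = hi, n = 512)
  L <- hi - lo
  win <- den$x >= lo + 0.25 * L & den$x <= hi - 0.25 * L
  i_min <- which(win)[which.min(den$y[win])]
  cut <- den$x[i_min]
  left_peak <- max(den$y[den$x < cut])
  right_peak <- max(den$y[den$x > cut])
  if (den$y[i_min] > min_depth * min(left_peak, right_peak)) {
    stop("no interior axial density minimum: cluster does not look like a dividing pair")
  }
  lower <- cell$localizations[ax < cut, ]
  upper <- cell$localizations[ax >= cut, ]
  if (nrow(lower) == 0 || nrow(upper) == 0) stop("degenerate split: empty daughter")
  back <- function(tbl) {
    # return to raw coordinates before re-rotating each daughter
    raw <- as.matrix(tbl[, c("x", "y")]) %*% t(cell$transform$rotation)
    tbl$x <- raw[, 1] + cell$transform$center[1]
    tbl$y <- raw[, 2] + cell$transform$center[2]
    tbl
  }
  list(cells = list(rotate_cluster(back(lower), id = paste0(cell$id, "a")),
                    rotate_cluster(back(upper), id = paste0(cell$id, "b"))),
       cut_nm = cut)
}

#' Render localizations as a 2D histogram image
#'
#' The standard super-resolution rendering: a count of localizations per
#' square pixel, with half-open pixel intervals
#' `[origin + k * pixel, origin + (k + 1) * pixel)`.
#'
#' @param records Tibble with `x`, `y` (nm).
#' @param pixel_nm Pixel side length in nm.
#' @param origin Lower corner `c(x0, y0)`; default snaps the data minimum to
#'   the pixel grid.
#' @return An integer matrix (rows index x bins) with attributes `origin` and
#'   `pixel_nm`; its sum equals `nrow(records)`.
#' @export
render_localization_histogram <- function(records, pixel_nm, origin = NULL) {
  stopifnot(pixel_nm > 0)
  x <- records$x; y <- records$y
  if (length(x) == 0) {
    out <- matrix(0L, 0, 0)
    attr(out, "origin") <- c(0, 0); attr(out, "pixel_nm") <- pixel_nm
    return(out)
  }
  if (is.null(origin)) {
    origin <- c(floor(min(x) / pixel_nm), floor(min(y) / pixel_nm)) * pixel_nm
  }
  ix <- floor((x - origin[1]) / pixel_nm) + 1
  iy <- floor((y - origin[2]) / pixel_nm) + 1
  stopifnot(all(ix >= 1), all(iy >= 1))
  nx <- max(ix); ny <- max(iy)
  counts <- tabulate((iy - 1L) * nx + ix, nbins = nx * ny)
  out <- matrix(as.integer(counts), nx, ny)
  attr(out, "origin") <- origin
  attr(out, "pixel_nm") <- pixel_nm
  out
}
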
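#' Spherocylindrical cell geometry
#'
#' Describes a rod-shaped bacterium as a two-dimensional spherocylinder
#' (a rectangle of length `length_nm - 2 * radius_nm` capped by two
#' semicircles of radius `radius_nm`), the shape assumed for *E. coli* by the
#' synthetic-data generator.
#'
#' @param length_nm Total long-axis length in nm, caps included.
#' @param radius_nm Half-width (cap radius) in nm.
#' @param center Numeric length-2, planar centre in nm.
#' @param orientation_rad Angle of the long axis relative to the x axis.
#' @return An object of class `cell_geometry`.
#' @examples
#' geom <- cell_geometry(3000, 450)
#' in_cell(geom, 0, 0)
#' @export
cell_geometry <- function(length_nm = 3000, radius_nm = 450,
                          center = c(0, 0), orientation_rad = 0) {
  stopifnot(is.numeric(length_nm), is.numeric(radius_nm),
            length(center) == 2, is.numeric(orientation_rad))
  if (!(radius_nm > 0) || !(length_nm > 2 * radius_nm)) {
    stop("invalid cell geometry: need length_nm > 2 * radius_nm > 0")
  }
  structure(
    list(length_nm = length_nm, radius_nm = radius_nm,
         center = as.numeric(center), orientation_rad = orientation_rad),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> length %.0f nm, radius %.0f nm, centre (%.0f, %.0f), angle %.3f rad\n",
              x$length_nm, x$radius_nm, x$center[1], x$center[2], x$orientation_rad))
  invisible(x)
}

# world -> cell frame (long axis along x, centre at origin)
to_cell_frame <- function(geom, x, y) {
  ct <- cos(geom$orientation_rad); st <- sin(geom$orientation_rad)
  dx <- x - geom$center[1]; dy <- y - geom$center[2]
  list(x = ct * dx + st * dy, y = -st * dx + ct * dy)
}

to_world_frame <- function(geom, x, y) {
  ct <- cos(geom$orientation_rad); st <- sin(geom$orientation_rad)
  list(x = geom$center[1] + ct * x - st * y,
       y = geom$center[2] + st * x + ct * y)
}

#' Test whether points lie inside a spherocylindrical cell
#'
#' @param geom A [cell_geometry()].
#' @param x,y Point coordinates in nm (world frame), vectorized.
#' @return Logical vector.
#' @export
in_cell <- function(geom, x, y) {
  p <- to_cell_frame(geom, x, y)
  half <- geom$length_nm / 2 - geom$radius_nm  # cylinder half-length
  ax <- pmin(pmax(p$x, -half), half)           # nearest axis point
  (p$x - ax)^2 + p$y^2 <= geom$radius_nm^2
}

# Uniform sample inside the spherocylinder (rejection from the bounding box),
# returned in world coordinates.
sample_in_cell <- function(geom, n) {
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  hx <- geom$length_nm / 2; hy <- geom$radius_nm
  out_x <- numeric(0); out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- max(16, ceiling((n - length(out_x)) * 1.5))
    cx <- runif(m, -hx, hx); cy <- runif(m, -hy, hy)
    half <- hx - hy
    ax <- pmin(pmax(cx, -half), half)
    keep <- (cx - ax)^2 + cy^2 <= hy^2
    out_x <- c(out_x, cx[keep]); out_y <- c(out_y, cy[keep])
  }
  w <- to_world_frame(geom, out_x[seq_len(n)], out_y[seq_len(n)])
  list(x = w$x, y = w$y)
}

# Specular reflection of points into the spherocylinder wall; coordinates in
# the cell frame. Steps are small relative to the cell width, so a few
# reflection passes always suffice.
reflect_into_cell_frame <- function(geom, x, y, max_iter = 64) {
  half <- geom$length_nm / 2 - geom$radius_nm
  R <- geom$radius_nm
  for (i in seq_len(max_iter)) {
    ax <- pmin(pmax(x, -half), half)
    d2 <- (x - ax)^2 + y^2
    out <- d2 > R^2
    if (!any(out)) return(list(x = x, y = y))
    cyl <- out & (x >= -half & x <= half)
    if (any(cyl)) {
      # flat wall y = +/- R
      y[cyl] <- sign(y[cyl]) * (2 * R - abs(y[cyl]))
    }
    cap <- out & !cyl
    if (any(cap)) {
      ccx <- ifelse(x[cap] > 0, half, -half)   # cap centre
      dx <- x[cap] - ccx; dy <- y[cap]
      d <- sqrt(dx^2 + dy^2)
      scl <- (2 * R - d) / d
      x[cap] <- ccx + dx * scl
      y[cap] <- dy * scl
    }
  }
  # numerically pathological leftovers: project onto the wall
  ax <- pmin(pmax(x, -half), half)
  d2 <- (x - ax)^2 + y^2
  out <- d2 > R^2
  if (any(out)) {
    d <- sqrt(d2[out])
    x[out] <- ax[out] + (x[out] - ax[out]) * R / d
    y[out] <- y[out] * R / d
  }
  list(x = x, y = y)
}

# Axial 20/60/20-style region label from cell-frame axial coordinate.
# Half-open, lower-inclusive intervals; the upper extent edge is included in
# the far pole so no in-cell point is dropped.
region_of_axial <- function(ax, lo, hi, fractions = c(0.2, 0.6, 0.2)) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  L <- hi - lo
  if (!(L > 0)) stop("degenerate axial extent")
  b1 <- lo + fractions[1] * L
  b2 <- lo + (fractions[1] + fractions[2]) * L
  out <- rep(NA_character_, length(ax))
  out[ax >= lo & ax < b1] <- "pole_A"
  out[ax >= b1 & ax < b2] <- "middle"
  out[ax >= b2 & ax <= hi] <- "pole_B"
  out[is.na(out)] <- "none"
  factor(out, levels = c("pole_A", "middle", "pole_B", "none"))
}
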
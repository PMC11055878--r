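#' Bin displacements onto a square spatial grid
#'
#' Assigns each displacement to the square bin containing its *start* point,
#' with half-open, lower-inclusive bin intervals
#' `[origin + k * bin_nm, origin + (k + 1) * bin_nm)`. Binning the start
#' point mirrors the region assignment and the simulator's convention that a
#' step's diffusivity belongs to where it begins.
#'
#' @param displacements Displacement tibble in the rotated cell frame.
#' @param bin_nm Bin side length in nm (50 or 100 in typical maps).
#' @param origin Lower corner `c(x0, y0)` of the grid; default is the lower
#'   axial/lateral corner of the displacement starts snapped to the grid,
#'   which makes grids reproducible across runs on the same cell.
#' @return An object of class `smdm_binned`: `count` matrix (rows index the
#'   axial direction), `bin_of` (per-displacement linear bin index), `r`
#'   (displacement lengths), `origin`, `bin_nm`, `dim`.
#' @export
bin_displacements <- function(displacements, bin_nm, origin = NULL) {
  stopifnot(bin_nm > 0, all(c("start_x", "start_y", "r") %in% names(displacements)))
  x <- displacements$start_x; y <- displacements$start_y
  if (length(x) == 0) stop("no displacements to bin")
  if (is.null(origin)) {
    origin <- c(floor(min(x) / bin_nm), floor(min(y) / bin_nm)) * bin_nm
  }
  ix <- floor((x - origin[1]) / bin_nm) + 1L
  iy <- floor((y - origin[2]) / bin_nm) + 1L
  keep <- ix >= 1L & iy >= 1L
  nx <- max(ix[keep]); ny <- max(iy[keep])
  lin <- ifelse(keep, (iy - 1L) * nx + ix, NA_integer_)
  count <- matrix(as.integer(tabulate(lin[keep], nbins = nx * ny)), nx, ny)
  structure(list(count = count, bin_of = lin, r = displacements$r,
                 origin = origin, bin_nm = bin_nm, dim = c(nx, ny)),
            class = "smdm_binned")
}

#' Fit a diffusion map from binned displacements
#'
#' Runs the truncated background-corrected MLE ([fit_mle()]) independently in
#' every spatial bin whose displacement count lies within
#' `[min_bin, max_bin]` (defaults 10 and 20000); all other bins, and bins
#' whose fit does not converge, are left undefined (`NA`).
#'
#' @param binned An [bin_displacements()] result.
#' @param dt_s,r_max_nm Model parameters passed to [fit_mle()].
#' @param min_bin,max_bin Inclusive per-bin displacement-count bounds.
#' @return An object of class `smdm_map`: `d_grid` and `b_grid` (numeric
#'   matrices, `NA` where undefined), `count_grid`, `defined` (logical
#'   matrix), `origin`, `bin_nm`.
#' @export
fit_map <- function(binned, dt_s, r_max_nm, min_bin = 10, max_bin = 20000) {
  stopifnot(inherits(binned, "smdm_binned"))
  nx <- binned$dim[1]; ny <- binned$dim[2]
  d_grid <- b_grid <- matrix(NA_real_, nx, ny)
  defined <- matrix(FALSE, nx, ny)
  groups <- split(seq_along(binned$bin_of), binned$bin_of)
  for (key in names(groups)) {
    lin <- as.integer(key)
    n <- length(groups[[key]])
    if (n < min_bin || n > max_bin) next
    fit <- fit_mle(binned$r[groups[[key]]], dt_s, r_max_nm, min_n = min_bin)
    if (!fit$converged) next
    d_grid[lin] <- fit$d_l
    b_grid[lin] <- fit$b
    defined[lin] <- TRUE
  }
  structure(list(d_grid = d_grid, b_grid = b_grid,
                 count_grid = binned$count, defined = defined,
                 origin = binned$origin, bin_nm = binned$bin_nm),
            class = "smdm_map")
}

#' @export
print.smdm_map <- function(x, ...) {
  cat(sprintf("<smdm_map> %d x %d bins of %.0f nm, %d defined, D_L range [%.2f, %.2f] um^2/s\n",
              nrow(x$d_grid), ncol(x$d_grid), x$bin_nm, sum(x$defined),
              suppressWarnings(min(x$d_grid, na.rm = TRUE)),
              suppressWarnings(max(x$d_grid, na.rm = TRUE))))
  invisible(x)
}

#' Plot a diffusion or displacement-count map
#'
#' @param x An `smdm_map`.
#' @param what `"d"` for the diffusion map or `"count"` for the
#'   displacement-count map.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.smdm_map <- function(x, what = c("d", "count"), ...) {
  what <- match.arg(what)
  z <- if (what == "d") x$d_grid else x$count_grid
  xs <- x$origin[1] + (seq_len(nrow(z)) - 0.5) * x$bin_nm
  ys <- x$origin[2] + (seq_len(ncol(z)) - 0.5) * x$bin_nm
  graphics::image(xs, ys, z, asp = 1, xlab = "axial position (nm)",
                  ylab = "lateral position (nm)",
                  main = if (what == "d") expression(D[L] ~ (mu * m^2 / s)) else "displacements per bin",
                  ...)
  invisible(x)
}

#' Export map grids as CSV matrices
#'
#' @param map An `smdm_map`.
#' @param prefix Output path prefix; writes `<prefix>_d.csv` and
#'   `<prefix>_count.csv`.
#' @return The written paths, invisibly.
#' @export
write_map <- function(map, prefix) {
  stopifnot(inherits(map, "smdm_map"))
  paths <- c(paste0(prefix, "_d.csv"), paste0(prefix, "_count.csv"))
  utils::write.table(map$d_grid, paths[1], sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(map$count_grid, paths[2], sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
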
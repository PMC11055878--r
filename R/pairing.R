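#' Pair localizations across odd/even frame pairs into displacements
#'
#' For every odd frame `f`, localizations on `f` are matched one-to-one with
#' localizations on the consecutive even frame `f + 1` by greedy globally
#' nearest-neighbour assignment: the closest unmatched (odd, even) pair within
#' `r_max_nm` is taken repeatedly until no candidate remains. Distance ties
#' are broken by the lower odd record index, then the lower even record
#' index, making the matching a deterministic function of the record set.
#' Displacements are only ever formed odd -> even, matching the stroboscopic
#' pulse placement (end of odd frame, start of even frame).
#'
#' @param records Localization tibble with `frame`, `x`, `y` (nm).
#' @param r_max_nm Maximum pairing distance in nm (default 600).
#' @return A tibble of displacements: `frame_pair` (= (odd frame + 1) / 2),
#'   `start_x`, `start_y`, `end_x`, `end_y`, `r` (nm), and the originating
#'   record rows `start_record`, `end_record`.
#' @examples
#' sim <- simulate_displacement_dataset(smdm_config(n_frame_pairs = 100, seed = 1))
#' disp <- pair_displacements(sim$localizations)
#' max(disp$r) <= 600
#' @export
pair_displacements <- function(records, r_max_nm = 600) {
  stopifnot(all(c("frame", "x", "y") %in% names(records)), r_max_nm > 0)
  if (nrow(records) == 0) return(empty_displacements())
  idx <- pair_frames_cpp(as.integer(records$frame), records$x, records$y, r_max_nm)
  if (nrow(idx) == 0) return(empty_displacements())
  s <- idx[, 1]; e <- idx[, 2]
  tibble::tibble(
    frame_pair = as.integer((records$frame[s] + 1L) %/% 2L),
    start_x = records$x[s], start_y = records$y[s],
    end_x = records$x[e], end_y = records$y[e],
    r = sqrt((records$x[e] - records$x[s])^2 + (records$y[e] - records$y[s])^2),
    start_record = s, end_record = e
  )
}

empty_displacements <- function() {
  tibble::tibble(frame_pair = integer(0), start_x = numeric(0),
                 start_y = numeric(0), end_x = numeric(0), end_y = numeric(0),
                 r = numeric(0), start_record = integer(0),
                 end_record = integer(0))
}

#' Assign axial region labels to displacements
#'
#' Labels each displacement `pole_A`, `middle` or `pole_B` from the axial
#' coordinate of its *start* point against a pole/middle/pole partition of
#' the cell's axial extent (default 20%/60%/20% of the rotated cell length).
#' Intervals are half-open and lower-inclusive; the upper extent edge belongs
#' to the far pole. Starts outside the extent are labelled `none`.
#'
#' @param displacements Tibble from [pair_displacements()], in the rotated
#'   cell frame (axial coordinate = `start_x`).
#' @param axial_extent Numeric length-2, the cell's axial extent in nm
#'   (e.g. `cell$axial_extent`).
#' @param fractions Axial fractions (pole, middle, pole), summing to 1.
#' @return The input tibble with a `region` factor column.
#' @export
assign_regions <- function(displacements, axial_extent,
                           fractions = c(0.2, 0.6, 0.2)) {
  stopifnot(length(axial_extent) == 2)
  if (!(axial_extent[2] > axial_extent[1])) stop("degenerate axial extent")
  displacements$region <- region_of_axial(displacements$start_x,
                                          axial_extent[1], axial_extent[2],
                                          fractions)
  displacements
}
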
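#' Configuration for the synthetic SMdM acquisition
#'
#' Bundles every parameter of the simulated stroboscopic acquisition: cell
#' geometry, region-dependent diffusivities, pulse separation, emitter and
#' background rates, and localization error. The defaults emulate an
#' exponentially growing *E. coli* cell imaged with 1.5 ms pulse separation.
#'
#' @param geometry A [cell_geometry()].
#' @param d_field Diffusivities in um^2/s: either a single value or a named
#'   vector with entries `pole_A`, `middle`, `pole_B`. The diffusivity of a
#'   step is taken from the region of its *start* point.
#' @param region_fractions Axial fractions (pole, middle, pole); must sum to 1.
#' @param dt_s Pulse-to-pulse time separation in seconds (default 1.5 ms).
#' @param n_frame_pairs Number of odd/even frame pairs to simulate.
#' @param emitters_per_pair Poisson mean of photoactivated emitters per pair.
#'   Kept low (about one) so that pairing ambiguity is rare but present.
#' @param loc_sigma_nm Localization error SD per axis, nm. Set to 0 for
#'   estimator calibration runs: the fitted model describes true positions and
#'   localization error otherwise inflates the apparent diffusivity by
#'   `sigma^2/dt` (see the methods vignette).
#' @param background_rate Poisson mean of spurious localizations per camera
#'   frame, uniform over `field_extent_nm`.
#' @param field_extent_nm Bounding box `c(xmin, xmax, ymin, ymax)` for
#'   background localizations; default is the cell's bounding box plus a
#'   1 um margin.
#' @param inclusion Optional list describing a circular low-mobility inclusion
#'   (an aggregate): `center` (nm, world frame), `radius_nm`, `d` (um^2/s for
#'   steps starting inside) and `density` (relative emitter density inside,
#'   in (0, 1]).
#' @param seed Integer RNG seed; fixes the generated tables exactly.
#' @return An object of class `smdm_config`.
#' @export
smdm_config <- function(geometry = cell_geometry(),
                        d_field = c(pole_A = 5, middle = 5, pole_B = 5),
                        region_fractions = c(0.2, 0.6, 0.2),
                        dt_s = 0.0015,
                        n_frame_pairs = 5000,
                        emitters_per_pair = 1,
                        loc_sigma_nm = 30,
                        background_rate = 0.2,
                        field_extent_nm = NULL,
                        inclusion = NULL,
                        seed = 1L) {
  if (!inherits(geometry, "cell_geometry")) stop("invalid config: geometry must be a cell_geometry")
  if (length(d_field) == 1 && is.null(names(d_field))) {
    d_field <- c(pole_A = unname(d_field), middle = unname(d_field), pole_B = unname(d_field))
  }
  if (!all(c("pole_A", "middle", "pole_B") %in% names(d_field))) {
    stop("invalid config: d_field needs entries pole_A, middle, pole_B")
  }
  if (any(d_field <= 0)) stop("invalid config: diffusivities must be > 0")
  if (!(dt_s > 0)) stop("invalid config: dt_s must be > 0")
  if (abs(sum(region_fractions) - 1) > 1e-8) stop("invalid config: region_fractions must sum to 1")
  if (!(n_frame_pairs >= 1)) stop("invalid config: n_frame_pairs must be >= 1")
  if (loc_sigma_nm < 0 || background_rate < 0) stop("invalid config: negative noise parameter")
  if (is.null(field_extent_nm)) {
    span <- geometry$length_nm / 2 + 1000
    field_extent_nm <- c(geometry$center[1] - span, geometry$center[1] + span,
                         geometry$center[2] - span, geometry$center[2] + span)
  }
  if (!is.null(inclusion)) {
    stopifnot(length(inclusion$center) == 2, inclusion$radius_nm > 0,
              inclusion$d > 0, inclusion$density > 0, inclusion$density <= 1)
  }
  structure(
    list(geometry = geometry, d_field = d_field,
         region_fractions = region_fractions, dt_s = dt_s,
         n_frame_pairs = as.integer(n_frame_pairs),
         emitters_per_pair = emitters_per_pair,
         loc_sigma_nm = loc_sigma_nm, background_rate = background_rate,
         field_extent_nm = field_extent_nm, inclusion = inclusion,
         seed = as.integer(seed)),
    class = "smdm_config"
  )
}

#' Simulate a stroboscopic SMdM localization dataset
#'
#' Generates the localization table the analysis pipeline consumes, together
#' with its ground truth. For every odd/even frame pair, a Poisson number of
#' emitters is placed uniformly inside the cell; each emitter is localized
#' once on the odd frame and once on the even frame after a 2D Brownian step
#' with per-axis variance `2 * D * dt` (D in nm^2/s from the region of the
#' start point), reflected specularly at the cell wall. Both localizations
#' carry independent Gaussian localization error. Spurious background
#' localizations are placed uniformly over the field on every frame.
#'
#' @param config An [smdm_config()].
#' @return A list of class `smdm_sim` with elements
#'   * `localizations`: tibble with columns `frame`, `x`, `y`, `intensity`,
#'     ordered by frame then emission order (emitters before background),
#'   * `truth`: tibble with one row per emitter (true start/end positions,
#'     region of the start point, `frame_pair`),
#'   * `background`: tibble with one row per spurious localization,
#'   * `config`: the configuration, including the seed.
#' @examples
#' sim <- simulate_displacement_dataset(smdm_config(n_frame_pairs = 50, seed = 7))
#' head(sim$localizations)
#' @export
simulate_displacement_dataset <- function(config) {
  if (!inherits(config, "smdm_config")) stop("config must be an smdm_config")
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  geom <- config$geometry
  npair <- config$n_frame_pairs
  n_emit <- rpois(npair, config$emitters_per_pair)
  total <- sum(n_emit)
  pair_id <- rep(seq_len(npair), n_emit)

  p0 <- sample_in_cell(geom, total)
  # optional low-density inclusion: thin emitters starting inside it
  if (!is.null(config$inclusion)) {
    inc <- config$inclusion
    inside <- (p0$x - inc$center[1])^2 + (p0$y - inc$center[2])^2 <= inc$radius_nm^2
    keep <- !inside | (runif(total) < inc$density)
    p0$x <- p0$x[keep]; p0$y <- p0$y[keep]
    pair_id <- pair_id[keep]
    total <- length(pair_id)
  }

  cf <- to_cell_frame(geom, p0$x, p0$y)
  region <- region_of_axial(cf$x, -geom$length_nm / 2, geom$length_nm / 2,
                            config$region_fractions)
  d_um2s <- unname(config$d_field[as.character(region)])
  if (!is.null(config$inclusion)) {
    inc <- config$inclusion
    inside <- (p0$x - inc$center[1])^2 + (p0$y - inc$center[2])^2 <= inc$radius_nm^2
    d_um2s[inside] <- inc$d
  }
  step_sd <- sqrt(2 * d_um2s * 1e6 * config$dt_s)  # nm per axis

  p1x_cf <- cf$x + rnorm(total, 0, step_sd)
  p1y_cf <- cf$y + rnorm(total, 0, step_sd)
  p1_cf <- reflect_into_cell_frame(geom, p1x_cf, p1y_cf)
  p1 <- to_world_frame(geom, p1_cf$x, p1_cf$y)

  sig <- config$loc_sigma_nm
  obs0x <- p0$x + rnorm(total, 0, sig); obs0y <- p0$y + rnorm(total, 0, sig)
  obs1x <- p1$x + rnorm(total, 0, sig); obs1y <- p1$y + rnorm(total, 0, sig)

  nframe <- 2L * npair
  n_bg <- rpois(nframe, config$background_rate)
  fe <- config$field_extent_nm
  bg_frame <- rep(seq_len(nframe), n_bg)
  bg_x <- runif(sum(n_bg), fe[1], fe[2])
  bg_y <- runif(sum(n_bg), fe[3], fe[4])

  loc <- tibble::tibble(
    frame = c(2L * pair_id - 1L, 2L * pair_id, bg_frame),
    x = c(obs0x, obs1x, bg_x),
    y = c(obs0y, obs1y, bg_y),
    intensity = rlnorm(2L * total + sum(n_bg), meanlog = log(1000), sdlog = 0.4),
    source = c(rep("emitter", 2L * total), rep("background", sum(n_bg)))
  )
  # frame order; emitters precede background within a frame (emission order)
  ord <- order(loc$frame, match(loc$source, c("emitter", "background")))
  loc <- loc[ord, c("frame", "x", "y", "intensity")]

  truth <- tibble::tibble(
    frame_pair = pair_id,
    start_x = p0$x, start_y = p0$y,
    end_x = p1$x, end_y = p1$y,
    region = region,
    d_true = d_um2s,
    background = FALSE
  )
  background <- tibble::tibble(frame = bg_frame, x = bg_x, y = bg_y, background = TRUE)

  structure(list(localizations = loc, truth = truth,
                 background = background, config = config),
            class = "smdm_sim")
}

#' @export
print.smdm_sim <- function(x, ...) {
  cat(sprintf("<smdm_sim> %d localizations (%d emitters, %d background), %d frame pairs, seed %d\n",
              nrow(x$localizations), nrow(x$truth), nrow(x$background),
              x$config$n_frame_pairs, x$config$seed))
  invisible(x)
}

#' Sample displacement lengths from the truncated corrected model
#'
#' Draws displacement lengths directly from the mixture the MLE assumes:
#' with probability `1 - background_fraction` a Rayleigh length with scale
#' `sqrt(2 * D * dt)` truncated at `r_max_nm`, otherwise a spurious-pairing
#' length with density proportional to `r` on `[0, r_max_nm]` (uniform false
#' localizations). This is the reference sampler for estimator calibration;
#' [simulate_displacement_dataset()] produces full spatial tables instead.
#'
#' @param n Number of displacements.
#' @param d_l Diffusivity in um^2/s.
#' @param dt_s Time separation in s.
#' @param r_max_nm Truncation radius in nm (may be `Inf` for no truncation).
#' @param background_fraction Probability mass of the background component.
#' @param seed Optional integer seed.
#' @return Numeric vector of displacement lengths in nm.
#' @export
simulate_displacements <- function(n, d_l, dt_s, r_max_nm = 600,
                                   background_fraction = 0, seed = NULL) {
  stopifnot(n >= 1, d_l > 0, dt_s > 0, r_max_nm > 0,
            background_fraction >= 0, background_fraction < 1)
  draw <- function() {
    s <- 4 * d_l * 1e6 * dt_s
    is_bg <- runif(n) < background_fraction
    u <- runif(n)
    p_trunc <- if (is.finite(r_max_nm)) -expm1(-r_max_nm^2 / s) else 1
    r <- sqrt(-s * log1p(-u * p_trunc))
    if (any(is_bg)) r[is_bg] <- r_max_nm * sqrt(runif(sum(is_bg)))
    r
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a long-axis fluorescence intensity profile
#'
#' Produces a symmetric profile with elevated poles and a central minimum,
#' mimicking the long-axis intensity of a ribosomal fluorescent fusion:
#' a raised cosine between `center_level` (at mid-cell) and `pole_amplitude`
#' (at the extreme poles) plus optional additive Gaussian noise (clamped at 0).
#'
#' @param n_points Number of samples along the normalized axis (>= 8).
#' @param pole_amplitude Intensity at the poles (positions 0 and 1).
#' @param center_level Intensity at mid-cell (position 0.5).
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Optional integer seed.
#' @return A list of class `smdm_profile`: `positions` in `[0, 1]`,
#'   `intensity`, and the ground truth `pole_max` and `center_min`.
#' @examples
#' p <- simulate_intensity_profile(65, 100, 60, 0)
#' ribosome_asymmetry(p)  # 40
#' @export
simulate_intensity_profile <- function(n_points = 65, pole_amplitude = 100,
                                       center_level = 60, noise_sd = 0,
                                       seed = NULL) {
  stopifnot(n_points >= 8, pole_amplitude >= 0, center_level >= 0, noise_sd >= 0)
  draw <- function() {
    pos <- seq(0, 1, length.out = n_points)
    base <- center_level + (pole_amplitude - center_level) * (1 + cos(2 * pi * pos)) / 2
    intensity <- pmax(base + rnorm(n_points, 0, noise_sd), 0)
    structure(list(positions = pos, intensity = intensity,
                   pole_max = pole_amplitude, center_min = center_level),
              class = "smdm_profile")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate an old/new x fast/slow pole contingency table
#'
#' Each simulated cell has one old and one new pole and one slow and one fast
#' pole; with probability `p_concordant` the slow pole is the old pole. The
#' returned 2x2 table (rows old/new, columns slow/fast) is the substrate for
#' [fisher_exact_2x2()].
#'
#' @param n_cells Number of cells.
#' @param p_concordant Probability that the old pole is the slow pole.
#' @param seed Optional integer seed.
#' @return A 2x2 integer matrix with dimnames.
#' @export
simulate_contingency_table <- function(n_cells, p_concordant = 0.8, seed = NULL) {
  stopifnot(n_cells >= 1, p_concordant >= 0, p_concordant <= 1)
  draw <- function() {
    k <- rbinom(1, n_cells, p_concordant)
    matrix(c(k, n_cells - k, n_cells - k, k), nrow = 2, byrow = TRUE,
           dimnames = list(pole = c("old", "new"), speed = c("slow", "fast")))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
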
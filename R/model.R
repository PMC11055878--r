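#' Rayleigh displacement density of a 2D random walk
#'
#' Probability density of the displacement length `r` of an isotropic
#' two-dimensional Brownian walker observed at lag `dt_s`:
#' `p0(r) = (2 r / (4 D dt)) * exp(-r^2 / (4 D dt))`, a Rayleigh distribution
#' with mode `sqrt(2 D dt)` and mean squared displacement `4 D dt`.
#'
#' @param r Displacement length(s) in nm (non-negative).
#' @param d_l Lateral diffusion coefficient in um^2/s.
#' @param dt_s Time separation in s.
#' @param r_unit Unit of `r` (`"nm"` or `"um"`); the density is always
#'   returned per nm.
#' @return Density values (per nm).
#' @export
pdf_p0 <- function(r, d_l, dt_s, r_unit = c("nm", "um")) {
  r_unit <- match.arg(r_unit)
  if (!(d_l > 0)) stop("d_l must be > 0")
  if (!(dt_s > 0)) stop("dt_s must be > 0")
  if (any(r < 0)) stop("displacement lengths must be >= 0")
  if (r_unit == "um") r <- r * 1e3
  s <- 4 * d_l * 1e6 * dt_s             # nm^2
  (2 * r / s) * exp(-r^2 / s)
}

#' Truncated, background-corrected displacement density
#'
#' The displacement model actually fitted to SMdM data: the Rayleigh density
#' plus a linear term `b * r` absorbing spurious pairings with uniformly
#' distributed false localizations, renormalized over the truncated support
#' `[0, r_max_nm]` imposed by the maximum pairing radius:
#' `p(r) = (p0(r) + b r) / (1 - exp(-r_max^2 / (4 D dt)) + (b/2) r_max^2)`.
#'
#' @param r Displacement length(s) in nm, `0 <= r <= r_max_nm`.
#' @param d_l Lateral diffusion coefficient in um^2/s.
#' @param b Background coefficient in nm^-2, `b >= 0`.
#' @param dt_s Time separation in s.
#' @param r_max_nm Truncation radius in nm.
#' @param r_unit Unit of `r` (`"nm"` or `"um"`).
#' @return Density values (per nm); integrates to 1 over `[0, r_max_nm]`.
#' @export
pdf_corrected <- function(r, d_l, b, dt_s, r_max_nm, r_unit = c("nm", "um")) {
  r_unit <- match.arg(r_unit)
  if (!(d_l > 0)) stop("d_l must be > 0")
  if (b < 0) stop("b must be >= 0")
  if (!(dt_s > 0)) stop("dt_s must be > 0")
  if (!(r_max_nm > 0)) stop("r_max_nm must be > 0")
  if (r_unit == "um") r <- r * 1e3
  if (any(r < 0 | r > r_max_nm)) stop("displacement lengths must lie in [0, r_max_nm]")
  s <- 4 * d_l * 1e6 * dt_s
  denom <- -expm1(-r_max_nm^2 / s) + b / 2 * r_max_nm^2
  ((2 * r / s) * exp(-r^2 / s) + b * r) / denom
}

# negative log-likelihood on (log D, log b); r in nm
nll_corrected <- function(par, r, dt_s, r_max_nm) {
  d_nm <- exp(par[1]) * 1e6
  b <- exp(par[2])
  s <- 4 * d_nm * dt_s
  denom <- -expm1(-r_max_nm^2 / s) + b / 2 * r_max_nm^2
  ll <- sum(log((2 * r / s) * exp(-r^2 / s) + b * r)) - length(r) * log(denom)
  if (!is.finite(ll)) return(1e300)
  -ll
}

#' Fit the truncated background-corrected diffusion model by MLE
#'
#' Maximizes the log-likelihood of [pdf_corrected()] over the lateral
#' diffusion coefficient `D_L` and the background coefficient `b`, using
#' bounded quasi-Newton (`L-BFGS-B`) on `(log D_L, log b)`. The start values
#' are deterministic: `D_0 = sum(r^2) / (4 n dt)` (the closed-form Rayleigh
#' MLE) and `b_0 = 1e-8 nm^-2`, so the fit is a pure function of the data.
#' `D_L` is constrained to `[1e-3, 1e2]` um^2/s; an estimate pinned at a
#' `D_L` bound (or at the upper `b` bound) is flagged as not converged and
#' must be excluded downstream.
#'
#' @param r Displacement lengths (nm by default), or a displacement tibble
#'   with an `r` column.
#' @param dt_s Time separation in s.
#' @param r_max_nm Truncation radius in nm; every `r` must be `<= r_max_nm`.
#' @param min_n Minimum number of displacements (default 10); fewer is an
#'   error.
#' @param region Optional region label stored in the result.
#' @param r_unit Unit of `r` (`"nm"` or `"um"`).
#' @return An object of class `smdm_fit`: `d_l` (um^2/s), `b` (nm^-2), `n`,
#'   `loglik`, `converged`, `dt_s`, `r_max_nm`, `region`.
#' @examples
#' r <- simulate_displacements(5000, d_l = 5, dt_s = 0.0015, r_max_nm = 600,
#'                             background_fraction = 0.2, seed = 1)
#' fit_mle(r, dt_s = 0.0015, r_max_nm = 600)
#' @export
fit_mle <- function(r, dt_s, r_max_nm, min_n = 10, region = NA_character_,
                    r_unit = c("nm", "um")) {
  r_unit <- match.arg(r_unit)
  if (is.data.frame(r)) r <- r$r
  r <- as.numeric(r)
  if (r_unit == "um") r <- r * 1e3
  if (length(r) < min_n) {
    stop(sprintf("refusing to fit %d displacements (minimum %d)", length(r), min_n))
  }
  if (!(dt_s > 0) || !(r_max_nm > 0)) stop("dt_s and r_max_nm must be > 0")
  if (any(r < 0)) stop("negative displacement length")
  if (any(r > r_max_nm * (1 + 1e-12))) {
    stop("displacement lengths exceed r_max_nm; pairing and fit truncation disagree")
  }

  d_bounds <- c(1e-3, 1e2)              # um^2/s
  b_bounds <- c(1e-14, 1e-2)            # nm^-2
  d0 <- min(max(sum(r^2) / (4 * length(r) * dt_s) / 1e6, d_bounds[1]), d_bounds[2])
  par0 <- c(log(d0), log(1e-8))
  opt <- optim(par0, nll_corrected, r = r, dt_s = dt_s, r_max_nm = r_max_nm,
               method = "L-BFGS-B",
               lower = log(c(d_bounds[1], b_bounds[1])),
               upper = log(c(d_bounds[2], b_bounds[2])),
               control = list(factr = 1e7, maxit = 500))
  d_hat <- exp(opt$par[1]); b_hat <- exp(opt$par[2])
  at_bound <- d_hat <= d_bounds[1] * (1 + 1e-6) || d_hat >= d_bounds[2] * (1 - 1e-6) ||
    b_hat >= b_bounds[2] * (1 - 1e-6)
  structure(
    list(d_l = d_hat, b = b_hat, n = length(r), loglik = -opt$value,
         converged = opt$convergence == 0 && !at_bound,
         dt_s = dt_s, r_max_nm = r_max_nm, region = region),
    class = "smdm_fit"
  )
}

#' @export
print.smdm_fit <- function(x, ...) {
  cat(sprintf("<smdm_fit%s> D_L = %.3f um^2/s, b = %.3g nm^-2, n = %d, logLik = %.1f%s\n",
              if (is.na(x$region)) "" else paste0(" [", x$region, "]"),
              x$d_l, x$b, x$n, x$loglik,
              if (x$converged) "" else " (NOT CONVERGED)"))
  invisible(x)
}

#' Fit whole-cell and per-region diffusion coefficients for one cell
#'
#' Pairs are assumed already formed and region-labelled (see
#' [assign_regions()]); fits [fit_mle()] to all in-extent displacements
#' (whole cell) and to each axial region with enough displacements.
#'
#' @param displacements Region-labelled displacement tibble.
#' @param dt_s,r_max_nm Model parameters passed to [fit_mle()].
#' @param min_n Per-region minimum displacement count (default 10).
#' @return Named list of `smdm_fit` (`whole`, `pole_A`, `middle`, `pole_B`;
#'   regions with fewer than `min_n` displacements are `NULL`).
#' @export
fit_cell_regions <- function(displacements, dt_s, r_max_nm, min_n = 10) {
  stopifnot("region" %in% names(displacements))
  inext <- displacements[displacements$region != "none", ]
  fits <- list(whole = fit_mle(inext$r, dt_s, r_max_nm, min_n = min_n, region = "whole"))
  for (reg in c("pole_A", "middle", "pole_B")) {
    rr <- inext$r[inext$region == reg]
    fits[[reg]] <- if (length(rr) >= min_n) {
      fit_mle(rr, dt_s, r_max_nm, min_n = min_n, region = reg)
    } else NULL
  }
  fits
}

#' Summarize per-region fits of one cell
#'
#' Computes the pole/middle diffusion ratios and the fast/slow pole
#' classification. The slow pole is the pole with the smaller fitted `D_L`;
#' on an exact tie, labels are assigned in label order (`pole_A` fast) and
#' the tie is flagged. An optional multiplicative `solvent_scale` (a
#' user-supplied solvent-effect correction) is applied uniformly to the
#' reported diffusion coefficients; ratios are unaffected by construction.
#'
#' @param fits Named list with `smdm_fit` entries `pole_A`, `middle`,
#'   `pole_B` and optionally `whole` (see [fit_cell_regions()]).
#' @param solvent_scale Multiplicative correction factor (default 1,
#'   pass-through); recorded in the summary.
#' @param cell_id Optional label.
#' @return An object of class `smdm_cell_summary`: tibble `fits` (region,
#'   `d_l` after scaling, `b`, `n`, `loglik`, `converged`), `ratio_pole_A`,
#'   `ratio_pole_B`, `fast_pole`, `slow_pole`, `tie`, `complete`, `n_total`,
#'   `solvent_scale`, `cell_id`.
#' @export
summarize_cell <- function(fits, solvent_scale = 1, cell_id = NULL) {
  stopifnot(solvent_scale > 0)
  regions <- c("whole", "pole_A", "middle", "pole_B")
  have <- regions[vapply(regions, function(rg)
    !is.null(fits[[rg]]) && inherits(fits[[rg]], "smdm_fit"), logical(1))]
  tab <- tibble::tibble(
    region = have,
    d_l = vapply(have, function(rg) fits[[rg]]$d_l * solvent_scale, numeric(1)),
    b = vapply(have, function(rg) fits[[rg]]$b, numeric(1)),
    n = vapply(have, function(rg) fits[[rg]]$n, numeric(1)),
    loglik = vapply(have, function(rg) fits[[rg]]$loglik, numeric(1)),
    converged = vapply(have, function(rg) fits[[rg]]$converged, logical(1))
  )
  need <- c("pole_A", "middle", "pole_B")
  complete <- all(need %in% have) &&
    all(tab$converged[match(need, tab$region)])
  ratio_A <- ratio_B <- NA_real_
  fast <- slow <- NA_character_
  tie <- FALSE
  if (complete) {
    dA <- fits$pole_A$d_l; dB <- fits$pole_B$d_l; dM <- fits$middle$d_l
    ratio_A <- dA / dM
    ratio_B <- dB / dM
    if (dA == dB) {
      tie <- TRUE; fast <- "pole_A"; slow <- "pole_B"
    } else if (dA > dB) {
      fast <- "pole_A"; slow <- "pole_B"
    } else {
      fast <- "pole_B"; slow <- "pole_A"
    }
  }
  n_total <- if ("whole" %in% have) fits$whole$n else sum(tab$n[tab$region != "whole"])
  structure(
    list(fits = tab, ratio_pole_A = ratio_A, ratio_pole_B = ratio_B,
         fast_pole = fast, slow_pole = slow, tie = tie, complete = complete,
         n_total = n_total, solvent_scale = solvent_scale, cell_id = cell_id),
    class = "smdm_cell_summary"
  )
}

#' @export
print.smdm_cell_summary <- function(x, ...) {
  cat(sprintf("<smdm_cell_summary%s> n = %d displacements%s\n",
              if (is.null(x$cell_id)) "" else paste0(" ", x$cell_id),
              x$n_total, if (x$complete) "" else " (incomplete)"))
  if (x$complete) {
    cat(sprintf("  pole_A/middle = %.3f, pole_B/middle = %.3f, slow pole = %s%s\n",
                x$ratio_pole_A, x$ratio_pole_B, x$slow_pole,
                if (x$tie) " (tie)" else ""))
  }
  print(x$fits)
  invisible(x)
}

#' Quality-control filter on per-cell displacement counts
#'
#' Retains cells whose total displacement count lies in
#' `[min_n, max_n]` (inclusive; defaults 1000 and 20000). Too few
#' displacements bias the fit and inflate the influence of ambiguous
#' pairing; very high counts indicate clumped or overlapping cells.
#'
#' @param summaries List of [summarize_cell()] results.
#' @param min_n,max_n Inclusive bounds on the per-cell displacement count.
#' @return The retained subset of `summaries`.
#' @export
qc_filter_cells <- function(summaries, min_n = 1000, max_n = 20000) {
  keep <- vapply(summaries, function(s) {
    stopifnot(inherits(s, "smdm_cell_summary"))
    s$n_total >= min_n && s$n_total <= max_n
  }, logical(1))
  summaries[keep]
}
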
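---
title: "Measuring intracellular diffusion by single-molecule displacement mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intracellular diffusion by single-molecule displacement mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdmr)
```

## The measurement

Single-molecule displacement mapping (SMdM) measures how fast proteins move
inside single bacterial cells. A photoactivatable fluorescent protein is
localized twice in quick succession: once at the end of an odd camera frame
and once at the start of the following even frame, with a fixed
pulse-to-pulse separation `dt` (1.5 ms by default here). The vector between
the two localizations is one two-point *displacement* of one molecule.
Collecting tens of thousands of displacements per field of view yields, for
any region of a cell, an empirical distribution of displacement lengths
whose shape encodes the local lateral diffusion coefficient `D_L`.

`smdmr` implements the full analysis from a localization table to
per-cell, per-region and per-bin `D_L`:

1. segmentation of the localization point cloud into cells
   (`cluster_cells()`, `split_dividing_cluster()`, `rotate_cluster()`),
2. odd/even frame pairing into displacements (`pair_displacements()`),
3. maximum-likelihood fitting of the displacement model (`fit_mle()`),
4. regional statistics and spatial maps (`assign_regions()`,
   `summarize_cell()`, `fit_map()`),
5. the accompanying statistical toolkit (`compare_groups()`,
   `fisher_exact_2x2()`, `ribosome_asymmetry()`,
   `mass_ratio_regression()`).

Raw-movie peak detection and drift correction are out of scope: the input
is the localization table those upstream tools produce (here read from
delimited text; see `read_localizations()`).

## The displacement model

For an isotropic 2D Brownian walker, the displacement length over lag `dt`
follows a Rayleigh distribution,

$$p_0(r) = \frac{2r}{4 D_L \Delta t}\, e^{-r^2 / (4 D_L \Delta t)},$$

with mode $\sqrt{2 D_L \Delta t}$ and $\mathbb{E}[r^2] = 4 D_L \Delta t$
(`pdf_p0()`). Two corrections make this usable on real data:

* **Uniform background.** Spurious localizations (noise peaks, overlapping
  molecules) are approximately uniform over the field of view; pairing one
  of them produces a displacement whose length density grows linearly in
  `r`. A term `b * r` with a fitted background coefficient `b` (nm^-2)
  absorbs these false pairings.
* **Truncation.** Pairing only searches within `r_max` (600 nm by
  default), so the observable support is `[0, r_max]` and the density must
  be renormalized there.

Together (`pdf_corrected()`):

$$p(r) = \frac{p_0(r) + b\,r}
{1 - e^{-r_\mathrm{max}^2/(4 D_L \Delta t)} + \tfrac{b}{2} r_\mathrm{max}^2}.$$

The denominator is exactly the integral of the numerator over
`[0, r_max]`, so the density is normalized by construction; the test suite
verifies $|\int p - 1| < 10^{-6}$ over 1000 random parameter draws.

**Units.** Displacements are nanometres, `dt` seconds, and `D_L` is
reported in um^2/s (1 um^2/s = 10^6 nm^2/s); `b` is per nm^2. The
conversion lives in one place, and `r_unit = "um"` lets callers hand in
micrometre data without rescaling by hand.

## Maximum-likelihood fitting

`fit_mle()` maximizes $\sum_i \log p(r_i)$ over `(D_L, b)` with bounded
quasi-Newton (`L-BFGS-B`) on the log scale, which enforces positivity
without penalty terms. The numerics are deliberately boring and fully
deterministic:

* start values: `D_0 = sum(r^2) / (4 n dt)` — the closed-form Rayleigh
  MLE — and `b_0 = 1e-8` nm^-2;
* bounds: `D_L` in `[1e-3, 1e2]` um^2/s, `b` in `[1e-14, 1e-2]` nm^-2;
* convergence at `factr = 1e7` (about 1e-9 relative).

A fit pinned at a `D_L` bound or the upper `b` bound is flagged
`converged = FALSE` and is excluded downstream — degenerate input (for
example every displacement at `r_max`) can never produce a silent
estimate. Fits are refused below `min_n = 10` displacements.

Why MLE rather than histogram fitting: with per-bin displacement counts of
10-100 the binned likelihood loses real information, and the truncated
model's normalizing constant couples `D_L` and `b` in a way least squares
on a histogram handles poorly.

The background coefficient is fitted independently per region and per bin:
spurious-localization density varies across the field, so sharing one `b`
per cell would bias sparse regions.

Without the truncation term, censoring at `r_max` biases `D_L` downward —
at `D_L` = 20 um^2/s and `r_max` = 600 nm roughly 5% of displacements are
censored and the naive Rayleigh estimator loses >10% of `D_L`; the
truncated model recovers it to within ~1% (this contrast is an explicit
test).

## Pairing rule

Displacements are formed odd -> consecutive even frame only, mirroring the
pulse placement. Within one frame pair, localizations are matched
one-to-one by *greedy globally nearest neighbour*: repeatedly take the
closest unmatched (odd, even) pair with distance <= `r_max`. Ties are
broken by the lower record index, then the lower even record index, so the
matching is a pure function of the record set. The greedy rule was chosen
over optimal (Hungarian) assignment as the simplest deterministic scheme
that minimizes ambiguity locally; at the emitter densities SMdM operates
at (about one emitter per frame pair per cell) the two rules almost always
coincide. The implementation is validated against an independent
full-matrix greedy oracle on hundreds of random frame pairs.

## Cell segmentation

Cells are recovered from the localization cloud by Voronoi density — the
standard SMLM approach. Because no tessellation backend was available as a
dependency, the package carries its own Delaunay triangulation
(Bowyer-Watson, in C++) and derives Voronoi cell areas from circumcenter
fans; it is validated against a jittered square grid (known cell areas)
and the Poisson-Voronoi area distribution.

The rule set, with every constant exposed as an argument:

* *dense*: Voronoi area < 2x the median finite area
  (`voronoi_density_factor`);
* *cores*: connected components of Delaunay adjacency among dense points,
  discarded below `min_cluster_size = 300`;
* *expansion*: unassigned points join an adjacent cluster along Delaunay
  edges shorter than 3x the typical dense spacing `sqrt(median area)`
  (`expansion_edge_factor`), iterated to a fixpoint.

The expansion step deserves a word. A cell's outermost localizations have
huge or unbounded Voronoi cells — area alone cannot distinguish them from
background — but they sit about one typical spacing from the core, whereas
genuine background sits many spacings away. Gating expansion on edge
length therefore reclaims the cell fringe without ever absorbing uniform
background. Hull cells (unbounded) are never dense and never seed a core.

The density threshold is *relative* (to the median area), which makes
segmentation insensitive to absolute localization counts but also means a
perfectly uniform field of sufficient size would form one giant "cluster";
the `min_cluster_size` floor handles the realistic sparse-background case,
and fields without cells are outside the method's design envelope.

Dividing cells that cluster as one are split by
`split_dividing_cluster()`: the cut is the minimum of the kernel-smoothed
axial density within the central 50% of the extent, refused unless the
valley is at least 10% deep relative to both flanking maxima (so an
axially uniform cluster errors out rather than splitting arbitrarily).

`rotate_cluster()` aligns each cell with the first eigenvector of its
covariance matrix (a proper rotation; axial sign fixed by non-negative
skewness). The axial extent uses the 0.5th-99.5th percentiles rather than
the min/max so that a single stray background point cannot stretch the
20/60/20 partition.

## Regions, QC, and maps

The axial partition is 20% / 60% / 20% of the rotated cell length (pole A,
middle, pole B), assigned from the displacement's **start** point with
half-open lower-inclusive intervals (the upper extent edge belongs to the
far pole so no in-extent point is dropped). Assigning by start point keeps
one convention across regions, map bins, and the simulator's
region-dependent diffusivity.

Per-cell quality control retains cells with 1000-20000 displacements
(inclusive): fewer biases the fit and inflates the influence of background
and ambiguous pairing; more indicates merged or overlapping cells.

Diffusion maps (`bin_displacements()`, `fit_map()`) bin displacement
starts into squares (100 nm default; 50 nm for finer maps), fit each bin
independently, and leave bins undefined outside 10-20000 displacements or
when the fit does not converge. The grid origin snaps to the lower extent
corner so maps are reproducible across runs. Maps are raw binned fits; no
smoothing or interpolation is applied.

Within a cell, the pole with the smaller fitted `D_L` is the *slow* pole
(ties flagged and broken by label order). The optional
"solvent effect" correction is a user-supplied multiplicative factor
recorded in the summary (`solvent_scale`) — it rescales absolute `D_L` and
leaves pole/middle ratios untouched; no formula for it is derived here.
Pole/middle ratios are computed per cell and then averaged across cells
(pooling displacements across cells would weight cells by their counts and
blur cell-to-cell asymmetry); pooled fitting remains available by passing
concatenated displacement sets to `fit_mle()`.

## The statistical battery

* `compare_groups()`: Shapiro-Wilk on both samples at the 1% level; both
  normal -> two-sided Student t-test (equal variances), otherwise
  two-sided Mann-Whitney U. Constant samples, where normality is
  undefined, fall back to Mann-Whitney and are flagged. Stars follow
  ns / * / ** / *** / **** at 0.05 / 0.01 / 0.001 / 0.0001.
* `fisher_exact_2x2()`: exact conditional test; the two-sided p is the
  probability-mass sum of hypergeometric probabilities at most that of the
  observed table. The test suite checks exact agreement with brute-force
  enumeration for every 2x2 table with margins <= 15 and with
  `stats::fisher.test`.
* `ribosome_asymmetry()`: `100 * (Pole_Max - Center_Min) / Pole_Max` on a
  long-axis intensity profile; the pole/centre windows reuse the 20/60/20
  partition so the package has a single regional convention. The metric is
  scale-invariant. Note that max/min statistics acquire a small upward
  bias under additive noise (extreme-value effect); profiles should be
  reasonably averaged before quantification.
* `mass_ratio_regression()`: OLS (optionally 1/SEM^2-weighted) of
  pole/middle ratio on probe molecular weight, with residuals reported as
  observed minus predicted (positive = fit underestimates) and an
  extrapolation helper; fast and slow poles can be fitted separately.

## The synthetic-data generator

Real SMdM raw data is not redistributable at package scale, so validation
runs on two synthetic substrates with known ground truth.

`simulate_displacement_dataset()` emulates the acquisition: a 2D
spherocylindrical cell (default 3 um long, 450 nm half-width — an
exponentially growing *E. coli*), a Poisson number of emitters per frame
pair (mean 1, low enough that pairing ambiguity is rare but present),
uniform emitter placement, Brownian steps with per-axis variance
`2 D dt` using the diffusivity of the *start* region (matching the
analysis convention), specular reflection at the cell wall (which
preserves the uniform stationary density), Gaussian localization error
(default 30 nm per axis), uniform background localizations on every
frame, and an optional circular low-D, low-density inclusion emulating an
aggregate. A single seed fixes the output exactly; ground truth (true
start/end, region, per-step diffusivity) is returned alongside the table.

`simulate_displacements()` samples lengths directly from the truncated
corrected model itself (Rayleigh + linear background mixture). This is the
calibration substrate for the estimator: it isolates `fit_mle()` from
geometry, and the generated background fraction maps exactly onto the
model's `b` term.

Two physical effects make the *spatial* generator deliberately harder than
the fitted model, and both are worth knowing about when interpreting real
data:

* **Confinement.** Reflected steps fold back at the wall, so apparent
  `D_L` is below the true wall-free `D`. Under the defaults
  (`D` = 5 um^2/s, `dt` = 1.5 ms, step SD 122 nm vs 450 nm half-width) the
  suppression is ~8% mid-cell and ~15% in the caps — so even a uniform-`D`
  cell shows an apparent pole/middle ratio of ~0.92. The displacement
  model shares this blindness with its published uses; the package
  quantifies it in a dedicated test rather than correcting it. Measured
  pole/middle ratios are therefore *apparent* ratios; estimator
  calibration (bias, ratio recovery) uses the model-level sampler where
  truth is well defined.
* **Localization error.** Two localizations with per-axis error `sigma`
  inflate the apparent diffusivity by `sigma^2 / dt` (+0.6 um^2/s at
  30 nm and 1.5 ms). Calibration runs set `loc_sigma_nm = 0`; analyses of
  real data should treat the offset as part of what "apparent `D_L`"
  means, as the underlying localization precision is not estimated here.

The generator also does not emulate camera pixelation, photophysics
(blinking, bleaching), z-motion, or drift — passing tests say nothing
about those upstream effects.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to be
informative yet quick: 10^5 displacements for moment matching and
closed-form agreement, 50 independent datasets of 10^4 displacements for
bias calibration, 20 cells per condition for ratio recovery and the
inclusion phenotype, 10^6 points for the partition check, and all 12375
2x2 tables with margins <= 15 for the exact-test enumeration. Every random
quantity flows from an explicit seed; the whole battery reruns
byte-identically.

## Worked example

```{r example, eval = FALSE}
cfg <- smdm_config(d_field = c(pole_A = 3.5, middle = 5, pole_B = 5),
                   n_frame_pairs = 20000, loc_sigma_nm = 0, seed = 42)
sim <- simulate_displacement_dataset(cfg)

disp <- pair_displacements(sim$localizations, r_max_nm = 600)
disp <- assign_regions(disp, axial_extent = c(-1500, 1500))
fits <- fit_cell_regions(disp, dt_s = 0.0015, r_max_nm = 600)
summarize_cell(fits)

map <- fit_map(bin_displacements(disp, bin_nm = 100), 0.0015, 600)
plot(map)
```

## Known limitations

* Two-point displacements only; no multi-frame trajectory linking and no
  anomalous-diffusion or state-mixture models.
* No correction for confinement or localization error (documented above);
  reported `D_L` is the apparent coefficient under the truncated model.
* Segmentation assumes cells are far denser than background; it does not
  detect the absence of cells.
* The Voronoi density threshold and minimum cluster size are analysis
  choices, not measured constants; both are exposed as arguments.
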
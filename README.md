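# smdmr

Single-molecule displacement mapping (SMdM) analysis of protein diffusion
inside bacterial cells, in R.

SMdM localizes individual photoactivated fluorescent proteins twice in
quick succession — at the end of an odd camera frame and the start of the
following even frame, separated by a fixed pulse-to-pulse time Δt (1.5 ms).
Each odd/even pair of localizations of the same molecule is one two-point
*displacement*; the distribution of displacement lengths in any region of a
cell encodes the local lateral diffusion coefficient D\_L. This package
takes localization tables (the output of upstream peak detection) through
the full analysis:

* **Segmentation** of the localization point cloud into cells by Voronoi
  density (`cluster_cells()`), splitting of joined dividing cells
  (`split_dividing_cluster()`), and rotation of each cell onto its
  principal axis (`rotate_cluster()`).
* **Pairing** of odd→consecutive-even frame localizations into
  displacements by greedy nearest-neighbour matching capped at 600 nm
  (`pair_displacements()`).
* **Diffusion inference** by maximum likelihood under the truncated,
  background-corrected 2D random-walk model (`fit_mle()`):

  p(r) = [ (2r / 4D\_LΔt) · exp(−r² / 4D\_LΔt) + b·r ] /
  [ 1 − exp(−r²\_max / 4D\_LΔt) + (b/2)·r²\_max ]

  — a Rayleigh displacement density plus a linear term `b·r` absorbing
  spurious pairings with uniformly distributed false localizations,
  renormalized over the truncated support [0, r\_max].
* **Regional statistics**: 20/60/20 pole/middle/pole partition,
  1000–20000 displacement per-cell QC, pole/middle D\_L ratios and
  fast/slow pole classification (`assign_regions()`, `qc_filter_cells()`,
  `summarize_cell()`).
* **Diffusion maps**: per-bin MLE on 50–100 nm square grids with 10–20000
  per-bin count bounds (`bin_displacements()`, `fit_map()`).
* **Statistics**: Shapiro-Wilk-gated Student-t / Mann-Whitney comparison,
  exact 2×2 Fisher test, intensity-profile pole asymmetry, and
  mass-vs-ratio regression (`compare_groups()`, `fisher_exact_2x2()`,
  `ribosome_asymmetry()`, `mass_ratio_regression()`).
* **Synthetic data** with known ground truth — a spatial simulator of the
  stroboscopic acquisition inside a spherocylindrical cell and a direct
  sampler of the displacement model — for validation and calibration
  (`simulate_displacement_dataset()`, `simulate_displacements()`).

The methods vignette (`vignettes/smdm-methods.Rmd`) documents the model,
every tunable constant, the numerical choices, and what the synthetic data
does and does not emulate.

## Worked example

Simulate one cell whose A pole diffuses at 3.5 µm²/s against 5 µm²/s
elsewhere, then run the pipeline:

```r
library(smdmr)

cfg <- smdm_config(d_field = c(pole_A = 3.5, middle = 5, pole_B = 5),
                   n_frame_pairs = 20000, loc_sigma_nm = 0, seed = 42)
sim <- simulate_displacement_dataset(cfg)
sim
#> <smdm_sim> 47830 localizations (19957 emitters, 7916 background), 20000 frame pairs, seed 42

disp <- pair_displacements(sim$localizations, r_max_nm = 600)
disp <- assign_regions(disp, axial_extent = c(-1500, 1500))
fits <- fit_cell_regions(disp, dt_s = 0.0015, r_max_nm = 600)
summarize_cell(fits)
#> <smdm_cell_summary> n = 19963 displacements
#>   pole_A/middle = 0.694, pole_B/middle = 0.955, slow pole = pole_A
#> # A tibble: 4 × 6
#>   region   d_l             b     n   loglik converged
#>   <chr>  <dbl>         <dbl> <dbl>    <dbl> <lgl>
#> 1 whole   4.21 0.0000000174  19963 -113730. TRUE
#> 2 pole_A  3.13 0.0000000242   3647  -20231. TRUE
#> 3 middle  4.50 0.0000000137  12688  -72638. TRUE
#> 4 pole_B  4.30 0.00000001000  3628  -20695. TRUE
```

The slow pole is correctly identified and its pole/middle ratio (0.69)
recovers the configured contrast (3.5/5 = 0.7). Absolute fitted values sit
below the configured diffusivities because displacements fold back at the
cell wall — the confinement effect quantified in the vignette.

Fitting the model sampler directly (no geometry) recovers D\_L within the
estimator's sampling error even with 20% background:

```r
r <- simulate_displacements(5000, d_l = 5, dt_s = 0.0015, r_max_nm = 600,
                            background_fraction = 0.2, seed = 1)
fit_mle(r, dt_s = 0.0015, r_max_nm = 600)
#> <smdm_fit> D_L = 5.066 um^2/s, b = 1.49e-06 nm^-2, n = 5000, logLik = -30620.2
```

And the pole-age association test on a simulated old/new × slow/fast
contingency table:

```r
tab <- simulate_contingency_table(42, p_concordant = 0.85, seed = 3)
tab
#>      speed
#> pole  slow fast
#>   old   38    4
#>   new    4   38
fisher_exact_2x2(tab)
#> [1] 1.508223e-14
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/smdm` (subcommands `simulate`, `segment`, `pair`, `fit`,
`map`).

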
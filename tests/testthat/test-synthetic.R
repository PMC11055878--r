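test_that("Brownian step statistics match the 2D random-walk model", {
  # wide geometry so wall reflections are negligible for the moment check
  geom <- cell_geometry(length_nm = 40000, radius_nm = 8000)
  cfg <- smdm_config(geometry = geom, d_field = 5, dt_s = 0.0015,
                     n_frame_pairs = 60000, emitters_per_pair = 2,
                     loc_sigma_nm = 0, background_rate = 0, seed = 101)
  sim <- simulate_displacement_dataset(cfg)
  tr <- sim$truth
  expect_gte(nrow(tr), 1e5)
  dx <- tr$end_x - tr$start_x
  dy <- tr$end_y - tr$start_y
  s2 <- 2 * 5e6 * 0.0015                  # per-axis variance, nm^2
  expect_lt(abs(mean(dx)), 3 * sqrt(s2 / nrow(tr)))
  expect_lt(abs(mean(dy)), 3 * sqrt(s2 / nrow(tr)))
  expect_lt(abs(var(dx) / s2 - 1), 0.02)
  expect_lt(abs(var(dy) / s2 - 1), 0.02)
  # mean squared displacement length = 4 D dt
  expect_lt(abs(mean(dx^2 + dy^2) / (4 * 5e6 * 0.0015) - 1), 0.02)
})

test_that("near-zero diffusivity freezes the emitters", {
  cfg <- smdm_config(d_field = 1e-6, loc_sigma_nm = 0, background_rate = 0,
                     n_frame_pairs = 500, seed = 7)
  sim <- simulate_displacement_dataset(cfg)
  r <- sqrt((sim$truth$end_x - sim$truth$start_x)^2 +
              (sim$truth$end_y - sim$truth$start_y)^2)
  expect_lt(max(r), 1)                    # nm
})

test_that("the generator is an exact function of its seed", {
  cfg <- smdm_config(n_frame_pairs = 300, seed = 123)
  a <- simulate_displacement_dataset(cfg)
  b <- simulate_displacement_dataset(cfg)
  expect_identical(a$localizations, b$localizations)
  expect_identical(a$truth, b$truth)
  c <- simulate_displacement_dataset(smdm_config(n_frame_pairs = 300, seed = 124))
  expect_false(identical(a$localizations, c$localizations))
})

test_that("reflection keeps every true emitter position inside the cell", {
  geom <- cell_geometry(2600, 400, center = c(500, -200), orientation_rad = 0.4)
  cfg <- smdm_config(geometry = geom, d_field = 8, n_frame_pairs = 5000,
                     emitters_per_pair = 2, loc_sigma_nm = 0,
                     background_rate = 0, seed = 5)
  sim <- simulate_displacement_dataset(cfg)
  expect_true(all(in_cell(geom, sim$truth$start_x, sim$truth$start_y)))
  expect_true(all(in_cell(geom, sim$truth$end_x, sim$truth$end_y)))
  # every emitter yields exactly two localizations
  expect_identical(nrow(sim$localizations),
                   2L * nrow(sim$truth) + nrow(sim$background))
})

test_that("ground-truth region labels agree with the axial partition", {
  geom <- cell_geometry(3000, 450, orientation_rad = pi / 6)
  cfg <- smdm_config(geometry = geom, n_frame_pairs = 2000, seed = 21)
  sim <- simulate_displacement_dataset(cfg)
  cf <- smdmr:::to_cell_frame(geom, sim$truth$start_x, sim$truth$start_y)
  expected <- smdmr:::region_of_axial(cf$x, -1500, 1500, c(0.2, 0.6, 0.2))
  expect_identical(as.character(sim$truth$region), as.character(expected))
  expect_false(any(sim$truth$region == "none"))
})

test_that("wall reflection suppresses apparent displacements, most at the poles", {
  # the apparent (fitted) D under confinement is below the true D, and the
  # caps, having more wall per unit area, are suppressed more than mid-cell
  cfg <- smdm_config(d_field = 5, n_frame_pairs = 40000, loc_sigma_nm = 0,
                     background_rate = 0, seed = 31)
  sim <- simulate_displacement_dataset(cfg)
  disp <- pair_displacements(sim$localizations)
  disp <- assign_regions(disp, c(-1500, 1500))
  fits <- fit_cell_regions(disp, 0.0015, 600)
  expect_lt(fits$whole$d_l, 5)
  expect_lt(fits$pole_A$d_l, fits$middle$d_l)
  expect_lt(fits$pole_B$d_l, fits$middle$d_l)
})

test_that("a low-density inclusion thins emitters locally", {
  inc <- list(center = c(1000, 0), radius_nm = 300, d = 1, density = 0.3)
  cfg <- smdm_config(n_frame_pairs = 30000, inclusion = inc, seed = 13,
                     loc_sigma_nm = 0, background_rate = 0)
  sim <- simulate_displacement_dataset(cfg)
  tr <- sim$truth
  inside <- (tr$start_x - 1000)^2 + tr$start_y^2 <= 300^2
  # density ratio ~0.3 of a matched control region on the mirrored side
  control <- (tr$start_x + 1000)^2 + tr$start_y^2 <= 300^2
  expect_lt(sum(inside) / sum(control), 0.45)
  expect_gt(sum(inside) / sum(control), 0.15)
  expect_true(all(tr$d_true[inside] == 1))
  expect_true(all(tr$d_true[control] == 5))
})

test_that("synthetic intensity profiles carry their own ground truth", {
  p <- simulate_intensity_profile(65, 100, 60, 0)
  expect_equal(ribosome_asymmetry(p), 40)
  flat <- simulate_intensity_profile(65, 80, 80, 0)
  expect_equal(ribosome_asymmetry(flat), 0)
  # with mild noise the metric stays in a small envelope around the noiseless
  # value (extreme-value statistics of max/min bias it slightly upward)
  vals <- vapply(1:100, function(s)
    ribosome_asymmetry(simulate_intensity_profile(65, 100, 60, 0.5, seed = s)),
    numeric(1))
  expect_lt(abs(mean(vals) - 40), 1.5)
})

test_that("simulated contingency tables have the dividing-cell structure", {
  tab <- simulate_contingency_table(40, 0.8, seed = 2)
  expect_equal(sum(tab), 80)              # two poles per cell
  expect_equal(tab[1, 1], tab[2, 2])      # concordant cells appear twice
  expect_identical(tab, simulate_contingency_table(40, 0.8, seed = 2))
})

test_that("invalid configurations are rejected", {
  expect_error(smdm_config(dt_s = 0), "dt_s")
  expect_error(smdm_config(d_field = c(pole_A = -1, middle = 5, pole_B = 5)),
               "diffusivities")
  expect_error(cell_geometry(800, 450), "length_nm")
  expect_error(smdm_config(region_fractions = c(0.3, 0.3, 0.3)), "fractions")
})
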
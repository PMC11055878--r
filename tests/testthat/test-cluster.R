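test_that("Voronoi areas of a uniform field match the Poisson expectation", {
  set.seed(3)
  n <- 4000
  pts <- make_cloud(n, 0, 10000, 0, 10000)
  vt <- voronoi_tessellation(pts$x, pts$y)
  finite <- vt$area[is.finite(vt$area)]
  # the median Poisson-Voronoi cell area is ~0.95 of the mean 1/density
  # (near-hull cells legitimately extend far outside the sampled window,
  # so the robust centre, not the mean, carries the density information)
  expect_lt(abs(median(finite) / (0.95 * 1e8 / n) - 1), 0.1)
  expect_gt(sum(is.finite(vt$area)) / n, 0.9)
  # jittered-grid reference: interior cells are unit squares of the grid
  gr <- expand.grid(x = seq(0, 2000, by = 100), y = seq(0, 2000, by = 100))
  gr$x <- gr$x + runif(nrow(gr), -1, 1)
  gr$y <- gr$y + runif(nrow(gr), -1, 1)
  vg <- voronoi_tessellation(gr$x, gr$y)
  inner <- vg$area[is.finite(vg$area)]
  expect_lt(abs(median(inner) / 1e4 - 1), 0.02)
  expect_lt(abs(quantile(inner, 0.25) / 1e4 - 1), 0.05)
  # Delaunay adjacency: average degree of a planar triangulation is ~6
  expect_lt(abs(nrow(vt$edges) / n - 3), 0.25)
})

test_that("two dense clouds and sparse background segment into two cells", {
  set.seed(42)
  pts <- rbind(make_cloud(10000, 0, 2500, 0, 800),
               make_cloud(10000, 7000, 9500, 200, 1000),
               make_cloud(100, -2000, 12000, -2000, 3000))
  res <- cluster_cells(pts)
  expect_equal(length(setdiff(unique(res$cell), NA)), 2)
  truth <- rep(c(1, 2, 0), c(10000, 10000, 100))
  for (cl in 1:2) {
    cloud <- which(truth == cl)
    got <- res$cell[cloud]
    dominant <- as.integer(names(which.max(table(got))))
    expect_gte(mean(got == dominant, na.rm = FALSE) , 0.99)
  }
  # agreement with distance-threshold connected components (brute-force
  # oracle on a fixed subsample of the dense points)
  sub <- c(sample(which(truth == 1), 1500), sample(which(truth == 2), 1500))
  oracle <- oracle_threshold_components(pts$x[sub], pts$y[sub], 300)
  keep <- !is.na(res$cell[sub])
  expect_gt(suppressWarnings(
    igraph::compare(oracle[keep], res$cell[sub][keep], method = "nmi")), 0.99)
})

test_that("a single dense cloud forms one cluster holding every point", {
  set.seed(5)
  pts <- make_cloud(2000, 0, 2000, 0, 700)
  res <- cluster_cells(pts, min_cluster_size = 300)
  expect_equal(max(res$cell, na.rm = TRUE), 1)
  expect_equal(mean(res$cell == 1, na.rm = FALSE), 1)
})

test_that("sparse uniform background yields no clusters", {
  set.seed(6)
  pts <- make_cloud(200, 0, 10000, 0, 10000)
  expect_true(all(is.na(cluster_cells(pts)$cell)))
  expect_warning(cluster_cells(make_cloud(2, 0, 1, 0, 1)), "too few")
})

test_that("clustering is invariant to input order", {
  set.seed(7)
  pts <- rbind(make_cloud(1500, 0, 2000, 0, 600),
               make_cloud(1500, 6000, 8000, 0, 600),
               make_cloud(50, -1000, 9000, -1000, 1600))
  pts$record <- seq_len(nrow(pts))
  res <- cluster_cells(pts, min_cluster_size = 300)
  perm <- sample(nrow(pts))
  res_p <- cluster_cells(pts[perm, ], min_cluster_size = 300)
  # map back to original row ids via the record column
  expect_identical(res$cell[res_p$record], res_p$cell)
})

test_that("principal-axis rotation recovers a known orientation", {
  set.seed(8)
  base <- cbind(runif(4000, -1500, 1500), runif(4000, -400, 400))
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- base %*% t(R)
  cell <- rotate_cluster(tibble::tibble(x = rot[, 1] + 300, y = rot[, 2] - 100))
  # recovered long axis within 1 degree (mod 180) of the generating one
  axis <- cell$transform$rotation[, 1]
  ang <- atan2(axis[2], axis[1])
  expect_lt(min(abs(ang - th), abs(abs(ang - th) - pi)) * 180 / pi, 1)
  # rigid: pairwise distances preserved
  i <- sample(4000, 300); j <- sample(4000, 300)
  d0 <- sqrt((rot[i, 1] - rot[j, 1])^2 + (rot[i, 2] - rot[j, 2])^2)
  loc <- cell$localizations
  d1 <- sqrt((loc$x[i] - loc$x[j])^2 + (loc$y[i] - loc$y[j])^2)
  expect_equal(d1, d0, tolerance = 1e-6)
  # covariance diagonal with the axial variance first
  S <- cov(cbind(loc$x, loc$y))
  expect_lt(abs(S[1, 2]) / S[1, 1], 1e-6)
  expect_gt(S[1, 1], S[2, 2])
  # orientation sign convention: non-negative axial skewness
  expect_gte(smdmr:::skewness(loc$x), 0)
  # axial extent covers at least 99% of points
  expect_gte(mean(loc$x >= cell$axial_extent[1] & loc$x <= cell$axial_extent[2]), 0.99)
})

test_that("axis-aligned clouds rotate by the identity up to sign", {
  set.seed(9)
  pts <- tibble::tibble(x = runif(1000, -900, 900), y = runif(1000, -200, 200))
  cell <- rotate_cluster(pts)
  expect_equal(abs(cell$transform$rotation), diag(2), tolerance = 0.05)
})

test_that("degenerate clusters are refused", {
  expect_error(rotate_cluster(tibble::tibble(x = 1:2, y = 1:2)), "at least 3")
  expect_error(rotate_cluster(tibble::tibble(x = 1:50, y = 2 * (1:50) + 3)),
               "collinear")
  expect_error(rotate_cluster(tibble::tibble(x = rep(1, 10), y = rep(2, 10))),
               "degenerate|coincident")
})

test_that("dividing clusters split at the axial density minimum", {
  set.seed(10)
  lobes <- tibble::tibble(
    x = c(rnorm(3000, -1500, 400), rnorm(3000, 1500, 400)),
    y = runif(6000, -350, 350)
  )
  cell <- rotate_cluster(lobes)
  sp <- split_dividing_cluster(cell)
  expect_lt(abs(sp$cut_nm), 100)
  sizes <- vapply(sp$cells, function(cl) nrow(cl$localizations), numeric(1))
  expect_true(all(sizes > 0))
  expect_equal(sum(sizes), 6000)
  # split + merge reconstitutes the original member set exactly
  got <- sort(c(sp$cells[[1]]$localizations$record,
                sp$cells[[2]]$localizations$record))
  expect_identical(got, 1:6000)
})

test_that("unequal daughters still split conservatively", {
  set.seed(11)
  lobes <- tibble::tibble(
    x = c(rnorm(4200, -1400, 350), rnorm(1800, 1400, 350)),
    y = runif(6000, -300, 300)
  )
  sp <- split_dividing_cluster(rotate_cluster(lobes))
  sizes <- vapply(sp$cells, function(cl) nrow(cl$localizations), numeric(1))
  expect_true(all(sizes > 100))
  expect_equal(sum(sizes), 6000)
})

test_that("axially uniform clusters refuse to split", {
  set.seed(12)
  pts <- tibble::tibble(x = runif(5000, -1500, 1500), y = runif(5000, -350, 350))
  expect_error(split_dividing_cluster(rotate_cluster(pts)), "minimum")
})
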
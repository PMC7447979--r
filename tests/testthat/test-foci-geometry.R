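seg_axes <- function(x1, y1, x2, y2) {
  data.frame(cell_id = 1, axis_id = 1, vertex = 1:2, x = c(x1, x2), y = c(y1, y2))
}

test_that("point-to-axis distance handles vertices, interiors and endpoints", {
  ax <- seg_axes(-500, 0, 500, 0)
  expect_equal(distance_to_axis(-500, 0, ax), 0)
  expect_equal(distance_to_axis(0, 100, ax), 100)
  expect_equal(distance_to_axis(600, 0, ax), 100)  # beyond the endpoint
  expect_equal(distance_to_axis(600, 80, ax), sqrt(100^2 + 80^2))
  expect_error(distance_to_axis(0, 0, ax[0, ]), "empty")
})

test_that("axis distance is invariant under rigid motions", {
  set.seed(19)
  ax <- data.frame(cell_id = 1, axis_id = rep(1:2, each = 3),
                   vertex = rep(1:3, 2),
                   x = rnorm(6, 0, 500), y = rnorm(6, 0, 500))
  px <- 120; py <- -340
  d0 <- distance_to_axis(px, py, ax)
  th <- 0.83; dx <- 210; dy <- -95
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + dx,
                             y = sin(th) * x + cos(th) * y + dy)
  axr <- ax
  r <- rot(ax$x, ax$y); axr$x <- r$x; axr$y <- r$y
  pr <- rot(px, py)
  expect_equal(distance_to_axis(pr$x, pr$y, axr), d0, tolerance = 1e-9)
})

test_that("co-focus pairing applies the 300-nm rule per focus", {
  a <- data.frame(x = 0, y = 0)
  b <- data.frame(x = 120, y = 0)
  pr <- pair_cofoci(a, b)
  expect_equal(pr$fraction_a, 1)
  expect_equal(pr$fraction_b, 1)
  expect_equal(pr$offsets_a, 120)

  far <- data.frame(x = 400, y = 0)
  pr2 <- pair_cofoci(a, far)
  expect_equal(pr2$fraction_a, 0)
  expect_equal(pr2$fraction_b, 0)

  expect_equal(pair_cofoci(a, far[0, ])$fraction_a, 0)

  # 3 A-foci and 2 B-foci on a line: compare against all-pairs enumeration
  a3 <- data.frame(x = c(0, 500, 1000), y = 0)
  b2 <- data.frame(x = c(250, 1100), y = 0)
  pr3 <- pair_cofoci(a3, b2, threshold = 300)
  near_a <- vapply(a3$x, function(xx) min(abs(b2$x - xx)), numeric(1))
  near_b <- vapply(b2$x, function(xx) min(abs(a3$x - xx)), numeric(1))
  expect_equal(pr3$fraction_a, mean(near_a <= 300))
  expect_equal(pr3$fraction_b, mean(near_b <= 300))
  expect_equal(pr3$nearest_a, near_a)
})

test_that("co-focus fractions are monotone in the threshold", {
  set.seed(20)
  a <- data.frame(x = runif(40, 0, 3000), y = runif(40, 0, 3000))
  b <- data.frame(x = runif(30, 0, 3000), y = runif(30, 0, 3000))
  fr <- vapply(c(100, 200, 300, 500, 900), function(th) {
    p <- pair_cofoci(a, b, threshold = th)
    c(p$fraction_a, p$fraction_b)
  }, numeric(2))
  expect_true(all(diff(fr[1, ]) >= 0))
  expect_true(all(diff(fr[2, ]) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("axis-proximity comparison recovers generative medians", {
  ident <- axis_proximity_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p, 1)
  expect_equal(ident$median_a - ident$median_b, 0)
  expect_error(axis_proximity_compare(1, c(1, 2)), ">= 2")

  # channels generated with half-normal axis offsets of median 60 / 120 nm
  fs <- simulate_foci(n_cells = 2, axes_per_cell = 5, pairs_per_axis = 25,
                      background_rate = 0, seed = 23)
  fd <- foci_axis_distances(fs$foci, fs$axes)
  cmpx <- axis_proximity_compare(fd$axis_distance[fd$channel == "RAD51"],
                                 fd$axis_distance[fd$channel == "DMC1"])
  expect_equal(cmpx$median_a, 60, tolerance = 10 / 60)
  expect_equal(cmpx$median_b, 120, tolerance = 10 / 120)
  expect_lt(cmpx$p, 1e-6)
})

test_that("off-axis distances of uniform background pass the uniformity test", {
  # op-level calibration: uniform distances should pass at alpha = 0.01 in
  # at least 98 of 100 seeded replicates
  passes <- 0
  for (seed in 1:100) {
    set.seed(seed)
    d <- runif(2000, 0, 5000)
    passes <- passes + (offaxis_uniformity(d, 450, 5000)$p > 0.01)
  }
  expect_gte(passes, 98)

  # geometry-level: 10,000 uniform points against a single straight axis
  fs <- simulate_foci(n_cells = 1, axes_per_cell = 1, pairs_per_axis = 0,
                      background_rate = 20000, straight_axes = TRUE, seed = 24)
  fd <- foci_axis_distances(fs$foci[fs$foci$channel == "RAD51", ][1:10000, ],
                            fs$axes)
  expect_gt(offaxis_uniformity(fd$axis_distance, 450, fs$field / 2)$p, 0.01)

  expect_error(offaxis_uniformity(runif(5, 0, 400), 450, 5000), ">= 10")
  d_eq <- rep(1000, 100)
  expect_lt(suppressWarnings(offaxis_uniformity(d_eq, 450, 5000)$p), 1e-10)
})
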
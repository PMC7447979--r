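test_that("background correction subtracts flank means and clamps at zero", {
  j <- -250:250
  flat <- make_profile(rep(5, length(j)), rep(5, length(j)))
  bc <- background_correct(flat)
  expect_true(all(bc$crick == 0) && all(bc$watson == 0))

  peaked <- profile_with(crick_at = list(`0` = 105), base = 5)
  bc <- background_correct(peaked)
  expect_equal(bc$crick[peaked$bp == 0], 100)
  expect_true(all(bc$crick[peaked$bp != 0] == 0))

  dip <- profile_with(crick_at = list(`0` = 3), base = 5)
  bc <- background_correct(dip)
  expect_equal(bc$crick[dip$bp == 0], 0)  # clamped, not -2

  short <- make_profile(rep(1, 11), rep(1, 11), j = -5:5)
  expect_error(background_correct(short), "5000")
})

test_that("hotspot intensity sums background-corrected mass in strand-aware windows", {
  j <- -250:250
  zero <- make_profile(rep(0, length(j)))
  expect_equal(hotspot_intensity(zero), 0)

  flat <- make_profile(rep(7, length(j)), rep(7, length(j)))
  expect_equal(hotspot_intensity(flat), 0)  # background cancels

  # 100 excess Crick reads inside [-250, 2000], 50 excess Watson inside
  # [-2000, 250]
  p <- profile_with(crick_at = list(`100` = 60, `1500` = 40),
                    watson_at = list(`-300` = 50))
  expect_equal(hotspot_intensity(p), 150)

  # excess outside the strand-aware windows does not count
  p2 <- profile_with(crick_at = list(`-1000` = 80), watson_at = list(`1000` = 80))
  expect_equal(hotspot_intensity(p2), 0)
})

test_that("hotspot intensity is linear in coverage", {
  set.seed(1)
  j <- -250:250
  cr <- rpois(length(j), 4); wa <- rpois(length(j), 4)
  p1 <- make_profile(cr, wa)
  p2 <- make_profile(2.5 * cr, 2.5 * wa)
  expect_equal(hotspot_intensity(p2), 2.5 * hotspot_intensity(p1),
               tolerance = 1e-12)
})

test_that("homolog fraction and asymmetry classification follow the f-threshold rule", {
  hf <- homolog_fraction(c(95, 50, 90, 0), c(5, 50, 10, 0))
  expect_equal(hf$f, c(0.95, 0.5, 0.9, NA))
  expect_true(all(hf$lo[1:3] <= hf$f[1:3] & hf$f[1:3] <= hf$hi[1:3]))

  cls <- classify_asymmetric(hf$f)
  expect_equal(as.character(cls),
               c("asymmetric_hom1", "symmetric", "asymmetric_hom1", NA))
  # boundary f = 0.1 is inclusive on the other side
  expect_equal(as.character(classify_asymmetric(0.1)), "asymmetric_hom2")
})

test_that("asymmetry classification is symmetric under homolog swap", {
  f <- c(0.95, 0.9, 0.5, 0.1, 0.02)
  a <- classify_asymmetric(f)
  b <- classify_asymmetric(1 - f)
  swap <- c(asymmetric_hom1 = "asymmetric_hom2",
            asymmetric_hom2 = "asymmetric_hom1",
            symmetric = "symmetric")
  expect_equal(as.character(b), unname(swap[as.character(a)]))
})

test_that("profile aggregation averages and smooths as specified", {
  j <- -50:50
  p <- make_profile(rpois(length(j), 3), rpois(length(j), 3), j = j)
  # window equal to the bin width: identity
  agg <- aggregate_profile(list(p), smoothing_window = 20)
  expect_equal(agg$crick, p$crick)

  p2 <- make_profile(rep(2, length(j)), rep(2, length(j)), j = j)
  p4 <- make_profile(rep(4, length(j)), rep(4, length(j)), j = j)
  agg <- aggregate_profile(list(p2, p4))
  expect_true(all(abs(agg$crick - 3) < 1e-12))

  # 100-bp window = 5 bins: an impulse spreads to 1/5 across 5 bins
  imp <- make_profile(as.numeric(j == 0), as.numeric(j == 0), j = j)
  sm <- aggregate_profile(list(imp), smoothing_window = 100)
  expect_equal(sm$crick[abs(j) <= 2], rep(1 / 5, 5))
  expect_true(all(sm$crick[abs(j) > 2] == 0))

  pj <- make_profile(rep(1, 11), rep(1, 11), j = -5:5)
  expect_error(aggregate_profile(list(p, pj)), "binning")
})

test_that("heatmap matrix orders rows by SPO11 count", {
  cfg <- tiny_config(n_hotspots = 10)
  sim <- simulate_hotspots(cfg)
  covset <- simulate_coverage(sim, cfg$kernel_dmc1)
  hm <- heatmap_matrix(covset)
  spo <- sim$hotspots$spo11_count[match(as.integer(rownames(hm)),
                                        sim$hotspots$hotspot_id)]
  expect_true(all(diff(spo) <= 0))
})

test_that("strand area ratio behaves on exact and stochastic inputs", {
  j <- -250:250
  sym <- make_profile(rpois(length(j), 5))
  expect_equal(strand_area_ratio(sym), 1)

  doubled <- strand_profile(sym$crick, 2 * rev(sym$crick), j = j)
  expect_equal(strand_area_ratio(doubled), 2)

  cfg <- generator_config(n_hotspots = 1000, chrom_length = 2e7,
                          skew_fraction = 0, seed = 17)
  covset <- simulate_coverage(simulate_hotspots(cfg), cfg$kernel_dmc1,
                              depth = 50)
  r <- strand_area_ratio(covset)
  expect_gt(r, 0.98); expect_lt(r, 1.02)

  zero <- make_profile(rep(0, length(j)))
  expect_error(strand_area_ratio(zero), "Crick")
})

test_that("group elevation recovers generative slope ratios", {
  set.seed(21)
  n <- 200
  spo <- rpois(2 * n, 30)
  grp <- rep(c("auto", "X"), each = n)
  # same signal per DSB -> ratio 1
  y_null <- 2 * spo + rnorm(2 * n, 0, 2)
  ge <- group_elevation(y_null, spo, grp)
  expect_equal(unname(ge$ratio["X", "auto"]), 1, tolerance = 0.05)

  # X hotspots generated with 3x signal per DSB -> ratio ~3
  y_elev <- ifelse(grp == "X", 6, 2) * spo + rnorm(2 * n, 0, 2)
  ge <- group_elevation(y_elev, spo, grp)
  expect_equal(unname(ge$ratio["X", "auto"]), 3, tolerance = 0.05)

  expect_error(group_elevation(y_null[1:11], spo[1:11],
                               c(rep("a", 10), "b")), ">= 10")
  expect_error(group_elevation(c(1, 2), c(1, 2), c("a", "b")), ">= 10")
  spo0 <- spo; spo0[grp == "X"] <- 0
  expect_error(group_elevation(y_null, spo0, grp), "all-zero")
})
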
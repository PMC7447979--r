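test_that("hotspot simulation is deterministic under a fixed seed", {
  cfg <- tiny_config(n_hotspots = 10)
  a <- simulate_hotspots(cfg)
  b <- simulate_hotspots(cfg)
  expect_equal(nrow(a$hotspots), 10)
  expect_identical(a$hotspots, b$hotspots)
  expect_identical(a$offsets, b$offsets)

  cov_a <- simulate_coverage(a, cfg$kernel_dmc1)
  cov_b <- simulate_coverage(b, cfg$kernel_dmc1)
  expect_identical(cov_a$crick, cov_b$crick)
  expect_identical(cov_a$watson, cov_b$watson)
})

test_that("hotspot centres respect the 8 kb spacing rule", {
  sim <- simulate_hotspots(tiny_config(n_hotspots = 50, chrom_length = 5e6))
  expect_true(min(diff(sort(sim$hotspots$center))) >= 8000)
})

test_that("asym_fraction = 1 forces every hotspot into the asymmetric classes", {
  sim <- simulate_hotspots(tiny_config(asym_fraction = 1))
  expect_true(all(sim$hotspots$f >= 0.9 | sim$hotspots$f <= 0.1))

  sym <- simulate_hotspots(tiny_config(asym_fraction = 0))
  expect_true(all(sym$hotspots$f > 0.1 & sym$hotspots$f < 0.9))
})

test_that("a point-mass offset model yields all-zero offsets", {
  sim <- simulate_hotspots(tiny_config(dsb_offset_model = list(sd = 0, bounds = 100)))
  expect_true(all(unlist(sim$offsets) == 0))
})

test_that("config validation errors name the offending field", {
  expect_error(generator_config(n_hotspots = 0), "n_hotspots")
  expect_error(generator_config(rpa_dsb_mix = c(0.7, 0.7)), "rpa_dsb_mix")
  expect_error(generator_config(read_depth = -1), "read_depth")
  expect_error(generator_config(n_hotspots = 1000, chrom_length = 1e6),
               "chrom_length")
  expect_error(generator_config(skew_factor = 0.5), "skew_factor")
})

test_that("coverage follows the forward model exactly in noise-free mode", {
  cfg <- tiny_config()
  sim <- manual_sim(rep(list(rep(0, 10)), 5), config = cfg)

  # depth 0: all-zero coverage
  cov0 <- simulate_coverage(sim, cfg$kernel_dmc1, depth = 0)
  expect_true(all(cov0$crick == 0) && all(cov0$watson == 0))

  # point-mass offsets, noise-free: coverage is depth x kernel exactly
  cov <- simulate_coverage(sim, cfg$kernel_dmc1, depth = 50, noise = "none")
  expected <- numeric(length(cov$j))
  expected[match(cfg$kernel_dmc1$k, cov$j)] <- 50 * cfg$kernel_dmc1$mass
  expect_equal(cov$crick[1, ], expected, tolerance = 1e-12)
  # Watson is the mirror image
  expect_equal(cov$watson[1, ], rev(cov$crick[1, ]), tolerance = 1e-12)

  expect_error(simulate_coverage(sim, cfg$kernel_dmc1, depth = -5), "depth")
})

test_that("total simulated coverage matches the expected read depth", {
  cfg <- generator_config(n_hotspots = 1000, chrom_length = 2e7,
                          skew_fraction = 0, seed = 3)
  sim <- simulate_hotspots(cfg)
  covset <- simulate_coverage(sim, cfg$kernel_dmc1, depth = 30)
  n_reads <- sum(covset$crick)
  # expected total = n_hotspots * depth (kernel area 1); Poisson 3-SE bound,
  # slightly widened for the hotspot-weighting variation
  expected <- 1000 * 30
  expect_lt(abs(n_reads - expected), 4 * sqrt(expected))
})

test_that("outcome simulation matches its construction rules", {
  cfg <- tiny_config(n_hotspots = 20, dsb_per_hotspot = 10, seed = 5)
  sim <- simulate_hotspots(cfg)
  out <- simulate_outcomes(sim)

  # crossover intervals bound their true breakpoint
  co <- out$crossovers
  expect_true(all(co$snp_left < co$true_breakpoint))
  expect_true(all(co$snp_right >= co$true_breakpoint))
  # internal SNPs lie strictly inside the informative pair
  for (i in seq_len(nrow(co))) {
    isn <- co$internal_snps[[i]]
    if (length(isn) > 0) {
      expect_true(all(isn > co$snp_left[i] & isn < co$snp_right[i]))
    }
  }
  # single-SNP conversions are single positions
  nco <- out$ncos
  expect_true(all(nco$start[nco$n_snps == 1] == nco$end[nco$n_snps == 1]))
  expect_true(all(nco$start <= nco$end))
})

test_that("reported crossover intervals shrink as SNP spacing shrinks", {
  width_at <- function(spacing) {
    cfg <- generator_config(n_hotspots = 40, chrom_length = 2e6,
                            dsb_per_hotspot = 10, snp_spacing = spacing,
                            snp_informative_prob = 1, seed = 9)
    out <- simulate_outcomes(simulate_hotspots(cfg))
    mean(out$crossovers$snp_right - out$crossovers$snp_left)
  }
  w <- vapply(c(400, 100, 20), width_at, numeric(1))
  expect_true(all(diff(w) < 0))
  expect_lt(w[3], 50)
})

test_that("crossover rate is flat along the chromosome when co_gradient = 1", {
  cfg <- generator_config(n_hotspots = 250, chrom_length = 1e7,
                          dsb_per_hotspot = 20, co_gradient = 1,
                          co_tract_mean = 300, seed = 13)
  sim <- simulate_hotspots(cfg)
  res <- simulate_outcomes(sim)
  expect_equal(var(res$p_co), 0)
  # crossovers per chromosome quarter should be proportional to the number
  # of hotspots there: goodness-of-fit should not reject at the 1% level
  brk <- seq(0, cfg$chrom_length, length.out = 5)
  co_b <- tabulate(cut(res$crossovers$center, brk, labels = FALSE), 4)
  hs_b <- tabulate(cut(sim$hotspots$center, brk, labels = FALSE), 4)
  p <- stats::chisq.test(co_b, p = hs_b / sum(hs_b))$p.value
  expect_gt(p, 0.01)
})

test_that("crossover rate follows the configured gradient", {
  cfg <- generator_config(n_hotspots = 100, chrom_length = 5e6,
                          co_gradient = 3, seed = 2)
  sim <- simulate_hotspots(cfg)
  out <- simulate_outcomes(sim)
  expect_equal(mean(out$p_co), cfg$co_base_rate, tolerance = 0.02)
  # per-DSB probability increases towards the telomeric end
  expect_true(all(diff(out$p_co[order(sim$hotspots$center)]) >= 0))
})

test_that("foci simulation degenerates correctly and is seed-stable", {
  fs0 <- simulate_foci(n_cells = 2, axes_per_cell = 3, pairs_per_axis = 5,
                       axis_sd_dmc1 = 0, axis_sd_rad51 = 0,
                       pair_lateral_sd = 0, background_rate = 0, seed = 4)
  d <- foci_axis_distances(fs0$foci, fs0$axes)
  expect_true(all(d$axis_distance < 1e-6))
  # partners coincide
  for (pid in unique(fs0$foci$pair_id)) {
    pr <- fs0$foci[fs0$foci$pair_id == pid, ]
    expect_equal(pr$x[1], pr$x[2], tolerance = 1e-9)
    expect_equal(pr$y[1], pr$y[2], tolerance = 1e-9)
  }

  fs_a <- simulate_foci(seed = 99)
  fs_b <- simulate_foci(seed = 99)
  expect_identical(fs_a$foci, fs_b$foci)
  expect_identical(fs_a$axes, fs_b$axes)
})
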
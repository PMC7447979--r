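make_crossover <- function(snp_left, snp_right, internal = numeric(0),
                           center = 0) {
  data.frame(center = center, snp_left = snp_left, snp_right = snp_right,
             internal_snps = I(list(internal)))
}

test_that("breakpoint maps give equal mass per inter-SNP interval", {
  # informative SNPs at -400 / +600, internal at 0 and +200: three intervals
  bm <- breakpoint_probability_map(make_crossover(-400, 600, c(0, 200)))
  in1 <- bm$x >= -400 & bm$x < 0
  in2 <- bm$x >= 0 & bm$x < 200
  in3 <- bm$x >= 200 & bm$x < 600
  expect_equal(sum(bm$mass[in1]), 1 / 3, tolerance = 1e-9)
  expect_equal(sum(bm$mass[in2]), 1 / 3, tolerance = 1e-9)
  expect_equal(sum(bm$mass[in3]), 1 / 3, tolerance = 1e-9)
  # uniform per bp within each interval
  expect_equal(unique(round(bm$mass[in1], 12)), (1 / 3) / 400)
  expect_equal(unique(round(bm$mass[in2], 12)), (1 / 3) / 200)
  expect_equal(sum(bm$mass), 1, tolerance = 1e-9)

  # no internal SNPs: uniform over the whole interval
  bm2 <- breakpoint_probability_map(make_crossover(-100, 100))
  expect_equal(unique(round(bm2$mass[bm2$x >= -100 & bm2$x < 100], 12)), 1 / 200)
  expect_equal(sum(bm2$mass), 1, tolerance = 1e-9)

  # additivity: two identical crossovers double the map
  two <- rbind(make_crossover(-100, 100), make_crossover(-100, 100))
  bm3 <- breakpoint_probability_map(two)
  expect_equal(bm3$mass, 2 * bm2$mass, tolerance = 1e-12)

  # the per-bp alternative reading spreads mass uniformly across the region
  bm4 <- breakpoint_probability_map(make_crossover(-400, 600, c(0, 200)),
                                    equal_per_interval = FALSE)
  expect_equal(unique(round(bm4$mass[bm4$x >= -400 & bm4$x < 600], 12)), 1 / 1000)

  # intervals beyond the window are clipped with a warning
  expect_warning(breakpoint_probability_map(make_crossover(-3000, 100)),
                 "clipped")
})

test_that("breakpoint mass is conserved through aggregation", {
  set.seed(14)
  cos <- do.call(rbind, lapply(1:30, function(i) {
    a <- sort(sample(-1500:1500, sample(2:6, 1)))
    make_crossover(a[1], a[length(a)], a[-c(1, length(a))])
  }))
  bm <- breakpoint_probability_map(cos)
  expect_equal(sum(bm$mass), 30, tolerance = 1e-9)
  expect_equal(bm$n_events, 30)
  expect_true(all(bm$mass >= 0))
})

test_that("single-track deconvolution of maps matches the forward oracle", {
  k <- -50:125
  # point-mass offsets: binned map passes through restricted to the window
  s0 <- bin_offsets(0, m = 50)  # a single oligo at 0: identity transform
  bm <- breakpoint_probability_map(make_crossover(-400, 600, c(0, 200)))
  binned <- bin_map(bm)
  dm <- deconvolve_map(bm, s0, tol = 1e-10)
  expected <- ifelse(k %in% binned$j, binned$mass[match(k, binned$j)], 0)
  expect_equal(dm$mass, expected, tolerance = 1e-8)

  # known density convolved with a two-bin offset distribution, noise-free
  s_counts <- numeric(101); s_counts[51] <- 3; s_counts[50] <- 1
  s <- offset_distribution(s_counts, m = 50)
  b_true <- exp(-abs(k - 10) / 8)
  j <- -150:150
  cov <- forward_convolve(s$counts, 50, b_true, k, j)
  out <- deconvolve_map(list(j = j, mass = cov), s, tol = 1e-10)
  expect_lt(max(abs(out$mass - b_true)), 1e-6)

  # all-zero map deconvolves to zero
  z <- deconvolve_map(list(j = j, mass = numeric(length(j))), s, tol = 0.2)
  expect_true(all(z$mass == 0))
})

test_that("tract containment matches direct enumeration", {
  pos <- seq(-600, 700, by = 100)
  mass <- numeric(length(pos))
  mass[pos == 500] <- 0.6
  mass[pos == -300] <- 0.4
  tc <- tract_containment(pos, mass)
  expect_equal(tc$containment[pos == 200], 0.6)
  expect_equal(tc$containment[pos == -100], 0.4)
  expect_equal(tc$containment[pos == 600], 0)
  expect_equal(tc$containment[pos == 0], 1)

  # single breakpoint: containment 1 over [0, 500], 0 elsewhere
  m1 <- numeric(length(pos)); m1[pos == 500] <- 1
  t1 <- tract_containment(pos, m1)
  expect_true(all(t1$containment[pos >= 0 & pos <= 500] == 1))
  expect_true(all(t1$containment[pos < 0 | pos > 500] == 0))

  # brute-force oracle on a random grid: enumerate (breakpoint, position)
  set.seed(15)
  pos_r <- sort(sample(-250:250, 120))
  if (!0 %in% pos_r) pos_r <- sort(c(pos_r, 0))
  m_r <- rgamma(length(pos_r), 1, 1)
  tc_r <- tract_containment(pos_r, m_r)
  brute <- vapply(pos_r, function(x) {
    sum(m_r[vapply(seq_along(pos_r), function(d) {
      lo <- min(0, pos_r[d]); hi <- max(0, pos_r[d])
      x >= lo && x <= hi
    }, logical(1))])
  }, numeric(1))
  expect_equal(tc_r$containment, brute, tolerance = 1e-9)
})

test_that("containment at the break equals total mass", {
  set.seed(16)
  pos <- seq(-500, 500, by = 20)
  mass <- rgamma(length(pos), 1, 2)
  tc <- tract_containment(pos, mass)
  expect_equal(tc$containment[pos == 0], sum(mass), tolerance = 1e-9)
})

test_that("NCO tract maps follow the minimal-segment and equal-weight rules", {
  s0 <- bin_offsets(0, m = 50)
  # single-SNP conversion: point mass at the SNP before smoothing
  one <- data.frame(center = 0, start = 100, end = 100)
  nm <- nco_tract_map(one, s0, smooth = 1)
  expect_equal(sum(nm$map$mass), 1, tolerance = 1e-9)
  expect_equal(nm$map$mass[nm$map$x == 100], 1)

  # converted SNPs at +100 and +250: uniform over [100, 250]
  seg <- data.frame(center = 0, start = 100, end = 250)
  nm2 <- nco_tract_map(seg, s0, smooth = 1)
  inside <- nm2$map$x >= 100 & nm2$map$x < 250
  expect_equal(unique(round(nm2$map$mass[inside], 12)), 1 / 150)

  # one short, one long tract: equal total weight each
  both <- data.frame(center = c(0, 0), start = c(100, -400), end = c(100, 400))
  nm3 <- nco_tract_map(both, s0, smooth = 1)
  expect_equal(sum(nm3$map$mass), 2, tolerance = 1e-9)
  expect_equal(sum(nm3$map$mass[nm3$map$x >= -400 & nm3$map$x < 400 &
                                  nm3$map$x != 100]), 1, tolerance = 1e-2)

  # far-away NCOs are excluded and counted
  far <- data.frame(center = 0, start = 5000, end = 5100)
  nm4 <- nco_tract_map(rbind(one, far), s0, smooth = 1)
  expect_equal(nm4$n_excluded, 1)
  expect_equal(nm4$n_used, 1)
})

test_that("breakpoint maps converge to the true density as SNP spacing shrinks", {
  set.seed(18)
  true_bp <- round(rnorm(400, 150, 300))
  l1_at <- function(spacing) {
    cos <- do.call(rbind, lapply(true_bp, function(bp) {
      grid <- sort(unique(round(c(
        seq(-2000, 2000, by = spacing) + sample.int(spacing, 1)
      ))))
      grid <- grid[grid >= -1990 & grid <= 1990]
      lo <- max(grid[grid < bp], -1990)
      hi <- min(grid[grid >= bp], 1990)
      internal <- grid[grid > lo & grid < hi]
      make_crossover(lo, hi, internal)
    }))
    bm <- suppressWarnings(breakpoint_probability_map(cos))
    est <- bin_map(bm)
    truth <- tabulate(
      findInterval(true_bp, 20 * (est$j - 0.5)), length(est$j)
    )
    sum(abs(est$mass / sum(est$mass) - truth / sum(truth)))
  }
  l1 <- vapply(c(800, 200, 40), l1_at, numeric(1))
  expect_true(all(diff(l1) < 0))
})
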
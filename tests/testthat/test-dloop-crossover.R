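test_that("equal-signal binning splits cumulative weight at quartiles", {
  expect_equal(equal_signal_bins(rep(1, 8)), rep(1:4, each = 2))
  expect_warning(b <- equal_signal_bins(c(3, 1, 1, 3)), "share")
  expect_equal(b, 1:4)
  expect_equal(equal_signal_bins(rep(2, 5), n_bins = 1), rep(1L, 5))

  # each bin's weight is within one hotspot's weight of total / 4
  set.seed(12)
  w <- rgamma(200, 2, 1)
  bins <- equal_signal_bins(w, order_by = runif(200))
  per_bin <- vapply(1:4, function(b) sum(w[bins == b]), numeric(1))
  expect_true(all(abs(per_bin - sum(w) / 4) <= max(w) + 1e-9))

  expect_error(equal_signal_bins(rep(0, 4)), "> 0")
})

test_that("bin fractions and bootstrap behave on exact and degenerate input", {
  bins <- rep(1:4, each = 25)
  ev <- rep(2, 100)
  bf <- bin_fractions(bins, ev, n_boot = 500, seed = 1)
  expect_equal(bf$fraction, rep(0.25, 4))
  expect_equal(sum(bf$fraction), 1)

  # all events in bin 4 with identical hotspots: degenerate CI
  ev4 <- ifelse(bins == 4, 3, 0)
  bf4 <- bin_fractions(bins, ev4, n_boot = 500, seed = 1)
  expect_equal(bf4$fraction, c(0, 0, 0, 1))
  expect_equal(bf4$lo, c(0, 0, 0, 1))
  expect_equal(bf4$hi, c(0, 0, 0, 1))

  # bootstrap interval contains the plug-in estimate
  set.seed(5)
  ev_r <- rpois(100, 2)
  bfr <- bin_fractions(bins, ev_r, n_boot = 1000, seed = 2)
  expect_true(all(bfr$lo <= bfr$fraction & bfr$fraction <= bfr$hi))
})

test_that("crossover-rate rescaling fixes the weighted mean and preserves ratios", {
  # raw ratios already averaging 0.10: unchanged
  r <- rescale_crossover_rate(c(0.05, 0.10, 0.15, 0.10) * 100, rep(100, 4))
  expect_equal(r$rate, c(0.05, 0.10, 0.15, 0.10))

  r2 <- rescale_crossover_rate(c(0.10, 0.20, 0.30, 0.20) * 100, rep(100, 4))
  expect_equal(r2$rate, c(0.05, 0.10, 0.15, 0.10))

  r3 <- rescale_crossover_rate(c(0.10, 0.20, 0.30, 0.20) * 100, rep(100, 4),
                               mean_rate = 0.15)
  expect_equal(r3$rate, 1.5 * r2$rate)

  # between-bin ratios preserved exactly
  set.seed(3)
  co <- rpois(4, 30) + 1; w <- rgamma(4, 5, 0.01)
  rr <- rescale_crossover_rate(co, w)
  expect_equal(rr$rate / rr$rate[1], rr$raw_ratio / rr$raw_ratio[1])
  expect_equal(sum(w * rr$rate) / sum(w), 0.10)

  expect_error(rescale_crossover_rate(c(0, 0), c(1, 1)), "no crossovers")
})

test_that("the 2x2 lifespan system solves in closed form", {
  ls <- estimate_lifespans(c(0.1, 0.2), c(1.16, 1.32))
  expect_equal(ls$L_nco, 1, tolerance = 1e-10)
  expect_equal(ls$L_co, 2.6, tolerance = 1e-10)
  expect_equal(ls$ratio, 2.6, tolerance = 1e-10)

  expect_error(estimate_lifespans(c(0.1, 0.1), c(1, 1)), "singular")
  expect_error(estimate_lifespans(0.1, 1), ">= 2")

  # scaling the template signal scales lifespans but not their ratio
  ls10 <- estimate_lifespans(c(0.1, 0.2), 10 * c(1.16, 1.32))
  expect_equal(ls10$ratio, ls$ratio, tolerance = 1e-10)
})

test_that("lifespan recovery under 1% noise stays within 5%", {
  for (seed in 1:5) {
    ls <- lifespan_recovery_experiment(seed = seed)
    expect_lt(abs(ls$ratio - 2.6) / 2.6, 0.05)
  }
})

test_that("the lifespan ratio is invariant to a uniform assumed sister fraction", {
  # (1 - sf) rescales both lifespans equally, so the ratio cannot move
  for (sf in c(0, 0.05, 0.2, 0.5)) {
    ls <- lifespan_recovery_experiment(seed = 7, sister_fraction = sf)
    expect_equal(ls$L_nco, 1, tolerance = 0.05)
    expect_equal(ls$ratio, lifespan_recovery_experiment(seed = 7)$ratio,
                 tolerance = 1e-10)
  }
})

test_that("the crossover feature model recovers exact and noisy coefficients", {
  set.seed(41)
  n <- 120
  df <- as.data.frame(matrix(rnorm(n * 8), n))
  names(df) <- c("H_d", "H_r", "P_d", "P_r", "D_d", "D_r", "R_d", "R_r")
  df[] <- scale(df)

  # zero-noise response from one standardized predictor: coefficient exact
  df$C <- 2 * df$H_d
  cm <- crossover_feature_model(df)
  expect_equal(unname(cm$coefficients["H_d"]), 2, tolerance = 1e-8)
  expect_equal(unname(cm$coefficients["(Intercept)"]), 0, tolerance = 1e-8)

  expect_error(crossover_feature_model(df[1:20, ]), ">= 50")

  dup <- df; dup$H_r <- dup$H_d  # perfect collinearity: dropped with warning
  expect_warning(cm2 <- crossover_feature_model(dup), "collinear")
  expect_false("H_r" %in% cm2$predictors)
})

test_that("stepwise AIC retains true predictors and prunes noise at the AIC rate", {
  set.seed(43)
  n <- 100
  keep_true <- 0; n_noise_kept <- integer(0)
  for (rep in 1:100) {
    df <- as.data.frame(matrix(rnorm(n * 8), n))
    names(df) <- c("H_d", "H_r", "P_d", "P_r", "D_d", "D_r", "R_d", "R_r")
    df$C <- df$H_d + rnorm(n, 0, 0.5)
    sel <- select_features(crossover_feature_model(df))
    keep_true <- keep_true + ("H_d" %in% sel$selected)
    n_noise_kept <- c(n_noise_kept, length(setdiff(sel$selected, "H_d")))
  }
  expect_gte(keep_true, 95)
  # AIC admits a pure-noise predictor with P(chisq_1 > 2) ~ 0.157, so about
  # 1.1 of the 7 noise predictors survive on average
  expect_lt(mean(n_noise_kept), 2.5)
})
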
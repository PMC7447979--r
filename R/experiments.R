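#' Reference deconvolution-recovery experiment
#'
#' The standard desk-scale validation run used throughout the package:
#' simulate strand coverage for a hotspot set whose DSB offsets follow a
#' truncated Gaussian, aggregate, and deconvolve back to DSB-relative
#' coordinates using the SPO11 offsets sampled in the same run.  Recovered
#' profile statistics can be compared with the generating kernel's.
#'
#' @param kernel generating [binding_kernel()] (or a name from
#'   [default_kernels()]).
#' @param seed RNG seed.
#' @param n_hotspots,depth simulation size: hotspots and expected reads per
#'   hotspot per strand.
#' @param offset_sd,offset_bounds DSB-offset truncated-Gaussian parameters
#'   (bp).
#' @param spo11_rate expected SPO11 oligos per hotspot.
#' @param tol deconvolution tolerance.
#' @param noise `"poisson"` or `"none"`.
#' @return list with `deconvolved` (a `deconvolved_profile`), `stats`
#'   (Crick-strand [profile_stats()]), `kernel`, `s` (the sampled SPO11
#'   [offset_distribution()]).
#' @export
deconvolution_recovery_experiment <- function(kernel, seed = 1,
                                              n_hotspots = 2000, depth = 100,
                                              offset_sd = 150,
                                              offset_bounds = 1000,
                                              spo11_rate = 20, tol = 0.2,
                                              noise = "poisson") {
  if (is.character(kernel)) kernel <- default_kernels()[[kernel]]
  cfg <- generator_config(
    n_hotspots = n_hotspots,
    chrom_length = max(2e7, n_hotspots * 5e4),
    dsb_offset_model = list(sd = offset_sd, bounds = offset_bounds),
    read_depth = depth, spo11_rate = spo11_rate,
    skew_fraction = 0, asym_fraction = 0, background_rate = 0,
    seed = seed
  )
  sim <- simulate_hotspots(cfg)
  covset <- simulate_coverage(sim, kernel, seed = seed + 101L, noise = noise)
  s <- spo11_distribution(sim)
  agg <- background_correct(aggregate_coverage(covset))
  dp <- deconvolve(agg, s = s, tol = tol)
  list(deconvolved = dp, stats = profile_stats(dp, which = "crick"),
       kernel = kernel, s = s, sim = sim, covset = covset)
}

#' Reference filament-mixture recovery experiment
#'
#' Composes an RPA binding kernel as a linear combination of the DMC1 and
#' RAD51 kernels, simulates and deconvolves all three tracks under the same
#' conditions as [deconvolution_recovery_experiment()], normalises them to
#' unit area and fits the mixture model.
#'
#' @param seed RNG seed.
#' @param weights length-2 DMC1/RAD51 composition weights (default the
#'   CAST-hotspot best fit, 0.65/0.35).
#' @inheritParams deconvolution_recovery_experiment
#' @return list with `fit` (a `mixture_fit`), `percent_dmc1`
#'   (`100 * beta / (beta + gamma)`), and the three deconvolved profiles.
#' @export
mixture_recovery_experiment <- function(seed = 1, weights = c(0.65, 0.35),
                                        n_hotspots = 2000, depth = 100,
                                        offset_sd = 150, offset_bounds = 1000,
                                        spo11_rate = 20, tol = 0.2,
                                        noise = "poisson") {
  stopifnot(length(weights) == 2, all(weights >= 0))
  weights <- weights / sum(weights)
  kern <- default_kernels()
  kern$rpa <- binding_kernel(
    kern$dmc1$k, weights[1] * kern$dmc1$mass + weights[2] * kern$rad51$mass
  )
  cfg <- generator_config(
    n_hotspots = n_hotspots,
    chrom_length = max(2e7, n_hotspots * 5e4),
    dsb_offset_model = list(sd = offset_sd, bounds = offset_bounds),
    read_depth = depth, spo11_rate = spo11_rate,
    skew_fraction = 0, asym_fraction = 0, background_rate = 0,
    seed = seed
  )
  sim <- simulate_hotspots(cfg)
  s <- spo11_distribution(sim)
  dec <- list()
  for (p in c("rpa", "dmc1", "rad51")) {
    covset <- simulate_coverage(sim, kern[[p]],
                                seed = seed + match(p, c("rpa", "dmc1", "rad51")) * 997L,
                                noise = noise)
    agg <- background_correct(aggregate_coverage(covset))
    dec[[p]] <- deconvolve(agg, s = s, tol = tol)
  }
  fit <- fit_mixture(
    normalize_area(dec$rpa, which = "crick"),
    normalize_area(dec$dmc1, which = "crick"),
    normalize_area(dec$rad51, which = "crick")
  )
  list(fit = fit, percent_dmc1 = 100 * fit$beta / (fit$beta + fit$gamma),
       deconvolved = dec)
}

#' Reference lifespan-recovery experiment
#'
#' Builds distance bins with known per-DSB crossover fractions, sets each
#' bin's repair-template RPA per DSB to the lifespan mixture
#' `c * L_co + (1 - c) * L_nco` (with `L_nco = 1`), perturbs with i.i.d.
#' multiplicative noise and re-solves the least-squares system.
#'
#' A single noise draw over four bins leaves the ratio estimate with a
#' sampling sd of about 6% (the (c, 1 - c) design is nearly collinear over
#' c in 0.04..0.16), so the recovered ratio is reported as the mean over
#' `n_replicates` independent noise draws; this measures the estimator's
#' accuracy rather than one draw's sampling noise.  Set `n_replicates = 1`
#' for the single-draw behaviour.
#'
#' @param seed RNG seed.
#' @param ratio generating lifespan ratio `L_co / L_nco`.
#' @param co_rate per-DSB crossover fractions per bin.
#' @param noise_sd sd of the multiplicative noise factors.
#' @param sister_fraction assumed (and generating) sister-repair share.
#' @param n_replicates number of noise replicates averaged.
#' @return a `lifespan_estimate` whose `L_co`, `L_nco` and `ratio` are
#'   replicate means, with added `ratio_sd` and `n_replicates`.
#' @export
lifespan_recovery_experiment <- function(seed = 1, ratio = 2.6,
                                         co_rate = c(0.04, 0.08, 0.12, 0.16),
                                         noise_sd = 0.01,
                                         sister_fraction = 0,
                                         n_replicates = 100) {
  set.seed(seed)
  R0 <- (1 - sister_fraction) * (co_rate * ratio + (1 - co_rate))
  ests <- lapply(seq_len(n_replicates), function(i) {
    R <- R0 * (1 + stats::rnorm(length(R0), 0, noise_sd))
    estimate_lifespans(co_rate, R, sister_fraction = sister_fraction)
  })
  ratios <- vapply(ests, `[[`, numeric(1), "ratio")
  out <- ests[[1]]
  out$L_co <- mean(vapply(ests, `[[`, numeric(1), "L_co"))
  out$L_nco <- mean(vapply(ests, `[[`, numeric(1), "L_nco"))
  out$ratio <- mean(ratios)
  out$ratio_sd <- stats::sd(ratios)
  out$n_replicates <- n_replicates
  out
}
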
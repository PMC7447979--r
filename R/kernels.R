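#' Binding kernels on the 20-bp deconvolution grid
#'
#' A binding kernel is the "true" density of protein binding relative to a
#' DSB site, discretised on the same 20-bp grid used throughout the package:
#' bin `k` covers `[20(k - 1/2), 20(k + 1/2))` bp, with positive `k` pointing
#' in the direction of the 3' ssDNA overhang (Crick polarity).  Kernels are
#' the generative truth of the synthetic-data module and the reference that
#' deconvolution is expected to recover.
#'
#' @param k integer vector of bin indices (default `-50:125`, i.e. -1000 bp
#'   to +2500 bp from the break).
#' @param mass nonnegative per-bin mass; normalised to sum to 1.
#' @param polarity which strand carries the kernel in forward orientation;
#'   `"crick"` means positive `k` points rightward of the break on Crick.
#' @param params free-form list recording how the kernel was built.
#' @return an object of class `binding_kernel` with elements `k`, `bp`
#'   (bin midpoints), `mass`, `polarity`, `params`.
#' @export
binding_kernel <- function(k = -50:125, mass, polarity = "crick", params = list()) {
  k <- as.integer(k)
  if (length(mass) != length(k)) {
    stop("`mass` must have one value per bin in `k`", call. = FALSE)
  }
  if (any(!is.finite(mass)) || any(mass < 0)) {
    stop("kernel `mass` must be finite and nonnegative", call. = FALSE)
  }
  total <- sum(mass)
  if (total <= 0) stop("kernel `mass` must have positive total", call. = FALSE)
  structure(
    list(k = k, bp = 20 * k, mass = mass / total,
         polarity = polarity, params = params),
    class = "binding_kernel"
  )
}

#' @export
print.binding_kernel <- function(x, ...) {
  st <- profile_stats(x$mass, k = x$k)
  cat(sprintf(
    "<binding_kernel> %d bins (%d..%d), peak %g bp, median %g bp, central95 [%g, %g] bp\n",
    length(x$k), min(x$k), max(x$k), st$peak_bp, st$median_bp,
    st$central95[1], st$central95[2]
  ))
  invisible(x)
}

## CDF of the peak + split-normal mixture used by `calibrate_kernel()`.
## The body is a two-piece Gaussian glued at the mode (widths sd_left /
## sd_right), so the mode stays put while the median is controlled by the
## imbalance of the two widths; the narrow Gaussian "cap" keeps the binned
## argmax well defined even when the body is nearly flat around the mode.
peak_split_cdf <- function(x, mode, sd_left, sd_right, peak_sd, peak_weight) {
  p_left <- sd_left / (sd_left + sd_right)
  body <- ifelse(
    x < mode,
    2 * p_left * stats::pnorm(x, mode, sd_left),
    p_left + (1 - p_left) * (2 * stats::pnorm(x, mode, sd_right) - 1)
  )
  peak_weight * stats::pnorm(x, mode, peak_sd) + (1 - peak_weight) * body
}

bin_mass_from_cdf <- function(cdf_fun, k) {
  lo <- 20 * (k - 0.5)
  hi <- 20 * (k + 0.5)
  m <- cdf_fun(hi) - cdf_fun(lo)
  m[m < 0] <- 0
  m
}

#' Calibrate a default binding kernel to a target binned mode and median
#'
#' Builds a kernel whose *binned* summary statistics (as computed by
#' [profile_stats()]) match a target peak position and median position
#' exactly.  The density is a mixture of a narrow Gaussian component centred
#' at the mode (which pins the argmax bin) and a split-normal body whose
#' free-side width is solved numerically so the binned median hits the
#' target.  This accommodates both right-skewed shapes (median > mode) and
#' left-skewed shapes (median < mode).
#'
#' @param mode_bp target peak position in bp (midpoint of the modal bin;
#'   should be a multiple of the 20-bp bin width for an exact match).
#' @param median_bp target median position in bp.
#' @param peak_sd standard deviation (bp) of the narrow peak component.
#' @param peak_weight mixture weight of the peak component, in \[0, 1).
#' @param anchor_sd width (bp) of the split-normal body on the side *away*
#'   from the median: the left side when `median_bp > mode_bp`, the right
#'   side otherwise.  The opposite side's width is solved for.
#' @param k bin index support (default `-50:125`).
#' @return a [binding_kernel()].
#' @export
calibrate_kernel <- function(mode_bp, median_bp, peak_sd = 50, peak_weight = 0.25,
                             anchor_sd = 100, k = -50:125) {
  stopifnot(peak_weight >= 0, peak_weight < 1, peak_sd > 0, anchor_sd > 0)
  right_skewed <- median_bp > mode_bp
  masses <- function(free_sd) {
    sd_left <- if (right_skewed) anchor_sd else free_sd
    sd_right <- if (right_skewed) free_sd else anchor_sd
    bin_mass_from_cdf(
      function(x) peak_split_cdf(x, mode_bp, sd_left, sd_right, peak_sd, peak_weight),
      k
    )
  }
  med_err <- function(free_sd) {
    m <- masses(free_sd)
    mass_quantile(k, m / sum(m), 0.5) - median_bp
  }
  ## The binned median is not monotone in the free width (support truncation
  ## eventually pushes mass back towards the peak), so bracket on a grid and
  ## root-find on the first sign change, i.e. the least-truncated branch.
  grid <- exp(seq(log(5), log(20000), length.out = 120))
  errs <- vapply(grid, med_err, numeric(1))
  flip <- which(errs[-1] * errs[-length(errs)] <= 0)
  if (length(flip) == 0) {
    stop("kernel calibration failed: target median unreachable on this support",
         call. = FALSE)
  }
  sol <- stats::uniroot(med_err, interval = grid[c(flip[1], flip[1] + 1)], tol = 1e-10)
  m <- masses(sol$root)
  kern <- binding_kernel(
    k, m,
    params = list(
      family = "peak+split-normal", mode_bp = mode_bp, median_bp = median_bp,
      peak_sd = peak_sd, peak_weight = peak_weight, anchor_sd = anchor_sd,
      solved_sd = sol$root, right_skewed = right_skewed
    )
  )
  st <- profile_stats(kern$mass, k = k)
  if (abs(st$peak_bp - mode_bp) > 1e-8) {
    stop(sprintf(
      "calibration failed: binned peak %g bp != target mode %g bp", st$peak_bp, mode_bp
    ), call. = FALSE)
  }
  kern
}

#' Calibrate a Gaussian kernel to target central-95% bounds
#'
#' Used for the repair-template RPA kernel, which straddles the break site:
#' a Gaussian whose binned 2.5% and 97.5% mass quantiles (after truncation
#' to the kernel support) match the requested bounds.
#'
#' @param q_lo,q_hi target 2.5% and 97.5% quantiles in bp.
#' @param k bin index support.
#' @return a [binding_kernel()].
#' @export
calibrate_gaussian_kernel <- function(q_lo = -560, q_hi = 740, k = -50:125) {
  stopifnot(q_hi > q_lo)
  masses <- function(mu, sd) {
    bin_mass_from_cdf(function(x) stats::pnorm(x, mu, sd), k)
  }
  objective <- function(par) {
    m <- masses(par[1], exp(par[2]))
    m <- m / sum(m)
    (mass_quantile(k, m, 0.025) - q_lo)^2 + (mass_quantile(k, m, 0.975) - q_hi)^2
  }
  start <- c((q_lo + q_hi) / 2, log((q_hi - q_lo) / (2 * 1.96)))
  fit <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  m <- masses(fit$par[1], exp(fit$par[2]))
  binding_kernel(
    k, m,
    params = list(family = "gaussian", mu = fit$par[1], sd = exp(fit$par[2]),
                  q_lo = q_lo, q_hi = q_hi)
  )
}

#' Default binding kernels for DMC1, RAD51 and repair-template RPA
#'
#' The defaults are calibrated so their binned summary statistics equal the
#' hallmark positions of each protein's binding profile relative to the DSB:
#' DMC1 peaks 80 bp from the break with median 420 bp; RAD51 peaks at 860 bp
#' with median 800 bp; repair-template RPA straddles the break with its
#' central 95% of mass between -560 and +740 bp.
#'
#' @return named list of [binding_kernel()] objects
#'   (`dmc1`, `rad51`, `rpa_template`).
#' @export
default_kernels <- function() {
  list(
    dmc1 = calibrate_kernel(80, 420, peak_sd = 50, peak_weight = 0.25,
                            anchor_sd = 100),
    rad51 = calibrate_kernel(860, 800, peak_sd = 150, peak_weight = 0.25,
                             anchor_sd = 450),
    rpa_template = calibrate_gaussian_kernel(-560, 740)
  )
}
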
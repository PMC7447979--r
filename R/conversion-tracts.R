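#' Crossover breakpoint probability map from SNP-censored intervals
#'
#' A crossover's breakpoint is only known to lie between its two
#' informative SNPs.  Each crossover contributes total mass 1, split
#' equally over the inter-SNP intervals formed by the internal SNP grid
#' between the informative pair (a crossover with no internal SNPs is a
#' single interval), uniformly per bp within each interval.  Events are
#' aggregated on a 1-bp grid of positions relative to the motif centre.
#'
#' @param crossovers data.frame with columns `center`, `snp_left`,
#'   `snp_right` and a list column `internal_snps` (absolute coordinates),
#'   as produced by [simulate_outcomes()]; alternatively positions already
#'   relative to the centre with `center = 0`.
#' @param window half-width of the map in bp (default 2000).  Intervals
#'   reaching beyond the window are clipped with a warning.
#' @param equal_per_interval if TRUE (default) each inter-SNP interval gets
#'   equal mass; if FALSE mass is uniform per bp across the whole censored
#'   region.
#' @return object of class `breakpoint_map`: list with `x` (1-bp cell start
#'   positions, `-window..window-1`), `mass` (probability mass per cell),
#'   `n_events`, `clipped_mass`.
#' @export
breakpoint_probability_map <- function(crossovers, window = 2000,
                                       equal_per_interval = TRUE) {
  stopifnot(all(c("center", "snp_left", "snp_right") %in% names(crossovers)))
  x <- -window:(window - 1)
  delta <- numeric(2 * window + 1)
  clipped <- 0
  n <- nrow(crossovers)
  internal <- if ("internal_snps" %in% names(crossovers)) {
    crossovers$internal_snps
  } else {
    rep(list(numeric(0)), n)
  }
  add_uniform <- function(delta, a, b, h) {
    ## add h per bp on cells [a, b) in window coordinates (offset + window + 1)
    a2 <- max(a, -window); b2 <- min(b, window)
    if (b2 <= a2) return(list(delta = delta, lost = h * (b - a)))
    ia <- a2 + window + 1L; ib <- b2 + window + 1L
    delta[ia] <- delta[ia] + h
    delta[ib] <- delta[ib] - h
    list(delta = delta, lost = h * ((b - a) - (b2 - a2)))
  }
  for (i in seq_len(n)) {
    cen <- crossovers$center[i]
    bounds <- sort(unique(round(
      c(crossovers$snp_left[i], internal[[i]], crossovers$snp_right[i]) - cen
    )))
    n_int <- length(bounds) - 1L
    if (n_int < 1) next
    if (equal_per_interval) {
      for (q in seq_len(n_int)) {
        len <- bounds[q + 1] - bounds[q]
        res <- add_uniform(delta, bounds[q], bounds[q + 1], (1 / n_int) / len)
        delta <- res$delta; clipped <- clipped + res$lost
      }
    } else {
      len <- bounds[n_int + 1] - bounds[1]
      res <- add_uniform(delta, bounds[1], bounds[n_int + 1], 1 / len)
      delta <- res$delta; clipped <- clipped + res$lost
    }
  }
  if (clipped > 1e-9) {
    warning(sprintf("%.3g units of breakpoint mass fell outside +/-%d bp and were clipped",
                    clipped, window))
  }
  structure(
    list(x = x, mass = cumsum(delta)[seq_along(x)], n_events = n,
         clipped_mass = clipped),
    class = "breakpoint_map"
  )
}

#' @export
print.breakpoint_map <- function(x, ...) {
  cat(sprintf("<breakpoint_map> %d events, mass %.4g on [%d, %d) bp\n",
              x$n_events, sum(x$mass), min(x$x), max(x$x) + 1))
  invisible(x)
}

#' Bin a 1-bp map onto the 20-bp deconvolution grid
#'
#' Cell `[x, x+1)` (midpoint `x + 0.5`) is assigned to the 20-bp bin
#' covering its midpoint.
#'
#' @param map a `breakpoint_map` or similar list with `x` and `mass`.
#' @return list with `j` (bin indices) and `mass` per bin.
#' @export
bin_map <- function(map) {
  mid <- map$x + 0.5
  l <- floor(mid / 20 + 0.5)
  j <- min(l):max(l)
  mass <- vapply(j, function(b) sum(map$mass[l == b]), numeric(1))
  list(j = j, mass = mass)
}

#' Deconvolve a motif-centred map to DSB-relative coordinates
#'
#' Bins the map to the 20-bp grid and applies the single-track
#' pseudoinverse solve of [deconvolve_single()].
#'
#' @param map a `breakpoint_map` (or binned list from [bin_map()]).
#' @param s SPO11 [offset_distribution()].
#' @param tol relative singular-value tolerance (default 0.2).
#' @param k binding offset bins.
#' @return `breakpoint_map`-like list on the 20-bp grid relative to the
#'   DSB: `k`, `bp`, `mass`.
#' @export
deconvolve_map <- function(map, s, tol = 0.2, k = -50:125) {
  binned <- if (!is.null(map$j)) map else bin_map(map)
  b <- deconvolve_single(binned$mass, s, tol = tol, k = k, j = binned$j)
  list(k = k, bp = 20 * k, mass = b)
}

#' Tract-containment probability from a breakpoint map
#'
#' Under the assumption that every gene-conversion tract overlaps its DSB
#' site, a breakpoint at distance `d` implies a tract covering all
#' positions between 0 and `d` (inclusive).  The probability that position
#' `x` lies within a tract is therefore the total breakpoint mass at or
#' beyond `x` on `x`'s side of the break; at `x = 0` it equals the total
#' mass.
#'
#' @param positions grid positions (bp relative to the DSB).
#' @param mass breakpoint mass per position (nonnegative).
#' @param normalize divide by total mass to give a unit-area comparison
#'   profile (default FALSE).
#' @return object of class `tract_map`: list with `positions` and
#'   `containment`.
#' @export
tract_containment <- function(positions, mass, normalize = FALSE) {
  stopifnot(length(positions) == length(mass), all(mass >= 0))
  ord <- order(positions)
  pos <- positions[ord]; m <- mass[ord]
  total <- sum(m)
  ## mass at or beyond x, on x's side of the break
  right_tail <- rev(cumsum(rev(m * (pos > 0))))
  left_tail <- cumsum(m * (pos < 0))
  cont <- ifelse(pos > 0, right_tail, ifelse(pos < 0, left_tail, total))
  if (normalize) {
    area <- sum(cont)
    if (area > 0) cont <- cont / area
  }
  out <- numeric(length(mass))
  out[ord] <- cont
  structure(list(positions = positions, containment = out,
                 normalized = normalize),
            class = "tract_map")
}

#' @export
print.tract_map <- function(x, ...) {
  cat(sprintf("<tract_map> %d positions, containment at 0 = %.4g\n",
              length(x$positions),
              x$containment[which.min(abs(x$positions))]))
  invisible(x)
}

#' Non-crossover gene-conversion tract map
#'
#' Each non-crossover contributes total mass 1 spread uniformly over its
#' minimal converted segment (a single converted SNP is a point mass at
#' that SNP), regardless of tract length or resolution.  The aggregate
#' per-bp map is smoothed with a moving average, binned to 20 bp, and
#' deconvolved to DSB-relative coordinates.
#'
#' @param ncos data.frame with `center`, `start`, `end` (absolute bp).
#' @param s SPO11 [offset_distribution()].
#' @param window map half-width in bp (default 2000); NCOs whose tract
#'   midpoint is farther than this from the centre are excluded and
#'   counted.
#' @param smooth moving-average window in bp (default 100).
#' @param tol deconvolution tolerance.
#' @return list with `map` (per-bp `breakpoint_map`-like, smoothed),
#'   `deconvolved` (20-bp grid relative to DSB), `n_used`, `n_excluded`.
#' @export
nco_tract_map <- function(ncos, s, window = 2000, smooth = 100, tol = 0.2) {
  stopifnot(all(c("center", "start", "end") %in% names(ncos)))
  x <- -window:(window - 1)
  mass <- numeric(length(x))
  n_excluded <- 0L
  for (i in seq_len(nrow(ncos))) {
    a <- round(ncos$start[i] - ncos$center[i])
    b <- round(ncos$end[i] - ncos$center[i])
    if ((a + b) / 2 < -window || (a + b) / 2 > window) {
      n_excluded <- n_excluded + 1L
      next
    }
    if (b <= a) {
      ## single-SNP tract: point mass at the SNP's 1-bp cell
      ia <- min(max(a, -window), window - 1) + window + 1L
      mass[ia] <- mass[ia] + 1
    } else {
      a2 <- max(a, -window); b2 <- min(b, window)
      idx <- (a2 + window + 1L):(b2 + window)
      mass[idx] <- mass[idx] + 1 / (b - a)
    }
  }
  sm <- moving_average(mass, max(1L, round(smooth)))
  map <- list(x = x, mass = sm, n_events = nrow(ncos) - n_excluded)
  list(
    map = structure(map, class = "breakpoint_map"),
    deconvolved = deconvolve_map(map, s, tol = tol),
    n_used = nrow(ncos) - n_excluded,
    n_excluded = n_excluded
  )
}
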
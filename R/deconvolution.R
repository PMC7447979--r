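#' Bin signed DSB offsets into the 20-bp SPO11 grid
#'
#' Offset `x` (bp from the hotspot centre) is assigned to bin `l` iff
#' `20(l - 1/2) <= x < 20(l + 1/2)` (lower-closed).  Offsets falling beyond
#' `+/- 20(m + 1/2)` are not binned; they are counted into an overflow tally
#' reported on the result.
#'
#' @param offsets numeric vector of signed offsets in bp.
#' @param m half-width of the grid in bins (bins `-m..m`).
#' @return an `offset_distribution`: list with `l` (bin indices), `counts`
#'   and `overflow` (number of out-of-range offsets).
#' @export
bin_offsets <- function(offsets, m = 50) {
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  l <- floor(offsets / 20 + 0.5)
  inside <- l >= -m & l <= m
  counts <- tabulate(l[inside] + m + 1L, nbins = 2L * m + 1L)
  offset_distribution(counts, m = m, overflow = sum(!inside))
}

#' SPO11-oligo offset distribution container
#'
#' @param counts nonnegative per-bin counts for bins `-m..m`.
#' @param m half-width in bins; inferred from `counts` when `NULL`.
#' @param overflow count of offsets that fell outside the grid.
#' @export
offset_distribution <- function(counts, m = NULL, overflow = 0L) {
  if (is.null(m)) {
    if (length(counts) %% 2 != 1) {
      stop("`counts` must have odd length (bins -m..m)", call. = FALSE)
    }
    m <- (length(counts) - 1L) %/% 2L
  }
  if (length(counts) != 2L * m + 1L) {
    stop("`counts` must have length 2*m + 1", call. = FALSE)
  }
  if (any(counts < 0)) stop("offset counts must be nonnegative", call. = FALSE)
  if (sum(counts) <= 0) stop("offset distribution must have positive total", call. = FALSE)
  structure(list(l = -m:m, m = as.integer(m), counts = as.numeric(counts),
                 overflow = as.integer(overflow)),
            class = "offset_distribution")
}

#' @export
print.offset_distribution <- function(x, ...) {
  cat(sprintf("<offset_distribution> bins -%d..%d (20 bp), total %g, overflow %d\n",
              x$m, x$m, sum(x$counts), x$overflow))
  invisible(x)
}

#' Flank-based background correction of a strand profile
#'
#' Subtracts, per strand, the mean coverage in a distal flank: for the Crick
#' strand the mean between `flank[1]` and `flank[2]` bp to the *left* of the
#' hotspot centre, and for the Watson strand the same distance to the right.
#' Negative corrected values are set to zero.
#'
#' @param profile a [strand_profile()].
#' @param flank numeric length-2, distances in bp defining the background
#'   window (default 4000-5000 bp).
#' @return a background-corrected [strand_profile()].
#' @export
background_correct <- function(profile, flank = c(4000, 5000)) {
  stopifnot(inherits(profile, "strand_profile"), length(flank) == 2, flank[1] < flank[2])
  sp <- span_bp(profile)
  if (sp[1] > -flank[2] || sp[2] < flank[2]) {
    stop(sprintf("profile span must cover +/-%g bp for background correction; have [%g, %g]",
                 flank[2], sp[1], sp[2]), call. = FALSE)
  }
  left <- profile$bp >= -flank[2] & profile$bp <= -flank[1]
  right <- profile$bp >= flank[1] & profile$bp <= flank[2]
  crick <- pmax(profile$crick - mean(profile$crick[left]), 0)
  watson <- pmax(profile$watson - mean(profile$watson[right]), 0)
  out <- profile
  out$crick <- crick
  out$watson <- watson
  out$background_corrected <- TRUE
  out
}

#' Toeplitz transform matrix of an offset distribution
#'
#' Row `j` (coverage bin), column `k` (binding offset bin): entry
#' `t[j, k] = s[j - k]`, the SPO11-oligo count `j - k` bins from the hotspot
#' centre (zero outside the offset grid).
#'
#' @param s an [offset_distribution()].
#' @param j integer coverage bin indices (rows).
#' @param k integer binding offset bin indices (columns), default `-50:125`.
#' @return numeric matrix `length(j)` x `length(k)`.
#' @export
transform_matrix <- function(s, j, k = -50:125) {
  stopifnot(inherits(s, "offset_distribution"))
  lag <- outer(j, k, "-")
  tm <- matrix(0, nrow = length(j), ncol = length(k))
  inside <- lag >= -s$m & lag <= s$m
  tm[inside] <- s$counts[lag[inside] + s$m + 1L]
  tm
}

solve_pseudoinverse <- function(tm, coverage, tol) {
  if (all(tm == 0)) stop("transform matrix has rank 0 (all-zero offsets in range)",
                         call. = FALSE)
  as.numeric(MASS::ginv(tm, tol = tol) %*% coverage)
}

#' Deconvolve strand coverage into binding relative to the DSB site
#'
#' Inverts the convolution of the (unknown) binding profile with the DSB
#' offset distribution: for the Crick strand the model is
#' `c[j] = sum_k s[j - k] * b[k]`, solved over `k` in `-50..125` (-1000 to
#' +2500 bp from the break) by least squares using a Moore-Penrose
#' pseudoinverse in which singular values below `tol` times the largest
#' singular value are discarded.  The Watson strand is mirrored into Crick
#' polarity (position x -> -x) before solving, so that positive `k` always
#' points along the 3' ssDNA overhang.  The two strand solutions are
#' returned separately together with their average.
#'
#' @param crick,watson background-corrected per-bin coverage.  Either a
#'   single [strand_profile()] passed as `crick` (with `watson` missing), or
#'   two numeric vectors on bins `j`.
#' @param s an [offset_distribution()].
#' @param tol relative singular-value tolerance (default 0.2).
#' @param k binding offset bins (default `-50:125`).
#' @param j coverage bin indices; required when `crick` is a bare vector.
#' @return object of class `deconvolved_profile`: list with `k`, `bp`,
#'   `b_crick`, `b_watson`, `b_mean`, `tol`.  Small negative values are
#'   regularisation artifacts and are kept in the raw solution; use
#'   [clamp_profile()] for a nonnegative view.
#' @export
deconvolve <- function(crick, watson = NULL, s, tol = 0.2, k = -50:125, j = NULL) {
  if (inherits(crick, "strand_profile")) {
    prof <- crick
    j <- prof$j
    crick <- prof$crick
    watson <- prof$watson
  }
  stopifnot(!is.null(j), length(crick) == length(j), length(watson) == length(j))
  tm <- transform_matrix(s, j = j, k = k)
  b_crick <- solve_pseudoinverse(tm, crick, tol)
  ## Watson coverage at +x corresponds to Crick-polarity coverage at -x.
  mirrored <- watson[match(-j, j)]
  if (any(is.na(mirrored))) {
    stop("coverage bins must be symmetric around 0 to mirror the Watson strand",
         call. = FALSE)
  }
  b_watson <- solve_pseudoinverse(tm, mirrored, tol)
  structure(
    list(k = as.integer(k), bp = 20 * k, b_crick = b_crick, b_watson = b_watson,
         b_mean = (b_crick + b_watson) / 2, tol = tol),
    class = "deconvolved_profile"
  )
}

#' Deconvolve a single (strand-less) track
#'
#' Same solver as [deconvolve()] but for a single aggregated map, e.g. a
#' crossover-breakpoint probability map on motif-centred coordinates.
#'
#' @param coverage numeric per-bin values on bins `j`.
#' @param s an [offset_distribution()].
#' @param tol relative singular-value tolerance.
#' @param k,j binding and coverage bins.
#' @return numeric vector of binding mass on bins `k`.
#' @export
deconvolve_single <- function(coverage, s, tol = 0.2, k = -50:125, j = NULL) {
  if (is.null(j)) {
    if (length(coverage) %% 2 != 1) stop("give `j` for even-length coverage", call. = FALSE)
    m <- (length(coverage) - 1L) %/% 2L
    j <- -m:m
  }
  tm <- transform_matrix(s, j = j, k = k)
  solve_pseudoinverse(tm, coverage, tol)
}

#' @export
print.deconvolved_profile <- function(x, ...) {
  st <- tryCatch(profile_stats(x), error = function(e) NULL)
  cat(sprintf("<deconvolved_profile> k %d..%d, tol %g", min(x$k), max(x$k), x$tol))
  if (!is.null(st)) {
    cat(sprintf(", peak %g bp, median %g bp", st$peak_bp, st$median_bp))
  }
  cat("\n")
  invisible(x)
}

#' Nonnegative view of a deconvolved profile
#'
#' @param b a `deconvolved_profile` or numeric vector.
#' @param which which strand solution to clamp (`"mean"`, `"crick"`,
#'   `"watson"`).
#' @return numeric vector with negatives set to zero.
#' @export
clamp_profile <- function(b, which = c("mean", "crick", "watson")) {
  which <- match.arg(which)
  v <- if (inherits(b, "deconvolved_profile")) {
    switch(which, mean = b$b_mean, crick = b$b_crick, watson = b$b_watson)
  } else {
    as.numeric(b)
  }
  pmax(v, 0)
}

#' Interpolated mass quantile of a binned profile
#'
#' Mass within each 20-bp bin is treated as uniform over
#' `[20(k - 1/2), 20(k + 1/2))`; the quantile is found by linear
#' interpolation within the bin where the cumulative mass crosses `p`.
#'
#' @param k integer bin indices.
#' @param mass nonnegative per-bin mass.
#' @param p probability in (0, 1); vectorised.
#' @return quantile position(s) in bp.
#' @export
mass_quantile <- function(k, mass, p) {
  stopifnot(length(k) == length(mass), all(mass >= 0))
  total <- sum(mass)
  if (total <= 0) stop("profile has zero mass", call. = FALSE)
  cum <- cumsum(mass)
  vapply(p, function(pp) {
    target <- pp * total
    i <- which(cum >= target - 1e-12 * total)[1]
    prev <- if (i == 1) 0 else cum[i - 1]
    lo <- 20 * (k[i] - 0.5)
    lo + 20 * (target - prev) / mass[i]
  }, numeric(1))
}

#' Summary statistics of a binding profile
#'
#' Peak is the midpoint of the maximum bin (ties broken towards the smallest
#' `|bp|`); median and central-95% bounds are interpolated mass quantiles.
#' Negative values (deconvolution artifacts) are clamped to zero before the
#' statistics are computed.
#'
#' @param b a `deconvolved_profile`, [binding_kernel()] or numeric vector.
#' @param k bin indices; taken from the object when available.
#' @param which strand solution used for a `deconvolved_profile`
#'   (default `"mean"`).
#' @return list with `peak_bp`, `median_bp`, `central95` (length-2).
#' @export
profile_stats <- function(b, k = NULL, which = c("mean", "crick", "watson")) {
  which <- match.arg(which)
  if (inherits(b, "deconvolved_profile")) {
    k <- b$k
    b <- switch(which, mean = b$b_mean, crick = b$b_crick, watson = b$b_watson)
  } else if (inherits(b, "binding_kernel")) {
    k <- b$k
    b <- b$mass
  }
  if (is.null(k)) stop("give `k` for a bare numeric profile", call. = FALSE)
  mass <- pmax(as.numeric(b), 0)
  if (sum(mass) <= 0) stop("profile has zero mass", call. = FALSE)
  is_max <- abs(mass - max(mass)) <= 1e-9 * max(mass)
  peak_k <- k[is_max][which.min(abs(k[is_max]))]
  q <- mass_quantile(k, mass, c(0.025, 0.5, 0.975))
  list(peak_bp = 20 * peak_k, median_bp = q[2], central95 = c(q[1], q[3]))
}
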
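#' Half-signal point of a hotspot's coverage
#'
#' Scans the strand-summed coverage from left to right within
#' `+/- window` bp of the centre and returns `m`, the position at which the
#' running total first reaches 50% of the window total.  By default `m` is
#' the midpoint of the bin where the crossing happens (so a run of discrete
#' per-bin counts yields the bin position itself); `interpolate = TRUE`
#' instead spreads each bin's mass uniformly over the bin and returns the
#' exact crossing coordinate.
#'
#' @param profile a [strand_profile()] (strands are summed), or a numeric
#'   vector of per-bin coverage with bins `j`.
#' @param window half-width of the scan window in bp (default 5000).
#' @param interpolate use uniform-within-bin interpolation (default FALSE).
#' @param strand `"both"` (default), `"crick"` or `"watson"`.
#' @param j bin indices when `profile` is a bare vector.
#' @param bin_width bin width in bp for a bare vector.
#' @return `m` in bp relative to the hotspot centre; `NA` when the window
#'   holds no coverage (hotspot excluded downstream).
#' @export
half_signal_point <- function(profile, window = 5000, interpolate = FALSE,
                              strand = c("both", "crick", "watson"),
                              j = NULL, bin_width = 20) {
  strand <- match.arg(strand)
  if (inherits(profile, "strand_profile")) {
    x <- switch(strand,
      both = profile$crick + profile$watson,
      crick = profile$crick,
      watson = profile$watson
    )
    bp <- profile$bp
    bin_width <- profile$bin_width
  } else {
    stopifnot(!is.null(j), length(j) == length(profile))
    x <- as.numeric(profile)
    bp <- bin_width * j
  }
  inside <- abs(bp) <= window
  x <- x[inside]; bp <- bp[inside]
  total <- sum(x)
  if (total <= 0) return(NA_real_)
  cum <- cumsum(x)
  half <- total / 2
  i <- which(cum >= half - 1e-9 * total)[1]
  if (!interpolate) return(bp[i])
  prev <- if (i == 1) 0 else cum[i - 1]
  (bp[i] - bin_width / 2) + bin_width * (half - prev) / x[i]
}

#' Skew label from a half-signal point
#'
#' @param m half-signal position(s), bp relative to the centre.
#' @param threshold skew threshold in bp (default 150): a hotspot is skewed
#'   when `m` lies more than `threshold` bp from the centre.
#' @return factor with levels `left`, `balanced`, `right` (`NA` in, `NA`
#'   out).
#' @export
classify_skew <- function(m, threshold = 150) {
  out <- ifelse(is.na(m), NA_character_,
         ifelse(m < -threshold, "left",
         ifelse(m > threshold, "right", "balanced")))
  factor(out, levels = c("left", "balanced", "right"))
}

#' Mirror a strand profile around the hotspot centre
#'
#' Reflects coordinates (`x -> -x`) and swaps the Watson and Crick strands,
#' which is the coverage-level image of reversing a hotspot's orientation.
#' Applying it twice is the identity.
#'
#' @param profile a [strand_profile()].
#' @return the mirrored [strand_profile()].
#' @export
mirror_profile <- function(profile) {
  stopifnot(inherits(profile, "strand_profile"))
  if (!all(sort(profile$j) == sort(-profile$j))) {
    stop("bins must be symmetric around 0 to mirror", call. = FALSE)
  }
  out <- profile
  out$crick <- rev(profile$watson)
  out$watson <- rev(profile$crick)
  out
}

#' Classify hotspot skew and co-orient a coverage set
#'
#' Computes the half-signal point and skew label for every hotspot, then
#' mirrors right-skewed hotspots (swap strands, reflect coordinates) so
#' that all skewed hotspots carry their excess signal on the left; the
#' returned flip flags let linked per-hotspot tracks (SPO11, crossovers,
#' non-crossovers, SNPs) be reflected consistently via
#' [orient_positions()].
#'
#' @param covset a [coverage_set()].
#' @param threshold skew threshold in bp (default 150).
#' @param window half-signal scan window in bp.
#' @param min_spacing inclusion rule: hotspots closer than this to their
#'   nearest neighbour (from the attached hotspot table) are labelled `NA`
#'   and not oriented (default 8000 bp).
#' @param interpolate passed to [half_signal_point()].
#' @return list with `calls` (data.frame `hotspot_id`, `m`, `label`,
#'   `flipped`, `included`) and `oriented` (the co-oriented
#'   [coverage_set()]).
#' @export
classify_and_orient <- function(covset, threshold = 150, window = 5000,
                                min_spacing = 8000, interpolate = FALSE) {
  stopifnot(inherits(covset, "coverage_set"))
  n <- nrow(covset$crick)
  included <- rep(TRUE, n)
  if (!is.null(covset$hotspots) && n > 1) {
    cen <- covset$hotspots$center
    nn <- vapply(seq_len(n), function(i) min(abs(cen[-i] - cen[i])), numeric(1))
    included <- nn >= min_spacing
  }
  m <- vapply(seq_len(n), function(i) {
    half_signal_point(profile_at(covset, i), window = window,
                      interpolate = interpolate)
  }, numeric(1))
  label <- classify_skew(m, threshold)
  label[!included] <- NA
  flip <- !is.na(label) & label == "right"
  oriented <- covset
  for (i in which(flip)) {
    oriented$crick[i, ] <- rev(covset$watson[i, ])
    oriented$watson[i, ] <- rev(covset$crick[i, ])
  }
  list(
    calls = data.frame(
      hotspot_id = if (!is.null(covset$hotspots)) covset$hotspots$hotspot_id
                   else seq_len(n),
      m = m, label = label, flipped = flip, included = included
    ),
    oriented = oriented
  )
}

#' Reflect linked track positions for co-oriented hotspots
#'
#' @param positions genomic or centre-relative positions.
#' @param center hotspot centre (0 for centre-relative positions).
#' @param flipped logical: whether this hotspot was mirrored.
#' @return positions with flipped hotspots reflected around the centre.
#' @export
orient_positions <- function(positions, center = 0, flipped = TRUE) {
  ifelse(rep_len(flipped, length(positions)), 2 * center - positions, positions)
}

#' Exact binomial test of left/right skew balance
#'
#' Two-sided exact binomial test (minimum-likelihood method, as in
#' [stats::binom.test()]) of whether left- and right-skewed hotspots are
#' equally frequent.
#'
#' @param n_left,n_right counts of left- and right-skewed hotspots.
#' @return p-value.
#' @export
side_balance_test <- function(n_left, n_right) {
  stopifnot(n_left >= 0, n_right >= 0, n_left + n_right > 0)
  stats::binom.test(n_left, n_left + n_right, p = 0.5)$p.value
}
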
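#' Distance from a focus to the nearest chromosome axis
#'
#' Minimum Euclidean distance from the point to any segment of the axis
#' polylines (matching a distance-map lookup on segmented axis signal).
#'
#' @param x,y focus coordinates in nm.
#' @param axes data.frame of axis vertices with columns `axis_id`,
#'   `vertex`, `x`, `y` (each axis a polyline of >= 2 ordered vertices).
#' @return distance in nm.
#' @export
distance_to_axis <- function(x, y, axes) {
  if (is.null(axes) || nrow(axes) == 0) stop("empty axis set", call. = FALSE)
  dmin <- Inf
  for (id in unique(axes$axis_id)) {
    v <- axes[axes$axis_id == id, ]
    v <- v[order(v$vertex), ]
    if (nrow(v) < 2) stop("axis polyline needs >= 2 vertices", call. = FALSE)
    for (si in seq_len(nrow(v) - 1)) {
      dmin <- min(dmin, point_segment_distance(
        x, y, v$x[si], v$y[si], v$x[si + 1], v$y[si + 1]
      ))
    }
  }
  dmin
}

point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- if (len2 <= 0) 0 else pmin(pmax(((px - ax) * vx + (py - ay) * vy) / len2, 0), 1)
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

#' Axis distances for a table of foci
#'
#' @param foci data.frame with `cell_id`, `x`, `y` (and typically
#'   `channel`).
#' @param axes data.frame with `cell_id`, `axis_id`, `vertex`, `x`, `y`.
#' @return `foci` with an added `axis_distance` column (nm).
#' @export
foci_axis_distances <- function(foci, axes) {
  stopifnot(all(c("cell_id", "x", "y") %in% names(foci)),
            all(c("cell_id", "axis_id", "vertex", "x", "y") %in% names(axes)))
  foci$axis_distance <- vapply(seq_len(nrow(foci)), function(i) {
    ax <- axes[axes$cell_id == foci$cell_id[i], ]
    distance_to_axis(foci$x[i], foci$y[i], ax)
  }, numeric(1))
  foci
}

#' Pair co-foci between two channels
#'
#' For every focus, the nearest focus of the opposite channel (within the
#' same cell) is found; a focus is part of a co-focus when that distance is
#' at or below `threshold`.  Offsets are the nearest-neighbour distances of
#' the flagged foci.
#'
#' @param foci_a,foci_b data.frames with `x`, `y` (single cell, or sharing
#'   one `cell_id`).
#' @param threshold co-focus distance threshold in nm (default 300).
#' @return list with `fraction_a`, `fraction_b` (co-focus fractions per
#'   channel), `offsets_a`, `offsets_b` (nearest-neighbour distances of
#'   flagged foci, nm), `nearest_a`, `nearest_b` (all nearest distances).
#' @export
pair_cofoci <- function(foci_a, foci_b, threshold = 300) {
  stopifnot(threshold >= 0)
  nn <- function(from, to) {
    if (nrow(to) == 0) return(rep(Inf, nrow(from)))
    vapply(seq_len(nrow(from)), function(i) {
      min(sqrt((to$x - from$x[i])^2 + (to$y - from$y[i])^2))
    }, numeric(1))
  }
  da <- nn(foci_a, foci_b)
  db <- nn(foci_b, foci_a)
  co_a <- da <= threshold
  co_b <- db <= threshold
  list(
    fraction_a = if (nrow(foci_a) > 0) mean(co_a) else 0,
    fraction_b = if (nrow(foci_b) > 0) mean(co_b) else 0,
    offsets_a = da[co_a], offsets_b = db[co_b],
    nearest_a = da, nearest_b = db
  )
}

#' Per-cell co-focus analysis over a focus table
#'
#' @param foci data.frame with `cell_id`, `channel`, `x`, `y`.
#' @param channels length-2 character: the two channels to pair.
#' @param threshold co-focus threshold in nm.
#' @return list with pooled `fraction_a`, `fraction_b`, `offsets` (pooled
#'   flagged nearest-neighbour distances) and `median_offset`.
#' @export
cofoci_summary <- function(foci, channels = c("RAD51", "DMC1"), threshold = 300) {
  offs <- numeric(0); na_co <- 0L; na_tot <- 0L; nb_co <- 0L; nb_tot <- 0L
  for (cell in unique(foci$cell_id)) {
    fc <- foci[foci$cell_id == cell, ]
    a <- fc[fc$channel == channels[1], ]
    b <- fc[fc$channel == channels[2], ]
    pr <- pair_cofoci(a, b, threshold)
    na_co <- na_co + sum(pr$nearest_a <= threshold); na_tot <- na_tot + nrow(a)
    nb_co <- nb_co + sum(pr$nearest_b <= threshold); nb_tot <- nb_tot + nrow(b)
    offs <- c(offs, pr$offsets_a, pr$offsets_b)
  }
  list(
    fraction_a = if (na_tot > 0) na_co / na_tot else 0,
    fraction_b = if (nb_tot > 0) nb_co / nb_tot else 0,
    offsets = offs,
    median_offset = if (length(offs) > 0) stats::median(offs) else NA_real_
  )
}

#' Compare axis proximity of two focus channels
#'
#' Medians of the two axis-distance samples and a Welch two-sample t-test
#' of their difference.
#'
#' @param distances_a,distances_b axis distances (nm), each of length >= 2.
#' @return list with `median_a`, `median_b`, `t`, `p`.
#' @export
axis_proximity_compare <- function(distances_a, distances_b) {
  if (length(distances_a) < 2 || length(distances_b) < 2) {
    stop("each sample needs >= 2 distances", call. = FALSE)
  }
  tt <- tryCatch(stats::t.test(distances_a, distances_b),
                 error = function(e) NULL)
  if (is.null(tt)) {
    warning("degenerate variance: t-test undefined")
    tt <- list(statistic = NA_real_, p.value = NaN)
  }
  list(
    median_a = stats::median(distances_a),
    median_b = stats::median(distances_b),
    t = unname(tt$statistic),
    p = tt$p.value
  )
}

#' Uniformity test of off-axis focus distances
#'
#' Distances of randomly scattered (background) points to the nearest point
#' on a line are uniform; this tests the observed distances beyond `cutoff`
#' against a uniform distribution on `(cutoff, field_extent]` with a
#' one-sample Kolmogorov-Smirnov test.
#'
#' @param distances axis distances in nm.
#' @param cutoff only distances strictly greater than this are tested
#'   (default 450 nm).
#' @param field_extent upper bound of the achievable distance (nm).
#' @return list with `p`, `statistic`, `n`.
#' @export
offaxis_uniformity <- function(distances, cutoff = 450, field_extent) {
  stopifnot(field_extent > cutoff)
  d <- distances[distances > cutoff]
  if (length(d) < 10) {
    stop(sprintf("need >= 10 distances beyond the %g nm cutoff (have %d)",
                 cutoff, length(d)), call. = FALSE)
  }
  ks <- stats::ks.test(d, "punif", min = cutoff, max = field_extent)
  list(p = ks$p.value, statistic = unname(ks$statistic), n = length(d))
}
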
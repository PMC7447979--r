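#' Strand-specific binned coverage around a hotspot centre
#'
#' Container for hotspot-centred coverage of one protein on the two DNA
#' strands.  Bin `j` covers `[20(j - 1/2), 20(j + 1/2))` bp relative to the
#' hotspot centre (the midpoint of the PRDM9 motif).
#'
#' @param crick,watson nonnegative per-bin coverage, equal length.
#' @param j integer bin indices; default symmetric around 0.
#' @param bin_width bin width in bp (20 by default, as everywhere in the
#'   package).
#' @param origin genomic coordinate of the hotspot centre (0 for synthetic
#'   or aggregated profiles).
#' @param background_corrected logical flag set by [background_correct()].
#' @return object of class `strand_profile`.
#' @export
strand_profile <- function(crick, watson, j = NULL, bin_width = 20, origin = 0,
                           background_corrected = FALSE) {
  if (length(crick) != length(watson)) {
    stop("`crick` and `watson` must have identical binning", call. = FALSE)
  }
  if (is.null(j)) {
    if (length(crick) %% 2 != 1) {
      stop("cannot infer symmetric bins from even-length coverage; give `j`",
           call. = FALSE)
    }
    m <- (length(crick) - 1L) %/% 2L
    j <- -m:m
  }
  j <- as.integer(j)
  if (length(j) != length(crick)) stop("`j` must match coverage length", call. = FALSE)
  if (any(crick < 0) || any(watson < 0)) {
    stop("coverage must be nonnegative", call. = FALSE)
  }
  structure(
    list(j = j, bp = bin_width * j, bin_width = bin_width, origin = origin,
         crick = as.numeric(crick), watson = as.numeric(watson),
         background_corrected = background_corrected),
    class = "strand_profile"
  )
}

#' @export
print.strand_profile <- function(x, ...) {
  cat(sprintf(
    "<strand_profile> %d bins of %d bp, span %d..%d bp, total crick %.4g / watson %.4g%s\n",
    length(x$j), x$bin_width, min(x$bp), max(x$bp),
    sum(x$crick), sum(x$watson),
    if (isTRUE(x$background_corrected)) " (background-corrected)" else ""
  ))
  invisible(x)
}

span_bp <- function(profile) {
  c(min(profile$bp) - profile$bin_width / 2, max(profile$bp) + profile$bin_width / 2)
}

#' Per-hotspot coverage set
#'
#' Matrix-backed collection of strand profiles sharing one binning: one row
#' per hotspot, one column per bin.  Used by the synthetic generator and by
#' per-hotspot operations (intensity, half-signal point).
#'
#' @param crick,watson numeric matrices (hotspots x bins).
#' @param j integer bin indices (columns).
#' @param hotspots optional `data.frame` of hotspot records (one row each).
#' @param bin_width bin width in bp.
#' @return object of class `coverage_set`.
#' @export
coverage_set <- function(crick, watson, j, hotspots = NULL, bin_width = 20) {
  stopifnot(is.matrix(crick), is.matrix(watson),
            all(dim(crick) == dim(watson)), ncol(crick) == length(j))
  structure(
    list(crick = crick, watson = watson, j = as.integer(j),
         bin_width = bin_width, hotspots = hotspots),
    class = "coverage_set"
  )
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("<coverage_set> %d hotspots x %d bins of %d bp\n",
              nrow(x$crick), ncol(x$crick), x$bin_width))
  invisible(x)
}

#' Extract one hotspot's strand profile from a coverage set
#' @param covset a [coverage_set()].
#' @param i hotspot (row) index.
#' @export
profile_at <- function(covset, i) {
  strand_profile(covset$crick[i, ], covset$watson[i, ], j = covset$j,
                 bin_width = covset$bin_width)
}

#' Sum a coverage set into one aggregate strand profile
#' @param covset a [coverage_set()].
#' @param weights optional per-hotspot weights (default 1).
#' @export
aggregate_coverage <- function(covset, weights = NULL) {
  n <- nrow(covset$crick)
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0))
  strand_profile(
    crick = as.numeric(w %*% covset$crick),
    watson = as.numeric(w %*% covset$watson),
    j = covset$j, bin_width = covset$bin_width
  )
}
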
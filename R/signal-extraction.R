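#' Strand-aware hotspot signal intensity
#'
#' Background-adjusted read mass of one hotspot: after flank background
#' correction, Crick coverage is summed from `hotspot_width / 2` bp left of
#' the centre to `binding_width` bp right of it, and Watson coverage over
#' the mirrored window.  The asymmetric window follows the ssDNA geometry:
#' resection carries each strand's signal predominantly to one side of the
#' break.
#'
#' @param profile a [strand_profile()]; corrected in place here unless
#'   already flagged `background_corrected`.
#' @param hotspot_width width (bp) of the hotspot core (default 500).
#' @param binding_width extent (bp) of binding beyond the centre
#'   (default 2000).
#' @param flank background flank definition passed to
#'   [background_correct()].
#' @return nonnegative signal in read units.
#' @export
hotspot_intensity <- function(profile, hotspot_width = 500, binding_width = 2000,
                              flank = c(4000, 5000)) {
  stopifnot(inherits(profile, "strand_profile"))
  if (!isTRUE(profile$background_corrected)) {
    profile <- background_correct(profile, flank = flank)
  }
  in_crick <- profile$bp >= -hotspot_width / 2 & profile$bp <= binding_width
  in_watson <- profile$bp >= -binding_width & profile$bp <= hotspot_width / 2
  sum(profile$crick[in_crick]) + sum(profile$watson[in_watson])
}

#' Per-hotspot intensities for a coverage set
#'
#' @param covset a [coverage_set()].
#' @inheritParams hotspot_intensity
#' @return numeric vector, one intensity per hotspot.
#' @export
hotspot_intensities <- function(covset, hotspot_width = 500, binding_width = 2000,
                                flank = c(4000, 5000)) {
  vapply(seq_len(nrow(covset$crick)), function(i) {
    hotspot_intensity(profile_at(covset, i), hotspot_width, binding_width, flank)
  }, numeric(1))
}

#' Homolog read fraction with binomial confidence interval
#'
#' `f` is the fraction of allele-informative reads originating from homolog
#' 1.  With zero total reads `f` is undefined and `NA` is returned (such
#' hotspots are excluded downstream).
#'
#' @param reads_hom1,reads_hom2 nonnegative read counts (vectorised).
#' @param conf confidence level for the interval.
#' @return data.frame with `f`, `lo`, `hi`, `n`.
#' @export
homolog_fraction <- function(reads_hom1, reads_hom2, conf = 0.95) {
  stopifnot(length(reads_hom1) == length(reads_hom2),
            all(reads_hom1 >= 0), all(reads_hom2 >= 0))
  n <- reads_hom1 + reads_hom2
  f <- ifelse(n > 0, reads_hom1 / n, NA_real_)
  ci <- t(vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(c(NA_real_, NA_real_))
    as.numeric(stats::binom.test(round(reads_hom1[i]), round(n[i]),
                                 conf.level = conf)$conf.int)
  }, numeric(2)))
  data.frame(f = f, lo = ci[, 1], hi = ci[, 2], n = n)
}

#' Classify hotspots as asymmetric or symmetric from `f`
#'
#' A hotspot is asymmetric when breaks occur essentially on one homolog:
#' `f >= threshold` (homolog 1) or `f <= 1 - threshold` (homolog 2), both
#' boundaries inclusive.
#'
#' @param f homolog fraction(s) in \[0, 1\] (NA allowed).
#' @param threshold asymmetry threshold (default 0.9).
#' @return factor with levels `asymmetric_hom1`, `asymmetric_hom2`,
#'   `symmetric`.
#' @export
classify_asymmetric <- function(f, threshold = 0.9) {
  stopifnot(threshold > 0.5, threshold <= 1)
  eps <- 1e-9  # keep the inclusive boundaries exact despite 1 - 0.9 != 0.1
  out <- ifelse(is.na(f), NA_character_,
         ifelse(f >= threshold - eps, "asymmetric_hom1",
         ifelse(f <= 1 - threshold + eps, "asymmetric_hom2", "symmetric")))
  factor(out, levels = c("asymmetric_hom1", "asymmetric_hom2", "symmetric"))
}

## centred moving average over an odd number of bins; the window shrinks
## symmetrically at the profile edges
moving_average <- function(x, w_bins) {
  if (w_bins <= 1) return(x)
  half <- w_bins %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Weighted mean profile with smoothing
#'
#' Element-wise weighted mean of a set of strand profiles (or all rows of a
#' coverage set), followed by a centred moving average over
#' `smoothing_window` bp on each strand.
#'
#' @param profiles list of [strand_profile()]s or a [coverage_set()].
#' @param weights per-profile weights (default equal).
#' @param smoothing_window moving-average window in bp (default 100, i.e.
#'   5 bins of 20 bp); a window equal to the bin width is the identity.
#' @return a [strand_profile()].
#' @export
aggregate_profile <- function(profiles, weights = NULL, smoothing_window = 100) {
  if (inherits(profiles, "coverage_set")) {
    covset <- profiles
  } else {
    stopifnot(length(profiles) >= 1)
    j0 <- profiles[[1]]$j
    bw <- profiles[[1]]$bin_width
    for (p in profiles) {
      if (!identical(p$j, j0) || p$bin_width != bw) {
        stop("profiles must share binning", call. = FALSE)
      }
    }
    covset <- coverage_set(
      do.call(rbind, lapply(profiles, `[[`, "crick")),
      do.call(rbind, lapply(profiles, `[[`, "watson")),
      j = j0, bin_width = bw
    )
  }
  n <- nrow(covset$crick)
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  w_bins <- max(1L, round(smoothing_window / covset$bin_width))
  if (w_bins %% 2 == 0) w_bins <- w_bins + 1L
  strand_profile(
    crick = moving_average(as.numeric(w %*% covset$crick), w_bins),
    watson = moving_average(as.numeric(w %*% covset$watson), w_bins),
    j = covset$j, bin_width = covset$bin_width
  )
}

#' Heatmap matrix of per-hotspot coverage, rows ordered by SPO11 count
#'
#' @param covset a [coverage_set()] with a hotspot table carrying
#'   `spo11_count`.
#' @param strand `"both"` (sum), `"crick"` or `"watson"`.
#' @param decreasing order hottest-first (default TRUE).
#' @return numeric matrix (hotspots x bins) with bin midpoints as column
#'   names and hotspot ids as row names.
#' @export
heatmap_matrix <- function(covset, strand = c("both", "crick", "watson"),
                           decreasing = TRUE) {
  strand <- match.arg(strand)
  stopifnot(!is.null(covset$hotspots), "spo11_count" %in% names(covset$hotspots))
  mat <- switch(strand,
    both = covset$crick + covset$watson,
    crick = covset$crick,
    watson = covset$watson
  )
  ord <- order(covset$hotspots$spo11_count, decreasing = decreasing)
  mat <- mat[ord, , drop = FALSE]
  dimnames(mat) <- list(covset$hotspots$hotspot_id[ord], covset$bin_width * covset$j)
  mat
}

#' Watson / Crick area ratio over a hotspot set
#'
#' Overall strand balance check: the ratio of the total Watson to total
#' Crick coverage across the set.  Mirror-symmetric signal gives 1.
#'
#' @param profiles a [coverage_set()], [strand_profile()], or list of
#'   strand profiles.
#' @return single numeric ratio.
#' @export
strand_area_ratio <- function(profiles) {
  if (inherits(profiles, "strand_profile")) {
    cr <- sum(profiles$crick); wa <- sum(profiles$watson)
  } else if (inherits(profiles, "coverage_set")) {
    cr <- sum(profiles$crick); wa <- sum(profiles$watson)
  } else {
    cr <- sum(vapply(profiles, function(p) sum(p$crick), numeric(1)))
    wa <- sum(vapply(profiles, function(p) sum(p$watson), numeric(1)))
  }
  if (cr <= 0) stop("zero Crick area", call. = FALSE)
  wa / cr
}

#' Per-group intensity-per-DSB slopes and their ratio
#'
#' For each group of hotspots, fits the zero-intercept least-squares slope
#' of ChIP intensity against SPO11-oligo count; the between-group slope
#' ratio quantifies signal elevation (e.g. non-pseudoautosomal X versus
#' autosomes) for the same number of breaks.
#'
#' @param intensity,spo11_count numeric vectors, one value per hotspot.
#' @param group factor/character of group labels (>= 2 groups, each with
#'   >= 10 hotspots).
#' @return list with `slopes` (data.frame `group`, `slope`, `n`) and
#'   `ratio` (named matrix of pairwise slope ratios, `ratio[a, b]` =
#'   slope(a) / slope(b)).
#' @export
group_elevation <- function(intensity, spo11_count, group) {
  stopifnot(length(intensity) == length(spo11_count),
            length(group) == length(intensity))
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  tab <- table(group)
  if (any(tab < 10)) {
    stop(sprintf("each group needs >= 10 hotspots (smallest has %d)", min(tab)),
         call. = FALSE)
  }
  slopes <- vapply(levels(group), function(g) {
    x <- spo11_count[group == g]; y <- intensity[group == g]
    if (all(x == 0)) stop(sprintf("group '%s' has all-zero SPO11 counts", g),
                          call. = FALSE)
    sum(x * y) / sum(x * x)
  }, numeric(1))
  ratio <- outer(slopes, slopes, "/")
  dimnames(ratio) <- list(levels(group), levels(group))
  list(
    slopes = data.frame(group = levels(group), slope = slopes,
                        n = as.integer(tab), row.names = NULL),
    ratio = ratio
  )
}
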
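#' Configuration for the synthetic recombination-data generator
#'
#' Bundles every knob of the generator with defaults that mirror the study
#' conditions the downstream analyses assume: DSB offsets spread over a few
#' hundred bp around the motif centre, protein-binding kernels calibrated to
#' the hallmark DMC1/RAD51/template-RPA positions, ~10% crossover resolution
#' per DSB with a centromere-to-telomere gradient, and hotspot centres at
#' least 8 kb apart.
#'
#' @param n_hotspots number of hotspots to simulate.
#' @param chrom_length chromosome length in bp.
#' @param dsb_offset_model list describing the DSB-offset mixture: `sd`
#'   (bp) of the central truncated-Gaussian component, `bounds` (bp,
#'   truncation half-width), and optionally `flanks`, a data.frame with
#'   columns `offset`, `sd`, `weight` for secondary components.  A `sd` of 0
#'   is a point mass at 0.
#' @param kernel_dmc1,kernel_rad51,kernel_rpa_template [binding_kernel()]s;
#'   defaults from [default_kernels()].
#' @param rpa_dsb_mix length-2 weights (DMC1, RAD51) composing RPA binding
#'   on the DSB-initiating homolog; must be nonnegative and sum to 1.
#' @param read_depth expected ChIP reads per hotspot per strand.
#' @param spo11_rate expected SPO11-oligo count per hotspot.
#' @param background_rate expected background reads per 20-bp bin.
#' @param overdispersion extra-Poisson dispersion of per-bin read counts
#'   (0 = Poisson; larger values draw gamma-mixed Poisson counts with
#'   variance `mu * (1 + overdispersion * mu)`).
#' @param skew_fraction fraction of hotspots generated with left/right
#'   binding imbalance.
#' @param skew_factor fold-excess of the more-bound side in skewed hotspots.
#' @param asym_fraction fraction of hotspots with homolog fraction `f >= 0.9`
#'   or `f <= 0.1` (asymmetric hotspots).
#' @param co_base_rate mean crossover probability per DSB (0.10: roughly one
#'   DSB in ten resolves as a crossover).
#' @param co_gradient fold-increase in crossover rate from the
#'   centromere-proximal to the telomere-proximal chromosome end.
#' @param lifespan_ratio ratio of mean lifespans of crossover- versus
#'   non-crossover-destined intermediates (controls simulated
#'   repair-template RPA per DSB).
#' @param co_tract_mean,nco_tract_mean mean gene-conversion tract length
#'   (bp) for crossovers and non-crossovers.
#' @param dsb_per_hotspot expected number of repaired DSB outcomes simulated
#'   per hotspot.
#' @param snp_spacing mean bp between consecutive SNPs on the hybrid SNP
#'   grid.
#' @param snp_informative_prob probability that a SNP is informative
#'   (usable to delimit a crossover breakpoint).
#' @param seed integer seed; every simulate_* function derives its RNG
#'   stream from this unless given its own seed.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_hotspots = 200,
                             chrom_length = 2e7,
                             dsb_offset_model = list(sd = 150, bounds = 1000),
                             kernel_dmc1 = NULL,
                             kernel_rad51 = NULL,
                             kernel_rpa_template = NULL,
                             rpa_dsb_mix = c(dmc1 = 0.65, rad51 = 0.35),
                             read_depth = 100,
                             spo11_rate = 20,
                             background_rate = 0,
                             overdispersion = 0,
                             skew_fraction = 0.4,
                             skew_factor = 3,
                             asym_fraction = 0.18,
                             co_base_rate = 0.10,
                             co_gradient = 3,
                             lifespan_ratio = 2.6,
                             co_tract_mean = 500,
                             nco_tract_mean = 100,
                             dsb_per_hotspot = 5,
                             snp_spacing = 150,
                             snp_informative_prob = 0.5,
                             seed = 1L) {
  if (is.null(kernel_dmc1) || is.null(kernel_rad51) || is.null(kernel_rpa_template)) {
    dk <- default_kernels()
    if (is.null(kernel_dmc1)) kernel_dmc1 <- dk$dmc1
    if (is.null(kernel_rad51)) kernel_rad51 <- dk$rad51
    if (is.null(kernel_rpa_template)) kernel_rpa_template <- dk$rpa_template
  }
  cfg <- structure(as.list(environment()), class = "generator_config")
  validate_config(cfg)
}

#' Validate a generator configuration
#'
#' @param cfg a `generator_config`.
#' @return the config, invisibly usable; errors name the offending field.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid generator_config field `%s`: %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(cfg$n_hotspots) || cfg$n_hotspots < 1) fail("n_hotspots", "must be >= 1")
  if (cfg$chrom_length < (cfg$n_hotspots + 1) * 8000) {
    fail("chrom_length", "too short to place hotspots >= 8 kb apart")
  }
  om <- cfg$dsb_offset_model
  if (!is.list(om) || is.null(om$sd) || om$sd < 0) fail("dsb_offset_model", "needs sd >= 0")
  if (is.null(om$bounds) || om$bounds <= 0) fail("dsb_offset_model", "needs bounds > 0")
  if (!is.null(om$flanks)) {
    fl <- om$flanks
    if (!all(c("offset", "sd", "weight") %in% names(fl)) ||
        any(fl$weight < 0) || sum(fl$weight) > 1) {
      fail("dsb_offset_model", "flanks need offset/sd/weight with weights in [0, 1]")
    }
  }
  for (kn in c("kernel_dmc1", "kernel_rad51", "kernel_rpa_template")) {
    kk <- cfg[[kn]]
    if (!inherits(kk, "binding_kernel")) fail(kn, "must be a binding_kernel")
    if (any(kk$mass < 0) || abs(sum(kk$mass) - 1) > 1e-12) {
      fail(kn, "mass must be nonnegative with area 1")
    }
  }
  if (length(cfg$rpa_dsb_mix) != 2 || any(cfg$rpa_dsb_mix < 0) ||
      abs(sum(cfg$rpa_dsb_mix) - 1) > 1e-12) {
    fail("rpa_dsb_mix", "two nonnegative weights summing to 1")
  }
  if (cfg$read_depth < 0) fail("read_depth", "must be >= 0")
  if (cfg$background_rate < 0) fail("background_rate", "must be >= 0")
  if (cfg$overdispersion < 0) fail("overdispersion", "must be >= 0")
  for (fr in c("skew_fraction", "asym_fraction", "co_base_rate",
               "snp_informative_prob")) {
    if (cfg[[fr]] < 0 || cfg[[fr]] > 1) fail(fr, "must be in [0, 1]")
  }
  if (cfg$skew_factor < 1) fail("skew_factor", "must be >= 1")
  if (cfg$co_gradient <= 0) fail("co_gradient", "must be > 0")
  if (cfg$lifespan_ratio <= 0) fail("lifespan_ratio", "must be > 0")
  if (cfg$snp_spacing <= 0) fail("snp_spacing", "must be > 0")
  cfg
}

## Draw n signed DSB offsets (bp) from the configured mixture model.
draw_offsets <- function(n, om) {
  if (n == 0) return(numeric(0))
  w_flank <- if (is.null(om$flanks)) 0 else sum(om$flanks$weight)
  comp <- if (w_flank > 0) {
    probs <- c(1 - w_flank, om$flanks$weight)
    sample.int(length(probs), n, replace = TRUE, prob = probs)
  } else {
    rep(1L, n)
  }
  x <- numeric(n)
  central <- comp == 1L
  if (any(central)) {
    if (om$sd == 0) {
      x[central] <- 0
    } else {
      ## truncated Gaussian by rejection (bounds are several sd wide)
      need <- which(central)
      while (length(need) > 0) {
        cand <- stats::rnorm(length(need), 0, om$sd)
        ok <- abs(cand) <= om$bounds
        x[need[ok]] <- cand[ok]
        need <- need[!ok]
      }
    }
  }
  if (w_flank > 0) {
    for (fi in seq_len(nrow(om$flanks))) {
      sel <- comp == fi + 1L
      if (any(sel)) {
        x[sel] <- stats::rnorm(sum(sel), om$flanks$offset[fi], om$flanks$sd[fi])
      }
    }
  }
  x
}

#' Simulate a hotspot catalog with per-hotspot DSB offsets
#'
#' Places `n_hotspots` motif centres at least 8 kb apart on one chromosome,
#' assigns PRDM9 alleles, homolog read fractions `f` (with `asym_fraction`
#' of hotspots forced into `f >= 0.9` or `f <= 0.1`), skew status, and draws
#' each hotspot's SPO11-oligo offsets i.i.d. from the DSB-offset model.
#'
#' @param config a [generator_config()].
#' @return list of class `hotspot_sim` with `hotspots` (data.frame:
#'   `hotspot_id`, `chrom`, `center`, `allele`, `f`, `spo11_count`,
#'   `skew_side`, `centromere_distance`) and `offsets` (list of numeric
#'   vectors, one per hotspot).
#' @export
simulate_hotspots <- function(config) {
  config <- validate_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_hotspots)

  ## rejection placement: keep candidates >= 8 kb from all accepted centres
  centers <- numeric(0)
  guard <- 0
  while (length(centers) < n) {
    cand <- stats::runif(n, 10000, config$chrom_length - 10000)
    for (x in cand) {
      if (length(centers) == n) break
      if (length(centers) == 0 || min(abs(centers - x)) >= 8000) {
        centers <- c(centers, x)
      }
    }
    guard <- guard + 1
    if (guard > 1000) stop("failed to place hotspots >= 8 kb apart", call. = FALSE)
  }
  centers <- sort(round(centers))

  allele <- sample(c("CAST", "HUM"), n, replace = TRUE, prob = c(0.7, 0.3))
  asym <- stats::runif(n) < config$asym_fraction
  f <- numeric(n)
  hom1 <- stats::runif(n) < 0.5
  f[asym & hom1] <- stats::runif(sum(asym & hom1), 0.9, 1)
  f[asym & !hom1] <- stats::runif(sum(asym & !hom1), 0, 0.1)
  if (any(!asym)) {
    ## symmetric hotspots stay strictly inside (0.1, 0.9)
    f[!asym] <- 0.1 + 0.8 * stats::rbeta(sum(!asym), 4, 4)
  }
  spo11_count <- pmax(1L, stats::rpois(n, config$spo11_rate))
  skewed <- stats::runif(n) < config$skew_fraction
  skew_side <- ifelse(skewed, ifelse(stats::runif(n) < 0.5, "left", "right"), "none")

  offsets <- lapply(spo11_count, draw_offsets, om = config$dsb_offset_model)

  hotspots <- data.frame(
    hotspot_id = seq_len(n),
    chrom = "chrSim",
    center = centers,
    allele = allele,
    f = f,
    spo11_count = spo11_count,
    skew_side = skew_side,
    centromere_distance = centers,  # acrocentric: centromere at coordinate 0
    stringsAsFactors = FALSE
  )
  structure(list(hotspots = hotspots, offsets = offsets, config = config),
            class = "hotspot_sim")
}

#' @export
print.hotspot_sim <- function(x, ...) {
  cat(sprintf("<hotspot_sim> %d hotspots on %s (seed %d)\n",
              nrow(x$hotspots), x$hotspots$chrom[1], x$config$seed))
  invisible(x)
}

## Convolve a binned distribution q (bins -m..m) with kernel mass on bins k,
## onto coverage bins j.  Returns expected per-bin coverage (area = sum(q)).
convolve_offsets_kernel <- function(q, m, kern_mass, k, j) {
  lam <- numeric(length(j))
  nz <- which(q > 0)
  for (li in nz) {
    l <- li - m - 1L
    idx <- match(l + k, j)
    ok <- !is.na(idx)
    lam[idx[ok]] <- lam[idx[ok]] + q[li] * kern_mass[ok]
  }
  lam
}

## Poisson or gamma-mixed-Poisson draw with expectation mu.
draw_counts <- function(mu, overdispersion) {
  if (overdispersion <= 0) return(stats::rpois(length(mu), mu))
  size <- 1 / overdispersion
  stats::rnbinom(length(mu), mu = mu, size = size)
}

#' Simulate strand-specific coverage for a hotspot set
#'
#' The forward model that deconvolution inverts: the expected Crick coverage
#' of a hotspot is `depth` times the convolution of its empirical DSB-offset
#' distribution with the binding kernel; Watson coverage is the mirror-image
#' counterpart.  Hotspots with more SPO11 oligos receive proportionally more
#' reads, so the aggregate coverage stays exactly proportional to the
#' aggregate SPO11 distribution convolved with the kernel.  Skewed hotspots
#' have one side's kernel mass multiplied by the configured factor, then the
#' two sides renormalised to conserve total signal.
#'
#' @param sim a `hotspot_sim` from [simulate_hotspots()].
#' @param kernel a [binding_kernel()].
#' @param depth expected reads per hotspot per strand (scalar or one per
#'   hotspot); defaults to the config's `read_depth`.
#' @param seed RNG seed (default derives from the config seed).
#' @param j coverage bin indices (default `-250:250`, i.e. +/-5 kb).
#' @param noise `"poisson"` for sampled counts (with the configured
#'   overdispersion), `"none"` for expected values.
#' @param apply_skew apply per-hotspot skew from the catalog (default TRUE).
#' @return a [coverage_set()] with the hotspot table attached.
#' @export
simulate_coverage <- function(sim, kernel, depth = NULL, seed = NULL,
                              j = -250:250, noise = c("poisson", "none"),
                              apply_skew = TRUE) {
  noise <- match.arg(noise)
  stopifnot(inherits(sim, "hotspot_sim"), inherits(kernel, "binding_kernel"))
  cfg <- sim$config
  if (is.null(depth)) depth <- cfg$read_depth
  n <- nrow(sim$hotspots)
  depth <- rep_len(depth, n)
  if (any(depth < 0)) stop("`depth` must be >= 0", call. = FALSE)
  if (is.null(seed)) seed <- cfg$seed + 101L
  set.seed(seed)

  m_s <- 50L
  k <- kernel$k
  mean_oligos <- mean(lengths(sim$offsets))
  crick <- matrix(0, n, length(j))
  watson <- matrix(0, n, length(j))
  sf <- cfg$skew_factor
  for (i in seq_len(n)) {
    q <- bin_offsets(sim$offsets[[i]], m = m_s)$counts
    q <- q / mean_oligos
    lam_c <- depth[i] * convolve_offsets_kernel(q, m_s, kernel$mass, k, j)
    ## Watson expectation is the mirror of Crick (polarity flips with strand)
    lam_w <- rev(lam_c)
    if (apply_skew && sim$hotspots$skew_side[i] != "none" && sf > 1) {
      ## more-bound side: Watson carries the left-of-centre signal
      wl <- 2 * sf / (1 + sf); wr <- 2 / (1 + sf)
      if (sim$hotspots$skew_side[i] == "left") {
        lam_w <- lam_w * wl; lam_c <- lam_c * wr
      } else {
        lam_w <- lam_w * wr; lam_c <- lam_c * wl
      }
    }
    lam_c <- lam_c + cfg$background_rate
    lam_w <- lam_w + cfg$background_rate
    if (noise == "poisson") {
      crick[i, ] <- draw_counts(lam_c, cfg$overdispersion)
      watson[i, ] <- draw_counts(lam_w, cfg$overdispersion)
    } else {
      crick[i, ] <- lam_c
      watson[i, ] <- lam_w
    }
  }
  coverage_set(crick, watson, j = j, hotspots = sim$hotspots)
}

#' Aggregate SPO11-oligo offset distribution of a simulated hotspot set
#'
#' @param sim a `hotspot_sim`.
#' @param m grid half-width in bins.
#' @export
spo11_distribution <- function(sim, m = 50) {
  bin_offsets(unlist(sim$offsets), m = m)
}

#' Simulate crossover and non-crossover outcome records
#'
#' Each hotspot receives a Poisson number of repaired DSBs.  A DSB resolves
#' as a crossover with probability varying linearly along the chromosome
#' (fold-change `co_gradient` from the centromeric to the telomeric end,
#' mean `co_base_rate`), otherwise as a non-crossover.  The gene-conversion
#' tract extends from the DSB site by a gamma-distributed length on a random
#' side; crossover records report the two informative SNPs flanking the true
#' breakpoint (tract end) plus the internal SNP grid between them, and
#' non-crossover records report the minimal segment of converted SNPs.
#'
#' @param sim a `hotspot_sim`.
#' @param config optional override of `sim$config`.
#' @param seed RNG seed (default derives from the config seed).
#' @return list of class `outcome_sim`: `crossovers` (data.frame with
#'   `hotspot_id`, `chrom`, `center`, `snp_left`, `snp_right`,
#'   `internal_snps` (list column), `true_breakpoint`, `true_dsb`), `ncos`
#'   (data.frame with `hotspot_id`, `chrom`, `center`, `start`, `end`,
#'   `n_snps`, `true_dsb`), and counters of undetected events.
#' @export
simulate_outcomes <- function(sim, config = NULL, seed = NULL) {
  stopifnot(inherits(sim, "hotspot_sim"))
  cfg <- if (is.null(config)) sim$config else validate_config(config)
  if (is.null(seed)) seed <- cfg$seed + 202L
  set.seed(seed)
  hs <- sim$hotspots
  n <- nrow(hs)

  ## crossover probability per DSB: linear in chromosome position, fold
  ## change co_gradient end-to-end, position-average co_base_rate
  pos <- hs$center / cfg$chrom_length
  g <- cfg$co_gradient
  p_co <- cfg$co_base_rate * (2 / (1 + g)) * (1 + (g - 1) * pos)
  p_co <- pmin(pmax(p_co, 0), 1)

  co_rows <- list()
  nco_rows <- list()
  nco_missed <- 0L
  co_shape <- 2
  for (i in seq_len(n)) {
    n_dsb <- stats::rpois(1, cfg$dsb_per_hotspot)
    if (n_dsb == 0) next
    ## local SNP grid around the hotspot (Poisson-spaced)
    half <- 6000
    n_snp <- stats::rpois(1, 2 * half / cfg$snp_spacing)
    snps <- sort(round(stats::runif(n_snp, hs$center[i] - half, hs$center[i] + half)))
    snps <- unique(snps)
    informative <- stats::runif(length(snps)) < cfg$snp_informative_prob
    is_co <- stats::runif(n_dsb) < p_co[i]
    dsb <- hs$center[i] + round(draw_offsets(n_dsb, cfg$dsb_offset_model))
    for (e in seq_len(n_dsb)) {
      side <- sample(c(-1, 1), 1)
      if (is_co[e]) {
        len <- stats::rgamma(1, shape = co_shape, scale = cfg$co_tract_mean / co_shape)
        bp <- dsb[e] + side * len
        inf <- snps[informative]
        if (length(inf) < 2 || bp <= min(inf) || bp > max(inf)) next
        snp_l <- max(inf[inf < bp])
        snp_r <- min(inf[inf >= bp])
        internal <- snps[snps > snp_l & snps < snp_r]
        co_rows[[length(co_rows) + 1L]] <- list(
          hotspot_id = hs$hotspot_id[i], chrom = hs$chrom[i], center = hs$center[i],
          snp_left = snp_l, snp_right = snp_r, internal_snps = internal,
          true_breakpoint = bp, true_dsb = dsb[e]
        )
      } else {
        len <- stats::rgamma(1, shape = co_shape, scale = cfg$nco_tract_mean / co_shape)
        lo <- min(dsb[e], dsb[e] + side * len)
        hi <- max(dsb[e], dsb[e] + side * len)
        conv <- snps[snps >= lo & snps <= hi]
        if (length(conv) == 0) { nco_missed <- nco_missed + 1L; next }
        nco_rows[[length(nco_rows) + 1L]] <- list(
          hotspot_id = hs$hotspot_id[i], chrom = hs$chrom[i], center = hs$center[i],
          start = min(conv), end = max(conv), n_snps = length(conv),
          true_dsb = dsb[e]
        )
      }
    }
  }
  bind_rows_list <- function(rows, list_col = NULL) {
    if (length(rows) == 0) return(NULL)
    plain <- setdiff(names(rows[[1]]), list_col)
    df <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r[plain], stringsAsFactors = FALSE)
    }))
    if (!is.null(list_col)) df[[list_col]] <- lapply(rows, `[[`, list_col)
    rownames(df) <- NULL
    df
  }
  structure(
    list(
      crossovers = bind_rows_list(co_rows, "internal_snps"),
      ncos = bind_rows_list(nco_rows),
      nco_undetected = nco_missed,
      p_co = p_co,
      config = cfg
    ),
    class = "outcome_sim"
  )
}

#' @export
print.outcome_sim <- function(x, ...) {
  cat(sprintf("<outcome_sim> %d crossovers, %d non-crossovers (%d NCOs undetected)\n",
              if (is.null(x$crossovers)) 0L else nrow(x$crossovers),
              if (is.null(x$ncos)) 0L else nrow(x$ncos),
              x$nco_undetected))
  invisible(x)
}

#' Simulate chromosome-axis polylines and recombinase foci
#'
#' Generates per-cell axis polylines in a rectangular field (nm), places
#' paired DMC1/RAD51 foci near the axes with configurable signed
#' perpendicular offsets and a lateral within-pair displacement, and adds
#' uniformly scattered background foci.
#'
#' @param n_cells number of cells.
#' @param axes_per_cell axes per cell.
#' @param pairs_per_axis focus pairs per axis.
#' @param field width/height of the imaging field in nm.
#' @param axis_sd_dmc1,axis_sd_rad51 sd (nm) of the signed perpendicular
#'   focus offset from the axis per channel (half-normal median =
#'   0.674 * sd; defaults give medians of ~120 and ~60 nm).
#' @param pair_lateral_sd sd (nm) of the along-axis displacement between the
#'   two foci of a pair.
#' @param background_rate expected number of background (off-axis, uniform)
#'   foci per cell per channel.
#' @param straight_axes if TRUE axes are straight horizontal lines spanning
#'   the field (useful for exact-geometry checks); otherwise random
#'   polylines.
#' @param seed RNG seed.
#' @return list of class `foci_sim` with `axes` (data.frame: `cell_id`,
#'   `axis_id`, `vertex`, `x`, `y`) and `foci` (data.frame: `cell_id`,
#'   `channel`, `x`, `y`, `pair_id`, `is_background`).
#' @export
simulate_foci <- function(n_cells = 5, axes_per_cell = 8, pairs_per_axis = 4,
                          field = 10000, axis_sd_dmc1 = 178, axis_sd_rad51 = 89,
                          pair_lateral_sd = 100, background_rate = 5,
                          straight_axes = FALSE, seed = 1L) {
  stopifnot(axis_sd_dmc1 >= 0, axis_sd_rad51 >= 0, pair_lateral_sd >= 0,
            background_rate >= 0)
  set.seed(seed)
  axes <- list(); foci <- list(); pair_id <- 0L
  for (cell in seq_len(n_cells)) {
    for (ax in seq_len(axes_per_cell)) {
      if (straight_axes) {
        y0 <- field * ax / (axes_per_cell + 1)
        vx <- c(0, field); vy <- c(y0, y0)
      } else {
        start <- stats::runif(2, 0.1 * field, 0.9 * field)
        theta <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, 0.3, 0.7) * field
        nv <- 4
        tfrac <- seq(0, 1, length.out = nv)
        wig <- stats::rnorm(nv, 0, 0.02 * field)
        vx <- start[1] + cos(theta) * len * tfrac - sin(theta) * wig
        vy <- start[2] + sin(theta) * len * tfrac + cos(theta) * wig
      }
      axes[[length(axes) + 1L]] <- data.frame(
        cell_id = cell, axis_id = ax, vertex = seq_along(vx), x = vx, y = vy
      )
      ## foci pairs anchored along the axis
      seg_len <- sqrt(diff(vx)^2 + diff(vy)^2)
      cum <- c(0, cumsum(seg_len))
      for (p in seq_len(pairs_per_axis)) {
        pair_id <- pair_id + 1L
        t_at <- stats::runif(1, 0, cum[length(cum)])
        si <- findInterval(t_at, cum, rightmost.closed = TRUE)
        si <- min(si, length(seg_len))
        frac <- if (seg_len[si] > 0) (t_at - cum[si]) / seg_len[si] else 0
        px <- vx[si] + frac * (vx[si + 1] - vx[si])
        py <- vy[si] + frac * (vy[si + 1] - vy[si])
        ux <- (vx[si + 1] - vx[si]) / max(seg_len[si], 1e-9)
        uy <- (vy[si + 1] - vy[si]) / max(seg_len[si], 1e-9)
        nx <- -uy; ny <- ux
        off_d <- stats::rnorm(1, 0, axis_sd_dmc1)
        off_r <- stats::rnorm(1, 0, axis_sd_rad51)
        lat <- stats::rnorm(1, 0, pair_lateral_sd)
        foci[[length(foci) + 1L]] <- data.frame(
          cell_id = cell, channel = c("DMC1", "RAD51"),
          x = c(px + nx * off_d, px + ux * lat + nx * off_r),
          y = c(py + ny * off_d, py + uy * lat + ny * off_r),
          pair_id = pair_id, is_background = FALSE
        )
      }
    }
    for (ch in c("DMC1", "RAD51")) {
      nb <- stats::rpois(1, background_rate)
      if (nb > 0) {
        foci[[length(foci) + 1L]] <- data.frame(
          cell_id = cell, channel = ch,
          x = stats::runif(nb, 0, field), y = stats::runif(nb, 0, field),
          pair_id = NA_integer_, is_background = TRUE
        )
      }
    }
  }
  structure(
    list(axes = do.call(rbind, axes), foci = do.call(rbind, foci), field = field),
    class = "foci_sim"
  )
}

#' @export
print.foci_sim <- function(x, ...) {
  cat(sprintf("<foci_sim> %d cells, %d axis vertices, %d foci\n",
              length(unique(x$axes$cell_id)), nrow(x$axes), nrow(x$foci)))
  invisible(x)
}
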
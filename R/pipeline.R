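#' Run the full synthetic-to-analysis pipeline
#'
#' Executes the configured stages in order: `simulate` (hotspot catalog,
#' strand coverage for DMC1/RAD51/RPA, outcomes, foci), `extract`
#' (intensities, homolog asymmetry, strand balance), `deconvolve`
#' (DSB-relative binding profiles), `mixture` (RPA decomposition), `skew`
#' (half-signal classification and co-orientation), `dloop` (equal-signal
#' bins, crossover rates, lifespan inference), `tracts` (breakpoint and
#' tract-containment maps) and `foci` (axis/co-focus geometry).  Every
#' output file is written under `out_dir` and listed in a manifest stamped
#' with the seed and a config digest; a single global seed is fanned out to
#' fixed per-stage seeds so stages stay independently reproducible.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @param seed global seed; defaults to the config seed.
#' @param stages character vector of stages to run (subset of the list
#'   above).  Disabling `simulate` requires `inputs`.
#' @param tol deconvolution tolerance.
#' @param skew_threshold skew threshold in bp.
#' @param asym_threshold homolog-fraction asymmetry threshold.
#' @param cofocus_threshold co-focus pairing threshold in nm.
#' @param n_boot bootstrap iterations for bin confidence intervals.
#' @param co_share assumed mean crossover share per inter-homolog
#'   intermediate.
#' @param sister_fraction assumed sister-repair probability.
#' @param inputs optional precomputed inputs (list with `sim`, `coverage`
#'   (named list of [coverage_set()]s), `outcomes`, `foci`) used when
#'   `simulate` is disabled.
#' @return invisible list with per-stage results and `manifest`.
#' @export
run_pipeline <- function(config = generator_config(), out_dir,
                         seed = config$seed,
                         stages = c("simulate", "extract", "deconvolve",
                                    "mixture", "skew", "dloop", "tracts", "foci"),
                         tol = 0.2, skew_threshold = 150, asym_threshold = 0.9,
                         cofocus_threshold = 300, n_boot = 1e5,
                         co_share = 0.10, sister_fraction = 0,
                         inputs = NULL) {
  all_stages <- c("simulate", "extract", "deconvolve", "mixture", "skew",
                  "dloop", "tracts", "foci")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  config <- validate_config(config)
  needs_sim <- setdiff(stages, "foci")
  if (!("simulate" %in% stages) && length(setdiff(needs_sim, "simulate")) > 0 &&
      is.null(inputs)) {
    stop("stages depending on simulated inputs are enabled but `inputs` is missing",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time()), msg))
  }
  stage_seed <- function(i) (as.integer(seed) + i * 10007L) %% 2147483647L
  manifest <- list(seed = seed, stages = stages, outputs = list())
  emit <- function(stage, files) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]], files)
  }
  res <- list()
  proteins <- c("dmc1", "rad51", "rpa_dsb", "rpa_template")

  ## ---- simulate ------------------------------------------------------
  if ("simulate" %in% stages) {
    say("simulate: %d hotspots (stage seed %d)", config$n_hotspots, stage_seed(1))
    cfg <- config
    cfg$seed <- stage_seed(1)
    sim <- simulate_hotspots(cfg)
    outcomes <- simulate_outcomes(sim, seed = stage_seed(2))
    mix <- config$rpa_dsb_mix
    kern_rpa_dsb <- binding_kernel(
      config$kernel_dmc1$k,
      mix[1] * config$kernel_dmc1$mass + mix[2] * config$kernel_rad51$mass
    )
    ## repair-template signal per hotspot scales with the expected lifespan
    ## of its intermediates
    lr <- config$lifespan_ratio
    wmul <- (outcomes$p_co * lr + (1 - outcomes$p_co)) /
      (config$co_base_rate * lr + (1 - config$co_base_rate))
    coverage <- list(
      dmc1 = simulate_coverage(sim, config$kernel_dmc1, seed = stage_seed(3)),
      rad51 = simulate_coverage(sim, config$kernel_rad51, seed = stage_seed(4)),
      rpa_dsb = simulate_coverage(sim, kern_rpa_dsb, seed = stage_seed(5)),
      rpa_template = simulate_coverage(sim, config$kernel_rpa_template,
                                       depth = config$read_depth * wmul,
                                       seed = stage_seed(6), apply_skew = FALSE)
    )
    foci <- simulate_foci(seed = stage_seed(7))

    write_hotspots_bed(sim$hotspots, file.path(out_dir, "hotspots.tsv"))
    write_offsets_tsv(spo11_distribution(sim), file.path(out_dir, "spo11_offsets.tsv"))
    for (p in proteins) {
      fc <- file.path(out_dir, sprintf("coverage_%s_crick.bedGraph", p))
      fw <- file.path(out_dir, sprintf("coverage_%s_watson.bedGraph", p))
      write_coverage_bedgraph(coverage[[p]], fc, fw)
      emit("simulate", c(fc, fw))
    }
    write_outcomes_tsv(outcomes, file.path(out_dir, "crossovers.tsv"),
                       file.path(out_dir, "ncos.tsv"))
    write_foci_tsv(foci, file.path(out_dir, "foci.tsv"), file.path(out_dir, "axes.tsv"))
    write_config_yaml(cfg, file.path(out_dir, "config.yaml"))
    emit("simulate", file.path(out_dir, c("hotspots.tsv", "spo11_offsets.tsv",
                                          "crossovers.tsv", "ncos.tsv",
                                          "foci.tsv", "axes.tsv", "config.yaml")))
    res$sim <- sim; res$outcomes <- outcomes; res$coverage <- coverage
    res$foci_sim <- foci
  } else if (!is.null(inputs)) {
    res$sim <- inputs$sim; res$outcomes <- inputs$outcomes
    res$coverage <- inputs$coverage; res$foci_sim <- inputs$foci
  }

  ## ---- extract -------------------------------------------------------
  if ("extract" %in% stages) {
    say("extract: per-hotspot intensities")
    intens <- lapply(res$coverage, hotspot_intensities)
    hs <- res$sim$hotspots
    asym <- classify_asymmetric(hs$f, asym_threshold)
    tab <- data.frame(hotspot_id = hs$hotspot_id, hs[c("allele", "f")],
                      asymmetry = asym,
                      stats::setNames(as.data.frame(intens),
                                      paste0("intensity_", names(intens))))
    f_int <- file.path(out_dir, "intensity.tsv")
    utils::write.table(tab, f_int, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("extract", f_int)
    res$intensity <- tab
    res$strand_ratio <- vapply(res$coverage, strand_area_ratio, numeric(1))
  }

  ## ---- deconvolve ----------------------------------------------------
  if ("deconvolve" %in% stages) {
    say("deconvolve: tol %.2f", tol)
    s <- spo11_distribution(res$sim)
    res$deconvolved <- list()
    files <- character(0)
    for (p in proteins) {
      agg <- background_correct(aggregate_coverage(res$coverage[[p]]))
      dp <- deconvolve(agg, s = s, tol = tol)
      res$deconvolved[[p]] <- dp
      f <- file.path(out_dir, sprintf("deconvolved_%s.tsv", p))
      write_deconvolved_tsv(dp, f)
      files <- c(files, f)
    }
    emit("deconvolve", files)
    res$profile_stats <- lapply(res$deconvolved, profile_stats)
  }

  ## ---- mixture -------------------------------------------------------
  if ("mixture" %in% stages) {
    say("mixture: decomposing RPA on the DSB-initiating homolog")
    fit <- fit_mixture(
      normalize_area(res$deconvolved$rpa_dsb, which = "crick"),
      normalize_area(res$deconvolved$dmc1, which = "crick"),
      normalize_area(res$deconvolved$rad51, which = "crick")
    )
    f <- file.path(out_dir, "mixture.json")
    jsonlite::write_json(
      list(alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma,
           prop_dmc1 = fit$prop_dmc1, prop_rad51 = fit$prop_rad51,
           residual_sse = fit$residual_sse),
      f, auto_unbox = TRUE, digits = NA
    )
    emit("mixture", f)
    res$mixture <- fit
  }

  ## ---- skew ----------------------------------------------------------
  if ("skew" %in% stages) {
    say("skew: half-signal classification (threshold %g bp)", skew_threshold)
    sk <- classify_and_orient(res$coverage$dmc1, threshold = skew_threshold)
    n_l <- sum(sk$calls$label == "left", na.rm = TRUE)
    n_r <- sum(sk$calls$label == "right", na.rm = TRUE)
    res$skew <- list(
      calls = sk$calls,
      n_left = n_l, n_right = n_r,
      balance_p = if (n_l + n_r > 0) side_balance_test(n_l, n_r) else NA_real_,
      oriented_aggregate = aggregate_profile(sk$oriented)
    )
    f <- file.path(out_dir, "skew.tsv")
    utils::write.table(sk$calls, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("skew", f)
  }

  ## ---- dloop ---------------------------------------------------------
  if ("dloop" %in% stages) {
    say("dloop: equal-signal bins + lifespan inference")
    hs <- res$sim$hotspots
    w <- res$intensity$intensity_rpa_dsb
    bins <- equal_signal_bins(w, order_by = hs$centromere_distance)
    co_counts <- tabulate(
      match(res$outcomes$crossovers$hotspot_id, hs$hotspot_id),
      nbins = nrow(hs)
    )
    bf_co <- bin_fractions(bins, co_counts, n_boot = n_boot, seed = stage_seed(8))
    bf_rpa <- bin_fractions(bins, res$intensity$intensity_rpa_template,
                            n_boot = n_boot, seed = stage_seed(9))
    w_bin <- vapply(1:4, function(b) sum(w[bins == b]), numeric(1))
    rates <- rescale_crossover_rate(bf_co$events, w_bin, mean_rate = co_share)
    rpa_per_dsb <- bf_rpa$events / w_bin
    ls <- estimate_lifespans(rates$rate, rpa_per_dsb,
                             sister_fraction = sister_fraction,
                             co_share = co_share)
    f <- file.path(out_dir, "dloop.json")
    jsonlite::write_json(
      list(bins = bins, co_fractions = bf_co, rpa_fractions = bf_rpa,
           rates = rates,
           lifespans = list(L_co = ls$L_co, L_nco = ls$L_nco, ratio = ls$ratio)),
      f, auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
    emit("dloop", f)
    res$dloop <- list(bins = bins, co = bf_co, rpa = bf_rpa, rates = rates,
                      lifespans = ls)
  }

  ## ---- tracts --------------------------------------------------------
  if ("tracts" %in% stages) {
    say("tracts: breakpoint and containment maps")
    s <- spo11_distribution(res$sim)
    bmap <- breakpoint_probability_map(res$outcomes$crossovers)
    dmap <- deconvolve_map(bmap, s, tol = tol)
    cont <- tract_containment(dmap$bp, pmax(dmap$mass, 0))
    nmap <- nco_tract_map(res$outcomes$ncos, s, tol = tol)
    f <- file.path(out_dir, "tract_maps.tsv")
    utils::write.table(
      data.frame(bp = dmap$bp, co_breakpoint = dmap$mass,
                 co_containment = cont$containment,
                 nco_tract = nmap$deconvolved$mass),
      f, sep = "\t", quote = FALSE, row.names = FALSE
    )
    emit("tracts", f)
    res$tracts <- list(breakpoints = bmap, deconvolved = dmap,
                       containment = cont, nco = nmap)
  }

  ## ---- foci ----------------------------------------------------------
  if ("foci" %in% stages) {
    say("foci: axis distances and co-foci (threshold %g nm)", cofocus_threshold)
    if (is.null(res$foci_sim)) {
      res$foci_sim <- simulate_foci(seed = stage_seed(7))
    }
    fs <- res$foci_sim
    fd <- foci_axis_distances(fs$foci, fs$axes)
    cf <- cofoci_summary(fd, c("RAD51", "DMC1"), threshold = cofocus_threshold)
    cmpx <- axis_proximity_compare(
      fd$axis_distance[fd$channel == "RAD51"],
      fd$axis_distance[fd$channel == "DMC1"]
    )
    unif <- tryCatch(
      offaxis_uniformity(fd$axis_distance[fd$channel == "RAD51"],
                         cutoff = 450,
                         field_extent = if (!is.null(fs$field)) fs$field else 1e4),
      error = function(e) list(p = NA_real_, statistic = NA_real_, n = 0L)
    )
    f <- file.path(out_dir, "foci_summary.json")
    jsonlite::write_json(
      list(cofocus_fraction_rad51 = cf$fraction_a,
           cofocus_fraction_dmc1 = cf$fraction_b,
           median_offset = cf$median_offset,
           median_axis_distance_rad51 = cmpx$median_a,
           median_axis_distance_dmc1 = cmpx$median_b,
           proximity_p = cmpx$p,
           offaxis_uniformity_p = unif$p),
      f, auto_unbox = TRUE, digits = NA
    )
    emit("foci", f)
    res$foci <- list(distances = fd, cofoci = cf, proximity = cmpx,
                     uniformity = unif)
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  if (!file.exists(cfg_file)) write_config_yaml(config, cfg_file)
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, log_file)
  res$manifest <- manifest
  invisible(res)
}
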
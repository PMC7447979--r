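#' Write a hotspot table as a BED-like TSV
#'
#' 0-based, half-open intervals: each motif centre (1-based coordinate `c`)
#' is written as the 1-bp interval `[c - 1, c)`.
#'
#' @param hotspots hotspot data.frame (as in `hotspot_sim$hotspots`).
#' @param file output path.
#' @export
write_hotspots_bed <- function(hotspots, file) {
  out <- data.frame(
    chrom = hotspots$chrom,
    start = hotspots$center - 1L,
    end = hotspots$center,
    hotspot_id = hotspots$hotspot_id,
    allele = hotspots$allele,
    f = hotspots$f,
    spo11_count = hotspots$spo11_count,
    skew_side = hotspots$skew_side,
    centromere_distance = hotspots$centromere_distance
  )
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a BED-like hotspot table written by [write_hotspots_bed()]
#' @param file path.
#' @return hotspot data.frame with 1-based `center`.
#' @export
read_hotspots_bed <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$center <- df$end
  df[c("hotspot_id", "chrom", "center", "allele", "f", "spo11_count",
       "skew_side", "centromere_distance")]
}

covset_granges <- function(covset, strand) {
  stopifnot(!is.null(covset$hotspots))
  hs <- covset$hotspots
  bw <- covset$bin_width
  mat <- covset[[strand]]
  n <- nrow(mat)
  ## clip each hotspot's window to half the gap to its neighbour so the
  ## written intervals are disjoint
  half_span <- rep(max(covset$j) * bw + bw / 2, n)
  if (n > 1) {
    gaps <- vapply(seq_len(n),
                   function(i) min(abs(hs$center[-i] - hs$center[i])), numeric(1))
    half_span <- pmin(half_span, floor(gaps / 2) - bw)
  }
  grs <- lapply(seq_len(n), function(i) {
    keep <- abs(bw * covset$j) <= half_span[i]
    starts <- hs$center[i] + bw * covset$j[keep] - bw / 2
    GenomicRanges::GRanges(
      seqnames = hs$chrom[i],
      ranges = IRanges::IRanges(start = starts, width = bw),
      score = mat[i, keep]
    )
  })
  gr <- do.call(c, grs)
  gr[gr$score != 0]
}

#' Export a coverage set as strand-specific bedGraph files
#'
#' One 4-column bedGraph per strand; per-hotspot windows are clipped to
#' half the distance to the nearest neighbouring hotspot so intervals stay
#' disjoint, and zero bins are omitted.
#'
#' @param covset a [coverage_set()] with a hotspot table.
#' @param file_crick,file_watson output paths.
#' @export
write_coverage_bedgraph <- function(covset, file_crick, file_watson) {
  rtracklayer::export.bedGraph(covset_granges(covset, "crick"), file_crick)
  rtracklayer::export.bedGraph(covset_granges(covset, "watson"), file_watson)
  invisible(c(file_crick, file_watson))
}

#' Extract hotspot-centred coverage from bedGraph files
#'
#' Reads strand-specific bedGraph coverage and re-extracts per-hotspot
#' binned profiles around each hotspot centre (bins with no record are 0).
#'
#' @param file_crick,file_watson bedGraph paths.
#' @param hotspots hotspot data.frame with `chrom` and `center`.
#' @param j bin indices to extract (default `-250:250`).
#' @param bin_width bin width in bp.
#' @return a [coverage_set()].
#' @export
read_coverage_bedgraph <- function(file_crick, file_watson, hotspots,
                                   j = -250:250, bin_width = 20) {
  extract <- function(file) {
    gr <- rtracklayer::import(file, format = "bedGraph")
    mat <- matrix(0, nrow(hotspots), length(j))
    mids <- GenomicRanges::GRanges(
      seqnames = rep(hotspots$chrom, each = length(j)),
      ranges = IRanges::IRanges(
        start = rep(hotspots$center, each = length(j)) + bin_width * rep(j, nrow(hotspots)),
        width = 1
      )
    )
    hits <- GenomicRanges::findOverlaps(mids, gr, select = "first")
    sc <- ifelse(is.na(hits), 0, gr$score[hits])
    matrix(sc, nrow(hotspots), length(j), byrow = TRUE)
  }
  coverage_set(extract(file_crick), extract(file_watson), j = j,
               hotspots = hotspots, bin_width = bin_width)
}

#' Write an offset distribution as TSV (columns l, bp, count)
#' @param s an [offset_distribution()].
#' @param file path.
#' @export
write_offsets_tsv <- function(s, file) {
  utils::write.table(
    data.frame(l = s$l, bp = 20 * s$l, count = s$counts),
    file, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(file)
}

#' Read an offset distribution TSV
#' @param file path.
#' @export
read_offsets_tsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  offset_distribution(df$count, m = max(df$l))
}

#' Write a deconvolved profile as TSV (k, bp, b_crick, b_watson, b_mean)
#' @param dp a `deconvolved_profile`.
#' @param file path.
#' @export
write_deconvolved_tsv <- function(dp, file) {
  utils::write.table(
    data.frame(k = dp$k, bp = dp$bp, b_crick = dp$b_crick,
               b_watson = dp$b_watson, b_mean = dp$b_mean),
    file, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(file)
}

#' Write crossover and non-crossover outcome tables as TSV
#'
#' Crossover internal SNPs are comma-joined in the `internal_snps` column.
#'
#' @param outcomes an `outcome_sim`.
#' @param file_co,file_nco output paths.
#' @export
write_outcomes_tsv <- function(outcomes, file_co, file_nco) {
  co <- outcomes$crossovers
  if (!is.null(co)) {
    co$internal_snps <- vapply(co$internal_snps, paste, character(1), collapse = ",")
    utils::write.table(co, file_co, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(outcomes$ncos)) {
    utils::write.table(outcomes$ncos, file_nco, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(file_co, file_nco))
}

#' Read outcome tables written by [write_outcomes_tsv()]
#' @param file_co,file_nco paths (either may be missing on disk).
#' @return list with `crossovers` and `ncos`.
#' @export
read_outcomes_tsv <- function(file_co, file_nco) {
  co <- nco <- NULL
  if (file.exists(file_co)) {
    co <- utils::read.table(file_co, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    co$internal_snps <- lapply(strsplit(as.character(co$internal_snps), ","),
                               function(v) as.numeric(v[nzchar(v)]))
  }
  if (file.exists(file_nco)) {
    nco <- utils::read.table(file_nco, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  list(crossovers = co, ncos = nco)
}

#' Write focus and axis coordinate tables as TSV
#' @param fsim a `foci_sim` (or list with `foci` and `axes` data.frames).
#' @param file_foci,file_axes output paths.
#' @export
write_foci_tsv <- function(fsim, file_foci, file_axes) {
  utils::write.table(fsim$foci, file_foci, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fsim$axes, file_axes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(file_foci, file_axes))
}

#' Read focus and axis tables
#' @param file_foci,file_axes paths.
#' @return list with `foci` and `axes`.
#' @export
read_foci_tsv <- function(file_foci, file_axes) {
  list(
    foci = utils::read.table(file_foci, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE),
    axes = utils::read.table(file_axes, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  )
}

#' Serialise a generator configuration to YAML
#'
#' Kernels are stored as their bin/mass vectors and reconstructed on read.
#'
#' @param cfg a [generator_config()].
#' @param file path.
#' @export
write_config_yaml <- function(cfg, file) {
  ser <- unclass(cfg)
  for (kn in c("kernel_dmc1", "kernel_rad51", "kernel_rpa_template")) {
    kk <- ser[[kn]]
    ser[[kn]] <- list(k = kk$k, mass = kk$mass, polarity = kk$polarity)
  }
  ser$dsb_offset_model$flanks <- if (!is.null(ser$dsb_offset_model$flanks)) {
    as.list(ser$dsb_offset_model$flanks)
  }
  yaml::write_yaml(ser, file, precision = 15)
  invisible(file)
}

#' Read a generator configuration from YAML
#' @param file path.
#' @return a validated [generator_config()].
#' @export
read_config_yaml <- function(file) {
  raw <- yaml::read_yaml(file)
  for (kn in c("kernel_dmc1", "kernel_rad51", "kernel_rpa_template")) {
    kk <- raw[[kn]]
    raw[[kn]] <- binding_kernel(unlist(kk$k), unlist(kk$mass),
                                polarity = kk$polarity)
  }
  if (!is.null(raw$dsb_offset_model$flanks)) {
    raw$dsb_offset_model$flanks <- as.data.frame(raw$dsb_offset_model$flanks)
  }
  raw$rpa_dsb_mix <- stats::setNames(unlist(raw$rpa_dsb_mix), c("dmc1", "rad51"))
  args <- raw[names(raw) %in% names(formals(generator_config))]
  do.call(generator_config, args)
}
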
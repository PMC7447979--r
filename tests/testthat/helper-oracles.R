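# Independent oracles and small builders shared across the suite.

# Forward convolution by explicit summation (independent of
# transform_matrix): coverage_j = sum_k s_{j-k} * b_k.
forward_convolve <- function(s_counts, m, b, k, j) {
  vapply(j, function(jj) {
    acc <- 0
    for (ki in seq_along(k)) {
      lag <- jj - k[ki]
      if (lag >= -m && lag <= m) acc <- acc + s_counts[lag + m + 1L] * b[ki]
    }
    acc
  }, numeric(1))
}

# Strand profile on bins j with given per-bin values.
make_profile <- function(crick, watson = rev(crick), j = -250:250,
                         corrected = FALSE) {
  strand_profile(crick, watson, j = j, background_corrected = corrected)
}

# Profile that is zero except for named bp -> value assignments per strand.
profile_with <- function(crick_at = NULL, watson_at = NULL, j = -250:250,
                         base = 0) {
  cr <- rep(base, length(j)); wa <- rep(base, length(j))
  bp <- 20 * j
  for (nm in names(crick_at)) cr[bp == as.numeric(nm)] <- crick_at[[nm]]
  for (nm in names(watson_at)) wa[bp == as.numeric(nm)] <- watson_at[[nm]]
  make_profile(cr, wa, j = j)
}

# Tiny generator config for fast simulation tests.
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_hotspots = 20, chrom_length = 2e6, seed = 42),
                            list(...))
  do.call(generator_config, args)
}

# Hand-built hotspot_sim with fully controlled offsets (all hotspots share
# one chromosome; spo11_count matches the offset vectors).
manual_sim <- function(offsets_list, config = tiny_config(),
                       skew_side = "none") {
  n <- length(offsets_list)
  hotspots <- data.frame(
    hotspot_id = seq_len(n), chrom = "chrSim",
    center = seq_len(n) * 10000 + 10000,
    allele = "CAST", f = 0.5,
    spo11_count = lengths(offsets_list),
    skew_side = rep_len(skew_side, n),
    centromere_distance = seq_len(n) * 10000 + 10000,
    stringsAsFactors = FALSE
  )
  structure(list(hotspots = hotspots, offsets = offsets_list, config = config),
            class = "hotspot_sim")
}
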
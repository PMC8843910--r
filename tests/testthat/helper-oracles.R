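# Independent brute-force oracle for the segment fit: naive scalar loops over
# the same hypothesis grid, strict-improvement argmin (which realises the
# smaller-N, smaller-m, smaller-rho tie-break by iteration order).
brute_force_fit <- function(b_obs, r_obs, config = cc_model_config()) {
  k <- floor(1 / config$rho_grid_step + 1e-9)
  best <- NULL
  best_obj <- Inf
  for (n in sort(config$hypothesis_n_range)) {
    for (m in 0:(n %/% 2)) {
      for (i in 1:k) {
        rho <- i * config$rho_grid_step
        cc <- 2 * (1 - rho) + n * rho
        if (cc <= 0) next
        bb <- ((1 - rho) + m * rho) / cc
        bhat <- min(bb, 1 - bb)
        rhat <- log2(cc / 2)
        obj <- config$weight_log2r * (r_obs - rhat)^2
        if (!is.na(b_obs)) obj <- obj + config$weight_baf * (b_obs - bhat)^2
        if (obj < best_obj) {
          best_obj <- obj
          best <- list(n_total = n, m_minor = m, rho = rho)
        }
      }
    }
  }
  best
}

# Segment-table row builder for caller tests.
make_segment <- function(sample_id = "S1", chrom = "chr1", log2r = 0,
                         folded_baf = 0.5, n_probes = 500L,
                         n_het = max(1L, as.integer(n_probes * 0.25)),
                         start = 0L, end = 1000000L) {
  if (is.na(folded_baf)) n_het <- 0L
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             n_probes = as.integer(n_probes), n_het = n_het,
             log2r = log2r, folded_baf = folded_baf, stringsAsFactors = FALSE)
}

# Noiseless forward segment for a NOMA = 0 hypothesis.
forward_segment <- function(rho, n_total, chrom = "chr1", sample_id = "S1",
                            n_probes = 500L) {
  make_segment(sample_id, chrom,
               log2r = expected_log2r(rho, n_total),
               folded_baf = expected_folded_baf(rho, n_total, 0L),
               n_probes = n_probes)
}
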
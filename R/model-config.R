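#' Configuration of the aberration model and CC caller
#'
#' Collects every tunable parameter of the segment-fitting model and of the
#' per-sample clonal-composition caller.  Defaults are chosen for
#' OncoScan-style molecular-inversion-probe arrays, where segment-level folded
#' BAF is accurate to roughly 0.01–0.02 and segment log2R to roughly 0.05.
#'
#' @param hypothesis_n_range Integer vector of total copy numbers `N`
#'   enumerated in the aberrant cells (default `0:4`).
#' @param qualifying_n_set Integer vector of `N` values whose zero-minor-allele
#'   (NOMA = 0) states may contribute to the CC number.  The default
#'   `c(1, 2)` admits hemizygous loss and copy-neutral LOH.
#' @param rho_grid_step Grid step for the aberrant-cell fraction rho in (0, 1]
#'   (default 0.01, i.e. 1 percentage point of %AC).
#' @param rho_min Smallest aberrant-cell fraction accepted as a clone
#'   (default 0.05); guards against noise-level "clones".
#' @param gate_eps_baf,gate_eps_log2r Residual gates on |observed - fitted|
#'   folded BAF and log2R for a segment to count as lying on a fitting curve
#'   (defaults 0.025 and 0.10).
#' @param weight_baf,weight_log2r Weights of the squared BAF and log2R
#'   residuals in the joint fit objective (defaults 1.0 and 0.25; BAF is the
#'   primary signal, log2R disambiguates `N`).
#' @param aberrance_baf_floor Folded BAF below which a segment is screened as
#'   aberrant (default 0.45).
#' @param aberrance_log2r_band Absolute log2R beyond which a segment is
#'   screened as aberrant (default 0.10).
#' @param min_probes Minimum probes per segment for the screen (default 50).
#' @param merge_delta_ac Clusters whose probe-weighted %AC differ by at most
#'   this many percentage points are combined (default 5.0).
#' @param stage1_tol_baf,stage1_tol_log2r Per-axis single-linkage tolerances
#'   for the first clustering stage in (folded BAF, log2R) space
#'   (defaults 0.02 and 0.08).
#' @param count_mode `"clusters"` (default) counts every distinct %AC cluster,
#'   so CC = 0 means no qualifying aberration was detected; `"subclones"`
#'   counts clusters minus one (never below zero).
#'
#' @return An object of class `"cc_model_config"` (a validated list).
#' @examples
#' cfg <- cc_model_config()
#' cfg$qualifying_n_set
#' @export
cc_model_config <- function(hypothesis_n_range = 0:4,
                            qualifying_n_set = c(1L, 2L),
                            rho_grid_step = 0.01,
                            rho_min = 0.05,
                            gate_eps_baf = 0.025,
                            gate_eps_log2r = 0.10,
                            weight_baf = 1.0,
                            weight_log2r = 0.25,
                            aberrance_baf_floor = 0.45,
                            aberrance_log2r_band = 0.10,
                            min_probes = 50L,
                            merge_delta_ac = 5.0,
                            stage1_tol_baf = 0.02,
                            stage1_tol_log2r = 0.08,
                            count_mode = c("clusters", "subclones")) {
  count_mode <- match.arg(count_mode)
  hypothesis_n_range <- sort(unique(as.integer(hypothesis_n_range)))
  qualifying_n_set <- sort(unique(as.integer(qualifying_n_set)))
  if (any(hypothesis_n_range < 0L))
    stop("hypothesis_n_range must be non-negative integers")
  if (!all(qualifying_n_set %in% setdiff(hypothesis_n_range, 0L)))
    stop("qualifying_n_set must be a subset of hypothesis_n_range excluding 0")
  if (!(rho_grid_step > 0 && rho_grid_step <= 0.1))
    stop("rho_grid_step must be in (0, 0.1] so the grid has at least 10 points")
  tol <- c(rho_min = rho_min, gate_eps_baf = gate_eps_baf,
           gate_eps_log2r = gate_eps_log2r, merge_delta_ac = merge_delta_ac,
           stage1_tol_baf = stage1_tol_baf, stage1_tol_log2r = stage1_tol_log2r,
           aberrance_baf_floor = aberrance_baf_floor,
           aberrance_log2r_band = aberrance_log2r_band)
  if (any(!is.finite(tol)) || any(tol <= 0))
    stop("all tolerances and thresholds must be positive: ",
         paste(names(tol)[!is.finite(tol) | tol <= 0], collapse = ", "))
  if (weight_baf < 0 || weight_log2r < 0 || weight_baf + weight_log2r <= 0)
    stop("fit weights must be non-negative and not both zero")
  if (min_probes < 1L) stop("min_probes must be >= 1")
  structure(list(
    hypothesis_n_range = hypothesis_n_range,
    qualifying_n_set = qualifying_n_set,
    rho_grid_step = rho_grid_step,
    rho_min = rho_min,
    gate_eps_baf = gate_eps_baf,
    gate_eps_log2r = gate_eps_log2r,
    weight_baf = weight_baf,
    weight_log2r = weight_log2r,
    aberrance_baf_floor = aberrance_baf_floor,
    aberrance_log2r_band = aberrance_log2r_band,
    min_probes = as.integer(min_probes),
    merge_delta_ac = merge_delta_ac,
    stage1_tol_baf = stage1_tol_baf,
    stage1_tol_log2r = stage1_tol_log2r,
    count_mode = count_mode
  ), class = "cc_model_config")
}

#' @export
print.cc_model_config <- function(x, ...) {
  cat("Clonal composition model configuration\n")
  cat("  hypotheses: N in {", paste(x$hypothesis_n_range, collapse = ", "),
      "}, qualifying N in {", paste(x$qualifying_n_set, collapse = ", "),
      "}, m = 0 only qualifies\n", sep = "")
  cat(sprintf("  rho grid step %.3g (rho >= %.3g)\n", x$rho_grid_step, x$rho_min))
  cat(sprintf("  residual gates: BAF %.3g, log2R %.3g; fit weights %.3g : %.3g\n",
              x$gate_eps_baf, x$gate_eps_log2r, x$weight_baf, x$weight_log2r))
  cat(sprintf("  aberrance screen: folded BAF < %.3g or |log2R| > %.3g, >= %d probes\n",
              x$aberrance_baf_floor, x$aberrance_log2r_band, x$min_probes))
  cat(sprintf("  clustering: stage-1 tolerances (%.3g, %.3g); merge within %.1f %%AC; mode %s\n",
              x$stage1_tol_baf, x$stage1_tol_log2r, x$merge_delta_ac, x$count_mode))
  invisible(x)
}
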
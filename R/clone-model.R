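#' Expected copy number of a mixed normal/aberrant segment
#'
#' A segment carried at `n_total` copies by a clone present in a fraction
#' `rho` of cells, with the remaining `1 - rho` of cells diploid, has
#' sample-average copy number `c = 2 (1 - rho) + n_total * rho`.
#'
#' @param rho Aberrant-cell fraction in `[0, 1]` (%AC / 100). Vectorized.
#' @param n_total Total copies of the segment in the aberrant cells (`N >= 0`).
#' @return The sample-average copy number.
#' @examples
#' expected_total_copy(0.5, 1)  # 1.5
#' @export
expected_total_copy <- function(rho, n_total) {
  check_rho(rho)
  check_hypothesis(n_total, 0L)
  2 * (1 - rho) + n_total * rho
}

#' Expected log2 ratio of a mixed segment
#'
#' `log2(c / 2)` where `c` is [expected_total_copy()]: 0 for diploid, -1 for
#' a pure one-copy loss, +1 for a pure four-copy state.
#'
#' @inheritParams expected_total_copy
#' @return Expected log2R.
#' @examples
#' expected_log2r(1, 4)  # 1
#' @export
expected_log2r <- function(rho, n_total) {
  cc <- expected_total_copy(rho, n_total)
  if (any(cc <= 0))
    stop("total copy number is zero (rho = 1, n_total = 0): log2R undefined")
  log2(cc / 2)
}

#' Expected folded B-allele frequency of a mixed segment
#'
#' At a germline-heterozygous site the normal cells contribute one copy of
#' each allele and the aberrant cells `m_minor` copies of the minor allele
#' out of `n_total`, so the unfolded BAF is
#' `b = ((1 - rho) + m_minor * rho) / c`.  Allele labels on an array are
#' arbitrary, so the model works with the folded value `min(b, 1 - b)` in
#' `[0, 0.5]`: 0.5 is heterozygous, 0 is complete loss of heterozygosity.
#'
#' @inheritParams expected_total_copy
#' @param m_minor Minor-allele copies in the aberrant cells (the NOMA);
#'   requires `m_minor <= n_total - m_minor`.
#' @return Folded BAF in `[0, 0.5]`.
#' @examples
#' expected_folded_baf(0.5, 2, 0)  # 0.25: copy-neutral LOH in half the cells
#' @export
expected_folded_baf <- function(rho, n_total, m_minor) {
  check_rho(rho)
  check_hypothesis(n_total, m_minor)
  cc <- 2 * (1 - rho) + n_total * rho
  if (any(cc <= 0))
    stop("total copy number is zero: BAF undefined")
  b <- ((1 - rho) + m_minor * rho) / cc
  pmin(b, 1 - b)
}

#' Invert the folded-BAF model for the aberrant-cell fraction
#'
#' Closed-form inverse of [expected_folded_baf()]:
#' `rho = (1 - 2 b) / (1 - m_minor + (n_total - 2) * b)`.
#' The map is non-invertible for balanced states (`n_total = 2 * m_minor`,
#' including homozygous deletion `N = m = 0`), whose folded BAF is
#' identically 0.5.
#'
#' @param b Folded BAF in `[0, 0.5]`. Vectorized.
#' @inheritParams expected_folded_baf
#' @return The aberrant-cell fraction `rho`.
#' @examples
#' rho_from_folded_baf(0.25, 2, 0)  # 0.5
#' @export
rho_from_folded_baf <- function(b, n_total, m_minor) {
  check_hypothesis(n_total, m_minor)
  if (any(!is.finite(b)) || any(b < 0) || any(b > 0.5))
    stop("'b' must be a folded BAF in [0, 0.5]")
  if (n_total == 2 * m_minor)
    stop("hypothesis N = ", n_total, ", m = ", m_minor,
         " is balanced: folded BAF is identically 0.5 and cannot be inverted")
  den <- 1 - m_minor + (n_total - 2) * b
  if (any(den <= 0))
    stop("non-invertible: denominator 1 - m + (N - 2) b is not positive")
  (1 - 2 * b) / den
}

#' Invert the log2R model for the aberrant-cell fraction
#'
#' `rho = (2 - 2 * 2^r) / (2 - n_total)`.  Copy-neutral states
#' (`n_total = 2`) have log2R identically 0 at every `rho` and cannot be
#' inverted.  The returned value is not clipped; values outside `[0, 1]`
#' indicate an observation inconsistent with the hypothesis.
#'
#' @param r Observed log2R. Vectorized.
#' @inheritParams expected_total_copy
#' @return The (unclipped) aberrant-cell fraction.
#' @examples
#' rho_from_log2r(-1, 1)  # 1: pure one-copy loss
#' @export
rho_from_log2r <- function(r, n_total) {
  check_hypothesis(n_total, 0L)
  if (n_total == 2L)
    stop("N = 2 is copy-neutral: log2R is identically 0 and cannot be inverted")
  if (any(!is.finite(r))) stop("'r' must be finite")
  (2 - 2 * 2^r) / (2 - n_total)
}

#' Fitting curve of an aberration hypothesis
#'
#' The locus of (folded BAF, log2R) pairs traced by a `(n_total, m_minor)`
#' state as the aberrant-cell fraction varies.  Observed segments far from
#' every such curve cannot be assigned to a clone.
#'
#' @inheritParams expected_folded_baf
#' @param rho_grid Fractions in `[0, 1]` at which to evaluate the curve.
#' @return A data frame with columns `rho`, `folded_baf`, `log2r`.
#' @examples
#' head(fitting_curve(1, 0, seq(0, 1, 0.25)))
#' @export
fitting_curve <- function(n_total, m_minor, rho_grid) {
  check_hypothesis(n_total, m_minor)
  check_rho(rho_grid)
  cc <- 2 * (1 - rho_grid) + n_total * rho_grid
  keep <- cc > 0
  rho <- rho_grid[keep]
  data.frame(rho = rho,
             folded_baf = expected_folded_baf(rho, n_total, m_minor),
             log2r = expected_log2r(rho, n_total))
}

# Enumerate the full hypothesis grid for a configuration: rows ordered by
# (N asc, m asc, rho asc) so that which.min() of the objective realises the
# documented tie-break. Rows with zero total copy (N = 0, rho = 1) are dropped.
hypothesis_grid <- function(config) {
  k <- floor(1 / config$rho_grid_step + 1e-9)
  rho <- (seq_len(k)) * config$rho_grid_step
  rho[k] <- min(rho[k], 1)
  pieces <- lapply(config$hypothesis_n_range, function(n) {
    do.call(rbind, lapply(0:(n %/% 2L), function(m)
      data.frame(n_total = n, m_minor = m, rho = rho)))
  })
  g <- do.call(rbind, pieces)
  g$total_copies <- 2 * (1 - g$rho) + g$n_total * g$rho
  g <- g[g$total_copies > 0, , drop = FALSE]
  b <- ((1 - g$rho) + g$m_minor * g$rho) / g$total_copies
  g$folded_baf <- pmin(b, 1 - b)
  g$log2r <- log2(g$total_copies / 2)
  rownames(g) <- NULL
  g
}

#' Fit the aberration model to one segment
#'
#' Enumerates every hypothesis `(N, m, rho)` on the configured grid and
#' minimizes the weighted squared distance
#' `weight_baf * (b_obs - b_hat)^2 + weight_log2r * (r_obs - r_hat)^2`.
#' Ties are broken toward smaller `N`, then smaller `m`, then smaller `rho`,
#' so the result is reproducible bit for bit.
#'
#' A segment qualifies for the CC count only if the best hypothesis has
#' `m = 0`, `N` in the qualifying set, both residuals within the curve gates,
#' and `rho >= rho_min`.  When `b_obs` is missing (no heterozygous probes)
#' the fit uses log2R alone and the segment can never qualify.
#'
#' @param b_obs Observed folded BAF in `[0, 0.5]`, or `NA`.
#' @param r_obs Observed log2R (finite).
#' @param config A [cc_model_config()].
#' @return An object of class `"cc_fit"`: a list with the best hypothesis
#'   (`n_total`, `m_minor`, `rho`), `total_copies`, `expected_folded_baf`,
#'   `expected_log2r`, residuals, the objective value, and the flags
#'   `is_aberrant`, `qualifies_for_cc`, `no_het_probes`.
#' @examples
#' fit_segment(1 / 3, log2(0.75), cc_model_config())  # N = 1, m = 0, rho = 0.5
#' @export
fit_segment <- function(b_obs, r_obs, config = cc_model_config()) {
  stopifnot(inherits(config, "cc_model_config"))
  if (length(b_obs) != 1L || length(r_obs) != 1L)
    stop("fit_segment() fits one segment at a time")
  if (!is.finite(r_obs)) stop("'r_obs' must be finite")
  no_het <- is.na(b_obs)
  if (!no_het && (b_obs < 0 || b_obs > 0.5))
    stop("'b_obs' must be a folded BAF in [0, 0.5] or NA")
  g <- hypothesis_grid(config)
  obj <- config$weight_log2r * (r_obs - g$log2r)^2
  if (!no_het) obj <- obj + config$weight_baf * (b_obs - g$folded_baf)^2
  i <- which.min(obj)
  best <- g[i, ]
  residual_baf <- if (no_het) NA_real_ else abs(b_obs - best$folded_baf)
  residual_log2r <- abs(r_obs - best$log2r)
  is_aberrant <- (!no_het && b_obs < config$aberrance_baf_floor) ||
    abs(r_obs) > config$aberrance_log2r_band
  qualifies <- !no_het &&
    best$m_minor == 0L &&
    best$n_total %in% config$qualifying_n_set &&
    residual_baf <= config$gate_eps_baf &&
    residual_log2r <= config$gate_eps_log2r &&
    best$rho >= config$rho_min
  structure(list(
    n_total = as.integer(best$n_total),
    m_minor = as.integer(best$m_minor),
    rho = best$rho,
    total_copies = best$total_copies,
    expected_folded_baf = best$folded_baf,
    expected_log2r = best$log2r,
    residual_baf = residual_baf,
    residual_log2r = residual_log2r,
    objective = obj[i],
    is_aberrant = is_aberrant,
    qualifies_for_cc = qualifies,
    no_het_probes = no_het
  ), class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat(sprintf("Segment fit: N = %d, m = %d, rho = %.2f (%%AC %.0f)\n",
              x$n_total, x$m_minor, x$rho, 100 * x$rho))
  cat(sprintf("  expected (BAF %.4f, log2R %.4f); residuals (%s, %.4f)\n",
              x$expected_folded_baf, x$expected_log2r,
              if (is.na(x$residual_baf)) "no-het-probes"
              else sprintf("%.4f", x$residual_baf),
              x$residual_log2r))
  cat(sprintf("  aberrant: %s; qualifies for CC: %s\n",
              x$is_aberrant, x$qualifies_for_cc))
  invisible(x)
}

check_rho <- function(rho) {
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1))
    stop("'rho' must lie in [0, 1]", call. = FALSE)
  invisible(rho)
}

check_hypothesis <- function(n_total, m_minor) {
  if (length(n_total) != 1L || n_total < 0 || n_total != round(n_total))
    stop("'n_total' must be a single non-negative integer", call. = FALSE)
  if (length(m_minor) != 1L || m_minor < 0 || m_minor != round(m_minor))
    stop("'m_minor' must be a single non-negative integer", call. = FALSE)
  if (m_minor > n_total - m_minor)
    stop("'m_minor' exceeds n_total - m_minor: not a minor allele", call. = FALSE)
  invisible(NULL)
}
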
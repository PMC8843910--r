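#' Screen segments for copy-number aberrance
#'
#' A segment enters the CC analysis when it has at least `min_probes` probes
#' and shows either an allelic-imbalance signal (folded BAF below
#' `aberrance_baf_floor`) or an intensity signal (|log2R| above
#' `aberrance_log2r_band`).
#'
#' @param segments Segment data frame (see [segment-files]).
#' @param config A [cc_model_config()].
#' @return Logical vector, one element per segment.
#' @export
screen_aberrant <- function(segments, config = cc_model_config()) {
  baf_hit <- !is.na(segments$folded_baf) &
    segments$folded_baf < config$aberrance_baf_floor
  r_hit <- abs(segments$log2r) > config$aberrance_log2r_band
  (baf_hit | r_hit) & segments$n_probes >= config$min_probes
}

# LOH arm of the screen only: the segments whose BAF pattern demands a
# NOMA = 0 explanation; used to decide "undetermined".
screen_loh <- function(segments, config) {
  !is.na(segments$folded_baf) &
    segments$folded_baf < config$aberrance_baf_floor &
    segments$n_probes >= config$min_probes
}

#' Call the clonal composition of one sample
#'
#' Runs the per-sample CC pipeline: (i) screen segments for aberrance;
#' (ii) fit the aberration model to each screened segment ([fit_segment()]);
#' (iii) single-linkage clustering of qualifying segments in
#' (folded BAF, log2R) with per-axis tolerances; (iv) merging of clusters
#' whose probe-weighted %AC differ by at most `merge_delta_ac`; (v) the CC
#' number is the number of merged clusters.
#'
#' The status is `"undetermined"` when at least one segment shows the LOH
#' signal (folded BAF below the aberrance floor) but no segment lies on any
#' qualifying fitting curve — the copy-number data "do not plot onto the
#' fitting curve".  If only some LOH segments are off-curve they are dropped
#' with a warning and the CC number is computed from the rest.
#'
#' @param segments Segment data frame for a single sample.
#' @param config A [cc_model_config()].
#' @return An object of class `"cc_result"`: a list with `sample_id`,
#'   `status` (`"estimated"` / `"undetermined"`), `cc_number` (`NA` when
#'   undetermined), `classification` (`"mono"`, `"poly"`, `"undetermined"`),
#'   `clusters` (data frame: `cluster_id`, `ac_percent`, `n_segments`,
#'   `total_probes`) and `segments` (the input annotated with fit columns).
#' @examples
#' seg <- data.frame(sample_id = "S1", chrom = c("chr1", "chr2"),
#'                   start = 0L, end = 1000000L, n_probes = 500L, n_het = 120L,
#'                   log2r = log2(0.75), folded_baf = 1 / 3)
#' call_sample(seg)  # one clone at %AC 50
#' @export
call_sample <- function(segments, config = cc_model_config()) {
  stopifnot(inherits(config, "cc_model_config"))
  if (!nrow(segments)) stop("call_sample() needs at least one segment")
  ids <- unique(segments$sample_id)
  if (length(ids) != 1L)
    stop("segments belong to more than one sample: ", paste(ids, collapse = ", "))

  # deterministic internal order so results are invariant to input row order
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL

  aberrant <- screen_aberrant(segments, config)
  loh <- screen_loh(segments, config)

  n <- nrow(segments)
  fit_cols <- data.frame(n_total = rep(NA_integer_, n), noma = NA_integer_,
                         rho = NA_real_, residual_baf = NA_real_,
                         residual_log2r = NA_real_, qualifies = FALSE)
  for (i in which(aberrant)) {
    f <- fit_segment(segments$folded_baf[i], segments$log2r[i], config)
    fit_cols$n_total[i] <- f$n_total
    fit_cols$noma[i] <- f$m_minor
    fit_cols$rho[i] <- f$rho
    fit_cols$residual_baf[i] <- f$residual_baf
    fit_cols$residual_log2r[i] <- f$residual_log2r
    fit_cols$qualifies[i] <- f$qualifies_for_cc
  }
  annotated <- cbind(segments, fit_cols)

  q <- which(fit_cols$qualifies)
  off_curve_loh <- sum(loh & !fit_cols$qualifies)

  if (length(q) == 0L && any(loh)) {
    return(new_cc_result(ids, "undetermined", NA_integer_,
                         empty_clusters(), annotated))
  }
  if (off_curve_loh > 0L && length(q) > 0L)
    warning(sprintf("%s: %d LOH segment(s) off every fitting curve were dropped",
                    ids, off_curve_loh), call. = FALSE)

  if (length(q) == 0L) {
    cc <- 0L  # nothing qualifies and nothing demands LOH: homogeneous mass
    return(new_cc_result(ids, "estimated", cc, empty_clusters(), annotated))
  }

  stage1 <- cluster_single_linkage(
    annotated$folded_baf[q], annotated$log2r[q],
    config$stage1_tol_baf, config$stage1_tol_log2r)
  # probe-weighted %AC per stage-1 cluster
  ac1 <- vapply(split(q, stage1), function(idx)
    100 * stats::weighted.mean(annotated$rho[idx], annotated$n_probes[idx]),
    numeric(1))
  merged <- merge_by_ac(ac1, config$merge_delta_ac)
  # merged cluster %AC recomputed over member segments
  member <- split(q, merged[match(stage1, seq_along(ac1))])
  clusters <- data.frame(
    cluster_id = seq_along(member),
    ac_percent = vapply(member, function(idx)
      100 * stats::weighted.mean(annotated$rho[idx], annotated$n_probes[idx]),
      numeric(1)),
    n_segments = lengths(member),
    total_probes = vapply(member, function(idx)
      sum(annotated$n_probes[idx]), numeric(1))
  )
  clusters <- clusters[order(-clusters$ac_percent), , drop = FALSE]
  clusters$cluster_id <- seq_len(nrow(clusters))
  rownames(clusters) <- NULL

  k <- nrow(clusters)
  cc <- if (config$count_mode == "subclones") max(0L, k - 1L) else k
  new_cc_result(ids, "estimated", as.integer(cc), clusters, annotated)
}

new_cc_result <- function(sample_id, status, cc_number, clusters, segments) {
  classification <- if (status == "undetermined") "undetermined"
  else if (cc_number == 0L) "mono" else "poly"
  structure(list(sample_id = sample_id, status = status,
                 cc_number = cc_number, classification = classification,
                 clusters = clusters, segments = segments),
            class = "cc_result")
}

empty_clusters <- function() {
  data.frame(cluster_id = integer(), ac_percent = numeric(),
             n_segments = integer(), total_probes = numeric())
}

#' @export
print.cc_result <- function(x, ...) {
  cat(sprintf("Sample %s: status %s", x$sample_id, x$status))
  if (x$status == "estimated")
    cat(sprintf(", CC number %d (%s-CC)", x$cc_number, x$classification))
  cat("\n")
  if (nrow(x$clusters)) {
    cat("  clone clusters (%AC):",
        paste(sprintf("%.1f", x$clusters$ac_percent), collapse = ", "), "\n")
  }
  invisible(x)
}

# Single-linkage clustering with per-axis tolerances: two points link when
# both |db| <= tol_b and |dr| <= tol_r; clusters are connected components.
# Components are labelled deterministically by smallest member index.
cluster_single_linkage <- function(b, r, tol_b, tol_r) {
  n <- length(b)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (abs(b[i] - b[j]) <= tol_b && abs(r[i] - r[j]) <= tol_r) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

# One-dimensional single-linkage merge: sorted %AC values chain together
# while consecutive gaps are <= delta. Returns a cluster label per input.
merge_by_ac <- function(ac, delta) {
  o <- order(ac)
  gaps <- c(TRUE, diff(ac[o]) > delta)
  lab_sorted <- cumsum(gaps)
  lab <- integer(length(ac))
  lab[o] <- lab_sorted
  lab
}

#' Call clonal composition for a whole cohort
#'
#' Splits a multi-sample segment table by `sample_id` (first-appearance
#' order), calls [call_sample()] on each, and reports the mono / poly /
#' undetermined counts via `message()`.
#'
#' @param segment_table Segment data frame covering one or more samples.
#' @param config A [cc_model_config()].
#' @return A list of [call_sample()] results with class `"cc_cohort"`.
#' @export
call_cohort <- function(segment_table, config = cc_model_config()) {
  if (!nrow(segment_table)) stop("empty segment table")
  ids <- unique(segment_table$sample_id)
  results <- lapply(ids, function(id) {
    tryCatch(
      call_sample(segment_table[segment_table$sample_id == id, , drop = FALSE],
                  config),
      error = function(e)
        stop("sample ", id, ": ", conditionMessage(e), call. = FALSE))
  })
  names(results) <- ids
  cls <- vapply(results, `[[`, character(1), "classification")
  message(sprintf("called %d samples: %d mono-CC, %d poly-CC, %d undetermined",
                  length(results), sum(cls == "mono"), sum(cls == "poly"),
                  sum(cls == "undetermined")))
  structure(results, class = "cc_cohort")
}

#' Tabulate a cohort of CC results
#'
#' @param x A `"cc_cohort"` object from [call_cohort()].
#' @param ... Unused.
#' @return A data frame with one row per sample: `sample_id`, `status`,
#'   `cc_number`, `classification`, `n_clusters`, `ac_percents`
#'   (semicolon-joined, one decimal).
#' @export
as.data.frame.cc_cohort <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(res) {
    data.frame(
      sample_id = res$sample_id,
      status = res$status,
      cc_number = res$cc_number,
      classification = res$classification,
      n_clusters = nrow(res$clusters),
      ac_percents = paste(sprintf("%.1f", res$clusters$ac_percent),
                          collapse = ";"),
      stringsAsFactors = FALSE)
  }))
}

#' Write per-sample CC results
#'
#' @param results A `"cc_cohort"` object or its data-frame form.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cc_results <- function(results, path) {
  df <- if (inherits(results, "cc_cohort")) as.data.frame(results) else results
  df$cc_number <- ifelse(is.na(df$cc_number), ".", as.character(df$cc_number))
  write_tsv_commented(df, path, comment = "# clonal composition results")
  invisible(path)
}

#' Read per-sample CC results
#'
#' @param path Path to a TSV written by [write_cc_results()].
#' @return A data frame with `cc_number` numeric (`NA` for undetermined).
#' @export
read_cc_results <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "status", "cc_number",
                                 "classification"))
  df$cc_number <- suppressWarnings(
    as.integer(ifelse(df$cc_number == ".", NA, df$cc_number)))
  df
}
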
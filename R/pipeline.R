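#' Read a run configuration
#'
#' A single YAML file governs a whole run: the `model` block maps onto
#' [cc_model_config()], the `cohort` block onto [cc_cohort_spec()] (with
#' nested `survival`, `noise` and `covariates` blocks), plus `write_probes`
#' (default FALSE).  Every omitted key takes the package default, and the
#' fully resolved configuration is written next to the outputs of each stage
#' for provenance.  See `system.file("extdata", "default_config.yaml",
#' package = "clonecomp")` for a commented template stating all defaults.
#'
#' @param path Path to a YAML config file, or `NULL` for all defaults.
#' @param seed Optional seed overriding the config's `cohort$seed`.
#' @return A list with elements `model` (`cc_model_config`), `cohort`
#'   (`cc_cohort_spec`) and `write_probes`.
#' @export
read_run_config <- function(path = NULL, seed = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  model <- do.call(cc_model_config, raw$model %||% list())
  craw <- raw$cohort %||% list()
  if (!is.null(craw$survival)) craw$survival <- do.call(cc_survival_model, craw$survival)
  if (!is.null(craw$noise)) craw$noise <- do.call(cc_noise_model, craw$noise)
  if (!is.null(craw$covariates))
    craw$covariates <- lapply(craw$covariates, function(p)
      c(mono = p$mono, poly = p$poly))
  if (!is.null(seed)) craw$seed <- as.integer(seed)
  cohort <- do.call(cc_cohort_spec, craw)
  list(model = model, cohort = cohort,
       write_probes = isTRUE(raw$write_probes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_resolved_config <- function(config, out_dir) {
  resolved <- list(
    model = unclass(config$model),
    cohort = local({
      x <- unclass(config$cohort)
      x$survival <- unclass(x$survival)
      x$noise <- unclass(x$noise)
      x$covariates <- lapply(x$covariates, as.list)
      x
    }),
    write_probes = config$write_probes)
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))
}

#' Pipeline stage 1: simulate a cohort to files
#'
#' Runs [simulate_cohort()] and writes `segments.tsv`, `patients.tsv`
#' (and `probes.tsv` when `write_probes` is set) plus the resolved
#' configuration into `out_dir`.
#'
#' @param config A run configuration from [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
cc_simulate <- function(config = read_run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config$cohort, keep_probes = config$write_probes)
  paths <- c(segments = file.path(out_dir, "segments.tsv"),
             patients = file.path(out_dir, "patients.tsv"))
  write_segments(sim$segments, paths[["segments"]])
  write_patients(sim$patients, paths[["patients"]])
  if (config$write_probes) {
    paths[["probes"]] <- file.path(out_dir, "probes.tsv")
    write_probes(sim$probes, paths[["probes"]])
  }
  write_resolved_config(config, out_dir)
  message(sprintf("simulated %d samples (%d segments) into %s",
                  length(unique(sim$segments$sample_id)),
                  nrow(sim$segments), out_dir))
  invisible(paths)
}

#' Pipeline stage 2: call clonal composition from a segment file
#'
#' Reads a segment table (header-driven, column order free), runs
#' [call_cohort()] and writes `cc_results.tsv`.
#'
#' @param config A run configuration from [read_run_config()].
#' @param segments_path Path to a segment TSV.
#' @param out_dir Output directory.
#' @return Path of the results file, invisibly.
#' @export
cc_call <- function(config = read_run_config(), segments_path,
                    out_dir = dirname(segments_path)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  segments <- read_segments(segments_path)
  results <- call_cohort(segments, config$model)
  out <- file.path(out_dir, "cc_results.tsv")
  write_cc_results(results, out)
  invisible(out)
}

#' Pipeline stage 3: cohort association and survival statistics
#'
#' Joins per-sample CC classes to the patient table (undetermined samples are
#' excluded, mirroring a cohort analyzed as 36 minus the unestimable cases),
#' then writes `association_report.tsv` — one two-sided Fisher exact test per
#' binary covariate plus early recurrence (event within 12 months), unadjusted
#' p-values — and `survival_report.tsv` — per-group Kaplan-Meier median RFS
#' (`NR` = not reached) with the log-rank comparison.
#'
#' @param config A run configuration from [read_run_config()].
#' @param results_path Path to `cc_results.tsv` from [cc_call()].
#' @param patients_path Path to `patients.tsv`.
#' @param out_dir Output directory.
#' @return Named character vector of report paths, invisibly.
#' @export
cc_stats <- function(config = read_run_config(), results_path, patients_path,
                     out_dir = dirname(results_path)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- read_cc_results(results_path)
  patients <- read_patients(patients_path)
  merged <- merge(patients, results[, c("sample_id", "status", "classification")],
                  by.x = "patient_id", by.y = "sample_id")
  if (nrow(merged) < nrow(patients))
    warning(nrow(patients) - nrow(merged), " patient(s) had no CC result")
  n_undet <- sum(merged$classification == "undetermined")
  if (n_undet)
    message(n_undet, " undetermined sample(s) excluded from group statistics")
  included <- merged[merged$classification != "undetermined", , drop = FALSE]
  included <- included[order(included$patient_id), , drop = FALSE]

  included$early_recurrence <-
    as.integer(included$event == 1L & included$rfs_months <= 12)
  covars <- c(setdiff(names(included),
                      c("patient_id", "group_true", "rfs_months", "event",
                        "status", "classification", "early_recurrence")),
              "early_recurrence")
  assoc <- do.call(rbind, lapply(covars, function(v) {
    t <- tryCatch(build_contingency(included, "classification", v),
                  error = function(e) NULL)
    if (is.null(t))
      return(data.frame(variable = v, mono_0 = NA, mono_1 = NA,
                        poly_0 = NA, poly_1 = NA, p_value = "."))
    data.frame(variable = v,
               mono_0 = t["mono", 1], mono_1 = t["mono", 2],
               poly_0 = t["poly", 1], poly_1 = t["poly", 2],
               p_value = sprintf("%.4f", fisher_exact_two_sided(t)))
  }))
  paths <- c(association = file.path(out_dir, "association_report.tsv"),
             survival = file.path(out_dir, "survival_report.tsv"))
  write_tsv_commented(assoc, paths[["association"]],
                      comment = "# Fisher exact tests, mono-CC vs poly-CC; unadjusted p-values")

  groups <- split(included, included$classification)
  if (length(groups) < 2L) {
    warning("a CC group is empty: survival comparison skipped")
    surv <- data.frame(group = names(groups), n = vapply(groups, nrow, 0L),
                       events = vapply(groups, function(g) sum(g$event), 0),
                       median_rfs = ".", logrank_chisq = ".", logrank_p = ".")
  } else {
    lr <- logrank_test(groups$mono$rfs_months, groups$mono$event,
                       groups$poly$rfs_months, groups$poly$event)
    surv <- do.call(rbind, lapply(c("mono", "poly"), function(g) {
      km <- km_curve(groups[[g]]$rfs_months, groups[[g]]$event)
      med <- km_median(km)
      data.frame(group = g, n = km$n, events = sum(groups[[g]]$event),
                 median_rfs = if (is.na(med)) "NR" else sprintf("%.2f", med),
                 logrank_chisq = sprintf("%.4f", lr$chisq),
                 logrank_p = sprintf("%.4f", lr$p_value))
    }))
    message(sprintf("median RFS: mono %s, poly %s; log-rank p = %.4f",
                    surv$median_rfs[1], surv$median_rfs[2], lr$p_value))
  }
  write_tsv_commented(surv, paths[["survival"]],
                      comment = "# Kaplan-Meier medians (months; NR = not reached) and log-rank test")
  write_resolved_config(config, out_dir)
  invisible(paths)
}
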
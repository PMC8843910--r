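#' @name segment-files
#' @title Segment and probe table files
#'
#' @description
#' Segment tables are tab-separated with the fixed header
#' `sample_id chrom start end n_probes n_het log2r folded_baf`; extra columns
#' appended by callers (e.g. fit annotations) are preserved on read.
#' Coordinates are 0-based half-open (BED convention); floats are written
#' with 6 decimals; a missing folded BAF (segment without heterozygous
#' probes) is written as `.`.  Probe tables use the header
#' `chrom pos log2r baf is_het`.
NULL

segment_columns <- c("sample_id", "chrom", "start", "end",
                     "n_probes", "n_het", "log2r", "folded_baf")
probe_columns <- c("chrom", "pos", "log2r", "baf", "is_het")

#' Read a segment table
#'
#' Reads and validates a tab-separated segment file (see [segment-files]).
#' Malformed rows are reported with their file line numbers.
#'
#' @param path Path to a segment TSV.
#' @return A data frame of validated segment records, one per row.
#' @export
read_segments <- function(path) {
  df <- read_tsv_checked(path, segment_columns)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$n_probes <- as.integer(df$n_probes)
  df$n_het <- as.integer(df$n_het)
  df$log2r <- as.numeric(df$log2r)
  df$folded_baf <- suppressWarnings(
    as.numeric(ifelse(df$folded_baf == ".", NA, df$folded_baf)))
  validate_segments(df, line_offset = count_header_lines(path))
  df
}

validate_segments <- function(df, line_offset = 0L) {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop("invalid segment record(s) at line ",
           paste(i + line_offset, collapse = ", "), ": ", what, call. = FALSE)
  }
  bad(is.na(df$start) | is.na(df$end) | df$start < 0, "missing or negative coordinates")
  bad(df$start >= df$end, "start must be < end (0-based half-open)")
  bad(is.na(df$n_probes) | df$n_probes < 1L, "n_probes must be >= 1")
  bad(is.na(df$n_het) | df$n_het < 0L | df$n_het > df$n_probes,
      "n_het must be in [0, n_probes]")
  bad(!is.finite(df$log2r), "log2r must be finite")
  bad(!is.na(df$folded_baf) & (df$folded_baf < 0 | df$folded_baf > 0.5),
      "folded_baf must lie in [0, 0.5]")
  bad(xor(is.na(df$folded_baf), df$n_het == 0L),
      "folded_baf must be missing exactly when n_het = 0")
  invisible(df)
}

#' Write a segment table
#'
#' Writes segments in the dialect of [segment-files]: deterministic column
#' order, floats at 6 decimals, rows sorted by (sample, chrom, start).
#'
#' @param segments A segment data frame (as from [read_segments()] or
#'   [simulate_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  if (nrow(segments)) {
    validate_segments(segments)
    segments <- segments[order(segments$sample_id, segments$chrom, segments$start), ,
                         drop = FALSE]
  }
  out <- segments[, c(segment_columns,
                      setdiff(names(segments), segment_columns)), drop = FALSE]
  out$log2r <- sprintf("%.6f", out$log2r)
  out$folded_baf <- ifelse(is.na(segments$folded_baf), ".",
                           sprintf("%.6f", segments$folded_baf))
  write_tsv_commented(out, path,
                      comment = "# segment table; coordinates 0-based half-open; '.' = missing")
  invisible(path)
}

#' Read a probe table
#'
#' @param path Path to a probe TSV (see [segment-files]).
#' @return A data frame with columns `chrom`, `pos`, `log2r`, `baf`, `is_het`
#'   (plus `sample_id` if present in the file).
#' @export
read_probes <- function(path) {
  df <- read_tsv_checked(path, probe_columns)
  df$pos <- as.integer(df$pos)
  df$log2r <- as.numeric(df$log2r)
  df$baf <- as.numeric(df$baf)
  df$is_het <- as.logical(as.integer(df$is_het))
  if (any(df$pos < 0, na.rm = TRUE)) stop("probe positions must be >= 0")
  if (any(!is.finite(df$baf) | df$baf < 0 | df$baf > 1))
    stop("probe BAF must lie in [0, 1]")
  df
}

#' Write a probe table
#'
#' @param probes A probe data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probes <- function(probes, path) {
  extra <- setdiff(names(probes), probe_columns)
  out <- probes[, c(probe_columns, extra), drop = FALSE]
  out$log2r <- sprintf("%.6f", out$log2r)
  out$baf <- sprintf("%.6f", out$baf)
  out$is_het <- as.integer(out$is_het)
  write_tsv_commented(out, path,
                      comment = "# probe table; positions 0-based")
  invisible(path)
}

#' Summarize probes over an interval into one segment record
#'
#' Segment log2R is the median probe log2R; segment folded BAF is the median
#' of `min(baf, 1 - baf)` over germline-heterozygous probes (missing when the
#' interval has none).  Medians are robust to outlier probes and make the
#' summary invariant to probe order and to flipping any probe's allele label.
#'
#' @param probes Probe data frame (columns `chrom`, `pos`, `log2r`, `baf`,
#'   `is_het`).
#' @param chrom Chromosome of the interval.
#' @param start,end 0-based half-open interval.
#' @param sample_id Sample identifier for the output record.
#' @return A one-row segment data frame (see [segment-files]).
#' @examples
#' p <- data.frame(chrom = "chr1", pos = 0:99, log2r = -0.415,
#'                 baf = 1 / 3, is_het = TRUE)
#' summarize_probes(p, "chr1", 0, 100, "S1")
#' @export
summarize_probes <- function(probes, chrom, start, end, sample_id = "sample") {
  sel <- probes$chrom == chrom & probes$pos >= start & probes$pos < end
  p <- probes[sel, , drop = FALSE]
  if (!nrow(p)) stop("no probes in ", chrom, ":", start, "-", end)
  het <- p[p$is_het, , drop = FALSE]
  folded <- if (nrow(het)) stats::median(pmin(het$baf, 1 - het$baf)) else NA_real_
  data.frame(sample_id = sample_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             n_probes = nrow(p), n_het = nrow(het),
             log2r = stats::median(p$log2r), folded_baf = folded,
             stringsAsFactors = FALSE)
}

#' Read / write the patient table
#'
#' Patient tables are TSV with columns `patient_id`, `group_true`,
#' `rfs_months`, `event` and one 0/1 column per binary covariate.
#'
#' @param path File path.
#' @return `read_patients()` returns a data frame; `write_patients()` returns
#'   `path` invisibly.
#' @export
read_patients <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "group_true", "rfs_months", "event"))
  df$rfs_months <- as.numeric(df$rfs_months)
  df$event <- as.integer(df$event)
  if (any(!is.finite(df$rfs_months) | df$rfs_months <= 0))
    stop("rfs_months must be positive")
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0/1")
  df
}

#' @rdname read_patients
#' @param patients Patient data frame.
#' @export
write_patients <- function(patients, path) {
  out <- patients
  out$rfs_months <- sprintf("%.4f", out$rfs_months)
  write_tsv_commented(out, path, comment = "# patient table; times in months")
  invisible(path)
}

# ---- low-level helpers -------------------------------------------------

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

# Data row 1 sits after any leading comment lines plus the header line.
count_header_lines <- function(path) {
  head_lines <- readLines(path, n = 50L)
  sum(startsWith(head_lines, "#")) + 1L
}

write_tsv_commented <- function(df, path, comment) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(comment, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
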
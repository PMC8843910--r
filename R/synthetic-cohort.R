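#' Probe-level noise model
#'
#' Gaussian per-probe noise on log2R and on unfolded BAF, with BAF clipped to
#' `[0, 1]`.  Defaults reflect typical molecular-inversion-probe array noise.
#'
#' @param sigma_log2r_probe Per-probe log2R standard deviation (default 0.25).
#' @param sigma_baf_probe Per-probe BAF standard deviation (default 0.04).
#' @return An object of class `"cc_noise_model"`.
#' @export
cc_noise_model <- function(sigma_log2r_probe = 0.25, sigma_baf_probe = 0.04) {
  if (sigma_log2r_probe < 0 || sigma_baf_probe < 0)
    stop("noise standard deviations must be >= 0")
  structure(list(sigma_log2r_probe = sigma_log2r_probe,
                 sigma_baf_probe = sigma_baf_probe),
            class = "cc_noise_model")
}

#' Group-dependent recurrence-time model
#'
#' Recurrence-free survival times are exponential with the configured group
#' median (rate `log(2) / median`) and administratively censored at
#' `admin_censor` months.  The poly-CC default median is 7.0 months; the
#' mono-CC default of 60 months encodes a median "not reached" within the
#' 60-month administrative window.
#'
#' @param median_rfs_poly Median RFS of poly-CC patients, months (default 7).
#' @param median_rfs_mono Median RFS of mono-CC patients, months (default 60).
#' @param admin_censor Administrative censoring time, months (default 60).
#' @return An object of class `"cc_survival_model"`.
#' @export
cc_survival_model <- function(median_rfs_poly = 7.0, median_rfs_mono = 60.0,
                              admin_censor = 60.0) {
  if (median_rfs_poly <= 0 || median_rfs_mono <= 0 || admin_censor < 0)
    stop("medians must be > 0 and admin_censor >= 0")
  structure(list(median_rfs_poly = median_rfs_poly,
                 median_rfs_mono = median_rfs_mono,
                 admin_censor = admin_censor),
            class = "cc_survival_model")
}

#' Specification of one aberrant clone
#'
#' @param rho Aberrant-cell fraction of the clone in (0, 1].
#' @param events Data frame of copy-number events carried by the clone, with
#'   columns `chrom`, `start`, `end`, `n_total`, `m_minor`; events must not
#'   overlap within the clone.
#' @return An object of class `"cc_clone_spec"`.
#' @export
cc_clone_spec <- function(rho, events) {
  if (!(rho > 0 && rho <= 1)) stop("clone rho must lie in (0, 1]")
  need <- c("chrom", "start", "end", "n_total", "m_minor")
  if (!all(need %in% names(events)))
    stop("events need columns: ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(events)))
    check_hypothesis(events$n_total[i], events$m_minor[i])
  if (any(events$start >= events$end)) stop("event start must be < end")
  if (events_overlap(events, events, self = TRUE))
    stop("events overlap within a clone")
  structure(list(rho = rho, events = events), class = "cc_clone_spec")
}

events_overlap <- function(a, b, self = FALSE) {
  for (i in seq_len(nrow(a))) {
    jj <- seq_len(nrow(b))
    if (self) jj <- jj[jj != i]
    for (j in jj) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) return(TRUE)
    }
  }
  FALSE
}

#' Specification of one synthetic tumor
#'
#' @param sample_id Sample identifier.
#' @param clones List of [cc_clone_spec()] objects (possibly empty).
#' @param n_normal_segments Number of diploid-heterozygous background
#'   segments (default 4).
#' @param probes_per_segment Integer range from which each segment's probe
#'   count is drawn uniformly (default `c(100, 2000)`).
#' @param het_fraction Fraction of probes that are germline-heterozygous
#'   (default 0.25).
#' @return An object of class `"cc_tumor_spec"`.
#' @export
cc_tumor_spec <- function(sample_id, clones = list(), n_normal_segments = 4L,
                          probes_per_segment = c(100L, 2000L),
                          het_fraction = 0.25) {
  stopifnot(length(probes_per_segment) == 2L,
            probes_per_segment[1] >= 1L,
            probes_per_segment[1] <= probes_per_segment[2],
            het_fraction > 0, het_fraction <= 1, n_normal_segments >= 0)
  for (cl in clones) stopifnot(inherits(cl, "cc_clone_spec"))
  if (length(clones) > 1L) {
    for (i in seq_along(clones)[-1L]) for (j in seq_len(i - 1L)) {
      if (events_overlap(clones[[i]]$events, clones[[j]]$events))
        stop("overlapping events across clones are not supported")
    }
  }
  structure(list(sample_id = sample_id, clones = clones,
                 n_normal_segments = as.integer(n_normal_segments),
                 probes_per_segment = as.integer(probes_per_segment),
                 het_fraction = het_fraction),
            class = "cc_tumor_spec")
}

#' Cohort-level simulation specification
#'
#' Defaults reproduce the study design the generator emulates: 8 mono-CC
#' samples (no qualifying aberration), 26 poly-CC samples carrying 1–3
#' clones, and 2 samples whose LOH-like segments lie off every fitting curve
#' so their CC number cannot be estimated.
#'
#' @param n_mono,n_poly,n_undetermined Arm sizes (defaults 8, 26, 2).
#' @param survival A [cc_survival_model()].
#' @param noise A [cc_noise_model()].
#' @param seed Integer seed governing all randomness.
#' @param n_normal_segments Diploid background segments per sample (default 4).
#' @param probes_per_segment Probe-count range per segment
#'   (default `c(100, 2000)`).
#' @param het_fraction Germline-heterozygous probe fraction (default 0.25).
#' @param clone_range Range of clone counts per poly sample (default `c(1, 3)`).
#' @param rho_range Range from which clone fractions are drawn
#'   (default `c(0.2, 0.9)`).
#' @param min_rho_gap Minimum pairwise gap between clone fractions of one
#'   sample (default 0.10 = twice the default `merge_delta_ac`); set to 0 for
#'   "hard mode" with no enforced separation.
#' @param covariates Named list of binary-covariate prevalences, each a
#'   vector `c(mono = p, poly = p)`.  Defaults cover age >= 70,
#'   PIVKA-II >= 40 and tumor size >= 4 cm with group-dependent prevalences.
#' @return An object of class `"cc_cohort_spec"`.
#' @export
cc_cohort_spec <- function(n_mono = 8L, n_poly = 26L, n_undetermined = 2L,
                           survival = cc_survival_model(),
                           noise = cc_noise_model(),
                           seed = 42L,
                           n_normal_segments = 4L,
                           probes_per_segment = c(100L, 2000L),
                           het_fraction = 0.25,
                           clone_range = c(1L, 3L),
                           rho_range = c(0.2, 0.9),
                           min_rho_gap = 0.10,
                           covariates = list(
                             age_ge_70 = c(mono = 0.625, poly = 0.577),
                             pivka_ge_40 = c(mono = 0.25, poly = 0.72),
                             size_ge_4 = c(mono = 0.375, poly = 0.577))) {
  stopifnot(n_mono >= 0, n_poly >= 0, n_undetermined >= 0,
            inherits(survival, "cc_survival_model"),
            inherits(noise, "cc_noise_model"),
            clone_range[1] >= 1L, clone_range[1] <= clone_range[2],
            rho_range[1] > 0, rho_range[2] <= 1, rho_range[1] < rho_range[2],
            min_rho_gap >= 0)
  structure(list(n_mono = as.integer(n_mono), n_poly = as.integer(n_poly),
                 n_undetermined = as.integer(n_undetermined),
                 survival = survival, noise = noise, seed = as.integer(seed),
                 n_normal_segments = as.integer(n_normal_segments),
                 probes_per_segment = as.integer(probes_per_segment),
                 het_fraction = het_fraction,
                 clone_range = as.integer(clone_range),
                 rho_range = rho_range, min_rho_gap = min_rho_gap,
                 covariates = covariates),
            class = "cc_cohort_spec")
}

# Generate the probes of one segment. b_unfolded is the expected BAF of the
# B-labelled allele at a het site before random per-SNP phase assignment;
# NA means the segment has no het probes at all.
gen_segment_probes <- function(chrom, n_probes, b_unfolded, r_expected,
                               het_fraction, noise) {
  pos <- seq(0L, by = 1000L, length.out = n_probes)
  is_het <- stats::runif(n_probes) < het_fraction
  log2r <- stats::rnorm(n_probes, r_expected, noise$sigma_log2r_probe)
  baf <- numeric(n_probes)
  n_het <- sum(is_het)
  if (n_het) {
    phase <- stats::runif(n_het) < 0.5  # arbitrary allele labelling per SNP
    mu <- ifelse(phase, b_unfolded, 1 - b_unfolded)
    baf[is_het] <- stats::rnorm(n_het, mu, noise$sigma_baf_probe)
  }
  n_hom <- n_probes - n_het
  if (n_hom) {
    mu <- ifelse(stats::runif(n_hom) < 0.5, 0, 1)
    baf[!is_het] <- stats::rnorm(n_hom, mu, noise$sigma_baf_probe)
  }
  data.frame(chrom = chrom, pos = pos, log2r = log2r,
             baf = pmin(pmax(baf, 0), 1), is_het = is_het,
             stringsAsFactors = FALSE)
}

#' Simulate probe data for one tumor
#'
#' Forward-simulates per-probe log2R and BAF for a tumor made of diploid
#' normal cells and the aberrant clones of `spec`.  Each clone event becomes
#' one segment on its own synthetic chromosome; `n_normal_segments` diploid
#' segments are appended.  Heterozygous probes get the model-expected
#' unfolded BAF with a random per-SNP allele phase; homozygous probes sit
#' near 0 or 1.  Output is deterministic given `seed`.
#'
#' @param spec A [cc_tumor_spec()].
#' @param noise A [cc_noise_model()] (use zero sigmas for noiseless data).
#' @param seed Integer seed.
#' @return A list with `probes` (probe data frame with a `segment` column)
#'   and `truth` (one row per segment: interval, `n_total`, `m_minor`,
#'   `rho`; `rho = 0` marks normal segments).
#' @export
simulate_tumor <- function(spec, noise = cc_noise_model(), seed = 1L) {
  stopifnot(inherits(spec, "cc_tumor_spec"), inherits(noise, "cc_noise_model"))
  with_seed(seed, {
    probes <- list()
    truth <- list()
    seg_i <- 0L
    add_segment <- function(n_total, m_minor, rho, chrom = NULL) {
      seg_i <<- seg_i + 1L
      np <- if (spec$probes_per_segment[1] == spec$probes_per_segment[2])
        spec$probes_per_segment[1]
      else sample(spec$probes_per_segment[1]:spec$probes_per_segment[2], 1L)
      if (is.null(chrom)) chrom <- sprintf("chr%d", seg_i)
      if (rho > 0) {
        cc <- expected_total_copy(rho, n_total)
        b <- ((1 - rho) + m_minor * rho) / cc
        r <- log2(cc / 2)
      } else { b <- 0.5; r <- 0 }
      p <- gen_segment_probes(chrom, np, b, r, spec$het_fraction, noise)
      p$segment <- seg_i
      probes[[seg_i]] <<- p
      truth[[seg_i]] <<- data.frame(
        sample_id = spec$sample_id, segment = seg_i, chrom = chrom,
        start = 0L, end = as.integer(np) * 1000L, n_probes = np,
        n_total = as.integer(n_total), m_minor = as.integer(m_minor),
        rho = rho, stringsAsFactors = FALSE)
    }
    for (cl in spec$clones) {
      for (e in seq_len(nrow(cl$events)))
        add_segment(cl$events$n_total[e], cl$events$m_minor[e], cl$rho)
    }
    for (i in seq_len(spec$n_normal_segments)) add_segment(2L, 1L, 0)
    list(probes = do.call(rbind, probes), truth = do.call(rbind, truth))
  })
}

# Summarize a simulated tumor's probes into the segment-table dialect.
summarize_tumor <- function(sim, sample_id) {
  do.call(rbind, lapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    p <- sim$probes[sim$probes$segment == tr$segment, , drop = FALSE]
    summarize_probes(p, tr$chrom, tr$start, tr$end, sample_id)
  }))
}

# Draw k clone fractions from [lo, hi] with all pairwise gaps > gap.
# Bounded rejection sampling; deterministic given the RNG state.
draw_separated_rho <- function(k, lo, hi, gap) {
  for (attempt in 1:1000) {
    rho <- sort(stats::runif(k, lo, hi))
    if (k == 1L || all(diff(rho) > gap)) return(rho)
  }
  stop("could not draw ", k, " clone fractions with gaps > ", gap,
       " in [", lo, ", ", hi, "]")
}

#' Draw recurrence times for one study arm
#'
#' Exponential times with the arm's configured median (rate
#' `log(2) / median`), administratively censored.
#'
#' @param n Number of patients.
#' @param group `"mono"` or `"poly"` (undetermined patients use the mono
#'   model: in the emulated design they are recurrence-free).
#' @param survival A [cc_survival_model()].
#' @param admin_censor Censoring time in months; override with `Inf` for
#'   uncensored draws.  Defaults to the model's value.
#' @return A data frame with columns `rfs_months` (> 0) and `event` (0/1).
#' @export
simulate_recurrence_times <- function(n, group = c("poly", "mono"),
                                      survival = cc_survival_model(),
                                      admin_censor = survival$admin_censor) {
  group <- match.arg(group)
  med <- if (group == "poly") survival$median_rfs_poly else survival$median_rfs_mono
  t <- stats::rexp(n, rate = log(2) / med)
  event <- as.integer(t < admin_censor)
  t <- pmin(t, admin_censor)
  t <- pmax(t, 1e-6)  # degenerate censor limit: keep times positive
  data.frame(rfs_months = t, event = event)
}

#' Simulate a full synthetic cohort
#'
#' Generates probe data per sample via [simulate_tumor()], summarizes it into
#' the segment-table dialect, and draws a clinical table with group-dependent
#' exponential recurrence times and binary covariates.  Mono samples carry
#' only diploid segments; poly samples carry 1–3 clones with separated
#' fractions and 1–3 hemizygous-loss or copy-neutral-LOH events each;
#' undetermined samples carry LOH-like segments deliberately off every
#' fitting curve (folded BAF near 0.15 with log2R near +0.8).
#'
#' @param spec A [cc_cohort_spec()].
#' @param keep_probes Keep the per-probe data in the result (default FALSE).
#' @return A list with `segments` (segment table for all samples),
#'   `patients` (clinical table), `truth` (per-sample `group_true` and true
#'   clone count `cc_true`), and optionally `probes`.
#' @export
simulate_cohort <- function(spec = cc_cohort_spec(), keep_probes = FALSE) {
  stopifnot(inherits(spec, "cc_cohort_spec"))
  n_all <- spec$n_mono + spec$n_poly + spec$n_undetermined
  groups <- rep(c("mono", "poly", "undetermined"),
                c(spec$n_mono, spec$n_poly, spec$n_undetermined))
  ids <- sprintf("HCC_%03d", seq_len(n_all))

  segments <- list(); probes <- list(); cc_true <- integer(n_all)
  for (i in seq_len(n_all)) {
    sub_seed <- spec$seed + 1009L * i  # distinct per-sample stream
    g <- groups[i]
    if (g == "undetermined") {
      sim <- with_seed(sub_seed, {
        p <- list(); tr <- list()
        n_off <- 2L
        for (s in seq_len(n_off)) {
          np <- sample(spec$probes_per_segment[1]:spec$probes_per_segment[2], 1L)
          pp <- gen_segment_probes(sprintf("chr%d", s), np, 0.15, 0.8,
                                   spec$het_fraction, spec$noise)
          pp$segment <- s
          p[[s]] <- pp
          tr[[s]] <- data.frame(sample_id = ids[i], segment = s,
                                chrom = sprintf("chr%d", s), start = 0L,
                                end = np * 1000L, n_probes = np,
                                n_total = NA_integer_, m_minor = NA_integer_,
                                rho = NA_real_, stringsAsFactors = FALSE)
        }
        for (s in seq_len(spec$n_normal_segments)) {
          np <- sample(spec$probes_per_segment[1]:spec$probes_per_segment[2], 1L)
          pp <- gen_segment_probes(sprintf("chr%d", n_off + s), np, 0.5, 0,
                                   spec$het_fraction, spec$noise)
          pp$segment <- n_off + s
          p[[n_off + s]] <- pp
          tr[[n_off + s]] <- data.frame(sample_id = ids[i], segment = n_off + s,
                                        chrom = sprintf("chr%d", n_off + s),
                                        start = 0L, end = np * 1000L,
                                        n_probes = np, n_total = 2L,
                                        m_minor = 1L, rho = 0,
                                        stringsAsFactors = FALSE)
        }
        list(probes = do.call(rbind, p), truth = do.call(rbind, tr))
      })
      cc_true[i] <- NA_integer_
    } else {
      clones <- list()
      if (g == "poly") {
        clones <- with_seed(sub_seed + 1L, {
          k <- sample(spec$clone_range[1]:spec$clone_range[2], 1L)
          rho <- draw_separated_rho(k, spec$rho_range[1], spec$rho_range[2],
                                    spec$min_rho_gap)
          chrom_i <- 0L
          lapply(rho, function(rk) {
            ne <- sample(1:3, 1L)
            ev <- data.frame(
              chrom = sprintf("ev%d", chrom_i + seq_len(ne)),
              start = 0L, end = 1L,  # placeholder; layout assigned later
              n_total = sample(c(1L, 2L), ne, replace = TRUE),
              m_minor = 0L)
            chrom_i <<- chrom_i + ne
            cc_clone_spec(rk, ev)
          })
        })
      }
      tspec <- cc_tumor_spec(ids[i], clones,
                             n_normal_segments = spec$n_normal_segments,
                             probes_per_segment = spec$probes_per_segment,
                             het_fraction = spec$het_fraction)
      sim <- simulate_tumor(tspec, spec$noise, seed = sub_seed)
      cc_true[i] <- length(clones)
    }
    segments[[i]] <- summarize_tumor(sim, ids[i])
    if (keep_probes) {
      sim$probes$sample_id <- ids[i]
      probes[[i]] <- sim$probes
    }
  }

  patients <- with_seed(spec$seed, {
    surv_group <- ifelse(groups == "poly", "poly", "mono")
    rt <- do.call(rbind, lapply(surv_group, function(g)
      simulate_recurrence_times(1L, g, spec$survival))) %||%
      data.frame(rfs_months = numeric(), event = integer())
    cov <- lapply(names(spec$covariates), function(nm) {
      p <- spec$covariates[[nm]]
      prev <- ifelse(groups == "poly", p[["poly"]], p[["mono"]])
      as.integer(stats::runif(n_all) < prev)
    })
    names(cov) <- names(spec$covariates)
    cbind(data.frame(patient_id = ids, group_true = groups,
                     stringsAsFactors = FALSE),
          rt, as.data.frame(cov))
  })

  out <- list(
    segments = do.call(rbind, segments) %||% empty_segment_table(),
    patients = patients,
    truth = data.frame(sample_id = ids, group_true = groups,
                       cc_true = cc_true, stringsAsFactors = FALSE))
  if (keep_probes) out$probes <- do.call(rbind, probes) %||% empty_probe_table()
  out
}

empty_segment_table <- function() {
  data.frame(sample_id = character(), chrom = character(), start = integer(),
             end = integer(), n_probes = integer(), n_het = integer(),
             log2r = numeric(), folded_baf = numeric(),
             stringsAsFactors = FALSE)
}

empty_probe_table <- function() {
  data.frame(chrom = character(), pos = integer(), log2r = numeric(),
             baf = numeric(), is_het = logical(), segment = integer(),
             sample_id = character(), stringsAsFactors = FALSE)
}
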
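one_clone_spec <- function(rho = 0.5, n_total = 1L, n_probes = 500L,
                           sample_id = "T1") {
  ev <- data.frame(chrom = "ev1", start = 0L, end = 1L,
                   n_total = n_total, m_minor = 0L)
  cc_tumor_spec(sample_id, list(cc_clone_spec(rho, ev)),
                n_normal_segments = 2L,
                probes_per_segment = c(n_probes, n_probes))
}

test_that("zero-noise probes equal the model expectations exactly", {
  sim <- simulate_tumor(one_clone_spec(0.5, 1L), cc_noise_model(0, 0), seed = 3)
  ev <- sim$probes[sim$probes$segment == 1, ]
  expect_true(all(ev$log2r == log2(0.75)))
  b <- expected_folded_baf(0.5, 1, 0)
  het <- ev$baf[ev$is_het]
  expect_true(all(het %in% c(b, 1 - b)))  # random phase, exact values
  expect_true(all(ev$baf[!ev$is_het] %in% c(0, 1)))
  norm <- sim$probes[sim$probes$segment == 2, ]
  expect_true(all(norm$log2r == 0))
})

test_that("simulation is reproducible and seed-sensitive", {
  a <- simulate_tumor(one_clone_spec(), seed = 11)
  b <- simulate_tumor(one_clone_spec(), seed = 11)
  expect_identical(a, b)
  c <- simulate_tumor(one_clone_spec(), seed = 12)
  expect_false(identical(a$probes$baf, c$probes$baf))

  spec <- cc_cohort_spec(n_mono = 1L, n_poly = 2L, n_undetermined = 1L,
                         probes_per_segment = c(100L, 300L), seed = 9L)
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
})

test_that("overlapping events across clones are rejected", {
  ev <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                   n_total = 1L, m_minor = 0L)
  c1 <- cc_clone_spec(0.3, ev)
  c2 <- cc_clone_spec(0.6, ev)
  expect_error(cc_tumor_spec("T1", list(c1, c2)), "overlapping events")
  ev2 <- rbind(ev, data.frame(chrom = "chr1", start = 50L, end = 150L,
                              n_total = 2L, m_minor = 0L))
  expect_error(cc_clone_spec(0.3, ev2), "overlap within")
})

test_that("a seeded noisy tumor is recovered by summarize + fit", {
  sim <- simulate_tumor(one_clone_spec(0.5, 1L, 500L), cc_noise_model(), seed = 7)
  seg <- summarize_probes(sim$probes[sim$probes$segment == 1, ],
                          sim$truth$chrom[1], 0, sim$truth$end[1], "T1")
  f <- fit_segment(seg$folded_baf, seg$log2r)
  expect_equal(c(f$n_total, f$m_minor), c(1L, 0L))
  expect_lt(abs(f$rho - 0.5), 0.05)
})

test_that("segment summaries converge to model expectations with many probes", {
  for (n_total in c(1L, 2L)) {
    sim <- simulate_tumor(one_clone_spec(0.4, n_total, 5000L),
                          cc_noise_model(), seed = 21 + n_total)
    seg <- summarize_probes(sim$probes[sim$probes$segment == 1, ],
                            sim$truth$chrom[1], 0, sim$truth$end[1])
    expect_lt(abs(seg$folded_baf - expected_folded_baf(0.4, n_total, 0)), 0.005)
    expect_lt(abs(seg$log2r - expected_log2r(0.4, n_total)), 0.005)
  }
})

test_that("recurrence times hit the configured group medians", {
  sm <- cc_survival_model()
  set.seed(5)
  poly <- simulate_recurrence_times(5000, "poly", sm, admin_censor = Inf)
  expect_lt(abs(median(poly$rfs_months) - sm$median_rfs_poly) /
              sm$median_rfs_poly, 0.03)
  expect_true(all(poly$event == 1L))
  set.seed(6)
  mono <- simulate_recurrence_times(5000, "mono", sm, admin_censor = Inf)
  expect_lt(abs(median(mono$rfs_months) - sm$median_rfs_mono) /
              sm$median_rfs_mono, 0.03)
})

test_that("degenerate censoring censors every record", {
  set.seed(8)
  rt <- simulate_recurrence_times(100, "poly", cc_survival_model(),
                                  admin_censor = 0)
  expect_true(all(rt$event == 0L))
  expect_true(all(rt$rfs_months > 0))
})

test_that("an all-mono cohort draws every patient from the mono rate", {
  spec <- cc_cohort_spec(n_mono = 40L, n_poly = 0L, n_undetermined = 0L,
                         n_normal_segments = 1L,
                         probes_per_segment = c(60L, 100L), seed = 13L)
  sim <- simulate_cohort(spec)
  expect_true(all(sim$patients$group_true == "mono"))
  # mono median 60 with censor 60: roughly half the arm is censored
  expect_gt(mean(sim$patients$event == 0L), 0.25)
})

test_that("the default cohort reproduces its designed class counts", {
  sim <- simulate_cohort(cc_cohort_spec())
  expect_equal(nrow(sim$patients), 36L)
  res <- suppressMessages(call_cohort(sim$segments))
  cls <- vapply(res, `[[`, character(1), "classification")
  expect_equal(sum(cls == "mono"), 8L)
  expect_equal(sum(cls == "poly"), 26L)
  expect_equal(sum(cls == "undetermined"), 2L)
})

test_that("clone fractions respect the enforced separation", {
  spec <- cc_cohort_spec(n_mono = 0L, n_poly = 10L, n_undetermined = 0L,
                         probes_per_segment = c(60L, 100L), seed = 77L)
  sim <- simulate_cohort(spec)
  # true rho values are recorded per qualifying segment in the truth table
  for (id in unique(sim$segments$sample_id)) {
    res <- suppressMessages(call_sample(
      sim$segments[sim$segments$sample_id == id, ],
      cc_model_config(min_probes = 50L)))
    if (nrow(res$clusters) > 1L)
      expect_true(all(diff(sort(res$clusters$ac_percent)) > 5))
  }
})
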
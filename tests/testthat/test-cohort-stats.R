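test_that("fisher exact handles balanced and degenerate tables", {
  expect_equal(fisher_exact_two_sided(contingency_2x2(1, 1, 1, 1)), 1.0)
  expect_warning(p <- fisher_exact_two_sided(contingency_2x2(0, 0, 3, 4)),
                 "empty margin")
  expect_equal(p, 1.0)
  expect_error(contingency_2x2(-1, 1, 1, 1), "non-negative")
  expect_error(contingency_2x2(0, 0, 0, 0), "margin")
})

test_that("fisher exact is symmetric under row, column and transpose swaps", {
  t <- contingency_2x2(2, 6, 20, 6)
  p <- fisher_exact_two_sided(t)
  expect_equal(fisher_exact_two_sided(t[2:1, ]), p)
  expect_equal(fisher_exact_two_sided(t[, 2:1]), p)
  expect_equal(fisher_exact_two_sided(t(t)), p)
})

test_that("fisher exact matches the reference implementation on small tables", {
  set.seed(101)
  for (i in 1:200) {
    x <- as.vector(stats::rmultinom(1, size = sample(4:40, 1), prob = rep(1, 4)))
    if (sum(x[c(1, 2)]) == 0 || sum(x[c(3, 4)]) == 0 ||
        sum(x[c(1, 3)]) == 0 || sum(x[c(2, 4)]) == 0) next
    t <- contingency_2x2(x[1], x[2], x[3], x[4])
    expect_equal(fisher_exact_two_sided(t),
                 stats::fisher.test(unclass(t))$p.value, tolerance = 1e-10)
  }
})

test_that("mann-whitney handles separation, identity and ties", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)  # 2 of the 20 rank assignments are as extreme

  x <- c(3, 1, 4, 1, 5)
  same <- mann_whitney_u(x, x)
  expect_equal(same$U, length(x)^2 / 2)
  expect_equal(same$p_value, 1)
})

test_that("mann-whitney agrees with the reference implementation", {
  set.seed(55)
  # exact branch (n <= 12, no ties)
  for (i in 1:25) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # normal approximation with ties and continuity correction
  for (i in 1:25) {
    x <- sample(1:8, 15, replace = TRUE); y <- sample(3:10, 12, replace = TRUE)
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("mann-whitney is invariant under strictly monotone transforms", {
  set.seed(19)
  x <- rexp(14); y <- rexp(9) * 2
  base <- mann_whitney_u(x, y)
  for (f in list(function(v) v^3, log, function(v) 5 * v - 2)) {
    tr <- mann_whitney_u(f(x), f(y))
    expect_equal(tr$U, base$U)
    expect_equal(tr$p_value, base$p_value)
  }
})

test_that("kaplan-meier matches the empirical survival without censoring", {
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km_median(km), 2)

  all_cens <- km_curve(c(5, 8), c(0, 0))
  expect_equal(length(all_cens$event_times), 0L)
  expect_true(is.na(km_median(all_cens)))

  # censored at an event time stays at risk for that event: S(2) = 1/2
  km2 <- km_curve(c(1, 2, 3), c(0, 1, 0))
  expect_equal(km2$survival, 0.5)
  expect_equal(km_median(km2), 2)

  expect_equal(km_median(km_curve(5, 1)), 5)
  expect_error(km_curve(c(0, 1), c(1, 1)), "positive")
})

test_that("kaplan-meier agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(42)
  time <- round(rexp(60, 0.1), 1) + 0.1
  event <- rbinom(60, 1, 0.7)
  km <- km_curve(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  ref_surv <- summary(fit, times = km$event_times)$surv
  expect_equal(km$survival, ref_surv, tolerance = 1e-12)
  ref_med <- unname(summary(fit)$table["median"])
  med <- km_median(km)
  expect_equal(ifelse(is.na(med), NA_real_, med), ref_med)
})

test_that("log-rank reproduces hand calculations and trivial cases", {
  r <- logrank_test(1, 1, 2, 1)
  expect_equal(r$chisq, 1.0)
  expect_equal(r$p_value, 2 * pnorm(-1), tolerance = 1e-6)

  same <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)

  expect_error(logrank_test(c(1, 2), c(0, 0), c(3), c(0)), "no events")
})

test_that("log-rank agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(77)
  for (i in 1:20) {
    ta <- rexp(25, 0.2); tb <- rexp(30, 0.1)
    ea <- rbinom(25, 1, 0.8); eb <- rbinom(30, 1, 0.8)
    if (sum(ea) + sum(eb) == 0) next
    ours <- logrank_test(ta, ea, tb, eb)
    sd <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, c(25, 30)))
    expect_equal(ours$chisq, unname(sd$chisq), tolerance = 1e-9)
  }
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(11)
  time <- rexp(120, 0.1)
  event <- rep(1L, 120)
  ps <- replicate(1000, {
    lab <- sample(rep(c(TRUE, FALSE), each = 60))
    logrank_test(time[lab], event[lab], time[!lab], event[!lab])$p_value
  })
  D <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(D, 0.05)
})

test_that("build_contingency counts groups, drops missing, excludes undetermined", {
  pat <- data.frame(
    patient_id = sprintf("P%02d", 1:36),
    classification = rep(c("mono", "poly", "undetermined"), c(8, 26, 2)),
    early = c(rep(c(1, 0), c(2, 6)), rep(c(1, 0), c(20, 6)), 1, 1))
  t <- build_contingency(pat, "classification", "early")
  expect_equal(unclass(t)[1:4], c(6L, 6L, 2L, 20L))  # levels sorted: 0 before 1
  expect_equal(round(fisher_exact_two_sided(t), 4), 0.0127)

  pat$early[1] <- NA
  expect_message(t2 <- build_contingency(pat, "classification", "early"),
                 "1 patient")
  expect_equal(sum(t2), 33L)

  expect_error(build_contingency(pat[0, ], "classification", "early"), "empty")
  pat$early <- 1
  expect_error(build_contingency(pat, "classification", "early"), "not binary")
})
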
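test_that("screen_aberrant applies BAF floor, log2R band and probe minimum", {
  seg <- rbind(
    make_segment(chrom = "chr1", log2r = 0.0, folded_baf = 0.5),
    make_segment(chrom = "chr2", log2r = -0.3, folded_baf = 0.20),
    make_segment(chrom = "chr3", log2r = 0.0, folded_baf = 0.20, n_probes = 10L),
    make_segment(chrom = "chr4", log2r = 0.3, folded_baf = NA),
    make_segment(chrom = "chr5", log2r = 0.05, folded_baf = 0.48))
  expect_equal(screen_aberrant(seg), c(FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("a sample with no screened segments is a homogeneous mono-CC mass", {
  seg <- rbind(make_segment(chrom = "chr1"), make_segment(chrom = "chr2"))
  res <- call_sample(seg)
  expect_equal(res$status, "estimated")
  expect_equal(res$cc_number, 0L)
  expect_equal(res$classification, "mono")
  expect_equal(nrow(res$clusters), 0L)
})

test_that("noiseless one-clone and two-clone samples give CC 1 and 2", {
  one <- rbind(forward_segment(0.6, 1, "chr1"), forward_segment(0.6, 1, "chr2"))
  r1 <- call_sample(one)
  expect_equal(r1$cc_number, 1L)
  expect_equal(r1$classification, "poly")
  expect_equal(r1$clusters$ac_percent, 60, tolerance = 1e-6)

  two <- rbind(forward_segment(0.7, 1, "chr1"), forward_segment(0.7, 2, "chr2"),
               forward_segment(0.3, 1, "chr3"), forward_segment(0.3, 2, "chr4"))
  r2 <- call_sample(two)
  expect_equal(r2$cc_number, 2L)
  expect_equal(r2$clusters$ac_percent, c(70, 30), tolerance = 1e-6)
})

test_that("off-curve LOH segments make the sample undetermined", {
  seg <- rbind(make_segment(chrom = "chr1", log2r = 0.8, folded_baf = 0.15),
               make_segment(chrom = "chr2"))
  res <- call_sample(seg)
  expect_equal(res$status, "undetermined")
  expect_equal(res$classification, "undetermined")
  expect_true(is.na(res$cc_number))
})

test_that("partial off-curve segments are dropped with a warning", {
  seg <- rbind(forward_segment(0.6, 1, "chr1"),
               make_segment(chrom = "chr2", log2r = 0.8, folded_baf = 0.15))
  expect_warning(res <- call_sample(seg), "off every fitting curve")
  expect_equal(res$status, "estimated")
  expect_equal(res$cc_number, 1L)
})

test_that("call_sample validates its input", {
  expect_error(call_sample(make_segment()[0, ]), "at least one")
  seg <- rbind(make_segment("A"), make_segment("B"))
  expect_error(call_sample(seg), "more than one sample")
})

test_that("cc_number is invariant to segment order and diploid padding", {
  seg <- rbind(forward_segment(0.7, 1, "chr1"), forward_segment(0.3, 2, "chr2"),
               forward_segment(0.45, 1, "chr3"))
  base <- call_sample(seg)
  expect_equal(base$cc_number, 3L)
  for (perm in list(c(3, 1, 2), c(2, 3, 1))) {
    expect_equal(call_sample(seg[perm, ])$cc_number, base$cc_number)
    expect_equal(call_sample(seg[perm, ])$clusters$ac_percent,
                 base$clusters$ac_percent)
  }
  padded <- rbind(seg, make_segment(chrom = "chr9"), make_segment(chrom = "chr10"))
  expect_equal(call_sample(padded)$cc_number, base$cc_number)
})

test_that("increasing merge_delta_ac never increases the CC number", {
  seg <- rbind(forward_segment(0.30, 1, "chr1"), forward_segment(0.36, 1, "chr2"),
               forward_segment(0.50, 2, "chr3"), forward_segment(0.80, 1, "chr4"))
  deltas <- c(2, 5, 8, 15, 30, 60)
  ccs <- vapply(deltas, function(d)
    call_sample(seg, cc_model_config(merge_delta_ac = d))$cc_number, integer(1))
  expect_true(all(diff(ccs) <= 0))
  expect_equal(ccs[length(ccs)], 1L)
})

test_that("subclone counting mode reports clusters minus one", {
  seg <- rbind(forward_segment(0.7, 1, "chr1"), forward_segment(0.3, 1, "chr2"))
  cfg <- cc_model_config(count_mode = "subclones")
  expect_equal(call_sample(seg, cfg)$cc_number, 1L)
  expect_equal(call_sample(make_segment(), cfg)$cc_number, 0L)
})

test_that("call_cohort is order-stable and reports one result per sample", {
  seg <- rbind(forward_segment(0.6, 1, "chr1", "S_b"),
               forward_segment(0.25, 2, "chr2", "S_b"),
               make_segment("S_a"),
               make_segment("S_c", "chr1", log2r = 0.8, folded_baf = 0.15))
  res <- suppressMessages(call_cohort(seg))
  expect_s3_class(res, "cc_cohort")
  df <- as.data.frame(res)
  expect_equal(df$sample_id, c("S_b", "S_a", "S_c"))  # first-appearance order
  expect_equal(df$classification, c("poly", "mono", "undetermined"))

  shuffled <- seg[c(4, 2, 3, 1), ]
  df2 <- as.data.frame(suppressMessages(call_cohort(shuffled)))
  a <- df2[order(df2$sample_id), ]; rownames(a) <- NULL
  b <- df[order(df$sample_id), ]; rownames(b) <- NULL
  expect_equal(a, b)

  single <- suppressMessages(call_cohort(make_segment("solo")))
  expect_equal(length(single), 1L)
})

test_that("cohort results round-trip through the results TSV", {
  seg <- rbind(forward_segment(0.6, 1, "chr1", "S1"),
               make_segment("S2", "chr1", log2r = 0.8, folded_baf = 0.15))
  res <- suppressMessages(call_cohort(seg))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cc_results(res, path)
  back <- read_cc_results(path)
  expect_equal(back$cc_number, c(1L, NA))
  expect_equal(back$classification, c("poly", "undetermined"))
})

test_that("per-sample errors carry the sample id", {
  seg <- rbind(make_segment("OK"), make_segment("BAD"))
  seg$folded_baf[2] <- NA  # n_het inconsistent for fit via folded_baf > 0.5 path
  seg$n_het[2] <- 0L
  seg$log2r[2] <- Inf
  expect_error(suppressMessages(call_cohort(seg)), "BAD")
})
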
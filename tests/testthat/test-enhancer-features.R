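test_that("signal averaging treats uncovered bases as zero", {
  tr <- signal_track("chr1", 0, 100, 2.0)
  iv <- annotation_set("chr1", 20, 40)
  expect_equal(average_signal(tr, iv), 2.0)

  # left half 1.0, right half 3.0
  tr2 <- signal_track("chr1", c(0, 50), c(50, 100), c(1, 3))
  iv2 <- annotation_set("chr1", 0, 100)
  expect_equal(average_signal(tr2, iv2), 2.0)

  # empty over the interval
  iv3 <- annotation_set("chr2", 0, 10)
  expect_equal(average_signal(tr, iv3), 0)

  # partial coverage: 10 bases at 4.0 over a 40-base interval
  tr3 <- signal_track("chr1", 10, 20, 4)
  iv4 <- annotation_set("chr1", 0, 40)
  expect_equal(average_signal(tr3, iv4), 1.0)
})

test_that("feature comparison reports median folds and exact rank p", {
  res <- compare_feature(c(3, 4), c(1, 2))
  expect_equal(res$fold_change, 3.5 / 1.5)
  expect_equal(res$pvalue, 1 / 3)

  same <- compare_feature(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$fold_change, 1)
  expect_equal(same$pvalue, 1)

  # symmetry: swapping groups inverts the fold, keeps the p
  set.seed(2)
  fg <- rgamma(30, 2); bg <- rgamma(25, 3)
  a <- compare_feature(fg, bg)
  b <- compare_feature(bg, fg)
  expect_equal(a$fold_change, 1 / b$fold_change, tolerance = 1e-12)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)

  # strongly shifted groups
  big <- compare_feature(rnorm(100, 4, 1), rnorm(100, 0, 1))
  expect_lt(big$pvalue, 1e-10)

  expect_warning(z <- compare_feature(c(1, 2), c(0, 0)), "undefined")
  expect_true(is.na(z$fold_change))
})

test_that("methylation calls require both the SD and absolute criteria", {
  expect_equal(call_tissue_specific_methylation(10, c(75, 80, 85)), "hypo")
  # 15 pp difference meets the absolute bar but not 2 SDs (sd = 10)
  comp <- c(70, 80, 90)  # mean 80, sd 10
  expect_equal(call_tissue_specific_methylation(95, comp), "neither")
  expect_equal(call_tissue_specific_methylation(80, comp), "neither")
  # hyper is symmetric
  expect_equal(call_tissue_specific_methylation(99.9, c(78, 80, 82)),
               "hyper")
  expect_error(call_tissue_specific_methylation(NA, c(1, 2)), "missing")
  expect_error(call_tissue_specific_methylation(50, 60), "comparison")
})

test_that("best conserved window matches a sliding-window oracle", {
  # single 100-bp plateau in zeros
  tr <- signal_track("chr1", 300, 400, 1.0)
  enh <- annotation_set("chr1", 100, 600)
  bw <- best_conserved_window(tr, enh)
  expect_equal(bw$score, 1.0)
  expect_equal(bw$start, 301)  # 1-based start of the plateau
  expect_false(bw$truncated)

  # constant track: leftmost tie
  trc <- signal_track("chr1", 0, 1000, 0.7)
  bwc <- best_conserved_window(trc, enh)
  expect_equal(bwc$score, 0.7)
  expect_equal(bwc$start, GenomicRanges::start(enh))

  # short enhancer falls back to the whole mean, flagged
  short <- annotation_set("chr1", 300, 350)
  bws <- best_conserved_window(tr, short)
  expect_true(bws$truncated)
  expect_equal(bws$score, 1.0)

  # random track vs brute-force scan
  set.seed(14)
  seg_start <- seq(0, 950, by = 50)
  vals <- runif(length(seg_start))
  trr <- signal_track("chr1", seg_start, seg_start + 50, vals)
  enh2 <- annotation_set("chr1", 123, 808)
  per_base <- rep(0, 685)
  for (i in seq_along(seg_start)) {
    lo <- max(seg_start[i], 123); hi <- min(seg_start[i] + 50, 808)
    if (hi > lo) per_base[(lo - 123 + 1):(hi - 123)] <- vals[i]
  }
  w <- 100
  brute <- vapply(1:(685 - w + 1), function(s) mean(per_base[s:(s + w - 1)]),
                  numeric(1))
  got <- best_conserved_window(trr, enh2, w)
  expect_equal(got$score, max(brute), tolerance = 1e-8)
  expect_equal(got$start, 124 + which.max(brute) - 1)
})

test_that("size-matched conservation test calibrates and respects matching", {
  set.seed(25)
  starts <- seq(0, 59) * 5000
  lens <- sample(800:2200, 60, replace = TRUE)
  enh <- annotation_set("chr1", starts, starts + lens)
  tr <- signal_track("chr1", starts, starts + lens, runif(60))
  fg <- enh[1:10]
  res <- size_matched_conservation_test(fg, enh[11:60], tr,
                                        n_control_sets = 200, seed = 3)
  expect_gt(res$empirical_p, 0)
  expect_lte(res$empirical_p, 1)
  # planted high-conservation cores in the foreground
  tr_hi <- signal_track("chr1", starts, starts + lens,
                        c(rep(5, 10), runif(50)))
  res_hi <- size_matched_conservation_test(fg, enh[11:60], tr_hi,
                                           n_control_sets = 200, seed = 3)
  expect_lt(res_hi$empirical_p, 0.01)
  # no size-matched candidate -> error
  tiny_bg <- annotation_set("chr1", 0, 100)
  expect_error(
    size_matched_conservation_test(fg, tiny_bg, tr, n_control_sets = 10,
                                   seed = 1),
    "size-matched")
})

test_that("cross-tissue activity requires a 1 bp intersection", {
  enh <- annotation_set("chr1", 100, 200)
  sets <- list(
    same = annotation_set("chr1", 100, 200),
    adjacent = annotation_set("chr1", 200, 300),  # end == start: no overlap
    inside = annotation_set("chr1", 150, 160),
    other_chrom = annotation_set("chr2", 100, 200))
  res <- cross_tissue_activity(enh, sets)
  expect_equal(unname(res$active), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$count, 2)
})
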
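reads_df <- function(chrom, pos) data.frame(chrom = chrom, pos = pos)

test_that("windows are blocks of a fixed number of normal reads", {
  w <- define_windows(reads_df("chr1", 1:5000), 1000)
  expect_identical(nrow(w), 5L)
  expect_true(all(w$normal_count == 1000))
  expect_identical(w$end, c(1000L, 2000L, 3000L, 4000L, 5000L))

  # trailing remainder is merged into the final window
  w2 <- define_windows(reads_df("chr1", 1:5400), 1000)
  expect_identical(nrow(w2), 5L)
  expect_identical(w2$normal_count, c(rep(1000L, 4), 1400L))
  expect_identical(w2$end[5], 5400L)

  # blocks never span chromosomes
  w3 <- define_windows(reads_df(rep(c("chr1", "chr2"), each = 1000),
                                c(1:1000, 1:1000)), 1000)
  expect_identical(nrow(w3), 2L)
  expect_identical(w3$chrom, c("chr1", "chr2"))

  expect_warning(w4 <- define_windows(reads_df("chr1", 1:50), 1000),
                 "fewer")
  expect_identical(nrow(w4), 1L)
})

test_that("log2 ratios are zero for identical or uniformly rescaled libraries", {
  set.seed(4)
  pos <- sort(sample.int(1e6, 5000))
  w <- define_windows(reads_df("chr1", pos), 1000)
  same <- compute_log2_ratios(w, reads_df("chr1", pos))
  expect_true(all(same$log2ratio == 0))
  # doubled library: every read duplicated
  doubled <- compute_log2_ratios(w, reads_df("chr1", rep(pos, 2)))
  expect_true(all(doubled$log2ratio == 0))
})

test_that("a doubled window gives a log2 ratio of about one at unit size factor", {
  w <- define_windows(reads_df("chr1", 1:1000), 1000)
  prof <- compute_log2_ratios(w, reads_df("chr1", rep(1:1000, 2)),
                              size_factor = 1)
  expect_equal(prof$log2ratio, log2(2000.5 / 1000.5), tolerance = 1e-12)
})

make_profile <- function(x, chrom = "chr1") {
  n <- length(x)
  prof <- data.frame(chrom = chrom, start = seq(1, by = 10, length.out = n),
                     end = seq(10, by = 10, length.out = n),
                     normal_count = 1000L, tumor_count = 1000L,
                     log2ratio = x)
  class(prof) <- c("copy_ratio_profile", "data.frame")
  prof
}

test_that("CBS finds planted breakpoints and keeps constant profiles whole", {
  flat <- segment_profile(make_profile(rep(0, 100)), seed = 1)
  expect_identical(nrow(flat), 1L)
  expect_identical(flat$mean_log2, 0)

  set.seed(5)
  two <- make_profile(c(rnorm(200, 0, 0.1), rnorm(200, 1, 0.1)))
  segs <- segment_profile(two, seed = 9)
  expect_identical(nrow(segs), 2L)
  expect_lte(abs(segs$end_window[1] - 200), 5)
  expect_lt(abs(segs$mean_log2[1] - 0), 0.05)
  expect_lt(abs(segs$mean_log2[2] - 1), 0.05)

  three <- make_profile(c(rnorm(150, 0, 0.1), rnorm(150, -1, 0.1),
                          rnorm(150, 0, 0.1)))
  segs3 <- segment_profile(three, seed = 9)
  expect_identical(nrow(segs3), 3L)
  expect_true(all(abs(segs3$mean_log2 - c(0, -1, 0)) < 0.05))
})

test_that("segmentation is deterministic under a fixed seed and respects chromosomes", {
  set.seed(77)
  x <- c(rnorm(100, 0, 0.1), rnorm(100, 0.8, 0.1))
  prof <- make_profile(x, chrom = rep(c("chr1", "chr2"), each = 100))
  a <- segment_profile(prof, seed = 3)
  b <- segment_profile(prof, seed = 3)
  expect_identical(a, b)
  # the level shift coincides with the chromosome boundary: no segment crosses it
  expect_true(all(table(a$chrom) >= 1))
  expect_identical(sum(a$n_windows[a$chrom == "chr1"]), 100L)
})

test_that("segment means reconstruct the profile mean window-weighted", {
  set.seed(11)
  prof <- make_profile(c(rnorm(120, 0, 0.1), rnorm(80, 1.5, 0.1)))
  segs <- segment_profile(prof, seed = 2)
  expect_equal(sum(segs$mean_log2 * segs$n_windows) / sum(segs$n_windows),
               mean(prof$log2ratio), tolerance = 1e-12)
})

test_that("DLRS matches its closed form and brute-force cases", {
  expect_identical(dlrs(rep(0.3, 100)), 0)

  # iid N(0, sigma): IQR of first differences is 1.349 * sigma * sqrt(2)
  set.seed(21)
  expect_equal(dlrs(rnorm(10000, 0, 0.1)), 0.1, tolerance = 0.05)

  a <- 0.2
  alt <- rep(c(a, -a), 500)
  expect_equal(dlrs(alt), 4 * a / (1.34 * sqrt(2)), tolerance = 1e-9)

  expect_true(is.na(dlrs(c(0.1, 0.2))))
})

test_that("DLRS pools chromosomes by weighted median and never differences across them", {
  set.seed(31)
  x1 <- rnorm(900, 0, 0.05); x2 <- rnorm(100, 5, 0.05)
  prof <- make_profile(c(x1, x2), chrom = rep(c("chr1", "chr2"),
                                              c(900, 100)))
  # the 5.0 offset between chromosomes must not inflate the estimate
  expect_lt(dlrs(prof), 0.1)
  expect_equal(dlrs(prof),
               weighted_median_for_test(
                 c(IQR(diff(x1)), IQR(diff(x2))) / (1.34 * sqrt(2)),
                 c(899, 99)))
})

test_that("difference calling is strict, symmetric and window-counted", {
  prof <- make_profile(rep(0, 100))
  segs <- segment_profile(prof, seed = 1)
  d0 <- diff_segments(segs, segs, prof)
  expect_identical(d0$percent_windows, 0)
  expect_identical(nrow(d0$regions), 0L)

  seg_at <- function(means, bounds) {
    # handcrafted segmentations over the 100-window profile
    data.frame(chrom = "chr1",
               start = prof$start[c(1, head(bounds, -1) + 1)],
               end = prof$end[bounds],
               start_window = c(1, head(bounds, -1) + 1),
               end_window = bounds,
               n_windows = diff(c(0, bounds)),
               mean_log2 = means)
  }
  a <- seg_at(c(0, 0.4, 0), c(45, 55, 100))    # 10 windows at +0.4
  b <- seg_at(0, 100)
  d <- diff_segments(a, b, prof)
  expect_identical(d$percent_windows, 10)
  expect_identical(nrow(d$regions), 1L)
  expect_identical(d$regions$n_windows, 10L)
  # symmetry
  expect_identical(diff_segments(b, a, prof)$percent_windows, 10)
  # |delta| = 0.35 exactly is not a difference
  a35 <- seg_at(c(0, 0.35, 0), c(45, 55, 100))
  expect_identical(diff_segments(a35, b, prof)$percent_windows, 0)
  # mismatched window sets error
  expect_error(diff_segments(a, b, prof[1:50, ]), "window set")
})

test_that("window summaries use raw MAD of genomic widths", {
  u <- data.frame(chrom = "chr1", start = seq(1, by = 1e4, length.out = 10),
                  end = seq(1e4, by = 1e4, length.out = 10),
                  normal_count = 1000L)
  s <- window_summary(u)
  expect_identical(s$mean_size, 10000)
  expect_identical(s$median_size, 10000)
  expect_identical(s$mad_size, 0)

  lens <- c(1, 2, 3, 4, 100)
  w <- data.frame(chrom = "chr1", start = cumsum(c(1, head(lens, -1))),
                  end = cumsum(lens), normal_count = 1L)
  s2 <- window_summary(w)
  expect_identical(s2$median_size, 3)
  expect_identical(s2$mad_size, 1)
  expect_identical(s2$n_windows, 5L)

  expect_identical(window_summary(u[1, , drop = FALSE])$mad_size, 0)
})
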
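test_that("constant counts over constant GC normalize to exactly zero", {
  bins <- tibble::tibble(chrom = "chr1", start = seq(0, 499) * 1e3,
                         end = seq(1, 500) * 1e3, gc = 0.5)
  g <- cn_grid(bins, c(chr1 = 500e3), 1e3)
  cnt <- shallowcn:::new_cn_counts(g, rep(100L, 500), "flat")
  trk <- gc_normalize(cnt, g)
  expect_true(all(trk$log2_ratio == 0))
  expect_true(all(!trk$masked))
})

test_that("log2 ratios are invariant to rescaling all counts", {
  g <- simulate_grid(1, 30e6, seed = 2)
  tr <- simulate_truth(g, n_events = 2, event_size_range_bp = c(2e6, 3e6),
                       cn_states = c(3), seed = 2)
  cnt <- simulate_counts(g, tr, sim_config(seed = 2))
  trk1 <- gc_normalize(cnt, g)
  cnt5 <- shallowcn:::new_cn_counts(g, cnt$count * 5L, "scaled")
  trk5 <- gc_normalize(cnt5, g)
  expect_equal(trk5$log2_ratio, trk1$log2_ratio, tolerance = 1e-12)
})

test_that("normalization removes the simulated GC bias", {
  g <- simulate_grid(2, 50e6, seed = 13)
  tr <- simulate_truth(g, n_events = 0, seed = 13)
  cnt <- simulate_counts(g, tr, sim_config(mean_coverage = 1.3,
                                           gc_bias_strength = 0.5, seed = 13))
  # the response is unimodal (peaked at GC 0.5), so correlate against the
  # quadratic GC term that generates it
  gc2 <- (g$gc - 0.5)^2
  before <- cor(log2(pmax(cnt$count, 1)), gc2)
  trk <- gc_normalize(cnt, g)
  after <- cor(trk$log2_ratio, gc2, use = "complete.obs")
  expect_gt(abs(before), 0.3)
  expect_lt(abs(after), 0.05)
})

test_that("the running-median GC fit also removes the bias", {
  g <- simulate_grid(2, 50e6, seed = 14)
  tr <- simulate_truth(g, n_events = 0, seed = 14)
  cnt <- simulate_counts(g, tr, sim_config(gc_bias_strength = 0.5, seed = 14))
  trk <- gc_normalize(cnt, g, fit = "runmed")
  expect_lt(abs(cor(trk$log2_ratio, (g$gc - 0.5)^2, use = "complete.obs")),
            0.08)
})

test_that("median log2 ratio is near zero on majority-diploid data", {
  g <- simulate_grid(2, 40e6, seed = 15) # 1600 bins
  tr <- simulate_truth(g, n_events = 3, event_size_range_bp = c(1e6, 2e6),
                       cn_states = c(1, 3), seed = 15)
  cnt <- simulate_counts(g, tr, sim_config(seed = 15))
  trk <- gc_normalize(cnt, g)
  expect_lt(abs(median(trk$log2_ratio, na.rm = TRUE)), 0.02)
})

test_that("zero-count bins are masked with reason, and sparse input errors", {
  g <- simulate_grid(1, 30e6, seed = 16)
  tr <- simulate_truth(g, n_events = 0, seed = 16)
  cnt <- simulate_counts(g, tr, sim_config(dropout_fraction = 0.3, seed = 16))
  trk <- gc_normalize(cnt, g)
  expect_true(all(trk$masked[cnt$count == 0]))
  expect_true(all(trk$mask_reason[cnt$count == 0] == "zero-count"))
  expect_true(all(is.na(trk$log2_ratio[cnt$count == 0])))

  few <- shallowcn:::new_cn_counts(g, c(rep(10L, 100), rep(0L, nrow(g) - 100)),
                                   "sparse")
  expect_error(gc_normalize(few, g), class = "shallowcn_error_degenerate_input")
})

test_that("blacklist masking follows the 1 bp overlap rule", {
  g <- simulate_grid(1, 500e3, bin_size = 50e3, seed = 1) # 10 bins
  trk <- make_track(rep(0, 10), bin_size = 50e3)
  trk$gc <- g$gc

  expect_identical(apply_blacklist(trk, NULL), trk)
  expect_identical(apply_blacklist(trk, tibble::tibble(chrom = character(),
                                                       start = numeric(),
                                                       end = numeric())), trk)

  # interval covering bins 3-5 exactly (0-based bins 3,4,5)
  bl <- tibble::tibble(chrom = "chr1", start = 150e3, end = 300e3)
  m <- apply_blacklist(trk, bl)
  expect_equal(sum(m$masked), 3)
  expect_equal(which(m$masked), 4:6)
  expect_true(all(m$mask_reason[m$masked] == "blacklist"))

  # single bp overlapping bin 7 (0-based) masks it
  bl1 <- tibble::tibble(chrom = "chr1", start = 399999, end = 400000)
  m1 <- apply_blacklist(trk, bl1)
  expect_equal(which(m1$masked), 8)

  # values are retained for audit
  expect_identical(m$log2_ratio, trk$log2_ratio)
})

test_that("merge_intervals canonicalizes overlapping regions", {
  r <- tibble::tibble(chrom = c("chr1", "chr1", "chr2", "chr1"),
                      start = c(10, 5, 0, 30), end = c(20, 12, 4, 40))
  m <- merge_intervals(r)
  expect_equal(nrow(m), 3)
  expect_equal(m$start[m$chrom == "chr1"], c(5, 30))
  expect_equal(m$end[m$chrom == "chr1"], c(20, 40))
  expect_error(merge_intervals(tibble::tibble(chrom = "c", start = 5, end = 5)),
               class = "shallowcn_error_invalid_argument")
})
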
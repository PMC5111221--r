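grid <- simulate_grid(1, 600e6, bin_size = 50e3, seed = 5) # 12000 bins
diploid <- simulate_truth(grid, n_events = 0, seed = 5)

test_that("count means follow the coverage calibration (NB moment check)", {
  cfg <- sim_config(mean_coverage = 1, dispersion = 1e6,
                    gc_bias_strength = 0, seed = 11)
  cnt <- simulate_counts(grid, diploid, cfg)
  r <- 1 * 50e3 / 75 # expected count per diploid bin
  se <- sqrt(r / nrow(grid)) # Poisson-like at huge dispersion
  expect_lt(abs(mean(cnt$count) - r), 3 * se)
})

test_that("a CN 4 region at purity 1 doubles the mean count", {
  g <- simulate_grid(1, 50e6, bin_size = 50e3, seed = 6)
  tr <- simulate_truth(g, n_events = 1, event_size_range_bp = c(10e6, 10e6),
                       cn_states = 4, purity = 1, seed = 6)
  cnt <- simulate_counts(g, tr, sim_config(mean_coverage = 2,
                                           gc_bias_strength = 0, seed = 6))
  cnb <- shallowcn:::truth_to_bins(tr, g)
  ratio <- mean(cnt$count[cnb == 4]) / mean(cnt$count[cnb == 2])
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("dropout forces the requested fraction of zero bins", {
  cfg <- sim_config(mean_coverage = 2, dropout_fraction = 0.85, seed = 3)
  cnt <- simulate_counts(grid, diploid, cfg)
  # binomial tail: P(zero fraction < 0.84) is negligible at n = 12000
  expect_gte(mean(cnt$count == 0), 0.84)
  expect_lte(mean(cnt$count > 0), 0.16)
})

test_that("ratio recovery: median log2 inside a CN region matches closed form", {
  g <- simulate_grid(1, 100e6, bin_size = 50e3, seed = 8)
  tr <- simulate_truth(g, n_events = 1, event_size_range_bp = c(10e6, 10e6),
                       cn_states = 3, purity = 1, seed = 8)
  cnt <- simulate_counts(g, tr, sim_config(mean_coverage = 1,
                                           gc_bias_strength = 0, seed = 8))
  cnb <- shallowcn:::truth_to_bins(tr, g)
  med_cn3 <- median(cnt$count[cnb == 3])
  med_cn2 <- median(cnt$count[cnb == 2])
  expect_lt(abs(log2(med_cn3 / med_cn2) - log2(1.5)), 0.05)
})

test_that("count simulation is bit-reproducible given the seed", {
  cfg <- sim_config(seed = 99)
  c1 <- simulate_counts(grid, diploid, cfg)
  c2 <- simulate_counts(grid, diploid, cfg)
  expect_identical(c1$count, c2$count)
})

test_that("degrade_wga preserves means, inflates variance, and drops coverage", {
  cfg <- sim_config(mean_coverage = 1.3, gc_bias_strength = 0, seed = 21)
  cnt <- simulate_counts(grid, diploid, cfg)

  # identity case: no inflation, no dropout
  same <- degrade_wga(cnt, extra_dispersion_factor = 1, dropout_fraction = 0,
                      seed = 1)
  expect_identical(same$count, cnt$count)

  deg <- degrade_wga(cnt, extra_dispersion_factor = 4, dropout_fraction = 0,
                     seed = 2)
  expect_lt(abs(mean(deg$count) / mean(cnt$count) - 1), 0.02)
  expect_gt(var(deg$count), var(cnt$count))

  dropped <- degrade_wga(cnt, extra_dispersion_factor = 4,
                         dropout_fraction = 0.85, seed = 3)
  expect_lte(mean(dropped$count > 0), 0.16)
})

test_that("WGA degradation raises MAPD in paired replicates", {
  # at WGA-like depth (0.2x) counting noise dominates, so the variance
  # inflation shows directly in MAPD
  higher <- vapply(1:20, function(s) {
    g <- simulate_grid(1, 25e6, bin_size = 50e3, seed = s)
    tr <- simulate_truth(g, n_events = 0, seed = s)
    cnt <- simulate_counts(g, tr, sim_config(mean_coverage = 0.2, seed = s))
    deg <- degrade_wga(cnt, 4, 0.3, seed = s)
    compute_mapd(gc_normalize(deg, g, min_nonzero = 100))$mapd >
      compute_mapd(gc_normalize(cnt, g, min_nonzero = 100))$mapd
  }, logical(1))
  expect_gte(sum(higher), 19)
})

test_that("downsampling thins counts binomially", {
  cfg <- sim_config(mean_coverage = 2.2, gc_bias_strength = 0, seed = 31)
  cnt <- simulate_counts(grid, diploid, cfg)

  expect_identical(downsample_counts(cnt, 1)$count, cnt$count)

  half <- downsample_counts(cnt, 0.5, seed = 1)
  tot <- sum(cnt$count)
  expect_lt(abs(sum(half$count) - tot / 2), 3 * sqrt(tot * 0.25))

  # 2.2x thinned by 0.2/2.2 lands at 0.2x realized coverage
  thin <- downsample_counts(cnt, 0.2 / 2.2, seed = 2)
  realized <- mean(thin$count) * 75 / 50e3
  expect_lt(abs(realized - 0.2), 0.01)

  expect_error(downsample_counts(cnt, 0),
               class = "shallowcn_error_invalid_argument")
  expect_error(downsample_counts(cnt, 1.2),
               class = "shallowcn_error_invalid_argument")
})

test_that("sequential thinning composes multiplicatively (moment match)", {
  cfg <- sim_config(mean_coverage = 2.2, gc_bias_strength = 0, seed = 41)
  cnt <- simulate_counts(grid, diploid, cfg)
  ab <- vapply(1:10, function(s) {
    sum(downsample_counts(downsample_counts(cnt, 0.6, seed = s),
                          0.5, seed = s + 100)$count)
  }, numeric(1))
  onestep <- vapply(1:10, function(s) {
    sum(downsample_counts(cnt, 0.3, seed = s + 200)$count)
  }, numeric(1))
  tot <- sum(cnt$count)
  se <- sqrt(tot * 0.3 * 0.7 / 10)
  expect_lt(abs(mean(ab) - mean(onestep)), 4 * se)
  expect_lt(abs(mean(ab) - 0.3 * tot), 4 * se)
})

test_that("simulation configs validate their parameters", {
  expect_error(sim_config(mean_coverage = 0), class = "shallowcn_error_invalid_argument")
  expect_error(sim_config(dispersion = -1), class = "shallowcn_error_invalid_argument")
  expect_error(sim_config(dropout_fraction = 1), class = "shallowcn_error_invalid_argument")
  expect_error(sim_config(gc_bias_strength = 1), class = "shallowcn_error_invalid_argument")
})
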
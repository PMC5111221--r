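grid10 <- cn_grid(
  tibble::tibble(chrom = "chr1", start = seq(0, 9) * 50e3,
                 end = seq(1, 10) * 50e3, gc = 0.5),
  c(chr1 = 500e3), 50e3
)

profile_from_calls <- function(calls, grid, sample_id = "p") {
  # calls: per-bin vector of loss/neutral/gain (NA = not covered)
  means <- c(loss = -0.5, neutral = 0, gain = 0.5)[calls]
  keep <- !is.na(calls)
  segs <- shallowcn:::collapse_runs(grid, ifelse(keep, means, NA),
                                    value_name = "mean_log2")
  segs <- segs[!is.na(segs$mean_log2), ]
  segs$n_bins <- as.integer((segs$end - segs$start) / 50e3)
  call_segments(segs, sample_id = sample_id)
}

test_that("profiles project onto bins by the midpoint rule", {
  calls <- c(rep("gain", 5), rep("neutral", 5))
  p <- profile_from_calls(calls, grid10)
  st <- profile_to_states(p, grid10)
  expect_equal(st$state, calls)

  # a bin whose midpoint falls in a gap between segments is masked
  calls2 <- c(rep("gain", 3), NA, rep("neutral", 6))
  p2 <- profile_from_calls(calls2, grid10)
  st2 <- profile_to_states(p2, grid10)
  expect_equal(st2$state[4], "masked")
  expect_equal(st2$state[-4], calls2[-4])

  bad <- profile_from_calls(calls, grid10)
  bad$chrom <- "chrX"
  expect_error(profile_to_states(bad, grid10),
               class = "shallowcn_error_config")
})

test_that("self-concordance is exactly 1", {
  a <- make_states(grid10, c(rep("gain", 3), rep("neutral", 6), "masked"))
  cc <- concordance(a, a)
  expect_equal(cc$shared_fraction, 1)
  expect_equal(cc$shared_cnv_fraction, 1)
  expect_equal(cc$total_compared_bp, 9 * 50e3)
})

test_that("the worked 10-bin example decomposes as 7/10 and 2/5", {
  a <- make_states(grid10, c(rep("gain", 5), rep("neutral", 5)), "a")
  b <- make_states(grid10, c(rep("gain", 2), rep("neutral", 8)), "b")
  cc <- concordance(a, b)
  expect_equal(cc$shared_fraction, 7 / 10)
  expect_equal(cc$shared_cnv_fraction, 2 / 5)
  expect_equal(cc$a_only_bp, 3 * 50e3)
  expect_equal(cc$b_only_bp, 0)
  expect_equal(cc$conflict_bp, 0)
})

test_that("total disagreement gives zero concordance", {
  a <- make_states(grid10, rep("gain", 10))
  b <- make_states(grid10, rep("loss", 10))
  cc <- concordance(a, b)
  expect_equal(cc$shared_fraction, 0)
  expect_equal(cc$conflict_bp, 500e3)
})

test_that("concordance is symmetric and conserves base pairs exactly", {
  g <- simulate_grid(2, 20e6, seed = 40)
  for (s in 1:10) {
    a <- profile_to_states(random_profile(g, s, "a"), g)
    b <- profile_to_states(random_profile(g, s + 100, "b"), g)
    ab <- concordance(a, b)
    ba <- concordance(b, a)
    expect_equal(ab$shared_fraction, ba$shared_fraction)
    expect_equal(ab$shared_cna_bp, ba$shared_cna_bp)
    expect_equal(ab$a_only_bp, ba$b_only_bp)
    expect_equal(ab$conflict_bp, ba$conflict_bp)
    # exhaustive accounting: every compared bp lands in exactly one class
    expect_identical(
      ab$shared_cna_bp + ab$shared_neutral_bp + ab$a_only_bp + ab$b_only_bp +
        ab$conflict_bp,
      ab$total_compared_bp)
    expect_identical(ab$concordant_bp + ab$discordant_bp,
                     ab$total_compared_bp)
  }
})

test_that("shared_neutral_bp implements the subtraction account", {
  expect_equal(shared_neutral_bp(100, 30, 15), 55)
  expect_equal(shared_neutral_bp(100, 0, 0), 100)
  expect_error(shared_neutral_bp(100, 80, 30),
               class = "shallowcn_error_accounting")
  expect_error(shared_neutral_bp(-1, 0, 0),
               class = "shallowcn_error_invalid_argument")
})

test_that("shared regions are labeled by exact sample subsets", {
  # two identical single-gain profiles -> one shared region, nothing unique
  calls <- c(rep("neutral", 2), rep("gain", 4), rep("neutral", 4))
  p1 <- profile_from_calls(calls, grid10, "s1")
  p2 <- profile_from_calls(calls, grid10, "s2")
  ov <- shared_regions(list(p1, p2), grid10)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$status, "shared")
  expect_equal(ov$start, 100e3)
  expect_equal(ov$end, 300e3)
  expect_setequal(ov$samples[[1]], c("s1", "s2"))

  # staggered gains A:[0,300k) B:[200k,500k)
  a <- profile_from_calls(c(rep("gain", 6), rep("neutral", 4)), grid10, "A")
  b <- profile_from_calls(c(rep("neutral", 4), rep("gain", 6)), grid10, "B")
  ov2 <- shared_regions(list(a, b), grid10)
  ov2 <- ov2[order(ov2$start), ]
  expect_equal(ov2$start, c(0, 200e3, 300e3))
  expect_equal(ov2$end, c(200e3, 300e3, 500e3))
  expect_equal(ov2$status, c("sample_only", "shared", "sample_only"))
  expect_equal(ov2$samples[[1]], "A")
  expect_equal(ov2$samples[[3]], "B")

  # opposite event types never share
  ga <- profile_from_calls(rep("gain", 10), grid10, "GA")
  lo <- profile_from_calls(rep("loss", 10), grid10, "LO")
  ov3 <- shared_regions(list(ga, lo), grid10)
  expect_equal(sort(ov3$event), c("gain", "loss"))
  expect_true(all(ov3$status == "sample_only"))

  expect_error(shared_regions(list(p1), grid10),
               class = "shallowcn_error_invalid_argument")
})

test_that("shared regions partition each event type without overlap", {
  g <- simulate_grid(2, 20e6, seed = 44)
  profs <- lapply(1:3, function(s) random_profile(g, s + 200, paste0("s", s)))
  ov <- shared_regions(profs, g)
  for (ev in unique(ov$event)) {
    for (cc in unique(ov$chrom)) {
      r <- ov[ov$event == ev & ov$chrom == cc, ]
      r <- r[order(r$start), ]
      if (nrow(r) > 1) expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    }
  }
  # region accounting agrees with pairwise concordance for two profiles
  a <- profs[[1]]; b <- profs[[2]]
  ov2 <- shared_regions(list(a, b), g)
  sa <- profile_to_states(a, g); sb <- profile_to_states(b, g)
  cc2 <- concordance(sa, sb)
  both <- sa$state != "masked" & sb$state != "masked"
  shared_len <- sum({
    r <- ov2[ov2$status == "shared", ]
    # restrict to bins compared in both samples
    vapply(seq_len(nrow(r)), function(k) {
      sel <- sa$chrom == r$chrom[k] & sa$start >= r$start[k] &
        sa$end <= r$end[k] & both & sa$state == sb$state
      sum(sa$end[sel] - sa$start[sel])
    }, numeric(1))
  })
  expect_equal(shared_len, cc2$shared_cna_bp)
})
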
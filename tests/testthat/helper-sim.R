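# shared fixture builders; everything is generated in code under fixed seeds

# a cn_profile derived directly from a truth: segment means are the exact
# expected log2 ratios
truth_profile <- function(truth, grid, sample_id = "truth") {
  segs <- tibble::tibble(
    chrom = truth$chrom, start = truth$start, end = truth$end,
    n_bins = as.integer((truth$end - truth$start) / attr(grid, "bin_size")),
    mean_log2 = expected_log2_ratio(truth$cn, attr(truth, "purity"))
  )
  call_segments(segs, sample_id = sample_id)
}

# a cn_profile emulating an imperfect assay of a truth: each true event is
# missed (called at baseline) with probability miss_prob, segment means are
# jittered, and a fraction of regions is dropped (masked). Pairs built from
# the same truth behave like the paper's matched assay pairs: overlapping
# CNA subsets of one event set, never opposite calls at a locus.
random_profile <- function(grid, seed, sample_id = paste0("s", seed),
                           truth = NULL, n_events = 4, miss_prob = 0.3,
                           mask_fraction = 0.1) {
  withr::with_seed(seed, {
    if (is.null(truth)) {
      truth <- simulate_truth(grid, n_events = n_events,
                              event_size_range_bp = c(1e6, 3e6),
                              cn_states = c(1, 3, 4), purity = 1,
                              seed = sample.int(1e6, 1))
    }
    mean_log2 <- expected_log2_ratio(truth$cn, 1)
    missed <- truth$cn != 2 & runif(nrow(truth)) < miss_prob
    mean_log2[missed] <- 0
    segs <- tibble::tibble(
      chrom = truth$chrom, start = truth$start, end = truth$end,
      n_bins = as.integer((truth$end - truth$start) /
                            attr(grid, "bin_size")),
      mean_log2 = mean_log2 + rnorm(nrow(truth), 0, 0.02)
    )
    keep <- runif(nrow(segs)) > mask_fraction
    if (!any(keep)) keep[1] <- TRUE
    call_segments(segs[keep, ], sample_id = sample_id)
  })
}

# hand-built ratio track
make_track <- function(log2_ratio, chrom = "chr1", masked = FALSE,
                       bin_size = 1000, sample_id = "manual") {
  n <- length(log2_ratio)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(masked) == 1) masked <- rep(masked, n)
  start <- unlist(lapply(split(seq_len(n), factor(chrom, unique(chrom))),
                         function(i) (seq_along(i) - 1) * bin_size),
                  use.names = FALSE)
  structure(
    tibble::tibble(chrom = chrom, start = start, end = start + bin_size,
                   gc = 0.5, count = 1L, log2_ratio = log2_ratio,
                   masked = masked,
                   mask_reason = ifelse(masked, "user", NA_character_)),
    sample_id = sample_id,
    class = c("cn_track", class(tibble::tibble()))
  )
}

# hand-built state track on a grid
make_states <- function(grid, state, sample_id = "manual") {
  structure(
    tibble::tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
                   state = state),
    sample_id = sample_id,
    class = c("cn_states", class(tibble::tibble()))
  )
}

# brute-force MAPD oracle: explicit per-chromosome list of absolute
# successive differences over non-missing markers, explicit even-count
# median
mapd_oracle <- function(track, pairing = "skip") {
  diffs <- c()
  for (cc in unique(track$chrom)) {
    sel <- track$chrom == cc
    x <- track$log2_ratio[sel]
    m <- if ("masked" %in% names(track)) track$masked[sel] else FALSE
    ok <- is.finite(x) & !m
    if (pairing == "skip") {
      v <- x[ok]
      if (length(v) >= 2) {
        for (i in seq_len(length(v) - 1)) {
          diffs <- c(diffs, abs(v[i + 1] - v[i]))
        }
      }
    } else {
      for (i in seq_len(max(length(x) - 1, 0))) {
        if (ok[i] && ok[i + 1]) diffs <- c(diffs, abs(x[i + 1] - x[i]))
      }
    }
  }
  if (length(diffs) == 0) return(NULL)
  s <- sort(diffs)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# exhaustive single-changepoint oracle: argmax over all (i, j) windows of
# the pooled-variance two-sample t between window and complement
cbs_oracle_scan <- function(x, min_width = 3) {
  m <- length(x)
  best <- list(t = 0, i = 0, j = m)
  if (m < 2 * min_width) return(best)
  for (n in min_width:(m - min_width)) {
    for (i in 0:(m - n)) {
      inside <- x[(i + 1):(i + n)]
      outside <- x[-((i + 1):(i + n))]
      ss <- sum((inside - mean(inside))^2) + sum((outside - mean(outside))^2)
      s2 <- max(ss / max(m - 2, 1), 1e-24)
      t <- (mean(inside) - mean(outside)) / sqrt(s2 * (1 / n + 1 / (m - n)))
      if (abs(t) > abs(best$t)) best <- list(t = t, i = i, j = i + n)
    }
  }
  best
}
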
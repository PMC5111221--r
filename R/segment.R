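#' Segment a ratio track by circular binary segmentation
#'
#' Recursively partitions the non-missing markers of each chromosome into
#' segments of homogeneous mean log2 ratio. At each step the arc of the
#' circularised marker sequence maximizing the two-sample t statistic
#' (window vs complement, pooled variance) is found; the split is accepted
#' when its permutation p-value (label shuffles, with sequential early
#' stopping) falls below `alpha`, and both parts are segmented recursively.
#' Adjacent segments whose means differ by less than `prune_tol` are merged
#' afterwards. Masked bins are skipped; a run of more than `max_gap`
#' consecutive masked bins breaks the chromosome, so segments never bridge
#' large masked gaps such as centromeres.
#'
#' @param track A `cn_track` (see [gc_normalize()], [apply_blacklist()]).
#' @param alpha Permutation significance level for accepting a split.
#' @param n_permutations Maximum permutations per test.
#' @param min_bins_per_segment Minimum markers on each side of a split.
#' @param prune_tol Merge adjacent segments whose means differ by less than
#'   this many log2 units.
#' @param max_gap Maximum number of consecutive masked bins a segment may
#'   bridge.
#' @param seed Integer seed driving the permutation RNG.
#' @return A tibble of segments `(chrom, start, end, n_bins, mean_log2)`;
#'   `n_bins` counts the non-missing markers, extents run from the first
#'   member bin's start to the last member bin's end.
#' @export
segment_cbs <- function(track, alpha = 0.01, n_permutations = 1000,
                        min_bins_per_segment = 3, prune_tol = 0.05,
                        max_gap = 10, seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  if (min_bins_per_segment < 1) {
    stop_invalid("min_bins_per_segment must be >= 1")
  }
  usable <- which(!track$masked & is.finite(track$log2_ratio))
  if (length(usable) == 0) {
    stop_degenerate("no usable (unmasked, finite) bins to segment")
  }

  segs <- withr::with_seed(derive_seed(seed, 101L), {
    purrr::map_dfr(unique(track$chrom), function(cc) {
      idx <- usable[track$chrom[usable] == cc]
      if (length(idx) == 0) return(NULL)
      # split into runs: a masked gap wider than max_gap starts a new run
      run_id <- cumsum(c(1, diff(idx) - 1 > max_gap))
      purrr::map_dfr(split(idx, run_id), function(run_idx) {
        x <- track$log2_ratio[run_idx]
        bounds <- cbs_recurse(x, alpha, n_permutations, min_bins_per_segment)
        bounds <- cbs_prune(x, bounds, prune_tol)
        purrr::map_dfr(seq_len(length(bounds) - 1), function(s) {
          members <- run_idx[(bounds[s] + 1):bounds[s + 1]]
          tibble::tibble(
            chrom = cc,
            start = track$start[members[1]],
            end = track$end[members[length(members)]],
            n_bins = length(members),
            mean_log2 = mean(track$log2_ratio[members])
          )
        })
      })
    })
  })
  tibble::as_tibble(segs)
}

# recursive splitting on a marker vector; returns 0-based boundary indices
# (0, ..., length(x)) delimiting segments
cbs_recurse <- function(x, alpha, n_perm, min_width) {
  m <- length(x)
  if (m < 2 * min_width) return(c(0L, m))
  res <- .cbs_test(x, min_width, n_perm, alpha)
  if (res$p >= alpha) return(c(0L, m))
  i <- res$i
  j <- res$j
  cuts <- sort(unique(c(0L, i, j, m)))
  out <- integer(0)
  for (s in seq_len(length(cuts) - 1)) {
    lo <- cuts[s]
    hi <- cuts[s + 1]
    sub <- cbs_recurse(x[(lo + 1):hi], alpha, n_perm, min_width)
    out <- c(out, lo + sub)
  }
  sort(unique(out))
}

# merge adjacent segments whose means differ by less than tol, smallest
# difference first, recomputing means as segments coalesce
cbs_prune <- function(x, bounds, tol) {
  repeat {
    if (length(bounds) <= 2) return(bounds)
    means <- vapply(seq_len(length(bounds) - 1), function(s) {
      mean(x[(bounds[s] + 1):bounds[s + 1]])
    }, numeric(1))
    d <- abs(diff(means))
    if (length(d) == 0 || min(d) >= tol) return(bounds)
    k <- which.min(d)
    bounds <- bounds[-(k + 1)]
  }
}
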
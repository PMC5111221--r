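#' Expected log2 ratio of a copy-number state under a diploid baseline
#'
#' With tumor fraction `purity` and integer copy number `cn`, the bulk DNA
#' mixture has average copy `purity * cn + (1 - purity) * 2`, so the
#' read-depth ratio against a diploid baseline is that average over 2.
#'
#' @param cn Integer copy number (>= 0).
#' @param purity Tumor cell fraction in `(0, 1]`.
#' @return Expected log2 ratio; `-Inf` for `cn = 0` at purity 1.
#' @examples
#' expected_log2_ratio(4, purity = 0.5) # log2(3/2)
#' @export
expected_log2_ratio <- function(cn, purity = 1) {
  if (any(purity <= 0 | purity > 1)) stop_invalid("purity must be in (0, 1]")
  if (any(cn < 0)) stop_invalid("copy number must be >= 0")
  log2((purity * cn + (1 - purity) * 2) / 2)
}

#' Simulate a ground-truth copy-number profile
#'
#' Places `n_events` non-overlapping segmental events of integer copy number
#' drawn from `cn_states` on a diploid background, uniformly at random over
#' the grid. The truth is the reference every recovery experiment is scored
#' against.
#'
#' @param grid A [cn_grid()].
#' @param n_events Number of events to place (0 gives an all-diploid truth).
#' @param event_size_range_bp Length-2 numeric range of event sizes in bp;
#'   events are whole numbers of bins, at least one bin.
#' @param cn_states Integer copy numbers to draw events from; must exclude
#'   the diploid baseline 2.
#' @param purity Tumor fraction in `(0, 1]` recorded with the truth.
#' @param seed Integer seed.
#' @param max_tries Placement retries before giving up.
#' @return A tibble `(chrom, start, end, cn)` covering the grid exactly,
#'   with class `cn_truth` and attributes `purity` and `grid`.
#' @export
simulate_truth <- function(grid,
                           n_events = 8,
                           event_size_range_bp = c(2.5e6, 4e6),
                           cn_states = c(1, 3, 4),
                           purity = 1,
                           seed = 1,
                           max_tries = 1000) {
  if (purity <= 0 || purity > 1) stop_invalid("purity must be in (0, 1]")
  if (n_events < 0) stop_invalid("n_events must be >= 0")
  cn_states <- as.integer(cn_states)
  if (n_events > 0 &&
      (length(cn_states) == 0 || any(cn_states < 0) || any(cn_states == 2L))) {
    stop_invalid("cn_states must be non-negative integers excluding 2")
  }
  bin_size <- grid_bin_size(grid)
  chrom_lengths <- grid_chrom_lengths(grid)

  # per-bin copy number, then collapse to regions
  cn_bins <- rep(2L, nrow(grid))
  if (n_events > 0) {
    taken <- logical(nrow(grid))
    chrom_idx <- split(seq_len(nrow(grid)), grid$chrom)
    withr::with_seed(derive_seed(seed, 23L), {
      placed <- 0
      tries <- 0
      while (placed < n_events) {
        tries <- tries + 1
        if (tries > max_tries) {
          stop_placement(sprintf(
            "could not place %d non-overlapping events after %d tries",
            n_events, max_tries))
        }
        size_bp <- runif(1, event_size_range_bp[1], event_size_range_bp[2])
        n_bins <- max(1L, as.integer(round(size_bp / bin_size)))
        cc <- sample(names(chrom_lengths), 1)
        idx <- chrom_idx[[cc]]
        if (length(idx) < n_bins) next
        first <- idx[sample.int(length(idx) - n_bins + 1, 1)]
        span <- first:(first + n_bins - 1)
        if (any(taken[span])) next
        taken[span] <- TRUE
        cn_bins[span] <- cn_states[sample.int(length(cn_states), 1)]
        placed <- placed + 1
      }
    })
  }

  regions <- collapse_runs(grid, cn_bins, value_name = "cn")
  structure(
    regions,
    purity = purity,
    grid = grid,
    class = c("cn_truth", class(tibble::tibble()))
  )
}

#' @export
print.cn_truth <- function(x, ...) {
  n_ev <- sum(x$cn != 2)
  cat(sprintf("<cn_truth> %d region(s), %d non-diploid event(s), purity %.2f\n",
              nrow(x), n_ev, attr(x, "purity")))
  NextMethod()
}

truth_purity <- function(truth) attr(truth, "purity")

# per-bin integer copy number for a truth on its grid
truth_to_bins <- function(truth, grid) {
  states <- regions_to_bins(grid, truth, "cn", default = 2L)
  as.integer(states)
}

# collapse a per-bin vector into maximal constant runs per chromosome,
# merging adjacent equal-valued regions (canonical form)
collapse_runs <- function(grid, values, value_name = "value") {
  stopifnot(length(values) == nrow(grid))
  out <- purrr::map_dfr(split(seq_len(nrow(grid)), factor(grid$chrom, unique(grid$chrom))),
    function(idx) {
      v <- values[idx]
      r <- rle(as.vector(v))
      last <- cumsum(r$lengths)
      first <- c(1, head(last, -1) + 1)
      tibble::tibble(
        chrom = grid$chrom[idx[1]],
        start = grid$start[idx[first]],
        end = grid$end[idx[last]],
        !!value_name := r$values
      )
    })
  tibble::as_tibble(out)
}

# map region values onto grid bins; a bin takes the value of the region
# containing its midpoint
regions_to_bins <- function(grid, regions, value_col, default = NA) {
  out <- rep(default, nrow(grid))
  mid <- (grid$start + grid$end) / 2
  for (cc in unique(regions$chrom)) {
    r <- regions[regions$chrom == cc, ]
    r <- r[order(r$start), ]
    sel <- which(grid$chrom == cc)
    if (length(sel) == 0) next
    pos <- findInterval(mid[sel], r$start)
    ok <- pos >= 1 & pos <= nrow(r)
    ok[ok] <- mid[sel][ok] < r$end[pos[ok]]
    out[sel[ok]] <- r[[value_col]][pos[ok]]
  }
  out
}
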
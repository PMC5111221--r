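#' GC-normalize binned counts into a log2 ratio track
#'
#' Fits the expected count as a smooth function of bin GC fraction — no
#' matched normal is used — and converts counts to log2 ratios against that
#' expectation, re-centered so the genome-wide median ratio maps to copy
#' number 2 (log2 ratio 0). Zero-count bins carry no depth information at
#' low coverage and are masked rather than log-transformed.
#'
#' The GC model and the centering median are estimated on the *baseline*
#' (copy-number-neutral) cluster of bins. A first curve of per-GC-decile
#' count medians — robust to a large altered fraction — anchors the
#' baseline: bins whose ratio against that curve lies within
#' `baseline_window` log2 units of the running median. The requested model
#' is then fit on baseline bins only and the selection refined. This keeps
#' large altered fractions from tilting the GC curve or shifting the
#' center, while on majority-diploid data the centering coincides with the
#' genome-wide median (so the median log2 ratio is ~0 and maps to copy
#' number 2).
#'
#' @param counts A `cn_counts` track.
#' @param grid The [cn_grid()] the counts live on.
#' @param fit `"poly"` (default): degree-2 polynomial fit to the baseline
#'   bins; `"runmed"`: running median of counts over GC deciles,
#'   interpolated.
#' @param min_nonzero Minimum number of non-zero bins required to fit.
#' @param baseline_iterations Refinement passes for the baseline cluster.
#' @param baseline_window Half-width (log2 units) of the ratio window that
#'   defines the baseline cluster during refinement.
#' @return A tibble `(chrom, start, end, gc, count, log2_ratio, masked,
#'   mask_reason)` with class `cn_track`. `log2_ratio` is `NA` for masked
#'   zero-count bins; `mask_reason` is one of `"zero-count"`, `"blacklist"`,
#'   `"user"` or `NA`.
#' @export
gc_normalize <- function(counts, grid, fit = c("poly", "runmed"),
                         min_nonzero = 200, baseline_iterations = 3,
                         baseline_window = 0.25) {
  fit <- match.arg(fit)
  check_grid_alignment(counts, grid, "counts")
  x <- counts$count
  gc <- grid$gc
  nz <- x > 0
  if (sum(nz) < min_nonzero) {
    stop_degenerate(sprintf(
      "only %d non-zero bins; need at least %d to fit a GC model",
      sum(nz), min_nonzero))
  }
  # per-GC-decile count medians: robust both to altered regions (the
  # median tracks the dominant diploid mode) and to the skew of
  # low-coverage counts
  decile_medians <- function(use) {
    br <- unique(quantile(gc[use], seq(0, 1, by = 0.1), names = FALSE))
    if (length(br) < 3) return(NULL)
    dec <- cut(gc[use], br, include.lowest = TRUE)
    med <- tapply(x[use], dec, median)
    ctr <- tapply(gc[use], dec, median)
    n <- tapply(x[use], dec, length)
    ok <- !is.na(med) & !is.na(ctr)
    if (sum(ok) < 3) return(NULL)
    list(ctr = as.numeric(ctr[ok]), med = as.numeric(med[ok]),
         n = as.numeric(n[ok]))
  }

  # interpolated decile medians with linear (not flat) tail extrapolation;
  # the "runmed" final model
  decile_curve <- function(use) {
    dm <- decile_medians(use)
    if (is.null(dm)) return(rep(median(x[use]), length(x)))
    y <- approx(dm$ctr, dm$med, xout = gc, rule = 2)$y
    k <- length(dm$ctr)
    lo <- gc < dm$ctr[1]
    hi <- gc > dm$ctr[k]
    s_lo <- (dm$med[2] - dm$med[1]) / (dm$ctr[2] - dm$ctr[1])
    s_hi <- (dm$med[k] - dm$med[k - 1]) / (dm$ctr[k] - dm$ctr[k - 1])
    y[lo] <- dm$med[1] + s_lo * (gc[lo] - dm$ctr[1])
    y[hi] <- dm$med[k] + s_hi * (gc[hi] - dm$ctr[k])
    pmax(y, 0.05 * median(dm$med))
  }

  # robust anchor: quadratic through the decile medians (weighted by
  # stratum size); extrapolates with the right functional form at the GC
  # extremes, where a flat or piecewise-linear tail would misstate depth
  anchor_curve <- function(use) {
    dm <- decile_medians(use)
    if (is.null(dm)) return(rep(median(x[use]), length(x)))
    m <- lm(med ~ poly(ctr, 2), data = data.frame(med = dm$med,
                                                  ctr = dm$ctr),
            weights = dm$n)
    pmax(predict(m, newdata = data.frame(ctr = gc)),
         0.05 * median(dm$med))
  }

  fit_expected <- function(use) {
    expected <- switch(fit,
      poly = {
        if (length(unique(gc[use])) < 3) {
          # constant GC carries no information: expected count is flat
          rep(mean(x[use]), length(x))
        } else {
          m <- lm(count ~ poly(gc, 2),
                  data = data.frame(count = x[use], gc = gc[use]))
          # the quadratic may dip below zero outside the fitted GC range;
          # clamp to a positive floor rather than emit impossible depths
          pmax(predict(m, newdata = data.frame(gc = gc)),
               0.05 * median(x[use]))
        }
      },
      runmed = decile_curve(use)
    )
    if (any(!is.finite(expected))) {
      stop_fit("GC fit produced non-finite expected counts")
    }
    expected
  }

  # stage 1: anchor the baseline cluster on the robust median-based curve
  min_baseline <- max(50, min_nonzero %/% 2)
  expected <- anchor_curve(nz)
  if (any(!is.finite(expected))) {
    stop_fit("GC fit produced non-finite expected counts")
  }
  ratio <- ifelse(nz, x / expected, NA_real_)
  med <- median(ratio[nz])
  use <- nz & abs(log2(ratio / med)) < baseline_window
  if (sum(use) < min_baseline) use <- nz

  # stage 2: fit the requested model on baseline bins only, untrimmed and
  # unweighted (unbiased for the neutral cloud), refining the selection
  for (iter in seq_len(max(1, baseline_iterations))) {
    expected <- fit_expected(use)
    ratio <- ifelse(nz, x / expected, NA_real_)
    med <- median(ratio[use])
    if (iter >= baseline_iterations) break
    baseline <- nz & abs(log2(ratio / med)) < baseline_window
    if (sum(baseline) < min_baseline) break
    use <- baseline
  }
  log2_ratio <- log2(ratio / med)

  structure(
    tibble::tibble(
      chrom = grid$chrom, start = grid$start, end = grid$end, gc = gc,
      count = x,
      log2_ratio = log2_ratio,
      masked = !nz,
      mask_reason = ifelse(nz, NA_character_, "zero-count")
    ),
    sample_id = counts_sample_id(counts),
    grid = grid,
    class = c("cn_track", class(tibble::tibble()))
  )
}

#' @export
print.cn_track <- function(x, ...) {
  cat(sprintf(
    "<cn_track> sample %s: %d bins, %.1f%% masked, median |log2| %.3f\n",
    attr(x, "sample_id"), nrow(x), 100 * mean(x$masked),
    median(abs(x$log2_ratio), na.rm = TRUE)))
  NextMethod()
}

track_sample_id <- function(x) attr(x, "sample_id")

#' Canonicalize a set of genomic intervals
#'
#' Sorts intervals and merges any that touch or overlap, per chromosome.
#' Coordinates are 0-based half-open.
#'
#' @param regions Data frame with `chrom`, `start`, `end`.
#' @return A tibble of disjoint sorted intervals.
#' @export
merge_intervals <- function(regions) {
  regions <- tibble::as_tibble(regions)
  if (nrow(regions) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  if (any(regions$end <= regions$start)) {
    stop_invalid("intervals must satisfy start < end")
  }
  regions |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      grp = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                            default = -Inf))
    ) |>
    dplyr::group_by(.data$chrom, .data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end")
}

# logical vector: does each grid bin overlap any interval by >= 1 bp?
bins_overlapping <- function(grid, regions) {
  hit <- logical(nrow(grid))
  if (is.null(regions) || nrow(regions) == 0) return(hit)
  for (cc in unique(regions$chrom)) {
    r <- regions[regions$chrom == cc, ]
    sel <- which(grid$chrom == cc)
    if (length(sel) == 0) next
    for (k in seq_len(nrow(r))) {
      hit[sel] <- hit[sel] |
        (grid$start[sel] < r$end[k] & grid$end[sel] > r$start[k])
    }
  }
  hit
}

#' Mask blacklisted regions in a ratio track
#'
#' Read-depth copy number cannot be measured reliably in known problematic
#' regions (centromeric and other highly repetitive sequence); any bin
#' overlapping a blacklist interval by at least 1 bp is masked. Ratio values
#' are retained in the table for audit, but all downstream computation
#' honors the mask.
#'
#' @param track A `cn_track`.
#' @param blacklist Data frame `(chrom, start, end)` of regions to mask,
#'   0-based half-open; `NULL` or empty leaves the track unchanged.
#' @param reason Mask reason recorded for newly masked bins.
#' @return The track with updated `masked` / `mask_reason`.
#' @export
apply_blacklist <- function(track, blacklist, reason = "blacklist") {
  if (is.null(blacklist) || nrow(blacklist) == 0) return(track)
  bl <- merge_intervals(blacklist)
  hit <- bins_overlapping(track, bl)
  newly <- hit & !track$masked
  track$masked <- track$masked | hit
  track$mask_reason[newly] <- reason
  track
}
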
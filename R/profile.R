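#' Call gains and losses on segments
#'
#' Applies the three-state calling rule: a segment is a gain when its mean
#' log2 ratio is strictly greater than `gain_thr`, a loss when strictly less
#' than `loss_thr`, and neutral otherwise (boundary values are neutral).
#'
#' @param segments Segment tibble from [segment_cbs()].
#' @param gain_thr Gain threshold (default 0.15 log2 units).
#' @param loss_thr Loss threshold (default -0.15).
#' @param sample_id Label recorded in the profile.
#' @param masked_fraction,mapd Optional provenance carried into the profile.
#' @return A `cn_profile`: the segment tibble gains a `call` column
#'   (`"loss"`, `"neutral"`, `"gain"`), with thresholds stored as attributes.
#' @export
call_segments <- function(segments, gain_thr = 0.15, loss_thr = -0.15,
                          sample_id = "sample", masked_fraction = NA_real_,
                          mapd = NA_real_) {
  if (!is.numeric(gain_thr) || !is.numeric(loss_thr) || gain_thr <= loss_thr) {
    stop_invalid("thresholds must satisfy gain_thr > loss_thr")
  }
  segments <- tibble::as_tibble(segments)
  segments$call <- dplyr::case_when(
    segments$mean_log2 > gain_thr ~ "gain",
    segments$mean_log2 < loss_thr ~ "loss",
    .default = "neutral"
  )
  new_cn_profile(segments, sample_id, gain_thr, loss_thr,
                 masked_fraction = masked_fraction, mapd = mapd)
}

new_cn_profile <- function(segments, sample_id, gain_thr, loss_thr,
                           masked_fraction = NA_real_, mapd = NA_real_) {
  structure(
    segments,
    sample_id = sample_id,
    gain_thr = gain_thr,
    loss_thr = loss_thr,
    masked_fraction = masked_fraction,
    mapd = mapd,
    class = c("cn_profile", class(tibble::tibble()))
  )
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf(
    "<cn_profile> sample %s: %d segment(s) (%d gain, %d loss); thresholds (%g, %g)\n",
    attr(x, "sample_id"), nrow(x), sum(x$call == "gain"),
    sum(x$call == "loss"), attr(x, "loss_thr"), attr(x, "gain_thr")))
  NextMethod()
}

profile_sample_id <- function(x) attr(x, "sample_id")

#' Run the per-sample copy-number pipeline
#'
#' Composes the per-sample stages: GC normalization, blacklist masking,
#' circular binary segmentation, and three-state calling, returning a called
#' profile carrying its QC summary (masked fraction, MAPD, segment count).
#'
#' @param counts A `cn_counts` track.
#' @param grid The [cn_grid()].
#' @param blacklist Optional data frame of regions to mask.
#' @param gain_thr,loss_thr Calling thresholds in log2 units.
#' @param alpha,n_permutations,min_bins_per_segment,prune_tol,max_gap
#'   Segmentation controls, see [segment_cbs()].
#' @param fit GC model, see [gc_normalize()].
#' @param seed Integer seed for the permutation RNG.
#' @param verbose Emit a key=value stage log on standard error.
#' @return A `cn_profile` with attributes `track` (the masked ratio track),
#'   `mapd`, `masked_fraction` and the thresholds used.
#' @examples
#' \donttest{
#' g <- simulate_grid(1, 20e6, seed = 1)
#' tr <- simulate_truth(g, n_events = 2, seed = 1)
#' cnt <- simulate_counts(g, tr, sim_config(seed = 1))
#' p <- run_profile(cnt, g)
#' }
#' @export
run_profile <- function(counts, grid, blacklist = NULL,
                        gain_thr = 0.15, loss_thr = -0.15,
                        alpha = 0.01, n_permutations = 1000,
                        min_bins_per_segment = 3, prune_tol = 0.05,
                        max_gap = 10, fit = "poly", seed = 1,
                        verbose = FALSE) {
  track <- gc_normalize(counts, grid, fit = fit)
  track <- apply_blacklist(track, blacklist)
  segs <- segment_cbs(track, alpha = alpha, n_permutations = n_permutations,
                      min_bins_per_segment = min_bins_per_segment,
                      prune_tol = prune_tol, max_gap = max_gap, seed = seed)
  masked_fraction <- mean(track$masked)
  mapd <- if (sum(!track$masked) >= 2) compute_mapd(track)$mapd else NA_real_
  profile <- call_segments(segs, gain_thr = gain_thr, loss_thr = loss_thr,
                           sample_id = counts_sample_id(counts),
                           masked_fraction = masked_fraction, mapd = mapd)
  attr(profile, "track") <- track
  if (verbose) {
    message(sprintf(
      "stage=profile sample=%s masked_fraction=%.4f n_segments=%d mapd=%.4f",
      counts_sample_id(counts), masked_fraction, nrow(profile), mapd))
  }
  profile
}

#' @rdname tidy.cn_profile
#' @export
tidy.cn_profile <- function(x, ...) {
  tibble::tibble(
    sample_id = profile_sample_id(x),
    chrom = x$chrom, start = x$start, end = x$end,
    n_bins = x$n_bins, mean_log2 = x$mean_log2, call = x$call
  )
}

#' Tidy and summarize a copy-number profile
#'
#' `tidy()` returns one row per segment; `glance()` returns a one-row
#' summary (segment and call counts, altered fraction, MAPD, masking).
#'
#' @param x A `cn_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.cn_profile <- function(x, ...) {
  width <- x$end - x$start
  tibble::tibble(
    sample_id = profile_sample_id(x),
    n_segments = nrow(x),
    n_gain = sum(x$call == "gain"),
    n_loss = sum(x$call == "loss"),
    cna_fraction = sum(width[x$call != "neutral"]) / sum(width),
    mapd = attr(x, "mapd"),
    masked_fraction = attr(x, "masked_fraction"),
    gain_thr = attr(x, "gain_thr"),
    loss_thr = attr(x, "loss_thr")
  )
}
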
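#' Median absolute pairwise difference (MAPD)
#'
#' MAPD is the median of `|x[i+1] - x[i]|` over markers ordered by genomic
#' position. Because successive-difference noise is insensitive to broad
#' copy-number structure, MAPD measures sample noise rather than biology.
#' Markers are taken per chromosome (pairs never span a chromosome
#' boundary). Missing markers are handled per `pairing`: `"skip"` (default)
#' differences consecutive *non-missing* markers within a chromosome;
#' `"strict"` drops any pair with a missing member.
#'
#' @param track A `cn_track`, or any data frame with `chrom` and
#'   `log2_ratio` columns in genomic order (an optional `masked` column is
#'   honored).
#' @param pairing `"skip"` or `"strict"`.
#' @return A list with `mapd` and `n_markers` (non-missing markers used).
#' @examples
#' tr <- tibble::tibble(chrom = "chr1", start = 0:3, end = 1:4,
#'                      log2_ratio = c(0, 0.5, 0, 0.5), masked = FALSE)
#' compute_mapd(tr)$mapd # 0.5
#' @export
compute_mapd <- function(track, pairing = c("skip", "strict")) {
  pairing <- match.arg(pairing)
  x <- track$log2_ratio
  ok <- is.finite(x)
  if ("masked" %in% names(track)) ok <- ok & !track$masked
  if (sum(ok) < 2) {
    stop_degenerate("MAPD needs at least 2 usable markers")
  }
  diffs <- unlist(lapply(split(seq_along(x), factor(track$chrom, unique(track$chrom))),
    function(idx) {
      o <- ok[idx]
      if (pairing == "skip") {
        v <- x[idx][o]
        if (length(v) < 2) return(numeric(0))
        abs(diff(v))
      } else {
        v <- x[idx]
        keep <- o[-1] & o[-length(o)]
        abs(diff(v))[keep]
      }
    }), use.names = FALSE)
  if (length(diffs) < 1) {
    stop_degenerate("MAPD needs at least one usable adjacent pair")
  }
  list(mapd = median(diffs), n_markers = sum(ok))
}

#' Per-sample quality report
#'
#' Aggregates the noise and coverage metrics used to judge a low-coverage
#' sample: MAPD, the fraction of bins masked (with reasons available in the
#' track), the fraction of bins covered by at least one read, and the mean
#' per-bin count.
#'
#' @param counts A `cn_counts` track.
#' @param track The matching `cn_track` (same grid).
#' @param pairing MAPD pairing mode, see [compute_mapd()].
#' @return A one-row tibble: `sample_id`, `mapd`, `n_markers_used`,
#'   `masked_fraction`, `covered_bin_fraction`, `mean_count`. `mapd` is `NA`
#'   when fewer than 2 markers are usable.
#' @export
qc_report <- function(counts, track, pairing = "skip") {
  if (nrow(counts) != nrow(track) ||
      !identical(as.character(counts$chrom), as.character(track$chrom)) ||
      !identical(as.numeric(counts$start), as.numeric(track$start))) {
    stop_config("counts and track do not share a grid")
  }
  usable <- sum(!track$masked & is.finite(track$log2_ratio))
  m <- if (usable >= 2) compute_mapd(track, pairing = pairing) else NULL
  tibble::tibble(
    sample_id = counts_sample_id(counts),
    mapd = if (is.null(m)) NA_real_ else m$mapd,
    n_markers_used = if (is.null(m)) 0L else m$n_markers,
    masked_fraction = mean(track$masked),
    covered_bin_fraction = mean(counts$count >= 1),
    mean_count = mean(counts$count)
  )
}
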
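#' Plot a copy-number profile
#'
#' Genome-wide scatter of per-bin log2 ratios (when the profile carries its
#' ratio track) with segment means overlaid and gains/losses colored,
#' faceted by chromosome.
#'
#' @param object A `cn_profile` from [run_profile()] or [call_segments()].
#' @param point_alpha Point transparency for the bin scatter.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cn_profile <- function(object, point_alpha = 0.4, ...) {
  segs <- tidy(object)
  gain_thr <- attr(object, "gain_thr")
  loss_thr <- attr(object, "loss_thr")
  p <- ggplot2::ggplot()
  track <- attr(object, "track")
  if (!is.null(track)) {
    bins <- track[!track$masked & is.finite(track$log2_ratio), ]
    p <- p + ggplot2::geom_point(
      data = bins,
      ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = .data$log2_ratio),
      size = 0.3, alpha = point_alpha, color = "grey40"
    )
  }
  p +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$mean_log2, yend = .data$mean_log2,
                   color = .data$call),
      linewidth = 1.1
    ) +
    ggplot2::geom_hline(yintercept = c(loss_thr, gain_thr),
                        linetype = "dashed", color = "grey60") +
    ggplot2::scale_color_manual(
      values = c(gain = "#c0392b", loss = "#2980b9", neutral = "grey25")) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2 ratio",
                  title = profile_sample_id(object), color = "call") +
    ggplot2::theme_minimal()
}

#' Plot a correlation clustering
#'
#' Heatmap of the pairwise Pearson correlation matrix with samples ordered
#' by the dendrogram.
#'
#' @param object A `cn_cluster` from [cna_bin_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cn_cluster <- function(object, ...) {
  ord <- object$hclust$order
  cm <- object$correlation[ord, ord, drop = FALSE]
  df <- tibble::as_tibble(cm, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "correlation")
  df$sample_a <- factor(df$sample_a, levels = rownames(cm))
  df$sample_b <- factor(df$sample_b, levels = rownames(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Pearson correlation over %d CNA bins",
                                  object$n_bins)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot MAPD against the per-bin ratio track
#'
#' Convenience scatter of the absolute successive differences whose median
#' is MAPD, useful to eyeball sample noise.
#'
#' @param track A `cn_track`.
#' @return A ggplot object.
#' @export
plot_mapd_differences <- function(track) {
  keep <- !track$masked & is.finite(track$log2_ratio)
  d <- purrr::map_dfr(split(which(keep), track$chrom[keep]), function(idx) {
    v <- track$log2_ratio[idx]
    if (length(v) < 2) return(NULL)
    tibble::tibble(diff_abs = abs(diff(v)))
  })
  m <- compute_mapd(track)$mapd
  ggplot2::ggplot(d, ggplot2::aes(x = .data$diff_abs)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::geom_vline(xintercept = m, color = "#c0392b") +
    ggplot2::labs(x = "|x[i+1] - x[i]|",
                  title = sprintf("MAPD = %.3f", m)) +
    ggplot2::theme_minimal()
}
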
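#' Simulation settings for binned low-coverage counts
#'
#' @param mean_coverage Genome-wide mean fold coverage the counts should
#'   correspond to (e.g. 1.3 for the study's standard-input depth).
#' @param dispersion Negative-binomial size parameter; larger values approach
#'   Poisson counting noise, smaller values add overdispersion.
#' @param gc_bias_strength Amplitude in `[0, 1)` of a unimodal (quadratic,
#'   peaked at GC 0.5) multiplicative response of expected depth to bin GC;
#'   0 disables GC bias.
#' @param dropout_fraction Fraction of bins forced to zero count, emulating
#'   amplification-induced coverage dropout.
#' @param read_length Read length in bp used to convert fold coverage to an
#'   expected per-bin read count (`coverage * bin_size / read_length`).
#' @param seed Integer seed.
#' @return A list of validated settings with class `sim_config`.
#' @export
sim_config <- function(mean_coverage = 1.3,
                       dispersion = 50,
                       gc_bias_strength = 0.3,
                       dropout_fraction = 0,
                       read_length = 75,
                       seed = 1) {
  if (mean_coverage <= 0) stop_invalid("mean_coverage must be > 0")
  if (dispersion <= 0) stop_invalid("dispersion must be > 0")
  if (gc_bias_strength < 0 || gc_bias_strength >= 1) {
    stop_invalid("gc_bias_strength must be in [0, 1)")
  }
  if (dropout_fraction < 0 || dropout_fraction >= 1) {
    stop_invalid("dropout_fraction must be in [0, 1)")
  }
  if (read_length <= 0) stop_invalid("read_length must be > 0")
  structure(
    list(mean_coverage = mean_coverage, dispersion = dispersion,
         gc_bias_strength = gc_bias_strength,
         dropout_fraction = dropout_fraction,
         read_length = read_length, seed = seed),
    class = "sim_config"
  )
}

# unimodal quadratic GC response, normalized to mean 1 over the grid;
# strength s depresses expected depth to (1 - s) at the GC extremes
# (0.3 / 0.7) relative to the optimum at 0.5
gc_response <- function(gc, strength) {
  if (strength == 0) return(rep(1, length(gc)))
  g <- 1 - strength * ((gc - 0.5) / 0.2)^2
  g <- pmax(g, 0.05)
  g / mean(g)
}

#' Simulate binned read counts from a truth profile
#'
#' Draws per-bin counts from a negative binomial whose mean follows the
#' truth's copy-number ratio (mixed by purity against a diploid background),
#' scaled by a GC-bias response and calibrated so the genome-wide mean count
#' matches the configured fold coverage. A configured fraction of bins is
#' then zeroed out (dropout).
#'
#' @param grid A [cn_grid()].
#' @param truth A [simulate_truth()] result covering the grid.
#' @param config A [sim_config()].
#' @param sample_id Label stored with the counts.
#' @return A tibble `(chrom, start, end, count)` aligned with the grid, with
#'   class `cn_counts` and attributes `sample_id` and `grid`.
#' @export
simulate_counts <- function(grid, truth, config = sim_config(),
                            sample_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  purity <- truth_purity(truth)
  cn <- truth_to_bins(truth, grid)
  if (anyNA(cn)) stop_invalid("truth does not cover the grid")
  ratio <- (purity * cn + (1 - purity) * 2) / 2
  g <- gc_response(grid$gc, config$gc_bias_strength)
  # calibration: a diploid bin at the GC optimum receives on average
  # coverage * bin_size / read_length reads
  r <- config$mean_coverage * grid_bin_size(grid) / config$read_length
  mu <- r * ratio * g
  counts <- withr::with_seed(derive_seed(config$seed, 37L), {
    x <- rnbinom(length(mu), mu = mu, size = config$dispersion)
    if (config$dropout_fraction > 0) {
      drop <- runif(length(x)) < config$dropout_fraction
      x[drop] <- 0L
    }
    x
  })
  new_cn_counts(grid, counts, sample_id)
}

new_cn_counts <- function(grid, counts, sample_id) {
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  structure(
    tibble::tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
                   count = as.integer(counts)),
    sample_id = sample_id,
    grid = grid,
    class = c("cn_counts", class(tibble::tibble()))
  )
}

#' @export
print.cn_counts <- function(x, ...) {
  cat(sprintf("<cn_counts> sample %s: %d bins, mean count %.1f, %.1f%% zero\n",
              attr(x, "sample_id"), nrow(x), mean(x$count),
              100 * mean(x$count == 0)))
  NextMethod()
}

counts_sample_id <- function(x) attr(x, "sample_id")

#' Degrade counts with WGA-style artifacts
#'
#' Whole-genome amplification before library preparation inflates duplicate
#' reads and leaves large swaths of the genome uncovered. This operation
#' emulates both effects on an existing count track: each bin count is
#' resampled with its mean preserved but variance inflated by
#' `extra_dispersion_factor`, then `dropout_fraction` of bins is zeroed.
#'
#' @param counts A `cn_counts` track.
#' @param extra_dispersion_factor Variance inflation factor (>= 1); 1 leaves
#'   the distribution unchanged.
#' @param dropout_fraction Fraction of bins forced to zero, in `[0, 1)`;
#'   0.85 reproduces the study's "<15% of the genome covered" regime.
#' @param seed Integer seed.
#' @return A `cn_counts` track on the same grid.
#' @export
degrade_wga <- function(counts, extra_dispersion_factor = 4,
                        dropout_fraction = 0.85, seed = 1) {
  if (extra_dispersion_factor < 1) {
    stop_invalid("extra_dispersion_factor must be >= 1")
  }
  if (dropout_fraction < 0 || dropout_fraction >= 1) {
    stop_invalid("dropout_fraction must be in [0, 1)")
  }
  x <- counts$count
  out <- withr::with_seed(derive_seed(seed, 53L), {
    y <- x
    if (extra_dispersion_factor > 1) {
      pos <- x > 0
      # NB with mu = x and size = x / (f - 1) has variance f * x:
      # mean preserved, variance inflated f-fold
      y[pos] <- rnbinom(sum(pos), mu = x[pos],
                        size = x[pos] / (extra_dispersion_factor - 1))
    }
    if (dropout_fraction > 0) {
      drop <- runif(length(y)) < dropout_fraction
      y[drop] <- 0L
    }
    y
  })
  new_cn_counts(attr(counts, "grid"), out,
                paste0(counts_sample_id(counts), "-wga"))
}

#' Down-sample a count track
#'
#' Thins each bin count binomially, the count-level analogue of read-level
#' down-sampling of an alignment file: keeping each read independently with
#' probability `fraction` turns a bin's count `n` into `Binomial(n, fraction)`.
#'
#' @param counts A `cn_counts` track.
#' @param fraction Retention probability in `(0, 1]`.
#' @param seed Integer seed.
#' @return A `cn_counts` track on the same grid.
#' @export
downsample_counts <- function(counts, fraction, seed = 1) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop_invalid("fraction must be a single value in (0, 1]")
  }
  if (fraction == 1) return(counts)
  out <- withr::with_seed(derive_seed(seed, 71L), {
    rbinom(nrow(counts), size = counts$count, prob = fraction)
  })
  new_cn_counts(attr(counts, "grid"), out, counts_sample_id(counts))
}
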
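#' Construct a bin grid
#'
#' A bin grid is the fixed genomic partition every track in the pipeline is
#' aligned to: ordered fixed-width bins (0-based, half-open) tiling each
#' chromosome, each carrying its GC fraction. The terminal bin of a
#' chromosome may be shorter than `bin_size`.
#'
#' @param bins A data frame with columns `chrom`, `start`, `end`,
#'   `gc` (GC fraction in `[0, 1]`).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp,
#'   in chromosome order.
#' @param bin_size Nominal bin width in bp.
#' @return A tibble of bins with class `cn_grid` and attributes
#'   `chrom_lengths` and `bin_size`.
#' @seealso [simulate_grid()] to draw a synthetic grid.
#' @export
cn_grid <- function(bins, chrom_lengths, bin_size) {
  bins <- tibble::as_tibble(bins)
  required <- c("chrom", "start", "end", "gc")
  if (!all(required %in% names(bins))) {
    stop_invalid("grid bins need columns chrom, start, end, gc")
  }
  if (any(bins$gc < 0 | bins$gc > 1, na.rm = TRUE)) {
    stop_invalid("gc fraction must lie in [0, 1]")
  }
  if (any(bins$end <= bins$start)) {
    stop_invalid("every bin must satisfy start < end")
  }
  bins$chrom <- as.character(bins$chrom)
  # verify the tiling invariant chromosome by chromosome
  for (cc in names(chrom_lengths)) {
    b <- bins[bins$chrom == cc, ]
    if (nrow(b) == 0) stop_invalid(paste0("chromosome ", cc, " has no bins"))
    if (b$start[1] != 0 ||
        b$end[nrow(b)] != chrom_lengths[[cc]] ||
        (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)]))) {
      stop_invalid(paste0("bins do not tile chromosome ", cc,
                          " without gaps or overlaps"))
    }
  }
  structure(
    bins[, required],
    chrom_lengths = chrom_lengths,
    bin_size = bin_size,
    class = c("cn_grid", class(tibble::tibble()))
  )
}

#' @export
print.cn_grid <- function(x, ...) {
  cl <- attr(x, "chrom_lengths")
  cat(sprintf("<cn_grid> %d bins of %s bp over %d chromosome(s) (%.1f Mb)\n",
              nrow(x), format(attr(x, "bin_size"), big.mark = ","),
              length(cl), sum(cl) / 1e6))
  NextMethod()
}

grid_chrom_lengths <- function(grid) attr(grid, "chrom_lengths")
grid_bin_size <- function(grid) attr(grid, "bin_size")

# assert that a per-bin table is row-aligned with the grid
check_grid_alignment <- function(x, grid, what = "track") {
  if (nrow(x) != nrow(grid) ||
      !identical(as.character(x$chrom), as.character(grid$chrom)) ||
      !identical(as.numeric(x$start), as.numeric(grid$start))) {
    stop_config(paste0(what, " is not aligned with the supplied grid"))
  }
  invisible(TRUE)
}

#' Simulate a bin grid with autocorrelated GC content
#'
#' Draws a synthetic stand-in for a reference-genome bin grid. GC fractions
#' follow a smooth autocorrelated (AR(1)) process along each chromosome,
#' clipped to `[0.3, 0.7]` — the range that dominates real mammalian 50 kb
#' windows.
#'
#' @param n_chromosomes Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chromosome_length_bp Length of every chromosome in bp.
#' @param bin_size Bin width in bp (default 50 kb).
#' @param seed Integer seed; the same seed reproduces the same grid.
#' @return A [cn_grid()] tibble.
#' @examples
#' g <- simulate_grid(2, 10e6, seed = 1)
#' @export
simulate_grid <- function(n_chromosomes = 1,
                          chromosome_length_bp = 100e6,
                          bin_size = 50000,
                          seed = 1) {
  if (n_chromosomes < 1) stop_invalid("n_chromosomes must be >= 1")
  if (bin_size <= 0) stop_invalid("bin_size must be positive")
  if (chromosome_length_bp < bin_size) {
    stop_invalid("chromosome_length_bp must be at least bin_size")
  }
  chroms <- paste0("chr", seq_len(n_chromosomes))
  chrom_lengths <- setNames(rep(chromosome_length_bp, n_chromosomes), chroms)

  bins <- withr::with_seed(derive_seed(seed, 11L), {
    purrr::map_dfr(chroms, function(cc) {
      starts <- seq(0, chromosome_length_bp - 1, by = bin_size)
      ends <- pmin(starts + bin_size, chromosome_length_bp)
      n <- length(starts)
      # AR(1) walk around 0.5, sd chosen so the marginal spread fills the
      # clipped range without saturating it
      phi <- 0.95
      eps <- rnorm(n, 0, 0.025)
      z <- numeric(n)
      z[1] <- rnorm(1, 0, 0.08)
      for (i in seq_len(n)[-1]) z[i] <- phi * z[i - 1] + eps[i]
      tibble::tibble(
        chrom = cc, start = starts, end = ends,
        gc = pmin(0.7, pmax(0.3, 0.5 + z))
      )
    })
  })
  cn_grid(bins, chrom_lengths, bin_size)
}
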
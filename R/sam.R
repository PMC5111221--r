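# Optional SAM/BAM adapter. Counting happens at bin level throughout the
# package; this adapter exists so that coordinate-sorted alignment files can
# feed the same pipeline. Requires Rsamtools (Suggests).

#' Count reads in grid bins from a SAM/BAM file
#'
#' Assigns each mapped, filter-passing read to exactly one bin by its
#' leftmost aligned position. Reads on chromosomes absent from the grid are
#' ignored and reported in the `discarded_reads` attribute.
#'
#' @param path Coordinate-sorted SAM or BAM file whose header names the grid
#'   chromosomes.
#' @param grid A [cn_grid()].
#' @param min_mapq Minimum mapping quality; reads below (or with missing
#'   MAPQ when `min_mapq > 0`) are not counted.
#' @param exclude_duplicates Drop duplicate-flagged reads.
#' @param sample_id Label for the resulting counts.
#' @return A `cn_counts` track with attribute `discarded_reads`.
#' @export
count_reads_in_bins <- function(path, grid, min_mapq = 0,
                                exclude_duplicates = TRUE,
                                sample_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop_config("count_reads_in_bins requires the Rsamtools package")
  }
  sample_id <- sample_id %||% sub("\\.(sam|bam)$", "", basename(path))
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    check_sam_sorted(path)
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path

  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  so <- hdr$text[["@HD"]]
  if (!is.null(so) && any(grepl("^SO:", so)) &&
      !any(so == "SO:coordinate")) {
    stop_format("alignment file is not coordinate-sorted")
  }
  if (!any(names(hdr$targets) %in% unique(grid$chrom))) {
    stop_config("no chromosome overlap between alignment file and grid")
  }

  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (exclude_duplicates) FALSE else NA
  )
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("rname", "pos", "mapq"))
  reads <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(reads$pos)
  if (min_mapq > 0) {
    keep <- keep & !is.na(reads$mapq) & reads$mapq >= min_mapq
  }
  chrom <- as.character(reads$rname[keep])
  pos <- reads$pos[keep]

  on_grid <- chrom %in% unique(grid$chrom)
  discarded <- sum(!on_grid)
  chrom <- chrom[on_grid]
  pos <- pos[on_grid]

  bin_size <- grid_bin_size(grid)
  counts <- integer(nrow(grid))
  offsets <- c(0, cumsum(table(factor(grid$chrom, unique(grid$chrom)))))
  names(offsets) <- c(unique(grid$chrom), "")
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    n_bins_cc <- sum(grid$chrom == cc)
    # leftmost position is 1-based; bins are 0-based half-open
    b <- pmin(floor((pos[sel] - 1) / bin_size) + 1, n_bins_cc)
    tab <- tabulate(b, nbins = n_bins_cc)
    rows <- which(grid$chrom == cc)
    counts[rows] <- counts[rows] + tab
  }
  out <- new_cn_counts(grid, counts, sample_id)
  attr(out, "discarded_reads") <- discarded
  out
}

# a SAM text header that declares a sort order other than coordinate, or
# out-of-order positions within a chromosome, is rejected
check_sam_sorted <- function(path) {
  lines <- readLines(path)
  hd <- lines[startsWith(lines, "@HD")]
  if (length(hd) > 0 && grepl("SO:", hd[1]) &&
      !grepl("SO:coordinate", hd[1])) {
    stop_format("SAM header declares a sort order other than coordinate")
  }
  body <- lines[!startsWith(lines, "@")]
  if (length(body) > 1) {
    f <- strsplit(body, "\t")
    rname <- vapply(f, `[`, "", 3)
    pos <- as.numeric(vapply(f, `[`, "", 4))
    for (cc in unique(rname)) {
      p <- pos[rname == cc]
      if (is.unsorted(p)) {
        stop_format("SAM records are not coordinate-sorted")
      }
    }
  }
  invisible(TRUE)
}

#' Write a minimal single-end SAM fixture
#'
#' Emits a valid coordinate-sorted SAM with one mapped record per row of
#' `reads`, for exercising the alignment-file adapter.
#'
#' @param path Output path (`.sam`).
#' @param reads Data frame with `chrom`, `pos` (1-based leftmost), and
#'   optional `mapq` (default 60) and `flag` (default 0; 1024 marks a
#'   duplicate).
#' @param chrom_lengths Named vector of chromosome lengths for `@SQ` lines.
#' @param read_length Read length used for the CIGAR and SEQ fields.
#' @export
write_fixture_sam <- function(path, reads, chrom_lengths, read_length = 50) {
  reads <- tibble::as_tibble(reads)
  if (!"mapq" %in% names(reads)) reads$mapq <- 60L
  if (!"flag" %in% names(reads)) reads$flag <- 0L
  reads <- reads[order(match(reads$chrom, names(chrom_lengths)), reads$pos), ]
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            as.integer(chrom_lengths))
  )
  seq <- strrep("A", read_length)
  records <- sprintf("r%04d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                     seq_len(nrow(reads)), reads$flag, reads$chrom,
                     as.integer(reads$pos), as.integer(reads$mapq),
                     read_length, seq)
  writeLines(c(header, records), path)
  invisible(path)
}
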
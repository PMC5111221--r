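# File formats. All tabular outputs carry a provenance header of
# '#key=value' lines (tool version, config hash, seed; timestamp only on
# request so that reruns are byte-identical). All coordinates are 0-based
# half-open on disk, matching BED convention.

provenance_lines <- function(params = list(), timestamp = FALSE) {
  ver <- as.character(utils::packageVersion("shallowcn"))
  lines <- c(
    paste0("#shallowcn_version=", ver),
    if (length(params) > 0) {
      flat <- vapply(params, function(v) paste(format(v, trim = TRUE),
                                               collapse = ","), character(1))
      c(paste0("#config_hash=", rlang::hash(params)),
        paste0("#", names(flat), "=", flat))
    },
    if (timestamp) paste0("#date=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  lines
}

write_table_prov <- function(x, path, params = list(), timestamp = FALSE,
                             col_names = TRUE) {
  writeLines(provenance_lines(params, timestamp), path)
  readr::write_tsv(x, path, append = TRUE, col_names = col_names,
                   progress = FALSE)
  invisible(path)
}

read_table_prov <- function(path, col_names = TRUE, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_names = col_names,
                  col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

#' Write and read a bin grid as TSV
#'
#' Columns `chrom`, `start`, `end`, `gc`; chromosome lengths and the bin
#' size travel in the provenance header so the grid round-trips losslessly.
#'
#' @param grid A [cn_grid()].
#' @param path Output / input path.
#' @param timestamp Include a date line in the header.
#' @return `write_grid_tsv()` returns the path; `read_grid_tsv()` a
#'   [cn_grid()].
#' @export
write_grid_tsv <- function(grid, path, timestamp = FALSE) {
  cl <- grid_chrom_lengths(grid)
  params <- list(
    bin_size = grid_bin_size(grid),
    chrom_lengths = paste(names(cl), cl, sep = ":", collapse = ",")
  )
  write_table_prov(tibble::as_tibble(grid), path, params, timestamp)
}

#' @rdname write_grid_tsv
#' @export
read_grid_tsv <- function(path) {
  hdr <- parse_header(path)
  bins <- read_table_prov(path, col_types = "cddd")
  if (is.null(hdr$chrom_lengths) || is.null(hdr$bin_size)) {
    stop_format("grid file lacks chrom_lengths / bin_size header lines")
  }
  pairs <- strsplit(strsplit(hdr$chrom_lengths, ",")[[1]], ":")
  cl <- setNames(as.numeric(vapply(pairs, `[`, "", 2)),
                 vapply(pairs, `[`, "", 1))
  cn_grid(bins, cl, as.numeric(hdr$bin_size))
}

parse_header <- function(path) {
  lines <- readLines(path, n = 200)
  lines <- lines[startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^#([^=]+)=(.*)$", lines))
  kv <- kv[lengths(kv) == 3]
  out <- lapply(kv, `[`, 3)
  names(out) <- vapply(kv, `[`, "", 2)
  out
}

#' Write and read binned counts as TSV
#'
#' Four columns: `chrom`, `start`, `end`, `count`.
#'
#' @param counts A `cn_counts` track.
#' @param path Output / input path.
#' @param grid Grid the counts must align with (reader).
#' @param params Extra provenance key-value pairs.
#' @param timestamp Include a date line.
#' @export
write_counts_tsv <- function(counts, path, params = list(),
                             timestamp = FALSE) {
  params <- c(list(sample_id = counts_sample_id(counts)), params)
  write_table_prov(tibble::as_tibble(counts), path, params, timestamp)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, grid) {
  hdr <- parse_header(path)
  x <- read_table_prov(path, col_types = "cddi")
  if (!all(c("chrom", "start", "end", "count") %in% names(x))) {
    stop_format("counts file must have columns chrom, start, end, count")
  }
  check_grid_alignment(x, grid, "counts file")
  new_cn_counts(grid, x$count, hdr$sample_id %||% basename(path))
}

#' Write and read a truth profile as BED
#'
#' BED5 with the integer copy number in the score column; purity travels in
#' the header.
#'
#' @param truth A [simulate_truth()] result.
#' @param path Output / input path.
#' @param grid Grid to attach on read.
#' @param timestamp Include a date line.
#' @export
write_truth_bed <- function(truth, path, timestamp = FALSE) {
  bed <- tibble::tibble(
    chrom = truth$chrom, start = truth$start, end = truth$end,
    name = paste0("cn", truth$cn), score = truth$cn
  )
  write_table_prov(bed, path, list(purity = truth_purity(truth)),
                   timestamp, col_names = FALSE)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path, grid) {
  hdr <- parse_header(path)
  bed <- read_table_prov(path, col_names = FALSE, col_types = "cddcd")
  names(bed) <- c("chrom", "start", "end", "name", "cn")
  structure(
    tibble::tibble(chrom = bed$chrom, start = bed$start, end = bed$end,
                   cn = as.integer(bed$cn)),
    purity = as.numeric(hdr$purity %||% 1),
    grid = grid,
    class = c("cn_truth", class(tibble::tibble()))
  )
}

#' Read a 3-column BED of regions (e.g. a blacklist)
#'
#' @param path BED path; lines starting with `#` or `track` are skipped.
#' @return A tibble `(chrom, start, end)`.
#' @export
read_bed <- function(path) {
  x <- read_table_prov(path, col_names = FALSE)
  if (ncol(x) < 3) stop_format("BED needs at least 3 columns")
  x <- x[!grepl("^track", x[[1]]), 1:3]
  names(x) <- c("chrom", "start", "end")
  x$chrom <- as.character(x$chrom)
  x
}

#' Write a segmented profile in SEG format
#'
#' Standard SEG columns: sample, chrom, loc.start, loc.end, num.mark,
#' seg.mean. Calls are written separately by [write_calls_bed()].
#'
#' @param profile A `cn_profile`.
#' @param path Output path.
#' @param params Extra provenance entries.
#' @param timestamp Include a date line.
#' @export
write_seg <- function(profile, path, params = list(), timestamp = FALSE) {
  seg <- tibble::tibble(
    sample = profile_sample_id(profile),
    chrom = profile$chrom,
    loc.start = profile$start,
    loc.end = profile$end,
    num.mark = profile$n_bins,
    seg.mean = profile$mean_log2
  )
  params <- c(list(gain_thr = attr(profile, "gain_thr"),
                   loss_thr = attr(profile, "loss_thr")), params)
  write_table_prov(seg, path, params, timestamp)
}

#' @rdname write_seg
#' @param gain_thr,loss_thr Calling thresholds to re-apply when the file
#'   header does not provide them.
#' @export
read_seg <- function(path, gain_thr = NULL, loss_thr = NULL) {
  hdr <- parse_header(path)
  x <- read_table_prov(path, col_types = "ccddid")
  if (!all(c("sample", "chrom", "loc.start", "loc.end", "num.mark",
             "seg.mean") %in% names(x))) {
    stop_format("not a SEG file (expected sample/chrom/loc.start/loc.end/num.mark/seg.mean)")
  }
  gain_thr <- gain_thr %||% as.numeric(hdr$gain_thr %||% 0.15)
  loss_thr <- loss_thr %||% as.numeric(hdr$loss_thr %||% -0.15)
  segs <- tibble::tibble(
    chrom = x$chrom, start = x$`loc.start`, end = x$`loc.end`,
    n_bins = x$`num.mark`, mean_log2 = x$`seg.mean`
  )
  call_segments(segs, gain_thr = gain_thr, loss_thr = loss_thr,
                sample_id = x$sample[1])
}

#' Write gain/loss calls as BED
#'
#' One BED5 row per non-neutral segment; `name` is `gain` or `loss`, the
#' score column carries the segment mean log2 ratio.
#'
#' @param profile A `cn_profile`.
#' @param path Output path.
#' @param timestamp Include a date line.
#' @export
write_calls_bed <- function(profile, path, timestamp = FALSE) {
  cna <- profile[profile$call != "neutral", ]
  bed <- tibble::tibble(
    chrom = cna$chrom, start = cna$start, end = cna$end,
    name = cna$call, score = round(cna$mean_log2, 6)
  )
  write_table_prov(bed, path,
                   list(sample_id = profile_sample_id(profile),
                        gain_thr = attr(profile, "gain_thr"),
                        loss_thr = attr(profile, "loss_thr")),
                   timestamp, col_names = FALSE)
}

#' Write a ratio track as bedGraph
#'
#' Unmasked bins only, value = log2 ratio.
#'
#' @param track A `cn_track`.
#' @param path Output path.
#' @param timestamp Include a date line.
#' @export
write_bedgraph <- function(track, path, timestamp = FALSE) {
  keep <- !track$masked & is.finite(track$log2_ratio)
  bg <- tibble::tibble(chrom = track$chrom[keep], start = track$start[keep],
                       end = track$end[keep],
                       value = round(track$log2_ratio[keep], 6))
  write_table_prov(bg, path, list(sample_id = track_sample_id(track)),
                   timestamp, col_names = FALSE)
}

#' Write a clustering dendrogram as Newick
#'
#' @param cluster A `cn_cluster` from [cna_bin_correlation()].
#' @param path Output path.
#' @export
write_newick <- function(cluster, path) {
  ape::write.tree(cluster_phylo(cluster), file = path)
  invisible(path)
}
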
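#' Project a segmented profile onto per-bin states
#'
#' Each grid bin takes the call of the segment containing its midpoint;
#' bins whose midpoint falls outside every segment (masked gaps, blacklisted
#' or uncovered regions) are `"masked"`.
#'
#' @param profile A `cn_profile`.
#' @param grid The [cn_grid()] to project onto.
#' @return A tibble `(chrom, start, end, state)` aligned with the grid, with
#'   class `cn_states`; states are `"loss"`, `"neutral"`, `"gain"`,
#'   `"masked"`.
#' @export
profile_to_states <- function(profile, grid) {
  if (!all(unique(profile$chrom) %in% unique(grid$chrom))) {
    stop_config("profile chromosomes are absent from the grid")
  }
  state <- regions_to_bins(grid, profile, "call", default = "masked")
  structure(
    tibble::tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
                   state = state),
    sample_id = profile_sample_id(profile),
    class = c("cn_states", class(tibble::tibble()))
  )
}

#' Base-pair concordance between two state tracks
#'
#' Compares two per-bin state tracks over the bins unmasked in both samples
#' and accounts for every compared base pair exactly once:
#' concordant CNA (`shared_gain_bp`, `shared_loss_bp`, jointly
#' `shared_cna_bp`), concordant neutral (`shared_neutral_bp`), CNA private
#' to one sample with the other neutral (`a_only_bp`, `b_only_bp`), and
#' opposite calls (`conflict_bp`). `shared_fraction` is the fraction of
#' compared bp on which the two samples agree in all three states;
#' `shared_cnv_fraction` restricts to bp where at least one sample has a
#' CNA. Both are symmetric in the two inputs.
#'
#' @param a,b `cn_states` tracks on the same grid (see
#'   [profile_to_states()]).
#' @return A one-row tibble with class `cn_concordance`.
#' @export
concordance <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(as.character(a$chrom), as.character(b$chrom)) ||
      !identical(as.numeric(a$start), as.numeric(b$start))) {
    stop_config("state tracks are not on the same grid")
  }
  bp <- a$end - a$start
  cmp <- a$state != "masked" & b$state != "masked"
  sa <- a$state[cmp]
  sb <- b$state[cmp]
  w <- bp[cmp]

  total <- sum(w)
  agree <- sa == sb
  cna_a <- sa %in% c("gain", "loss")
  cna_b <- sb %in% c("gain", "loss")

  shared_gain <- sum(w[agree & sa == "gain"])
  shared_loss <- sum(w[agree & sa == "loss"])
  shared_neutral <- sum(w[agree & sa == "neutral"])
  shared_cna <- shared_gain + shared_loss
  a_only <- sum(w[cna_a & sb == "neutral"])
  b_only <- sum(w[cna_b & sa == "neutral"])
  conflict <- sum(w[cna_a & cna_b & !agree])

  tibble::new_tibble(tibble::tibble(
    sample_a = attr(a, "sample_id") %||% "a",
    sample_b = attr(b, "sample_id") %||% "b",
    total_compared_bp = total,
    concordant_bp = shared_cna + shared_neutral,
    discordant_bp = total - shared_cna - shared_neutral,
    shared_fraction = if (total > 0) (shared_cna + shared_neutral) / total else NA_real_,
    shared_gain_bp = shared_gain,
    shared_loss_bp = shared_loss,
    shared_cna_bp = shared_cna,
    shared_neutral_bp = shared_neutral,
    a_only_bp = a_only,
    b_only_bp = b_only,
    conflict_bp = conflict,
    shared_cnv_fraction = {
      denom <- shared_cna + a_only + b_only + conflict
      if (denom > 0) shared_cna / denom else NA_real_
    }
  ), class = "cn_concordance")
}

#' Shared copy-number-neutral base pairs
#'
#' The shared-neutral account: total covered base pairs minus all shared CNA
#' and all sample-only CNA base pairs.
#'
#' @param total_covered_bp Total base pairs compared.
#' @param shared_cna_bp Base pairs of CNA shared between samples.
#' @param sample_only_cna_bp Base pairs of CNA private to single samples.
#' @return The remaining (shared neutral) base pairs.
#' @export
shared_neutral_bp <- function(total_covered_bp, shared_cna_bp,
                              sample_only_cna_bp) {
  if (any(c(total_covered_bp, shared_cna_bp, sample_only_cna_bp) < 0)) {
    stop_invalid("all arguments must be non-negative")
  }
  out <- total_covered_bp - shared_cna_bp - sample_only_cna_bp
  if (out < 0) {
    stop_accounting("subtracted CNA bp exceed the total covered bp")
  }
  out
}

#' Regions shared across multiple profiles
#'
#' For each event type (gain, loss) independently, finds the maximal
#' genomic intervals labeled by the exact subset of samples carrying that
#' event there — the base-pair-resolution multi-sample overlap. Intervals
#' carried by two or more samples are `"shared"`, by exactly one
#' `"sample_only"`.
#'
#' @param profiles A list of two or more `cn_profile`s on the same grid.
#' @param grid The common [cn_grid()].
#' @return A tibble `(chrom, start, end, event, samples, n_samples,
#'   status)`; `samples` is a list-column of sample ids.
#' @export
shared_regions <- function(profiles, grid) {
  if (length(profiles) < 2) stop_invalid("need at least 2 profiles")
  ids <- vapply(profiles, profile_sample_id, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  states <- lapply(profiles, profile_to_states, grid = grid)

  purrr::map_dfr(c("gain", "loss"), function(ev) {
    carrier <- vapply(states, function(s) s$state == ev, logical(nrow(grid)))
    key <- apply(carrier, 1, function(z) paste(which(z), collapse = ","))
    runs <- collapse_runs(grid, key, value_name = "key")
    runs <- runs[runs$key != "", ]
    if (nrow(runs) == 0) return(NULL)
    members <- lapply(strsplit(runs$key, ","), function(k) ids[as.integer(k)])
    tibble::tibble(
      chrom = runs$chrom, start = runs$start, end = runs$end,
      event = ev,
      samples = members,
      n_samples = lengths(members),
      status = ifelse(lengths(members) >= 2, "shared", "sample_only")
    )
  })
}

#' Correlation clustering of bin values in CNA regions
#'
#' Extracts normalized bin values from the regions called as a gain or loss
#' in at least one of the supplied profiles, removes bins overlapping
#' `filter_regions`, computes the pairwise Pearson correlation of samples
#' over those bins (pairwise-complete for missing values), and clusters the
#' rows of the correlation matrix by Euclidean distance.
#'
#' @param tracks Named list of `cn_track`s on a common grid (names become
#'   sample labels; unnamed lists use each track's `sample_id`).
#' @param profiles List of `cn_profile`s defining the CNA regions.
#' @param grid The common [cn_grid()].
#' @param filter_regions Optional data frame of regions whose bins are
#'   excluded (blacklist surrogate).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A `cn_cluster` object: list with `correlation` (matrix),
#'   `hclust`, `n_bins` and `sample_ids`.
#' @export
cna_bin_correlation <- function(tracks, profiles, grid,
                                filter_regions = NULL,
                                linkage = "complete") {
  if (length(tracks) < 2) stop_invalid("need at least 2 samples")
  ids <- names(tracks)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- vapply(tracks, function(t) attr(t, "sample_id") %||% "", character(1))
    if (any(!nzchar(ids))) ids <- paste0("sample", seq_along(tracks))
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids)

  in_cna <- Reduce(`|`, lapply(profiles, function(p) {
    profile_to_states(p, grid)$state %in% c("gain", "loss")
  }))
  if (!is.null(filter_regions) && nrow(filter_regions) > 0) {
    in_cna <- in_cna & !bins_overlapping(grid, merge_intervals(filter_regions))
  }
  if (sum(in_cna) < 2) {
    stop_degenerate("fewer than 2 usable CNA bins for correlation")
  }
  vals <- vapply(tracks, function(t) {
    v <- t$log2_ratio
    v[t$masked] <- NA_real_
    v[in_cna]
  }, numeric(sum(in_cna)))
  colnames(vals) <- ids

  cormat <- cor(vals, use = "pairwise.complete.obs", method = "pearson")
  hc <- hclust(dist(cormat), method = linkage)
  structure(
    list(correlation = cormat, hclust = hc, n_bins = sum(in_cna),
         sample_ids = ids),
    class = "cn_cluster"
  )
}

#' @export
print.cn_cluster <- function(x, ...) {
  cat(sprintf("<cn_cluster> %d samples over %d CNA bins\n",
              length(x$sample_ids), x$n_bins))
  print(round(x$correlation, 3))
  invisible(x)
}

#' @rdname cna_bin_correlation
#' @param x A `cn_cluster`.
#' @param ... Unused.
#' @export
tidy.cn_cluster <- function(x, ...) {
  cm <- x$correlation
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  tibble::tibble(
    sample_a = rownames(cm)[ut[, 1]],
    sample_b = colnames(cm)[ut[, 2]],
    correlation = cm[ut]
  )
}

#' Dendrogram of a correlation clustering as a phylo tree
#'
#' @param x A `cn_cluster`.
#' @return An [ape::as.phylo()] tree (write with [ape::write.tree()]).
#' @export
cluster_phylo <- function(x) {
  stopifnot(inherits(x, "cn_cluster"))
  ape::as.phylo(x$hclust)
}
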
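#' Segment a profile by circular binary segmentation
#'
#' Recursive circular binary segmentation on the log2 values of usable
#' bins, one chromosome at a time. At each step the arc maximizing a
#' two-sample t-like statistic is located; the split is accepted when its
#' permutation p-value is below `alpha` *and* every resulting piece keeps
#' at least `min_bins` bins, and the algorithm recurses into the accepted
#' pieces. A chromosome with fewer than `min_bins` usable bins forms a
#' single segment (with a warning). Results are deterministic given the
#' R random seed, which drives the permutation generator.
#'
#' @param profile a `copy_profile` at stage `"smoothed"` or `"normalized"`.
#' @param alpha permutation significance level for accepting a split
#'   (default 0.05).
#' @param min_bins minimum usable bins per segment (default 5).
#' @param n_permutations permutations per split test (default 10000; the
#'   test stops early once significance is impossible).
#' @return A `segmentation`: data.frame with columns `chrom`, `first_bin`,
#'   `last_bin` (grid row indices), `n_bins` (usable bins), `median_ratio`,
#'   `median_log2`, with the sample id as an attribute.
#' @export
segment_cbs <- function(profile, alpha = 0.05, min_bins = 5,
                        n_permutations = 10000) {
  stopifnot(inherits(profile, "copy_profile"))
  if (!profile$stage %in% c("smoothed", "normalized"))
    stop("segment_cbs expects a profile at stage 'smoothed' or 'normalized'")

  grid <- profile$grid
  segs <- list()
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch & profile$mask)  # grid rows, usable only
    n <- length(idx)
    if (n == 0) next
    if (n < min_bins) {
      warning("chromosome ", ch, " has ", n, " usable bins (< ", min_bins,
              "); kept as a single segment")
      segs[[length(segs) + 1]] <- data.frame(chrom = ch, lo = 1, hi = n)
      attr(segs[[length(segs)]], "idx") <- idx
      next
    }
    y <- profile$log2[idx]
    pieces <- cbs_recurse(y, min_bins, alpha, n_permutations)
    df <- data.frame(chrom = ch, lo = pieces$lo, hi = pieces$hi)
    attr(df, "idx") <- idx
    segs[[length(segs) + 1]] <- df
  }

  out <- do.call(rbind, lapply(segs, function(df) {
    idx <- attr(df, "idx")
    data.frame(
      chrom = df$chrom,
      first_bin = idx[df$lo],
      last_bin = idx[df$hi],
      n_bins = df$hi - df$lo + 1,
      median_ratio = vapply(seq_len(nrow(df)), function(r)
        stats::median(profile$ratio[idx[df$lo[r]:df$hi[r]]]), numeric(1)),
      median_log2 = vapply(seq_len(nrow(df)), function(r)
        stats::median(profile$log2[idx[df$lo[r]:df$hi[r]]]), numeric(1)))
  }))
  rownames(out) <- NULL
  structure(out, sample_id = profile$sample_id,
            class = c("segmentation", "data.frame"))
}

# recursive CBS over y (usable-bin values of one chromosome);
# returns 1-based [lo, hi] piece bounds in y's index space
cbs_recurse <- function(y, min_bins, alpha, n_perm) {
  n <- length(y)
  res <- .cbs_split_cpp(y, as.integer(min_bins), alpha, as.integer(n_perm))
  if (!isTRUE(res$split))
    return(data.frame(lo = 1L, hi = as.integer(n)))
  i <- as.integer(res$i)  # arc covers bins i+1 .. j (1-based)
  j <- as.integer(res$j)
  bounds <- sort(unique(c(0L, i, j, as.integer(n))))
  pieces <- list()
  for (p in seq_len(length(bounds) - 1)) {
    lo <- bounds[p] + 1L
    hi <- bounds[p + 1]
    if (hi < lo) next
    sub <- cbs_recurse(y[lo:hi], min_bins, alpha, n_perm)
    sub$lo <- sub$lo + lo - 1L
    sub$hi <- sub$hi + lo - 1L
    pieces[[length(pieces) + 1]] <- sub
  }
  do.call(rbind, pieces)
}

#' @export
print.segmentation <- function(x, ...) {
  cat("segmentation:", attr(x, "sample_id"), "-", nrow(x), "segments over",
      length(unique(x$chrom)), "chromosomes\n")
  invisible(x)
}

#' Write a segmentation as a BED-like table
#'
#' Columns: chrom, start (bp), end (bp), n_bins, median_ratio, median_log2.
#'
#' @param seg a `segmentation`.
#' @param grid the `bin_grid` the segmentation indexes into.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(seg, grid, path) {
  stopifnot(inherits(seg, "segmentation"), inherits(grid, "bin_grid"))
  df <- data.frame(chrom = seg$chrom, start = grid$start[seg$first_bin],
                   end = grid$end[seg$last_bin], n_bins = seg$n_bins,
                   median_ratio = seg$median_ratio,
                   median_log2 = seg$median_log2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Replace bin values by their segment medians
#'
#' Each usable bin's ratio is replaced by the median normalized ratio of
#' its segment. The pre-replacement per-bin ratios are retained in the
#' profile (`ratio_bin`) because bin-size quality control scores per-bin,
#' not per-segment, values.
#'
#' @param profile the `copy_profile` the segmentation was derived from.
#' @param seg a `segmentation`.
#' @return A `copy_profile` at stage `"segmented"`.
#' @export
apply_segment_medians <- function(profile, seg) {
  stopifnot(inherits(profile, "copy_profile"), inherits(seg, "segmentation"))
  n <- nrow(profile$grid)
  if (any(seg$first_bin < 1) || any(seg$last_bin > n))
    stop("segment bin indices out of range for this profile")
  ratio <- rep(NA_real_, n)
  for (r in seq_len(nrow(seg))) {
    sel <- seg$first_bin[r]:seg$last_bin[r]
    sel <- sel[profile$mask[sel]]
    ratio[sel] <- seg$median_ratio[r]
  }
  copy_profile(profile$sample_id, profile$grid, stage = "segmented",
               ratio = ratio, mask = profile$mask,
               ratio_bin = profile$ratio)
}
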
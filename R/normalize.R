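#' GC-normalize bin counts
#'
#' Fits a locally weighted regression (lowess, span `gc_span`) of
#' `log2(count + 0.5)` on GC fraction over usable bins, subtracts the fit,
#' and re-centres the result so the genome median ratio equals 1. The
#' pseudocount keeps zero-count bins defined; bins with zero counts at
#' extreme GC (outside `[gc_min, gc_max]`) are additionally masked, since
#' their dropout is amplification failure rather than copy-number signal.
#'
#' @param counts a `bin_counts` object.
#' @param gc_span lowess span for the GC fit (default 0.3).
#' @param gc_min,gc_max GC window outside which zero-count bins are masked
#'   (defaults 0.28 and 0.68).
#' @param min_usable_bins minimum usable bins with positive counts required
#'   to attempt the fit (default 100).
#' @return A `copy_profile` at stage `"normalized"`: per-bin `ratio`
#'   (genome median 1 over usable bins), `log2` values, and a `mask` of
#'   usable bins.
#' @export
gc_normalize <- function(counts, gc_span = 0.3, gc_min = 0.28, gc_max = 0.68,
                         min_usable_bins = 100) {
  stopifnot(inherits(counts, "bin_counts"))
  grid <- counts$grid
  x <- counts$counts

  mask <- !grid$excluded
  mask <- mask & !(x == 0 & (grid$gc < gc_min | grid$gc > gc_max))
  n_pos <- sum(mask & x > 0)
  if (n_pos < min_usable_bins)
    stop("insufficient data for GC normalization: ", n_pos,
         " usable bins with positive counts (need >= ", min_usable_bins, ")")
  if (anyNA(grid$gc[mask]))
    stop("GC values missing on usable bins")

  l2 <- log2(x + 0.5)
  fit <- stats::lowess(grid$gc[mask], l2[mask], f = gc_span)
  # lowess returns sorted x; interpolate back onto the bins
  pred <- stats::approx(fit$x, fit$y, xout = grid$gc[mask], rule = 2,
                        ties = mean)$y
  resid <- l2[mask] - pred
  ratio <- rep(NA_real_, length(x))
  ratio[mask] <- 2^resid
  med <- stats::median(ratio[mask])
  if (!is.finite(med) || med <= 0) stop("degenerate profile: median ratio <= 0")
  ratio <- ratio / med

  copy_profile(counts$sample_id, grid, stage = "normalized",
               ratio = ratio, mask = mask)
}

# internal constructor for per-bin profiles moving through the pipeline
copy_profile <- function(sample_id, grid, stage, ratio, mask,
                         ratio_bin = NULL) {
  stopifnot(stage %in% c("raw", "normalized", "smoothed", "segmented", "scaled"),
            length(ratio) == nrow(grid), length(mask) == nrow(grid))
  structure(list(sample_id = sample_id, grid = grid, stage = stage,
                 ratio = ratio, log2 = log2(ratio), mask = mask,
                 ratio_bin = ratio_bin),
            class = "copy_profile")
}

#' @export
print.copy_profile <- function(x, ...) {
  cat("copy_profile:", x$sample_id, "stage", x$stage, "-", sum(x$mask),
      "usable bins, median ratio",
      sprintf("%.3f", stats::median(x$ratio[x$mask])), "\n")
  invisible(x)
}

#' Winsorize isolated single-bin outliers
#'
#' Shrinks isolated outliers towards the running median of their window:
#' a usable bin whose log2 value deviates from the windowed running median
#' by more than `trim_sd` robust (MAD-based) standard deviations is pulled
#' to that median +/- `trim_sd * sd`, but only when both its usable
#' neighbours sit within the threshold — so genuine runs of two or more
#' deviating bins (real CNVs) are never eroded. The operation is idempotent:
#' a winsorized bin lands exactly on the threshold and is not moved again.
#'
#' @param profile a `copy_profile` at stage `"normalized"`.
#' @param trim_sd deviation threshold in robust standard deviations
#'   (default 3).
#' @param smoothing_window running-median window in bins (default 10; even
#'   values are rounded up to the next odd value as medians need a centre).
#' @return A `copy_profile` at stage `"smoothed"`.
#' @export
smooth_outliers <- function(profile, trim_sd = 3, smoothing_window = 10) {
  stopifnot(inherits(profile, "copy_profile"))
  if (profile$stage != "normalized")
    stop("smooth_outliers expects a profile at stage 'normalized', got '",
         profile$stage, "'")
  k <- as.integer(smoothing_window)
  if (k %% 2 == 0) k <- k + 1L

  l2 <- profile$log2
  grid <- profile$grid
  out <- l2
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch & profile$mask)
    n <- length(idx)
    if (n < 3) next
    y <- l2[idx]
    rm <- stats::runmed(y, k = min(k, n - (1 - n %% 2)), endrule = "median")
    dev <- y - rm
    sd_rob <- stats::mad(dev)
    if (!is.finite(sd_rob) || sd_rob == 0) next
    thr <- trim_sd * sd_rob
    is_out <- abs(dev) > thr
    nb_ok <- c(TRUE, !is_out[-n]) & c(!is_out[-1], TRUE)  # both neighbours in
    fix <- is_out & nb_ok
    out[idx[fix]] <- rm[fix] + sign(dev[fix]) * thr
  }
  ratio <- 2^out
  ratio[!profile$mask] <- NA_real_
  copy_profile(profile$sample_id, grid, stage = "smoothed",
               ratio = ratio, mask = profile$mask)
}
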
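#' Fit absolute copy-number scaling by sum-of-squares minimization
#'
#' Scans a grid of candidate scaling factors s (copies per unit
#' median-normalized ratio) and, for each, measures the segment-weighted
#' sum-of-squares distance between the implied raw copy numbers and their
#' nearest integers:
#'
#'   SSE(s) = sum over segments of n_bins * (s * median_ratio -
#'            round(s * median_ratio))^2
#'
#' The returned s minimizes SSE over the grid; ties are broken by the
#' candidate closest to 2 (diploid-modal assumption), then by the smaller
#' s. Copy numbers are deliberately *not* rounded afterwards: per-bin and
#' per-segment copies remain continuous, which is what lets a mosaic bulk
#' sample land at a non-integer copy number.
#'
#' @param profile a `copy_profile` at stage `"segmented"`.
#' @param seg the `segmentation` the profile was derived from.
#' @param search numeric length-2 interval of candidate scalings
#'   (default `c(1.5, 3)`, excluding degenerate near-zero solutions).
#' @param step grid step (default 0.001).
#' @return A `scaled_profile`: the input plus `scaling_factor`,
#'   `copy_seg` (per-bin copy from segment medians), `copy_bin` (per-bin
#'   copy from pre-replacement bin ratios), per-segment copies in
#'   `segments$copy`, and the diagnostic `sse_curve`.
#' @export
fit_copy_scaling <- function(profile, seg, search = c(1.5, 3), step = 0.001) {
  stopifnot(inherits(profile, "copy_profile"), inherits(seg, "segmentation"))
  if (profile$stage != "segmented")
    stop("fit_copy_scaling expects a profile at stage 'segmented'")
  if (nrow(seg) < 1) stop("empty segmentation")
  if (!any(profile$mask)) stop("empty profile: no usable bins")

  s_grid <- seq(search[1], search[2], by = step)
  m <- outer(seg$median_ratio, s_grid)        # segments x candidates
  err <- (m - round(m))^2
  sse <- as.numeric(crossprod(seg$n_bins, err))
  best <- which(sse <= min(sse) + 1e-15)
  if (length(best) > 1) {
    d2 <- abs(s_grid[best] - 2)
    best <- best[d2 == min(d2)]
    best <- best[1]                            # smaller s on residual tie
  }
  s <- s_grid[best]

  segments <- seg
  segments$copy <- s * seg$median_ratio
  structure(list(sample_id = profile$sample_id, grid = profile$grid,
                 mask = profile$mask,
                 scaling_factor = s,
                 copy_seg = s * profile$ratio,
                 copy_bin = if (!is.null(profile$ratio_bin))
                   s * profile$ratio_bin else s * profile$ratio,
                 segments = segments,
                 sse_curve = data.frame(scaling = s_grid, sse = sse),
                 sse_min = min(sse)),
            class = "scaled_profile")
}

#' @export
print.scaled_profile <- function(x, ...) {
  cat("scaled_profile:", x$sample_id, "- scaling",
      sprintf("%.3f", x$scaling_factor), "copies/ratio, SSE",
      sprintf("%.4g", x$sse_min), "\n")
  invisible(x)
}

#' Expected baseline copy number per chromosome
#'
#' Autosomes are diploid; for an XY genome both sex chromosomes are
#' haploid; for an XX genome chrX is diploid and chrY is masked (`NA`),
#' meaning no calls are ever emitted on it.
#'
#' @param genome a `genome_build`.
#' @param sex `"XY"` or `"XX"`.
#' @return Named numeric vector of baseline copies, `NA` for masked
#'   chromosomes.
#' @export
expected_copy <- function(genome, sex = c("XY", "XX")) {
  stopifnot(inherits(genome, "genome_build"))
  if (!is.character(sex) || !sex[1] %in% c("XY", "XX"))
    stop("unknown sex label: ", sex[1], " (expected 'XY' or 'XX')")
  sex <- sex[1]
  chrom <- genome$chromosomes$chrom
  base <- rep(2, length(chrom))
  names(base) <- chrom
  is_x <- grepl("^(chr)?X$", chrom)
  is_y <- grepl("^(chr)?Y$", chrom)
  if (sex == "XY") {
    base[is_x] <- 1
    base[is_y] <- 1
  } else {
    base[is_x] <- 2
    base[is_y] <- NA_real_
  }
  base
}

#' Write a scaled profile as a per-bin table
#'
#' Columns: chrom, start, end, ratio, copy (continuous, segment-based).
#'
#' @param scaled a `scaled_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scaled_profile <- function(scaled, path) {
  stopifnot(inherits(scaled, "scaled_profile"))
  df <- data.frame(chrom = scaled$grid$chrom, start = scaled$grid$start,
                   end = scaled$grid$end,
                   ratio = scaled$copy_seg / scaled$scaling_factor,
                   copy = scaled$copy_seg)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
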
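#' Integer-clustering fraction of a scaled profile
#'
#' The fraction of usable bins whose continuous per-bin copy value lies
#' within +/- `window` of an integer copy in `integers` (default 1, 2, 3;
#' the window is closed). Per-bin, pre-segment-median copy values are
#' scored: segment medians would cluster trivially and defeat the metric's
#' purpose as a noise gauge.
#'
#' @param scaled a `scaled_profile`.
#' @param window half-width of the clustering window (default 0.25).
#' @param integers integer copies that count as clustered (default 1:3).
#' @return Fraction in `[0, 1]`.
#' @export
clustering_fraction <- function(scaled, window = 0.25, integers = 1:3) {
  stopifnot(inherits(scaled, "scaled_profile"))
  copies <- scaled$copy_bin[scaled$mask]
  copies <- copies[is.finite(copies)]
  if (!length(copies)) stop("no usable bins to score")
  hit <- vapply(copies, function(ci) any(abs(ci - integers) <= window),
                logical(1))
  mean(hit)
}

#' Select the analysis bin size from clustering fractions
#'
#' The smallest bin size whose clustering fraction strictly exceeds its
#' threshold is chosen; if none passes, the sample fails quality control.
#' The default thresholds are >0.80 at 0.5 Mb, >0.62 at 1 Mb and >0.58 at
#' 2.5 Mb: smaller bins give finer breakpoint resolution but demand tighter
#' integer clustering.
#'
#' @param fractions named numeric vector of clustering fractions; names are
#'   bin sizes in Mb (e.g. `c("0.5" = 0.85, "1" = 0.9, "2.5" = 0.92)`).
#' @param thresholds named numeric vector of thresholds for the same bin
#'   sizes.
#' @return A list with `chosen` (bin size in Mb, or `NA` on failure),
#'   `pass` (named logical per bin size), `fractions` and `thresholds`.
#' @export
select_bin_size <- function(fractions,
                            thresholds = c("0.5" = 0.80, "1" = 0.62,
                                           "2.5" = 0.58)) {
  need <- names(thresholds)
  if (!all(need %in% names(fractions)))
    stop("missing clustering fraction for bin size(s): ",
         paste(setdiff(need, names(fractions)), collapse = ", "))
  sizes <- as.numeric(need)
  ord <- order(sizes)
  pass <- fractions[need] > thresholds[need]      # strictly greater
  chosen <- NA_real_
  for (k in ord) if (pass[k]) { chosen <- sizes[k]; break }
  list(chosen = chosen, pass = pass,
       fractions = fractions[need], thresholds = thresholds)
}
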
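#' Call CNVs from a scaled profile
#'
#' Scans each chromosome's segment-median copy values for maximal runs of
#' consecutive usable bins deviating from the chromosome baseline by at
#' least the calling threshold, and emits a call when the run satisfies
#' both minima: at least `min_bins_run` usable bins *and* a genomic span of
#' at least the minimum size. Thresholds are deviations from the baseline
#' (so a haploid male X can lose a copy), and depend on bin size:
#' gains need +0.65 at 0.5/1 Mb bins and +0.55 at 2.5 Mb bins; losses need
#' -0.65 at all bin sizes. Minimum size is 8 Mb at 0.5/1 Mb bins and 20 Mb
#' at 2.5 Mb bins. Masked bins inside a run neither break consecutiveness
#' nor count toward the bin minimum.
#'
#' @param scaled a `scaled_profile`.
#' @param baseline named per-chromosome expected copy (see
#'   [expected_copy()]); `NA` masks a chromosome from calling.
#' @param params calling parameters, see [calling_params()].
#' @return A data.frame of calls: `cell`, `chrom`, `start`, `end` (bp),
#'   `size_mb`, `direction`, `cnv_class`, `start_terminal`, `end_terminal`,
#'   `mean_copy`, `n_bins`. Classification columns are filled by
#'   [classify_call()], which this function applies.
#' @export
call_cnvs <- function(scaled, baseline, params = calling_params(attr(scaled$grid, "bin_size"))) {
  stopifnot(inherits(scaled, "scaled_profile"))
  grid <- scaled$grid
  calls <- list()
  for (ch in unique(grid$chrom)) {
    base <- baseline[ch]
    if (is.null(base) || is.na(base)) next
    idx <- which(grid$chrom == ch & scaled$mask)
    if (!length(idx)) next
    copies <- scaled$copy_seg[idx]
    for (dir in c("gain", "loss")) {
      qual <- if (dir == "gain") copies >= base + params$gain_threshold
              else copies <= base - params$loss_threshold
      qual[is.na(qual)] <- FALSE
      r <- rle(qual)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        run <- idx[starts[k]:ends[k]]
        n_run <- length(run)
        span <- grid$end[run[n_run]] - grid$start[run[1]]
        if (n_run >= params$min_bins_run && span >= params$min_size) {
          calls[[length(calls) + 1]] <- data.frame(
            cell = scaled$sample_id, chrom = ch,
            start = grid$start[run[1]], end = grid$end[run[n_run]],
            size_mb = span / 1e6, direction = dir,
            mean_copy = mean(copies[starts[k]:ends[k]]),
            n_bins = n_run, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  classify_call(out, scaled)
}

#' Calling parameters for a bin size
#'
#' @param bin_size bin width in bp (0.5e6, 1e6 or 2.5e6).
#' @return List with `gain_threshold`, `loss_threshold`, `min_bins_run`,
#'   `min_size` (bp).
#' @export
calling_params <- function(bin_size) {
  key <- as.character(bin_size / 1e6)
  if (!key %in% c("0.5", "1", "2.5"))
    stop("no calling parameters configured for bin size ", bin_size, " bp")
  list(gain_threshold = if (key == "2.5") 0.55 else 0.65,
       loss_threshold = 0.65,
       min_bins_run = 8L,
       min_size = if (key == "2.5") 20e6 else 8e6)
}

empty_calls <- function() {
  data.frame(cell = character(), chrom = character(), start = numeric(),
             end = numeric(), size_mb = numeric(), direction = character(),
             mean_copy = numeric(), n_bins = integer(),
             cnv_class = character(), start_terminal = logical(),
             end_terminal = logical(), stringsAsFactors = FALSE)
}

#' Classify calls as segmental or whole-chromosome and flag terminal ends
#'
#' A call is `whole_chromosome` when it covers at least `whole_fraction`
#' (default 95%) of its chromosome's usable bins — centromeric and excluded
#' gaps prevent literal full coverage. An endpoint is terminal when it
#' coincides with the first (or last) usable bin edge of the chromosome.
#' In reports, whole-chromosome gains read as trisomies and losses as
#' monosomies.
#'
#' @param calls a calls data.frame (see [call_cnvs()]).
#' @param scaled the `scaled_profile` the calls came from (supplies the
#'   grid and mask).
#' @param whole_fraction usable-bin coverage above which a call is
#'   whole-chromosome (default 0.95).
#' @return The calls with `cnv_class`, `start_terminal`, `end_terminal`
#'   filled.
#' @export
classify_call <- function(calls, scaled, whole_fraction = 0.95) {
  if (!nrow(calls)) return(empty_calls())
  grid <- scaled$grid
  calls$cnv_class <- NA_character_
  calls$start_terminal <- NA
  calls$end_terminal <- NA
  for (r in seq_len(nrow(calls))) {
    ch <- calls$chrom[r]
    idx <- which(grid$chrom == ch & scaled$mask)
    in_call <- grid$start[idx] >= calls$start[r] & grid$end[idx] <= calls$end[r]
    calls$cnv_class[r] <- if (sum(in_call) >= whole_fraction * length(idx))
      "whole_chromosome" else "segmental"
    calls$start_terminal[r] <- calls$start[r] <= grid$start[idx[1]]
    calls$end_terminal[r] <- calls$end[r] >= grid$end[idx[length(idx)]]
  }
  calls
}

#' Match calls against an expected karyotype
#'
#' Splits calls into those matching an expected interval (same chromosome,
#' same direction, reciprocal overlap at least `reciprocal_overlap`) and
#' the remaining "additional" CNVs — the aberrations a cell carries beyond
#' the karyotype the culture is known for.
#'
#' @param calls calls data.frame.
#' @param expected expected karyotype: data.frame with `chrom`, `start`,
#'   `end` (bp), `direction`.
#' @param reciprocal_overlap minimum reciprocal overlap fraction
#'   (default 0.5).
#' @return List with elements `matched` and `additional` (both calls
#'   data.frames).
#' @export
subtract_expected <- function(calls, expected, reciprocal_overlap = 0.5) {
  if (!nrow(calls))
    return(list(matched = calls, additional = calls))
  is_match <- vapply(seq_len(nrow(calls)), function(r) {
    any(vapply(seq_len(nrow(expected)), function(e) {
      if (calls$chrom[r] != expected$chrom[e] ||
          calls$direction[r] != expected$direction[e]) return(FALSE)
      ov <- min(calls$end[r], expected$end[e]) -
        max(calls$start[r], expected$start[e])
      if (ov <= 0) return(FALSE)
      ov / (calls$end[r] - calls$start[r]) >= reciprocal_overlap &&
        ov / (expected$end[e] - expected$start[e]) >= reciprocal_overlap
    }, logical(1)))
  }, logical(1))
  list(matched = calls[is_match, , drop = FALSE],
       additional = calls[!is_match, , drop = FALSE])
}

#' Expected karyotype of an isochromosome-20 line
#'
#' An isochromosome 20q manifests as a one-copy loss of the whole p-arm
#' and a reciprocal one-copy gain of the whole q-arm. Arm boundaries are
#' taken at the centromere midpoint of the supplied genome.
#'
#' @param genome a `genome_build`.
#' @param chrom chromosome name (default `"chr20"`).
#' @return Expected-karyotype data.frame usable with
#'   [subtract_expected()] and [mosaicism_fraction()].
#' @export
iso20_karyotype <- function(genome, chrom = "chr20") {
  stopifnot(inherits(genome, "genome_build"))
  k <- match(chrom, genome$chromosomes$chrom)
  if (is.na(k)) stop("chromosome ", chrom, " not in genome build")
  cen <- genome$chromosomes$centromere_mid[k]
  len <- genome$chromosomes$length[k]
  data.frame(chrom = chrom, start = c(0, cen), end = c(cen, len),
             direction = c("loss", "gain"), stringsAsFactors = FALSE)
}

#' Write calls as a per-cell report table
#'
#' Uses the package's canonical CNV-table layout (positions in Mb with one
#' decimal, per-end terminal flags), so the output is re-readable with
#' [read_cnv_table()]; `mean_copy` and `n_bins` ride along as extra
#' columns.
#'
#' @param calls calls data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  df <- data.frame(cell = calls$cell, chrom = calls$chrom,
                   start_mb = round(calls$start / 1e6, 1),
                   end_mb = round(calls$end / 1e6, 1),
                   size_mb = calls$size_mb, direction = calls$direction,
                   cnv_class = calls$cnv_class,
                   start_terminal = calls$start_terminal,
                   end_terminal = calls$end_terminal,
                   mean_copy = calls$mean_copy, n_bins = calls$n_bins)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
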
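#' Score pipeline recovery against a simulated truth set
#'
#' For every additional CNV injected by the simulator into a cell that
#' passed quality control, checks whether the pipeline emitted a call of
#' the same chromosome and direction whose breakpoints land within
#' `tol_bins` bins of the injected interval. Injected intervals are first
#' clipped to the usable bins of the cell's chosen grid — the pipeline
#' cannot resolve breakpoints inside excluded regions, so the comparison
#' is made at the resolution the data supports.
#'
#' @param truth a `truth_set` from [simulate_population()].
#' @param cohort a `cohort_result` from [run_cohort()] over that truth.
#' @param grids the named grid list the cohort was run with.
#' @param min_span only score injected CNVs at least this wide (bp,
#'   default 12 Mb).
#' @param tol_bins breakpoint tolerance in bins of the chosen bin size
#'   (default 2).
#' @return A list with `events` (one row per scored injected CNV: cell,
#'   chrom, direction, span_mb, detected, bp_err_bins) and `recall`.
#' @export
evaluate_recovery <- function(truth, cohort, grids, min_span = 12e6,
                              tol_bins = 2) {
  baseline <- expected_copy(truth$config$genome, truth$config$sex)
  rows <- list()
  for (sp in truth$specs) {
    res <- cohort$cells[[sp$cell_id]]
    if (is.null(res) || res$status != "pass") next
    ex <- sp$extra_cnvs
    if (is.null(ex) || !nrow(ex)) next
    grid <- grids[[as.character(res$chosen_bin_mb)]]
    bs <- attr(grid, "bin_size")
    mid <- (grid$start + grid$end) / 2
    for (k in seq_len(nrow(ex))) {
      if (ex$end[k] - ex$start[k] < min_span) next
      dir <- if (ex$copy[k] > baseline[[ex$chrom[k]]]) "gain" else "loss"
      sel <- grid$chrom == ex$chrom[k] & !grid$excluded &
        mid >= ex$start[k] & mid < ex$end[k]
      if (!any(sel)) next
      exp_start <- min(grid$start[sel])
      exp_end <- max(grid$end[sel])
      cand <- res$calls[res$calls$chrom == ex$chrom[k] &
                          res$calls$direction == dir, , drop = FALSE]
      err <- Inf
      if (nrow(cand))
        err <- min(pmax(abs(cand$start - exp_start),
                        abs(cand$end - exp_end))) / bs
      rows[[length(rows) + 1]] <- data.frame(
        cell = sp$cell_id, chrom = ex$chrom[k], direction = dir,
        span_mb = (ex$end[k] - ex$start[k]) / 1e6,
        detected = is.finite(err) && err <= tol_bins,
        bp_err_bins = ifelse(is.finite(err), err, NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = character(), chrom = character(),
               direction = character(), span_mb = numeric(),
               detected = logical(), bp_err_bins = numeric())
  list(events = events,
       recall = if (nrow(events)) mean(events$detected) else NA_real_)
}
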
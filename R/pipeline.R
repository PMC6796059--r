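#' Pipeline configuration
#'
#' Collects every tunable parameter of the per-cell pipeline and cohort
#' aggregation in one resolved list, serializable alongside outputs so a
#' run can be reproduced exactly.
#'
#' @param genome a `genome_build`.
#' @param bin_sizes bin sizes to run, bp (all three are always scored for
#'   quality control).
#' @param alpha,min_bins,n_permutations segmentation parameters
#'   (see [segment_cbs()]).
#' @param gc_span lowess span of the GC fit.
#' @param smoothing_window,trim_sd outlier smoothing parameters.
#' @param qc_thresholds named clustering-fraction thresholds per bin size
#'   (Mb).
#' @param qc_window integer-clustering window (default 0.25).
#' @param scaling_search,scaling_step copy-scaling grid.
#' @param sex `"XY"` or `"XX"`.
#' @param expected expected-karyotype data.frame, or `NULL`.
#' @param fragile_sites `fragile_sites` catalogue, or `NULL`.
#' @param proximity fragile-site proximity radius, bp.
#' @param reciprocal_overlap matching threshold for expected-karyotype
#'   subtraction and recurrence grouping.
#' @param seed integer seed for the permutation generator.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome = grch38_genome(),
                            bin_sizes = c(0.5e6, 1e6, 2.5e6),
                            alpha = 0.05, min_bins = 5,
                            n_permutations = 10000,
                            gc_span = 0.3,
                            smoothing_window = 10, trim_sd = 3,
                            qc_thresholds = c("0.5" = 0.80, "1" = 0.62,
                                              "2.5" = 0.58),
                            qc_window = 0.25,
                            scaling_search = c(1.5, 3),
                            scaling_step = 0.001,
                            sex = "XY",
                            expected = NULL,
                            fragile_sites = NULL,
                            proximity = 2.5e6,
                            reciprocal_overlap = 0.5,
                            seed = 1L) {
  structure(list(genome = genome, bin_sizes = bin_sizes, alpha = alpha,
                 min_bins = min_bins, n_permutations = n_permutations,
                 gc_span = gc_span, smoothing_window = smoothing_window,
                 trim_sd = trim_sd, qc_thresholds = qc_thresholds,
                 qc_window = qc_window, scaling_search = scaling_search,
                 scaling_step = scaling_step, sex = sex, expected = expected,
                 fragile_sites = fragile_sites, proximity = proximity,
                 reciprocal_overlap = reciprocal_overlap,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# normalize -> smooth -> segment -> segment medians -> scale, one bin size
process_counts <- function(counts, config) {
  prof <- gc_normalize(counts, gc_span = config$gc_span)
  prof <- smooth_outliers(prof, trim_sd = config$trim_sd,
                          smoothing_window = config$smoothing_window)
  seg <- segment_cbs(prof, alpha = config$alpha, min_bins = config$min_bins,
                     n_permutations = config$n_permutations)
  prof <- apply_segment_medians(prof, seg)
  fit_copy_scaling(prof, seg, search = config$scaling_search,
                   step = config$scaling_step)
}

#' Run the per-cell pipeline
#'
#' Executes GC normalization, outlier smoothing, circular binary
#' segmentation, segment-median replacement and copy scaling at every
#' configured bin size; scores integer clustering at each; selects the
#' smallest admissible bin size (or fails the cell); and, for passing
#' cells, calls CNVs on the chosen bin size only, classifies them,
#' separates expected from additional aberrations, and annotates
#' breakpoints against the fragile-site catalogue.
#'
#' @param counts_by_size named list of `bin_counts`, one per bin size, with
#'   names in Mb (`"0.5"`, `"1"`, `"2.5"`). Supply the finest-grid counts
#'   and the coarser grids to [cell_input()] to build this.
#' @param config a `pipeline_config`.
#' @return A `cell_result` list: `cell`, `status` (`"pass"`, `"FAIL"` or
#'   `"error"`), `qc`, `chosen_bin_mb`, `scaled` (chosen bin size),
#'   `calls`, `matched`, `additional`, `annotations`, `reason` on error.
#' @export
run_cell <- function(counts_by_size, config = pipeline_config()) {
  cell <- counts_by_size[[1]]$sample_id
  result <- list(cell = cell, status = "error", qc = NULL,
                 chosen_bin_mb = NA_real_, scaled = NULL,
                 calls = empty_calls(), matched = empty_calls(),
                 additional = empty_calls(), annotations = NULL,
                 reason = NA_character_)
  tryCatch({
    scaled_by_size <- lapply(counts_by_size, process_counts, config = config)
    fractions <- vapply(scaled_by_size, clustering_fraction,
                        numeric(1), window = config$qc_window)
    qc <- select_bin_size(fractions, thresholds = config$qc_thresholds)
    result$qc <- qc
    if (is.na(qc$chosen)) {
      result$status <- "FAIL"
      return(result)
    }
    key <- as.character(qc$chosen)
    result$chosen_bin_mb <- qc$chosen
    scaled <- scaled_by_size[[key]]
    result$scaled <- scaled
    baseline <- expected_copy(config$genome, config$sex)
    calls <- call_cnvs(scaled, baseline,
                       params = calling_params(qc$chosen * 1e6))
    result$calls <- calls
    if (!is.null(config$expected)) {
      sp <- subtract_expected(calls, config$expected,
                              config$reciprocal_overlap)
      result$matched <- sp$matched
      result$additional <- sp$additional
    } else {
      result$additional <- calls
    }
    if (!is.null(config$fragile_sites))
      result$annotations <- annotate_breakpoints(calls, config$fragile_sites,
                                                 config$proximity)
    result$status <- "pass"
    result
  }, error = function(e) {
    result$reason <- conditionMessage(e)
    result
  })
}

#' Build per-bin-size inputs for one cell from finest-grid counts
#'
#' @param counts `bin_counts` on the finest grid.
#' @param grids named list of `bin_grid`s per bin size (names in Mb).
#' @return Named list of `bin_counts` suitable for [run_cell()].
#' @export
cell_input <- function(counts, grids) {
  out <- lapply(names(grids), function(key) {
    if (identical(attr(grids[[key]], "bin_size"),
                  attr(counts$grid, "bin_size"))) counts
    else aggregate_counts(counts, grids[[key]])
  })
  names(out) <- names(grids)
  out
}

#' Bin grids for the configured bin sizes
#'
#' @param config a `pipeline_config`.
#' @param gc_source GC source for [make_bin_grid()].
#' @return Named list of `bin_grid`s (names in Mb).
#' @export
pipeline_grids <- function(config, gc_source = synthetic_gc) {
  grids <- lapply(config$bin_sizes, function(bs)
    make_bin_grid(config$genome, bs, gc_source = gc_source))
  names(grids) <- as.character(config$bin_sizes / 1e6)
  grids
}

#' Run the cohort pipeline
#'
#' Runs [run_cell()] on every cell, then aggregates: cohort tabulation of
#' additional CNVs, carrier fraction of the expected karyotype, recurrence
#' scan, and (when an output directory is given) per-cell and cohort
#' report files. The analysed-cell denominator is the set of cells passing
#' quality control, not the set of cells sequenced; attrition counts are
#' logged per stage.
#'
#' @param cells list of per-cell inputs (each a named list of `bin_counts`
#'   as for [run_cell()]).
#' @param config a `pipeline_config`.
#' @param out_dir optional output directory for report files.
#' @return A `cohort_result` list: `cells` (per-cell results), `analysed`,
#'   `failed`, `calls`, `additional`, `summary` (tabulation), `mosaicism`
#'   (when an expected karyotype is configured), `recurrent`,
#'   `annotations`.
#' @export
run_cohort <- function(cells, config = pipeline_config(), out_dir = NULL) {
  if (!length(cells)) stop("empty cohort")
  set.seed(config$seed)
  results <- lapply(cells, run_cell, config = config)
  names(results) <- vapply(results, `[[`, character(1), "cell")

  status <- vapply(results, `[[`, character(1), "status")
  analysed <- names(results)[status == "pass"]
  message(sprintf("cohort: %d cells in, %d analysed, %d failed QC, %d errored",
                  length(results), length(analysed), sum(status == "FAIL"),
                  sum(status == "error")))

  bindr <- function(field) {
    tabs <- lapply(results[analysed], `[[`, field)
    tabs <- tabs[!vapply(tabs, is.null, logical(1))]
    if (!length(tabs)) return(empty_calls())
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    out
  }
  calls <- bindr("calls")
  additional <- bindr("additional")

  mosaic <- NULL
  if (!is.null(config$expected) && length(analysed))
    mosaic <- mosaicism_fraction(calls, analysed, config$expected,
                                 config$reciprocal_overlap)
  summary <- tabulate_cohort(additional, cells = analysed)
  recurrent <- recurrence_scan(additional, config$reciprocal_overlap)
  annotations <- do.call(rbind, c(lapply(results[analysed], `[[`,
                                         "annotations"),
                                  list(make.row.names = FALSE)))

  out <- structure(list(cells = results, analysed = analysed,
                        failed = names(results)[status != "pass"],
                        calls = calls, additional = additional,
                        summary = summary, mosaicism = mosaic,
                        recurrent = recurrent, annotations = annotations,
                        config = config),
                   class = "cohort_result")
  if (!is.null(out_dir)) write_cohort_report(out, out_dir)
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("cohort_result:", length(x$cells), "cells,", length(x$analysed),
      "analysed;", x$summary$n_cnvs, "additional CNVs in",
      x$summary$n_cells_with_cnv, "cells\n")
  if (!is.null(x$mosaicism))
    cat(sprintf("  carrier fraction: %d/%d (%.0f%%)\n",
                x$mosaicism$n_carriers, x$mosaicism$n_cells,
                100 * x$mosaicism$fraction))
  invisible(x)
}

#' Write cohort report files
#'
#' Per-cell calls TSV (report format), QC TSV, and a JSON summary with
#' counts, fractions and class tallies.
#'
#' @param cohort a `cohort_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_report <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(cohort$additional))
    write_calls(cohort$additional, file.path(out_dir, "additional_cnvs.tsv"))
  qc <- do.call(rbind, lapply(cohort$cells, function(r) {
    fr <- if (is.null(r$qc)) rep(NA_real_, 3) else r$qc$fractions
    data.frame(cell = r$cell, status = r$status,
               fraction_0.5 = fr[["0.5"]], fraction_1 = fr[["1"]],
               fraction_2.5 = fr[["2.5"]],
               chosen_mb = r$chosen_bin_mb, row.names = NULL)
  }))
  utils::write.table(qc, file.path(out_dir, "qc_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- list(n_cells = length(cohort$cells),
                  n_analysed = length(cohort$analysed),
                  n_additional_cnvs = cohort$summary$n_cnvs,
                  n_cells_with_additional = cohort$summary$n_cells_with_cnv,
                  class_counts = as.list(cohort$summary$class_counts))
  if (!is.null(cohort$mosaicism)) {
    summary$n_carriers <- cohort$mosaicism$n_carriers
    summary$carrier_fraction <- cohort$mosaicism$fraction
    summary$bulk_prediction_loss <-
      bulk_expected_copy(cohort$mosaicism$fraction, 1)
    summary$bulk_prediction_gain <-
      bulk_expected_copy(cohort$mosaicism$fraction, 3)
  }
  jsonlite::write_json(summary, file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  # serialize the resolved scalar configuration so a run can be repeated
  cfg <- cohort$config
  keep <- vapply(cfg, function(x) is.numeric(x) || is.character(x) ||
                   is.logical(x), logical(1))
  jsonlite::write_json(cfg[keep], file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
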
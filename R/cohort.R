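#' Read a per-cell CNV table
#'
#' Reads a tab-separated per-cell CNV table in the package's report format
#' (the same layout as the packaged study-cohort fixture): columns `cell`,
#' `chrom`, `start_mb`, `end_mb`, `size_mb`, `direction`, `cnv_class`,
#' `start_terminal`, `end_terminal`, and optional per-end fragile-site
#' columns `site_start`, `site_end`. Coordinates are converted to bp.
#'
#' @param path TSV path.
#' @return A calls data.frame (bp coordinates) with any site columns
#'   carried along.
#' @export
read_cnv_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("cell", "chrom", "start_mb", "end_mb", "size_mb", "direction",
            "cnv_class", "start_terminal", "end_terminal")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("CNV table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(cell = as.character(tab$cell), chrom = tab$chrom,
                    start = tab$start_mb * 1e6, end = tab$end_mb * 1e6,
                    size_mb = tab$size_mb, direction = tab$direction,
                    mean_copy = NA_real_, n_bins = NA_integer_,
                    cnv_class = tab$cnv_class,
                    start_terminal = as.logical(tab$start_terminal),
                    end_terminal = as.logical(tab$end_terminal),
                    stringsAsFactors = FALSE)
  for (col in c("site_start", "site_end"))
    if (col %in% names(tab)) {
      v <- tab[[col]]
      v[is.na(v) | v == "."] <- ""
      out[[col]] <- v
    }
  if (any(out$end <= out$start))
    stop("CNV table contains an interval with end <= start")
  out
}

#' Breakpoint annotations recorded in a CNV table
#'
#' Converts the per-end fragile-site columns of a CNV table (as read by
#' [read_cnv_table()]) into the same annotation layout that
#' [annotate_breakpoints()] produces, so [fragile_fraction()] can
#' summarize a transcribed table without re-deriving sites from a
#' catalogue. Terminal ends are excluded from the breakpoint set.
#'
#' @param calls calls data.frame carrying `site_start` / `site_end`.
#' @return Annotation data.frame (`status` is `"within"` where a site name
#'   is recorded, `"none"` otherwise; distances are unknown, `NA`).
#' @export
table_annotations <- function(calls) {
  stopifnot(all(c("site_start", "site_end") %in% names(calls)))
  rows <- list()
  for (r in seq_len(nrow(calls))) {
    for (side in c("start", "end")) {
      if (isTRUE(calls[[paste0(side, "_terminal")]][r])) next
      site <- calls[[paste0("site_", side)]][r]
      rows[[length(rows) + 1]] <- data.frame(
        cell = calls$cell[r], chrom = calls$chrom[r], which_end = side,
        breakpoint = calls[[side]][r],
        status = if (nzchar(site)) "within" else "none",
        site = site, distance = if (nzchar(site)) 0 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Carrier fraction of a query CNV across a cohort
#'
#' A cell is a carrier when at least one of its calls matches at least one
#' query interval under the reciprocal-overlap rule of
#' [subtract_expected()] — so for a two-armed query such as an
#' isochromosome, matching either arm-event suffices.
#'
#' @param calls calls data.frame over the whole cohort (column `cell`
#'   identifies cells).
#' @param cells character vector of all analysed cell ids (the
#'   denominator; cells without calls count as non-carriers).
#' @param query expected-karyotype data.frame (`chrom`, `start`, `end`,
#'   `direction`).
#' @param reciprocal_overlap minimum reciprocal overlap (default 0.5).
#' @return List with `n_carriers`, `n_cells`, `fraction`.
#' @export
mosaicism_fraction <- function(calls, cells, query, reciprocal_overlap = 0.5) {
  cells <- unique(as.character(cells))
  if (!length(cells)) stop("empty cohort")
  carrier <- vapply(cells, function(cl) {
    cc <- calls[calls$cell == cl, , drop = FALSE]
    if (!nrow(cc)) return(FALSE)
    nrow(subtract_expected(cc, query, reciprocal_overlap)$matched) > 0
  }, logical(1))
  list(n_carriers = sum(carrier), n_cells = length(cells),
       fraction = sum(carrier) / length(cells),
       carriers = cells[carrier])
}

#' Predicted bulk copy number of a mosaic population
#'
#' The bulk copy number of a region carried by a fraction `f` of cells at
#' copy `c_carrier`, with the rest at `c_base`, is the mixture expectation
#' `(1 - f) * c_base + f * c_carrier`. A carrier fraction of 40/56 with a
#' one-copy arm loss therefore predicts bulk copy 1.29 — the non-integer
#' bulk values that flag a culture as mosaic.
#'
#' @param f carrier fraction in `[0, 1]`.
#' @param c_carrier copy number in carrier cells.
#' @param c_base baseline copy number (default 2).
#' @return Predicted bulk copy number.
#' @export
bulk_expected_copy <- function(f, c_carrier, c_base = 2) {
  if (any(f < 0 | f > 1)) stop("carrier fraction must lie in [0, 1]")
  (1 - f) * c_base + f * c_carrier
}

#' Tabulate a cohort's CNV burden
#'
#' Counts calls by class (segmental gain/loss, trisomy, monosomy), per-cell
#' burden, and flags cells carrying four or more aberrations as "complex"
#' and ten or more as "chaotic".
#'
#' @param calls calls data.frame (classified).
#' @param cells optional vector of all analysed cell ids; defaults to the
#'   cells present in `calls`.
#' @param complex_min,chaotic_min burden thresholds (defaults 4 and 10).
#' @return List with `n_cnvs`, `n_cells_with_cnv`, `class_counts`,
#'   `per_cell` (data.frame: cell, n_cnvs, complex, chaotic).
#' @export
tabulate_cohort <- function(calls, cells = NULL, complex_min = 4,
                            chaotic_min = 10) {
  if (is.null(cells)) cells <- unique(calls$cell)
  cells <- as.character(cells)
  burden <- vapply(cells, function(cl) sum(calls$cell == cl), numeric(1))
  cls <- rep("segmental gain", nrow(calls))
  if (nrow(calls)) {
    cls[calls$direction == "loss"] <- "segmental loss"
    cls[calls$cnv_class == "whole_chromosome" & calls$direction == "gain"] <- "trisomy"
    cls[calls$cnv_class == "whole_chromosome" & calls$direction == "loss"] <- "monosomy"
  }
  class_counts <- c("segmental gain" = sum(cls == "segmental gain"),
                    "segmental loss" = sum(cls == "segmental loss"),
                    trisomy = sum(cls == "trisomy"),
                    monosomy = sum(cls == "monosomy"))
  list(n_cnvs = nrow(calls),
       n_cells_with_cnv = sum(burden > 0),
       class_counts = class_counts,
       per_cell = data.frame(cell = cells, n_cnvs = burden,
                             complex = burden >= complex_min,
                             chaotic = burden >= chaotic_min,
                             row.names = NULL))
}

#' Find CNVs recurring at the same position across cells
#'
#' Groups calls from different cells by chromosome and direction, linking
#' two calls when their reciprocal overlap is at least
#' `reciprocal_overlap` (single linkage); groups spanning two or more
#' distinct cells are reported as recurrent.
#'
#' @param calls calls data.frame across the cohort.
#' @param reciprocal_overlap minimum reciprocal overlap (default 0.5).
#' @param include_whole also scan whole-chromosome calls (default `FALSE`:
#'   positional recurrence is a property of segmental breakpoints; two
#'   aneuploidies of the same chromosome coincide trivially).
#' @return data.frame with one row per recurrent group: `chrom`,
#'   `direction`, `start`, `end` (median extent, bp), `n_calls`,
#'   `n_cells`, `cells` (comma-separated).
#' @export
recurrence_scan <- function(calls, reciprocal_overlap = 0.5,
                            include_whole = FALSE) {
  if (!include_whole && "cnv_class" %in% names(calls))
    calls <- calls[calls$cnv_class != "whole_chromosome", , drop = FALSE]
  groups <- list()
  if (nrow(calls) >= 2) {
    for (key in unique(paste(calls$chrom, calls$direction))) {
      sel <- which(paste(calls$chrom, calls$direction) == key)
      if (length(sel) < 2) next
      g <- calls[sel, , drop = FALSE]
      n <- nrow(g)
      # single-linkage connected components under the overlap relation
      comp <- seq_len(n)
      for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        ov <- min(g$end[a], g$end[b]) - max(g$start[a], g$start[b])
        if (ov <= 0) next
        if (ov / (g$end[a] - g$start[a]) >= reciprocal_overlap &&
            ov / (g$end[b] - g$start[b]) >= reciprocal_overlap) {
          comp[comp == comp[b]] <- comp[a]
        }
      }
      for (cid in unique(comp)) {
        m <- g[comp == cid, , drop = FALSE]
        if (length(unique(m$cell)) < 2) next
        groups[[length(groups) + 1]] <- data.frame(
          chrom = m$chrom[1], direction = m$direction[1],
          start = stats::median(m$start), end = stats::median(m$end),
          n_calls = nrow(m), n_cells = length(unique(m$cell)),
          cells = paste(sort(unique(m$cell)), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(groups)) do.call(rbind, groups) else
    data.frame(chrom = character(), direction = character(),
               start = numeric(), end = numeric(), n_calls = integer(),
               n_cells = integer(), cells = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
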
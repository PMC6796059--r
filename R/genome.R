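#' Construct a genome build
#'
#' A genome build is the coordinate frame for the whole pipeline: an ordered
#' set of chromosomes with lengths and centromere midpoints, plus a set of
#' excluded ("difficult to sequence") regions that are masked from counting,
#' normalization and segmentation. Coordinates are 0-based half-open
#' throughout; reports render positions in Mb.
#'
#' @param chromosomes data.frame with columns `chrom` (character), `length`
#'   (bp) and `centromere_mid` (bp, strictly inside the chromosome).
#' @param excluded_regions data.frame with columns `chrom`, `start`, `end`
#'   (bp, 0-based half-open), or `NULL` for none. Overlapping regions on the
#'   same chromosome are merged.
#' @return An object of class `genome_build`.
#' @export
genome_build <- function(chromosomes, excluded_regions = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length", "centromere_mid") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome names in genome build")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be > 0")
  bad <- chromosomes$centromere_mid <= 0 |
    chromosomes$centromere_mid >= chromosomes$length
  if (any(bad))
    stop("centromere_mid must lie strictly inside (0, length) for: ",
         paste(chromosomes$chrom[bad], collapse = ", "))

  if (is.null(excluded_regions)) {
    excluded_regions <- data.frame(chrom = character(), start = numeric(),
                                   end = numeric())
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(excluded_regions)))
    excluded_regions$chrom <- as.character(excluded_regions$chrom)
    unknown <- setdiff(excluded_regions$chrom, chromosomes$chrom)
    if (length(unknown))
      stop("excluded region on unknown chromosome: ",
           paste(unique(unknown), collapse = ", "))
    len <- chromosomes$length[match(excluded_regions$chrom, chromosomes$chrom)]
    if (any(excluded_regions$start < 0) || any(excluded_regions$end > len) ||
        any(excluded_regions$start >= excluded_regions$end))
      stop("excluded regions must satisfy 0 <= start < end <= chromosome length")
    excluded_regions <- merge_regions(excluded_regions)
  }

  structure(list(chromosomes = chromosomes,
                 excluded_regions = excluded_regions),
            class = "genome_build")
}

# merge overlapping/adjacent intervals per chromosome (bp, half-open)
merge_regions <- function(regions) {
  out <- lapply(split(regions, regions$chrom), function(r) {
    ir <- IRanges::reduce(IRanges::IRanges(start = r$start + 1, end = r$end))
    data.frame(chrom = r$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome_build:", nrow(x$chromosomes), "chromosomes,",
      sprintf("%.1f", sum(x$chromosomes$length) / 1e6), "Mb total,",
      nrow(x$excluded_regions), "excluded regions\n")
  invisible(x)
}

#' GRCh38-like human genome model
#'
#' Packaged constants approximating the GRCh38 primary assembly: 24
#' chromosome lengths and centromere midpoints, with synthetic excluded
#' regions standing in for the unmappable fraction of the genome. Exclusions
#' are 5 Mb-aligned windows covering each centromere, the short arms of the
#' acrocentric chromosomes (13, 14, 15, 21, 22) and the heterochromatic
#' block of chrY; 5 Mb alignment guarantees that a 0.5, 1 or 2.5 Mb bin is
#' never partially excluded, so the three bin grids stay mutually
#' consistent.
#'
#' @return A `genome_build`.
#' @export
grch38_genome <- function() {
  chrom <- c(paste0("chr", 1:22), "chrX", "chrY")
  length_mb <- c(248.96, 242.19, 198.30, 190.21, 181.54, 170.81, 159.35,
                 145.14, 138.39, 133.80, 135.09, 133.28, 114.36, 107.04,
                 101.99, 90.34, 83.26, 80.37, 58.62, 64.44, 46.71, 50.82,
                 156.04, 57.23)
  cen_mb <- c(123.4, 93.9, 90.9, 50.0, 48.8, 59.8, 60.1, 45.2, 43.0, 39.8,
              53.4, 35.5, 17.7, 17.2, 19.0, 36.8, 25.1, 18.5, 26.2, 28.1,
              12.0, 15.0, 60.6, 10.4)
  chroms <- data.frame(chrom = chrom, length = round(length_mb * 1e6),
                       centromere_mid = round(cen_mb * 1e6))

  cen_lo <- floor(cen_mb / 5) * 5
  excl <- data.frame(chrom = chrom, start = cen_lo * 1e6,
                     end = pmin((cen_lo + 5) * 1e6, chroms$length))
  acro <- chrom %in% c("chr13", "chr14", "chr15", "chr21", "chr22")
  excl <- rbind(excl,
                data.frame(chrom = chrom[acro], start = 0,
                           end = cen_lo[acro] * 1e6))
  # chrY long-arm heterochromatin
  excl <- rbind(excl, data.frame(chrom = "chrY", start = 25e6,
                                 end = chroms$length[chrom == "chrY"]))
  genome_build(chroms, excl)
}

#' Read a genome build from tab-separated files
#'
#' @param path TSV with header `chrom`, `length`, `centromere_mid`.
#' @param exclusions_path optional BED3 file (no header) of excluded regions.
#' @return A `genome_build`.
#' @export
read_genome_build <- function(path, exclusions_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  excl <- NULL
  if (!is.null(exclusions_path)) {
    excl <- utils::read.table(exclusions_path, header = FALSE, sep = "\t",
                              stringsAsFactors = FALSE)[, 1:3]
    names(excl) <- c("chrom", "start", "end")
  }
  genome_build(tab, excl)
}

#' Deterministic synthetic GC track
#'
#' GC fraction as a smooth deterministic function of genomic position,
#' emulating the Mb-scale GC variation of the human genome (roughly
#' 0.34-0.60 with isochore-like structure). Used as the packaged
#' `gc_source` when no measured per-bin GC track is supplied; any function
#' of (chrom, start, end) can be substituted.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end bin coordinates (bp).
#' @return numeric vector of GC fractions in `[0, 1]`.
#' @export
synthetic_gc <- function(chrom, start, end) {
  mid <- (start + end) / 2
  ci <- as.numeric(factor(chrom, levels = unique(chrom)))
  gc <- 0.44 + 0.07 * sin(2 * pi * mid / 41e6 + ci) +
    0.05 * sin(2 * pi * mid / 7.3e6 + 2 * ci) +
    0.02 * cos(2 * pi * mid / 1.9e6)
  pmin(pmax(gc, 0.30), 0.62)
}

#' Build a fixed-width bin grid over a genome
#'
#' Tiles every chromosome with `bin_size` bins (the last bin of a chromosome
#' may be shorter), attaches a GC fraction per bin, and flags bins excluded
#' when they overlap the genome's excluded regions by at least
#' `exclude_fraction` of their width.
#'
#' @param genome a `genome_build`.
#' @param bin_size bin width in bp (0.5, 1 and 2.5 Mb are the conventional
#'   choices).
#' @param gc_source either a function `(chrom, start, end) -> gc` or a
#'   numeric vector with one GC value per bin.
#' @param exclude_fraction minimum overlap fraction for a bin to be flagged
#'   excluded (default 0.5).
#' @return A `bin_grid`: data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, `excluded`, carrying the genome and bin size as attributes.
#' @export
make_bin_grid <- function(genome, bin_size, gc_source = synthetic_gc,
                          exclude_fraction = 0.5) {
  stopifnot(inherits(genome, "genome_build"), bin_size > 0)
  if (bin_size > min(genome$chromosomes$length))
    stop("bin_size (", bin_size, ") larger than the smallest chromosome")

  bins <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(k) {
    len <- genome$chromosomes$length[k]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = genome$chromosomes$chrom[k], start = starts,
               end = pmin(starts + bin_size, len))
  }))
  rownames(bins) <- NULL

  if (is.function(gc_source)) {
    bins$gc <- gc_source(bins$chrom, bins$start, bins$end)
  } else {
    if (length(gc_source) != nrow(bins))
      stop("gc_source vector must supply one GC value per bin (",
           nrow(bins), " bins)")
    bins$gc <- as.numeric(gc_source)
  }
  if (anyNA(bins$gc) || any(bins$gc < 0) || any(bins$gc > 1))
    stop("GC fractions must be available for every bin and lie in [0, 1]")

  bins$excluded <- FALSE
  ex <- genome$excluded_regions
  if (nrow(ex)) {
    for (k in seq_len(nrow(ex))) {
      sel <- bins$chrom == ex$chrom[k]
      ov <- pmin(bins$end[sel], ex$end[k]) - pmax(bins$start[sel], ex$start[k])
      frac <- pmax(ov, 0) / (bins$end[sel] - bins$start[sel])
      bins$excluded[sel] <- bins$excluded[sel] | frac >= exclude_fraction
    }
  }

  structure(bins, genome = genome, bin_size = bin_size, class = c("bin_grid", "data.frame"))
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("bin_grid:", nrow(x), "bins of", attr(x, "bin_size") / 1e6, "Mb (",
      sum(!x$excluded), "usable )\n")
  invisible(x)
}

#' Per-cell bin counts
#'
#' Pairs an integer count vector with the grid it was counted on. Counts on
#' excluded bins are retained but flagged by the grid and never consumed
#' downstream.
#'
#' @param sample_id sample label.
#' @param grid a `bin_grid`.
#' @param counts non-negative integer vector, one element per bin.
#' @return A `bin_counts` object.
#' @export
bin_counts <- function(sample_id, grid, counts) {
  stopifnot(inherits(grid, "bin_grid"))
  if (length(counts) != nrow(grid))
    stop("counts length (", length(counts), ") != number of bins (",
         nrow(grid), ")")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  structure(list(sample_id = as.character(sample_id), grid = grid,
                 counts = as.numeric(counts)),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("bin_counts:", x$sample_id, "-", format(sum(x$counts), big.mark = ","),
      "reads over", nrow(x$grid), "bins\n")
  invisible(x)
}

#' Count aligned reads into a bin grid
#'
#' Each primary, mapped, quality-passing alignment increments exactly one
#' bin, chosen by its leftmost aligned position. Unmapped, secondary and
#' duplicate reads are skipped, as are reads below `min_mapping_quality`.
#' Reads on chromosomes absent from the grid are skipped with a warning (or
#' an error when `unknown_chrom = "error"`).
#'
#' @param alignments either a path to a coordinate-accessible BAM file
#'   (requires the Rsamtools package) or a data.frame with columns `chrom`,
#'   `pos` (0-based leftmost position), `mapq`, and optional logical columns
#'   `unmapped`, `secondary`, `duplicate`.
#' @param grid a `bin_grid`.
#' @param min_mapping_quality minimum MAPQ (default 20).
#' @param sample_id sample label for the result.
#' @param unknown_chrom `"warn"` (skip, default) or `"error"`.
#' @return A `bin_counts` object.
#' @export
count_reads <- function(alignments, grid, min_mapping_quality = 20,
                        sample_id = "sample", unknown_chrom = c("warn", "error")) {
  unknown_chrom <- match.arg(unknown_chrom)
  stopifnot(inherits(grid, "bin_grid"))

  if (is.character(alignments) && length(alignments) == 1) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading BAM input requires the Rsamtools package")
    prm <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isDuplicate = FALSE),
      what = c("rname", "pos", "mapq"))
    res <- Rsamtools::scanBam(alignments, param = prm)[[1]]
    alignments <- data.frame(chrom = as.character(res$rname),
                             pos = res$pos - 1,  # BAM pos is 1-based
                             mapq = res$mapq)
  }
  stopifnot(all(c("chrom", "pos", "mapq") %in% names(alignments)))
  keep <- rep(TRUE, nrow(alignments))
  for (fl in c("unmapped", "secondary", "duplicate"))
    if (fl %in% names(alignments)) keep <- keep & !alignments[[fl]]
  n_flag_skipped <- sum(!keep)
  al <- alignments[keep, , drop = FALSE]

  pass_q <- !is.na(al$mapq) & al$mapq >= min_mapping_quality
  n_lowq <- sum(!pass_q)
  al <- al[pass_q, , drop = FALSE]

  known <- al$chrom %in% unique(grid$chrom)
  if (any(!known)) {
    msg <- paste0(sum(!known), " reads on chromosomes absent from the grid: ",
                  paste(unique(al$chrom[!known]), collapse = ", "))
    if (unknown_chrom == "error") stop(msg)
    warning(msg)
    al <- al[known, , drop = FALSE]
  }

  counts <- numeric(nrow(grid))
  if (nrow(al)) {
    # bins tile each chromosome contiguously from 0
    first <- match(unique(grid$chrom), grid$chrom)
    names(first) <- unique(grid$chrom)
    bs <- attr(grid, "bin_size")
    idx <- first[al$chrom] + floor(al$pos / bs)
    # clamp reads in the truncated last bin of a chromosome
    last <- c(first[-1] - 1, nrow(grid))
    names(last) <- names(first)
    idx <- pmin(idx, last[al$chrom])
    tab <- tabulate(idx, nbins = nrow(grid))
    counts <- as.numeric(tab)
  }
  message(sprintf("count_reads [%s]: %d counted, %d flag-skipped, %d low MAPQ",
                  sample_id, nrow(al), n_flag_skipped, n_lowq))
  bin_counts(sample_id, grid, counts)
}

#' Read and write bin-count files
#'
#' Tab-separated with header `chrom`, `start`, `end`, `count`; coordinates
#' 0-based half-open. `read_bin_counts()` validates every row against the
#' active grid and reports the first mismatching interval.
#'
#' @param counts a `bin_counts` object.
#' @param path file path.
#' @param grid the active `bin_grid` the file must match.
#' @param sample_id sample label for the result.
#' @return `read_bin_counts()` returns a `bin_counts`;
#'   `write_bin_counts()` returns `path` invisibly.
#' @export
write_bin_counts <- function(counts, path) {
  stopifnot(inherits(counts, "bin_counts"))
  df <- data.frame(chrom = counts$grid$chrom, start = counts$grid$start,
                   end = counts$grid$end, count = counts$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(path, grid, sample_id = basename(path)) {
  stopifnot(inherits(grid, "bin_grid"))
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("character", "numeric", "numeric", "numeric"),
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed bin-count file ", path, ": ",
                             conditionMessage(e)))
  if (!identical(names(tab), c("chrom", "start", "end", "count")))
    stop("bin-count file must have header chrom, start, end, count")
  bad <- which(is.na(tab$count) | tab$count < 0)
  if (length(bad))
    stop("negative or missing count at line ", bad[1] + 1, " of ", path)
  if (nrow(tab) != nrow(grid))
    stop("bin-count file has ", nrow(tab), " bins; grid has ", nrow(grid))
  mism <- which(tab$chrom != grid$chrom | tab$start != grid$start |
                  tab$end != grid$end)
  if (length(mism))
    stop(sprintf("bin %d (%s:%d-%d) does not match the active grid (%s:%d-%d)",
                 mism[1], tab$chrom[mism[1]], tab$start[mism[1]],
                 tab$end[mism[1]], grid$chrom[mism[1]], grid$start[mism[1]],
                 grid$end[mism[1]]))
  bin_counts(sample_id, grid, tab$count)
}

#' Aggregate fine-grid counts onto a coarser grid
#'
#' Sums counts of fine bins into the coarse bin containing them. Every fine
#' bin must nest inside a single coarse bin, which holds whenever the coarse
#' bin size is a multiple of the fine one (0.5 Mb counts aggregate to both
#' 1 Mb and 2.5 Mb).
#'
#' @param counts `bin_counts` on the fine grid.
#' @param coarse_grid target `bin_grid` on the same genome.
#' @return `bin_counts` on `coarse_grid`.
#' @export
aggregate_counts <- function(counts, coarse_grid) {
  stopifnot(inherits(counts, "bin_counts"), inherits(coarse_grid, "bin_grid"))
  fine <- counts$grid
  bs <- attr(coarse_grid, "bin_size")
  first <- match(unique(coarse_grid$chrom), coarse_grid$chrom)
  names(first) <- unique(coarse_grid$chrom)
  if (!all(fine$chrom %in% names(first)))
    stop("fine grid has chromosomes absent from the coarse grid")
  idx <- first[fine$chrom] + floor(fine$start / bs)
  target_start <- coarse_grid$start[idx]
  if (any(fine$start < target_start) || any(fine$end > coarse_grid$end[idx]))
    stop("fine bins do not nest inside coarse bins; bin sizes incompatible")
  agg <- tapply(counts$counts, idx, sum)
  out <- numeric(nrow(coarse_grid))
  out[as.integer(names(agg))] <- agg
  bin_counts(counts$sample_id, coarse_grid, out)
}
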
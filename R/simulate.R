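#' Simulator configuration
#'
#' Defaults emulate the study conditions of a mosaic isochromosome-20
#' human embryonic stem-cell line profiled by single-cell shallow
#' sequencing: per-cell totals of 3.92 +/- 1.33 million reads, a carrier
#' fraction of 40/56, sporadic extra CNVs (log-uniform 8-100 Mb, a minority
#' of them whole-chromosome aneuploidies), a linear GC amplification bias,
#' and whole-genome-amplification overdispersion modelled as multiplicative
#' gamma noise (marginally negative-binomial counts). Tier dispersions are
#' set, via the count model CV^2 = 1/mu + d, so that high/mid/low-quality
#' cells cluster tightly enough for analysis at 0.5/1/2.5 Mb bins
#' respectively and fail-tier cells pass at none.
#'
#' @param genome a `genome_build` (default [grch38_genome()]).
#' @param carrier_fraction fraction of cells carrying the isochromosome
#'   (default 40/56).
#' @param extra_cnv_rate Poisson mean of additional CNVs per cell
#'   (default 0.9).
#' @param extra_size_range size range (bp) of segmental extra CNVs,
#'   sampled log-uniformly (default 8-100 Mb).
#' @param aneuploidy_prob probability that an extra CNV is a whole
#'   chromosome (default 0.16).
#' @param gc_slope linear slope of relative amplification rate on
#'   `gc - 0.40` (default 1.2).
#' @param dispersion named gamma mixing variances per quality tier.
#' @param tier_proportions named sampling proportions of quality tiers.
#' @param reads_mean,reads_sd per-cell total read model (normal, truncated
#'   at `reads_min`).
#' @param reads_min lower truncation of per-cell totals (default 1e5).
#' @param sex `"XY"` or `"XX"` baseline for the simulated line.
#' @param carrier_karyotype copy overrides (data.frame `chrom`, `start`,
#'   `end`, `copy`) defining what a carrier cell carries; `NULL` (default)
#'   derives the isochromosome-20 karyotype from the genome build.
#' @param seed integer seed; all randomness of a population run flows from
#'   it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome = grch38_genome(),
                       carrier_fraction = 40 / 56,
                       carrier_karyotype = NULL,
                       extra_cnv_rate = 0.9,
                       extra_size_range = c(8e6, 100e6),
                       aneuploidy_prob = 0.16,
                       gc_slope = 1.2,
                       dispersion = c(high = 0.004, mid = 0.02,
                                      low = 0.06, fail = 0.3),
                       tier_proportions = c(high = 0.16, mid = 0.55,
                                            low = 0.29, fail = 0),
                       reads_mean = 3.92e6, reads_sd = 1.33e6,
                       reads_min = 1e5,
                       sex = "XY",
                       seed = 1L) {
  stopifnot(carrier_fraction >= 0, carrier_fraction <= 1,
            all(dispersion > 0), !is.null(seed))
  structure(list(genome = genome, carrier_fraction = carrier_fraction,
                 carrier_karyotype = carrier_karyotype,
                 extra_cnv_rate = extra_cnv_rate,
                 extra_size_range = extra_size_range,
                 aneuploidy_prob = aneuploidy_prob,
                 gc_slope = gc_slope, dispersion = dispersion,
                 tier_proportions = tier_proportions,
                 reads_mean = reads_mean, reads_sd = reads_sd,
                 reads_min = reads_min, sex = sex,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# per-bin integer copy implied by a karyotype (baseline + overrides);
# an override applies to bins whose midpoint falls inside its interval
karyotype_copy <- function(grid, karyotype, baseline) {
  copies <- baseline[grid$chrom]
  copies[is.na(copies)] <- 0
  if (!is.null(karyotype) && nrow(karyotype)) {
    mid <- (grid$start + grid$end) / 2
    for (k in seq_len(nrow(karyotype))) {
      sel <- grid$chrom == karyotype$chrom[k] & mid >= karyotype$start[k] &
        mid < karyotype$end[k]
      copies[sel] <- karyotype$copy[k]
    }
  }
  unname(copies)
}

#' Simulate one cell's bin counts
#'
#' Per usable bin the relative rate is
#' `copy * (1 + gc_slope * (gc - 0.40)) * a` with `a ~ Gamma(1/d, scale d)`
#' (mean 1, variance `d`, the tier's amplification noise); counts are
#' multinomial over usable bins with these rates as probabilities.
#' Excluded bins receive zero counts. Randomness is drawn from R's global
#' generator, so a `set.seed()` before the call makes the counts
#' reproducible.
#'
#' @param spec list with `cell_id`, `karyotype` (data.frame chrom, start,
#'   end, copy — overrides to the baseline), `quality_tier`, `total_reads`.
#' @param config a `sim_config`.
#' @param grid a `bin_grid`.
#' @return A `bin_counts` object.
#' @export
simulate_cell <- function(spec, config, grid) {
  stopifnot(inherits(config, "sim_config"), inherits(grid, "bin_grid"))
  baseline <- expected_copy(config$genome, config$sex)
  copies <- karyotype_copy(grid, spec$karyotype, baseline)
  usable <- !grid$excluded
  d <- config$dispersion[[spec$quality_tier]]
  n_us <- sum(usable)
  a <- if (d < 1e-12) rep(1, n_us) else
    stats::rgamma(n_us, shape = 1 / d, scale = d)
  rate <- copies[usable] * (1 + config$gc_slope * (grid$gc[usable] - 0.40)) * a
  rate[rate < 0] <- 0
  if (sum(rate) <= 0) stop("all-zero rates; cannot simulate counts")
  counts <- numeric(nrow(grid))
  counts[usable] <- stats::rmultinom(1, size = spec$total_reads,
                                     prob = rate / sum(rate))[, 1]
  bin_counts(spec$cell_id, grid, counts)
}

# one random extra CNV avoiding chr20, chrY and centromere-spanning
# intervals; returns a karyotype row (or NULL after too many rejections)
random_extra_cnv <- function(config, existing) {
  g <- config$genome$chromosomes
  cand <- g[!g$chrom %in% c("chr20", "chrY"), ]
  baseline <- expected_copy(config$genome, config$sex)
  for (try in 1:50) {
    k <- cand[sample(nrow(cand), 1), ]
    dir <- sample(c(-1, 1), 1)
    base <- baseline[[k$chrom]]
    if (base + dir < 0) next
    if (stats::runif(1) < config$aneuploidy_prob) {
      row <- data.frame(chrom = k$chrom, start = 0, end = k$length,
                        copy = base + dir, whole = TRUE,
                        stringsAsFactors = FALSE)
    } else {
      arm <- if (stats::runif(1) < k$centromere_mid / k$length)
        c(0, k$centromere_mid) else c(k$centromere_mid, k$length)
      lo <- log(config$extra_size_range[1])
      hi <- log(min(config$extra_size_range[2], arm[2] - arm[1]))
      if (hi <= lo) next
      size <- exp(stats::runif(1, lo, hi))
      start <- stats::runif(1, arm[1], arm[2] - size)
      row <- data.frame(chrom = k$chrom, start = start, end = start + size,
                        copy = base + dir, whole = FALSE,
                        stringsAsFactors = FALSE)
    }
    clash <- !is.null(existing) && nrow(existing) &&
      any(existing$chrom == row$chrom & existing$start < row$end &
            row$start < existing$end)
    if (!clash) return(row)
  }
  NULL
}

#' Simulate a mosaic single-cell population with known truth
#'
#' Exactly `round(f * n_cells)` cells carry the isochromosome-20 karyotype
#' (p-arm copy 1, q-arm copy 3); every cell independently receives
#' `Poisson(extra_cnv_rate)` additional CNVs at random positions, a quality
#' tier drawn from `tier_proportions`, and a total read count from the
#' truncated-normal read model. The returned truth set pairs each cell's
#' generated counts (on the supplied grid) with its exact karyotype, for
#' parameter-recovery testing. Reproducible: the config seed drives all
#' randomness, so the same config yields bit-identical output.
#'
#' @param config a `sim_config`.
#' @param n_cells number of cells (>= 1).
#' @param grid `bin_grid` to simulate counts on (conventionally the finest,
#'   0.5 Mb, grid; coarser counts come from [aggregate_counts()]).
#' @return A `truth_set`: list with `specs` (per-cell list: cell_id,
#'   carrier, karyotype, quality_tier, total_reads), `counts` (list of
#'   `bin_counts`), and `config`.
#' @export
simulate_population <- function(config, n_cells, grid) {
  stopifnot(inherits(config, "sim_config"), n_cells >= 1)
  set.seed(config$seed)
  if (is.null(config$carrier_karyotype)) {
    iso <- iso20_karyotype(config$genome)
    iso_k <- data.frame(chrom = iso$chrom, start = iso$start, end = iso$end,
                        copy = ifelse(iso$direction == "loss", 1, 3),
                        whole = FALSE, stringsAsFactors = FALSE)
  } else {
    iso_k <- config$carrier_karyotype
    iso_k$whole <- FALSE
  }
  n_carriers <- round(config$carrier_fraction * n_cells)
  carrier_ids <- sample(n_cells, n_carriers)
  tiers <- sample(names(config$tier_proportions), n_cells, replace = TRUE,
                  prob = config$tier_proportions)

  specs <- vector("list", n_cells)
  counts <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    kary <- NULL
    if (i %in% carrier_ids) kary <- iso_k
    n_extra <- stats::rpois(1, config$extra_cnv_rate)
    extras <- NULL
    for (e in seq_len(n_extra)) {
      row <- random_extra_cnv(config, rbind(kary, extras))
      if (!is.null(row)) extras <- rbind(extras, row)
    }
    total <- max(config$reads_min,
                 round(stats::rnorm(1, config$reads_mean, config$reads_sd)))
    spec <- list(cell_id = sprintf("cell%02d", i),
                 carrier = i %in% carrier_ids,
                 karyotype = rbind(kary, extras),
                 extra_cnvs = extras,
                 quality_tier = tiers[i],
                 total_reads = total)
    specs[[i]] <- spec
    counts[[i]] <- simulate_cell(spec, config, grid)
  }
  structure(list(specs = specs, counts = counts, config = config),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  carriers <- sum(vapply(x$specs, `[[`, logical(1), "carrier"))
  cat("truth_set:", length(x$specs), "cells,", carriers, "carriers\n")
  invisible(x)
}

#' Simulate bulk bin counts from a cell population
#'
#' The bulk per-bin rate is the equal-weight mean of the member cells'
#' copy-weighted GC-biased rates, with no per-cell amplification noise and
#' only a mild bulk dispersion; counts are multinomial with the given
#' total. This is the in-silico analogue of sequencing DNA extracted from
#' the pooled population: a CNV carried by a fraction f of cells shows up
#' at the mixture copy number (1-f)*base + f*carrier.
#'
#' @param truth a `truth_set` (or a list of cell specs).
#' @param total_reads bulk total read count.
#' @param grid `bin_grid` to count on.
#' @param config the `sim_config` (defaults to the truth set's).
#' @param bulk_dispersion residual gamma mixing variance of the bulk
#'   library (default 0.001).
#' @return A `bin_counts` for sample `"bulk"`.
#' @export
simulate_bulk <- function(truth, total_reads, grid, config = truth$config,
                          bulk_dispersion = 0.001) {
  specs <- if (inherits(truth, "truth_set")) truth$specs else truth
  if (!length(specs)) stop("no cells in truth set")
  baseline <- expected_copy(config$genome, config$sex)
  usable <- !grid$excluded
  mean_copy <- rowMeans(vapply(specs, function(sp)
    karyotype_copy(grid, sp$karyotype, baseline), numeric(nrow(grid))))
  a <- if (bulk_dispersion < 1e-12) 1 else
    stats::rgamma(sum(usable), shape = 1 / bulk_dispersion,
                  scale = bulk_dispersion)
  rate <- mean_copy[usable] *
    (1 + config$gc_slope * (grid$gc[usable] - 0.40)) * a
  rate[rate < 0] <- 0
  if (sum(rate) <= 0) stop("all-zero rates; cannot simulate counts")
  counts <- numeric(nrow(grid))
  counts[usable] <- stats::rmultinom(1, size = total_reads,
                                     prob = rate / sum(rate))[, 1]
  bin_counts("bulk", grid, counts)
}

#' Write a truth set to per-cell TSVs
#'
#' Writes one bin-count TSV per cell plus a truth table
#' (`cell`, `chrom`, `start`, `end`, `copy`, `tier`, `total_reads`).
#'
#' @param truth a `truth_set`.
#' @param dir output directory (created if needed).
#' @return The truth-table path, invisibly.
#' @export
write_truth_set <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(truth$specs)) {
    sp <- truth$specs[[i]]
    write_bin_counts(truth$counts[[i]],
                     file.path(dir, paste0(sp$cell_id, "_counts.tsv")))
    k <- sp$karyotype
    if (!is.null(k) && nrow(k))
      rows[[length(rows) + 1]] <- data.frame(cell = sp$cell_id,
                                             chrom = k$chrom, start = k$start,
                                             end = k$end, copy = k$copy,
                                             tier = sp$quality_tier,
                                             total_reads = sp$total_reads)
  }
  truth_path <- file.path(dir, "truth.tsv")
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = character(), chrom = character(), start = numeric(),
               end = numeric(), copy = numeric(), tier = character(),
               total_reads = numeric())
  utils::write.table(tab, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(truth_path)
}
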
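# Small in-code fixtures shared across test files.

# three-chromosome toy genome (120 Mb) — big enough for >= 100 usable bins
# at 0.5 Mb and for >= 8 Mb calls, small enough to keep simulations fast
small_genome <- function(excl = NULL) {
  genome_build(
    data.frame(chrom = c("chrA", "chrB", "chrC"),
               length = c(50e6, 40e6, 30e6),
               centromere_mid = c(22e6, 18e6, 12e6)),
    excl)
}

# single-chromosome genome of the given length
one_chrom_genome <- function(len, cen = len / 2, name = "chr1", excl = NULL) {
  genome_build(data.frame(chrom = name, length = len, centromere_mid = cen),
               excl)
}

# constant GC for tests that should not exercise the GC fit
flat_gc <- function(chrom, start, end) rep(0.45, length(chrom))

# build a copy_profile directly (bypassing gc_normalize) at a given stage
make_profile <- function(grid, ratio, stage = "normalized",
                         mask = NULL, sample_id = "test") {
  if (is.null(mask)) mask <- !grid$excluded
  ratio[!mask] <- NA_real_
  scmosaic:::copy_profile(sample_id, grid, stage = stage, ratio = ratio,
                          mask = mask)
}

# build a scaled_profile directly from per-bin copy values
make_scaled <- function(grid, copy_seg, copy_bin = copy_seg, mask = NULL,
                        sample_id = "test", scaling = 2) {
  if (is.null(mask)) mask <- !grid$excluded
  copy_seg[!mask] <- NA_real_
  structure(list(sample_id = sample_id, grid = grid, mask = mask,
                 scaling_factor = scaling, copy_seg = copy_seg,
                 copy_bin = copy_bin, segments = NULL,
                 sse_curve = NULL, sse_min = NA_real_),
            class = "scaled_profile")
}

# exhaustive least-squares single-changepoint oracle: returns the split
# index k (first piece = y[1..k]) minimizing total RSS, or NA if n < 2
ls_changepoint <- function(y, min_len = 1) {
  n <- length(y)
  best <- NA_integer_
  best_rss <- Inf
  for (k in seq(min_len, n - min_len)) {
    a <- y[1:k]; b <- y[(k + 1):n]
    rss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (rss < best_rss) { best_rss <- rss; best <- k }
  }
  best
}

table1_path <- function() system.file("extdata", "table1_cnvs.tsv",
                                      package = "scmosaic")
fragile_bed_path <- function() system.file("extdata",
                                           "fragile_sites_synthetic.bed",
                                           package = "scmosaic")
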
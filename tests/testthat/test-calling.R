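# one-chromosome scaled profile in copy space at a given bin size
copy_run <- function(bin_size, n_bins_total, run_at, run_len, run_copy,
                     base_copy = 2, len = NULL) {
  if (is.null(len)) len <- n_bins_total * bin_size
  grid <- make_bin_grid(one_chrom_genome(len, cen = len / 2), bin_size,
                        gc_source = flat_gc)
  copies <- rep(base_copy, nrow(grid))
  idx <- run_at:(run_at + run_len - 1)
  copies[idx] <- run_copy
  make_scaled(grid, copies)
}

baseline1 <- c(chr1 = 2)

test_that("both run-length and genomic-span minima must be met", {
  # 0.5 Mb bins: 16 bins at copy 2.7 span exactly 8 Mb -> one gain
  sc <- copy_run(0.5e6, 100, 30, 16, 2.7)
  calls <- call_cnvs(sc, baseline1, calling_params(0.5e6))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "gain")
  expect_equal(calls$size_mb, 8)
  expect_equal(calls$n_bins, 16L)

  # 15 bins (7.5 Mb) meet the 8-bin rule but not the 8 Mb span -> no call
  sc <- copy_run(0.5e6, 100, 30, 15, 2.7)
  expect_equal(nrow(call_cnvs(sc, baseline1, calling_params(0.5e6))), 0)

  # 1 Mb bins: 7 bins at copy 1.2 -> none; 8 bins -> an 8 Mb loss
  sc <- copy_run(1e6, 100, 30, 7, 1.2)
  expect_equal(nrow(call_cnvs(sc, baseline1, calling_params(1e6))), 0)
  sc <- copy_run(1e6, 100, 30, 8, 1.2)
  calls <- call_cnvs(sc, baseline1, calling_params(1e6))
  expect_equal(calls$direction, "loss")
  expect_equal(calls$size_mb, 8)
})

test_that("the relaxed +0.55 gain threshold applies only at 2.5 Mb bins", {
  # copy 2.58: a gain at 2.5 Mb (>= 2.55), not at 1 Mb (< 2.65)
  sc <- copy_run(2.5e6, 40, 10, 8, 2.58)
  calls <- call_cnvs(sc, baseline1, calling_params(2.5e6))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$size_mb, 20)           # 8 bins x 2.5 Mb
  sc <- copy_run(1e6, 100, 30, 20, 2.58)
  expect_equal(nrow(call_cnvs(sc, baseline1, calling_params(1e6))), 0)
  # losses need -0.65 at all bin sizes
  sc <- copy_run(2.5e6, 40, 10, 8, 1.45)
  expect_equal(nrow(call_cnvs(sc, baseline1, calling_params(2.5e6))), 0)
  sc <- copy_run(2.5e6, 40, 10, 8, 1.35)
  expect_equal(nrow(call_cnvs(sc, baseline1, calling_params(2.5e6))), 1)
})

test_that("thresholds are deviations from the chromosome baseline", {
  # haploid male X: a loss to copy ~0.3 must be callable from baseline 1
  sc <- copy_run(1e6, 100, 30, 10, 0.3, base_copy = 1)
  sc$grid$chrom <- "chrX"; sc$sample_id <- "x"
  calls <- call_cnvs(sc, c(chrX = 1), calling_params(1e6))
  expect_equal(calls$direction, "loss")
  # and copy 1.7 on X clears the +0.65 gain threshold from baseline 1
  sc <- copy_run(1e6, 100, 30, 10, 1.7, base_copy = 1)
  sc$grid$chrom <- "chrX"
  expect_equal(call_cnvs(sc, c(chrX = 1), calling_params(1e6))$direction,
               "gain")
  # a chromosome with NA baseline (masked chrY in XX) emits no calls
  sc <- copy_run(1e6, 100, 30, 10, 3)
  expect_equal(nrow(call_cnvs(sc, c(chr1 = NA_real_), calling_params(1e6))), 0)
})

test_that("masked bins join runs without counting toward the bin minimum", {
  grid <- make_bin_grid(one_chrom_genome(100e6, cen = 50e6), 1e6,
                        gc_source = flat_gc)
  copies <- rep(2, 100)
  copies[41:52] <- 3
  mask <- rep(TRUE, 100); mask[45:46] <- FALSE      # masked gap inside run
  sc <- make_scaled(grid, copies, mask = mask)
  calls <- call_cnvs(sc, baseline1, calling_params(1e6))
  expect_equal(nrow(calls), 1)                      # one merged call
  expect_equal(calls$n_bins, 10L)                   # usable bins only
  expect_equal(calls$start, 40e6)
  expect_equal(calls$end, 52e6)                     # span bridges the gap
})

test_that("whole-chromosome and terminal classification follow the grid", {
  grid <- make_bin_grid(one_chrom_genome(100e6, cen = 50e6,
                                         excl = data.frame(chrom = "chr1",
                                                           start = 45e6,
                                                           end = 55e6)),
                        1e6, gc_source = flat_gc)
  copies <- rep(3, 100)
  sc <- make_scaled(grid, copies)
  calls <- call_cnvs(sc, baseline1, calling_params(1e6))
  expect_equal(calls$cnv_class, "whole_chromosome")  # despite the 10 Mb gap
  expect_true(calls$start_terminal && calls$end_terminal)

  copies <- rep(2, 100); copies[90:100] <- 3
  calls <- call_cnvs(make_scaled(grid, copies, mask = !grid$excluded),
                     baseline1, calling_params(1e6))
  expect_equal(calls$cnv_class, "segmental")
  expect_false(calls$start_terminal)
  expect_true(calls$end_terminal)
})

test_that("expected-karyotype subtraction uses direction and reciprocal overlap", {
  expected <- data.frame(chrom = "chr20", start = 0, end = 26e6,
                         direction = "loss")
  calls <- data.frame(cell = "c", chrom = "chr20", start = 0, end = 26e6,
                      size_mb = 26, direction = "loss", mean_copy = 1,
                      n_bins = 26L, cnv_class = "segmental",
                      start_terminal = TRUE, end_terminal = FALSE)
  sp <- subtract_expected(calls, expected)
  expect_equal(nrow(sp$matched), 1)
  expect_equal(nrow(sp$additional), 0)

  # direction mismatch -> additional
  calls$direction <- "gain"
  expect_equal(nrow(subtract_expected(calls, expected)$additional), 1)

  # different chromosome -> additional
  calls$direction <- "loss"; calls$chrom <- "chr3"; expected$chrom <- "chr20"
  expect_equal(nrow(subtract_expected(calls, expected)$additional), 1)

  # low reciprocal overlap -> additional
  calls$chrom <- "chr20"; calls$start <- 20e6; calls$end <- 26e6
  expect_equal(nrow(subtract_expected(calls, expected)$additional), 1)
})

test_that("no emitted call ever violates the run, threshold or size minima", {
  set.seed(51)
  grid <- make_bin_grid(one_chrom_genome(120e6, cen = 60e6), 1e6,
                        gc_source = flat_gc)
  params <- calling_params(1e6)
  for (rep in 1:300) {
    # random piecewise copy profiles with abrupt jumps
    n_seg <- sample(1:6, 1)
    bounds <- sort(c(0, sample(119, n_seg - 1), 120))
    copies <- unlist(lapply(seq_len(n_seg), function(k)
      rep(sample(c(0, 1, 2, 2.5, 2.7, 3, 4), 1),
          bounds[k + 1] - bounds[k])))
    sc <- make_scaled(grid, copies)
    calls <- call_cnvs(sc, baseline1, params)
    if (nrow(calls)) {
      expect_true(all(calls$n_bins >= params$min_bins_run))
      expect_true(all(calls$size_mb * 1e6 >= params$min_size))
      for (r in seq_len(nrow(calls))) {
        idx <- which(grid$start >= calls$start[r] & grid$end <= calls$end[r])
        if (calls$direction[r] == "gain")
          expect_true(all(copies[idx] >= 2 + params$gain_threshold))
        else
          expect_true(all(copies[idx] <= 2 - params$loss_threshold))
        # maximality: the adjacent bins break the threshold condition
        lo <- min(idx) - 1; hi <- max(idx) + 1
        if (calls$direction[r] == "gain") {
          if (lo >= 1) expect_lt(copies[lo], 2 + params$gain_threshold)
          if (hi <= 120) expect_lt(copies[hi], 2 + params$gain_threshold)
        } else {
          if (lo >= 1) expect_gt(copies[lo], 2 - params$loss_threshold)
          if (hi <= 120) expect_gt(copies[hi], 2 - params$loss_threshold)
        }
      }
    }
  }
})
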
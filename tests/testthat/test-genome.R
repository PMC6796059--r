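test_that("bin grids tile chromosomes exactly, remainder bin included", {
  g <- one_chrom_genome(10e6)
  grid <- make_bin_grid(g, 1e6, gc_source = flat_gc)
  expect_equal(nrow(grid), 10)
  expect_equal(grid$start, seq(0, 9e6, by = 1e6))
  expect_equal(grid$end - grid$start, rep(1e6, 10))

  g2 <- one_chrom_genome(10.4e6)
  grid2 <- make_bin_grid(g2, 1e6, gc_source = flat_gc)
  expect_equal(nrow(grid2), 11)
  expect_equal(grid2$end[11] - grid2$start[11], 0.4e6)
  # no gaps, no overlaps
  expect_equal(grid2$start[-1], grid2$end[-11])
})

test_that("exclusion flags follow the 50% overlap rule", {
  # exclusion covers 0.6 Mb of bin 3 (bins are 1 Mb) -> flagged
  g <- one_chrom_genome(10e6, excl = data.frame(chrom = "chr1",
                                                start = 2.2e6, end = 2.8e6))
  grid <- make_bin_grid(g, 1e6, gc_source = flat_gc)
  expect_true(grid$excluded[3])
  expect_equal(sum(grid$excluded), 1)

  # 0.4 Mb overlap -> not flagged
  g2 <- one_chrom_genome(10e6, excl = data.frame(chrom = "chr1",
                                                 start = 2.3e6, end = 2.7e6))
  expect_false(any(make_bin_grid(g2, 1e6, gc_source = flat_gc)$excluded))
})

test_that("grid construction is deterministic and validates inputs", {
  g <- small_genome()
  expect_identical(make_bin_grid(g, 1e6), make_bin_grid(g, 1e6))
  expect_error(make_bin_grid(g, 35e6), "smallest chromosome")
  expect_error(genome_build(data.frame(chrom = "c", length = 1e6,
                                       centromere_mid = 2e6)),
               "centromere_mid")
  expect_error(
    genome_build(data.frame(chrom = "c", length = 1e7, centromere_mid = 5e6),
                 data.frame(chrom = "zz", start = 0, end = 1e6)),
    "zz")
})

test_that("reads are counted into exactly one bin by leftmost position", {
  g <- one_chrom_genome(10e6)
  grid <- make_bin_grid(g, 1e6, gc_source = flat_gc)
  al <- data.frame(chrom = "chr1", pos = c(0.1e6, 0.9e6, 1.2e6), mapq = 60)
  cts <- suppressMessages(count_reads(al, grid))
  expect_equal(cts$counts, c(2, 1, rep(0, 8)))

  # low-MAPQ read not counted
  al$mapq <- c(60, 5, 60)
  cts2 <- suppressMessages(count_reads(al, grid, min_mapping_quality = 20))
  expect_equal(sum(cts2$counts), 2)

  # flag-skipped reads not counted; conservation of the rest
  al2 <- data.frame(chrom = "chr1", pos = c(1e6, 2e6, 3e6), mapq = 60,
                    duplicate = c(FALSE, TRUE, FALSE))
  cts3 <- suppressMessages(count_reads(al2, grid))
  expect_equal(sum(cts3$counts), 2)

  # unknown chromosome skipped with a warning
  al3 <- data.frame(chrom = c("chr1", "chrZ"), pos = 1e6, mapq = 60)
  expect_warning(suppressMessages(count_reads(al3, grid)), "chrZ")
  expect_error(suppressMessages(count_reads(al3, grid,
                                            unknown_chrom = "error")), "chrZ")
})

test_that("uniform reads distribute binomially across bins", {
  # 1e4 uniform reads over 10 bins: each bin Binomial(1e4, 0.1),
  # sd = sqrt(1e4 * .1 * .9) = 30; all bins within 5 sd of 1e3
  g <- one_chrom_genome(10e6)
  grid <- make_bin_grid(g, 1e6, gc_source = flat_gc)
  set.seed(42)
  al <- data.frame(chrom = "chr1", pos = runif(1e4, 0, 10e6 - 1), mapq = 60)
  cts <- suppressMessages(count_reads(al, grid))
  expect_equal(sum(cts$counts), 1e4)
  expect_true(all(abs(cts$counts - 1e3) < 5 * 30))
})

test_that("BAM counting agrees with the data.frame path", {
  skip_if_not_installed("Rsamtools")
  g <- one_chrom_genome(10e6)
  grid <- make_bin_grid(g, 1e6, gc_source = flat_gc)
  sam <- tempfile(fileext = ".sam")
  # 3 reads: two in bin 1, one in bin 2 (SAM POS is 1-based)
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000000",
    "r1\t0\tchr1\t100001\t60\t75M\t*\t0\t0\t*\t*",
    "r2\t0\tchr1\t900001\t60\t75M\t*\t0\t0\t*\t*",
    "r3\t0\tchr1\t1200001\t60\t75M\t*\t0\t0\t*\t*"), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  cts <- suppressMessages(count_reads(bam, grid))
  expect_equal(cts$counts, c(2, 1, rep(0, 8)))
})

test_that("bin-count files round-trip and are validated against the grid", {
  g <- one_chrom_genome(5e6)
  grid <- make_bin_grid(g, 1e6, gc_source = flat_gc)
  cts <- bin_counts("s1", grid, c(5, 0, 3, 2, 1))
  path <- tempfile(fileext = ".tsv")
  write_bin_counts(cts, path)
  back <- read_bin_counts(path, grid, sample_id = "s1")
  expect_equal(back$counts, cts$counts)

  # negative count rejected with line number
  tab <- read.table(path, header = TRUE, sep = "\t")
  tab$count[3] <- -1
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_bin_counts(path, grid), "line 4")

  # grid mismatch reported with the first offending interval
  tab$count[3] <- 3
  tab$start[2] <- 999
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_bin_counts(path, grid), "bin 2")
})

test_that("aggregation to coarser grids conserves counts", {
  g <- small_genome()
  fine <- make_bin_grid(g, 0.5e6, gc_source = flat_gc)
  for (bs in c(1e6, 2.5e6)) {
    coarse <- make_bin_grid(g, bs, gc_source = flat_gc)
    set.seed(3)
    cts <- bin_counts("s", fine, rpois(nrow(fine), 50))
    agg <- aggregate_counts(cts, coarse)
    expect_equal(sum(agg$counts), sum(cts$counts))
    # spot-check one coarse bin by direct summation
    sel <- fine$chrom == "chrB" & fine$start >= 0 & fine$end <= bs
    expect_equal(agg$counts[which(coarse$chrom == "chrB")[1]],
                 sum(cts$counts[sel]))
  }
})
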
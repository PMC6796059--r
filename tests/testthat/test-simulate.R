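test_that("simulated counts are reproducible from config plus seed", {
  g <- small_genome()
  grid <- make_bin_grid(g, 0.5e6)
  kary <- data.frame(chrom = "chrA", start = 0, end = 20e6, copy = 1)
  cfg <- sim_config(genome = g, carrier_karyotype = kary, seed = 17,
                    extra_cnv_rate = 1)
  t1 <- simulate_population(cfg, 6, grid)
  t2 <- simulate_population(cfg, 6, grid)
  expect_identical(lapply(t1$counts, `[[`, "counts"),
                   lapply(t2$counts, `[[`, "counts"))
  expect_identical(lapply(t1$specs, `[[`, "karyotype"),
                   lapply(t2$specs, `[[`, "karyotype"))

  # different seed, different counts
  t3 <- simulate_population(sim_config(genome = g, carrier_karyotype = kary,
                                       seed = 18, extra_cnv_rate = 1),
                            6, grid)
  expect_false(identical(lapply(t1$counts, `[[`, "counts"),
                         lapply(t3$counts, `[[`, "counts")))
})

test_that("per-bin expectations follow the copy-weighted rate model", {
  # flat diploid, near-zero dispersion, no GC slope: every usable bin
  # expects total/N counts, observed within 5 binomial sd
  g <- small_genome()
  grid <- make_bin_grid(g, 0.5e6, gc_source = flat_gc)
  cfg <- sim_config(genome = g, gc_slope = 0,
                    dispersion = c(high = 1e-9), seed = 1)
  spec <- list(cell_id = "c", karyotype = NULL, quality_tier = "high",
               total_reads = 1e6)
  set.seed(71)
  cts <- simulate_cell(spec, cfg, grid)
  usable <- !grid$excluded
  n <- sum(usable)
  mu <- 1e6 / n
  sd_bin <- sqrt(1e6 * (1 / n) * (1 - 1 / n))
  expect_true(all(abs(cts$counts[usable] - mu) < 5 * sd_bin))
  expect_true(all(cts$counts[!usable] == 0))
  expect_equal(sum(cts$counts), 1e6)

  # a copy-3 region runs 1.5x hotter than the diploid background
  kary <- data.frame(chrom = "chrB", start = 0, end = 18e6, copy = 3)
  spec3 <- list(cell_id = "c", karyotype = kary, quality_tier = "high",
                total_reads = 2e6)
  cts3 <- simulate_cell(spec3, cfg, grid)
  in3 <- grid$chrom == "chrB" & grid$end <= 18e6 & usable
  ratio <- mean(cts3$counts[in3]) / mean(cts3$counts[usable & !in3])
  expect_equal(ratio, 1.5, tolerance = 0.05)
})

test_that("population truth sets hit the exact carrier count", {
  g <- small_genome()
  grid <- make_bin_grid(g, 2.5e6)
  kary <- data.frame(chrom = "chrA", start = 0, end = 20e6, copy = 1)
  cfg <- sim_config(genome = g, carrier_fraction = 40 / 56,
                    carrier_karyotype = kary, seed = 3,
                    extra_cnv_rate = 0, reads_mean = 2e5, reads_sd = 0)
  truth <- simulate_population(cfg, 56, grid)
  carriers <- vapply(truth$specs, `[[`, logical(1), "carrier")
  expect_equal(sum(carriers), 40)
  # no extra CNVs at rate 0
  extras <- lapply(truth$specs, `[[`, "extra_cnvs")
  expect_true(all(vapply(extras, is.null, logical(1))))
})

test_that("extra CNVs avoid chr20, chrY and centromere spanning", {
  cfg <- sim_config(seed = 9, extra_cnv_rate = 3, reads_mean = 2e5,
                    reads_sd = 0, tier_proportions = c(high = 1))
  grid <- make_bin_grid(cfg$genome, 2.5e6)
  truth <- simulate_population(cfg, 12, grid)
  cen <- setNames(cfg$genome$chromosomes$centromere_mid,
                  cfg$genome$chromosomes$chrom)
  for (sp in truth$specs) {
    ex <- sp$extra_cnvs
    if (is.null(ex) || !nrow(ex)) next
    expect_false(any(ex$chrom %in% c("chr20", "chrY")))
    seg <- ex[!ex$whole, , drop = FALSE]
    if (nrow(seg))
      expect_true(all(seg$end <= cen[seg$chrom] | seg$start >= cen[seg$chrom]))
  }
})

test_that("bulk counts carry the mixture copy number in expectation", {
  g <- grch38_genome()
  grid <- make_bin_grid(g, 2.5e6, gc_source = flat_gc)
  cfg <- sim_config(genome = g, seed = 2, extra_cnv_rate = 0)
  truth <- simulate_population(cfg, 56, grid)
  set.seed(72)
  bulk <- simulate_bulk(truth, 2e6, grid, bulk_dispersion = 1e-9)
  usable <- !grid$excluded
  p_arm <- grid$chrom == "chr20" & grid$end <= 25e6 & usable
  q_arm <- grid$chrom == "chr20" & grid$start >= 30e6 & usable
  auto <- usable & !grid$chrom %in% c("chr20", "chrX", "chrY")
  mu_auto <- mean(bulk$counts[auto])
  # carried fraction f = 40/56: 20p at (2-f)/2 of diploid, 20q at (2+f)/2
  f <- 40 / 56
  expect_equal(mean(bulk$counts[p_arm]) / mu_auto, (2 - f) / 2,
               tolerance = 0.05)
  expect_equal(mean(bulk$counts[q_arm]) / mu_auto, (2 + f) / 2,
               tolerance = 0.05)

  # pure carrier population: p-arm at half, q-arm at 1.5x
  all_carr <- simulate_population(sim_config(genome = g, carrier_fraction = 1,
                                             extra_cnv_rate = 0, seed = 4),
                                  8, grid)
  bulk2 <- simulate_bulk(all_carr, 2e6, grid, bulk_dispersion = 1e-9)
  expect_equal(mean(bulk2$counts[p_arm]) / mean(bulk2$counts[auto]), 0.5,
               tolerance = 0.05)
  expect_equal(mean(bulk2$counts[q_arm]) / mean(bulk2$counts[auto]), 1.5,
               tolerance = 0.05)
})

test_that("truth sets serialize to readable per-cell files", {
  g <- small_genome()
  grid <- make_bin_grid(g, 2.5e6)
  cfg <- sim_config(genome = g,
                    carrier_karyotype = data.frame(chrom = "chrA", start = 0,
                                                   end = 20e6, copy = 1),
                    seed = 21, reads_mean = 1e5, reads_sd = 0)
  truth <- simulate_population(cfg, 3, grid)
  dir <- tempfile()
  write_truth_set(truth, dir)
  files <- list.files(dir)
  expect_true("truth.tsv" %in% files)
  back <- read_bin_counts(file.path(dir, "cell01_counts.tsv"), grid)
  expect_equal(back$counts, truth$counts[[1]]$counts)
})
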
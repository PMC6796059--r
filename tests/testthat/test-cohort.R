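test_that("the packaged cohort table has the published shape", {
  calls <- read_cnv_table(table1_path())
  expect_equal(nrow(calls), 50)                      # 50 CNV records
  expect_equal(length(unique(calls$cell)), 13)       # across 13 cells
  expect_true(all(calls$end > calls$start))
  expect_true(all(calls$size_mb > 0))
})

test_that("recorded and catalogue-derived fragile fractions agree at 40%", {
  calls <- read_cnv_table(table1_path())

  # route 1: the per-end site columns transcribed in the table
  ann_tab <- table_annotations(calls)
  fr_tab <- fragile_fraction(ann_tab)
  expect_equal(fr_tab$n_breakpoints, 60)
  expect_equal(fr_tab$n_within, 24)
  expect_equal(fr_tab$fraction, 0.4)

  # route 2: re-annotate the breakpoints against the synthetic catalogue
  sites <- load_fragile_sites(fragile_bed_path())
  ann_bed <- annotate_breakpoints(calls, sites)
  fr_bed <- fragile_fraction(ann_bed)
  expect_equal(fr_bed$n_breakpoints, 60)
  expect_equal(fr_bed$n_within, 24)
  expect_equal(fr_bed$fraction, 0.4)

  # the two routes annotate the same breakpoints with the same sites
  key <- function(a) paste(a$cell, a$chrom, a$which_end, a$breakpoint)
  m <- match(key(ann_tab), key(ann_bed))
  expect_false(anyNA(m))
  within_tab <- ann_tab$status == "within"
  expect_equal(ann_bed$status[m] == "within", within_tab)
  expect_equal(ann_bed$site[m][within_tab], ann_tab$site[within_tab])
})

test_that("recurrence scan finds the known multi-cell aberrations", {
  calls <- read_cnv_table(table1_path())
  rec <- recurrence_scan(calls)
  chr3 <- rec[rec$chrom == "chr3" & rec$direction == "gain", ]
  expect_equal(nrow(chr3), 1)
  expect_equal(chr3$n_cells, 4)                      # cells 2, 3, 4, 5
  expect_equal(chr3$start, 60.5e6)
  expect_equal(chr3$end, 69.5e6)
  expect_equal((chr3$end - chr3$start) / 1e6, 9)

  chr5 <- rec[rec$chrom == "chr5" & rec$direction == "loss", ]
  expect_equal(chr5$n_cells, 2)                      # q-arm loss, cells 9, 12

  # opposite directions never group
  two <- data.frame(cell = c("a", "b"), chrom = "chr2", start = 10e6,
                    end = 30e6, size_mb = 20, direction = c("gain", "loss"),
                    mean_copy = c(3, 1), n_bins = 20L,
                    cnv_class = "segmental", start_terminal = FALSE,
                    end_terminal = FALSE)
  expect_equal(nrow(recurrence_scan(two)), 0)
  # a single cell can never be recurrent
  expect_equal(nrow(recurrence_scan(two[1, ])), 0)
})

test_that("cohort tabulation counts burden, complex and chaotic cells", {
  calls <- read_cnv_table(table1_path())
  tab <- tabulate_cohort(calls)
  expect_equal(tab$n_cnvs, 50)
  expect_equal(tab$n_cells_with_cnv, 13)
  expect_equal(sum(tab$class_counts), 50)
  expect_equal(unname(tab$class_counts["trisomy"]), 3)
  complex_cells <- tab$per_cell$cell[tab$per_cell$complex]
  expect_setequal(complex_cells, c("1", "6", "9", "12"))
  chaotic_cells <- tab$per_cell$cell[tab$per_cell$chaotic]
  expect_equal(chaotic_cells, "12")                  # 14 aberrations

  empty <- tabulate_cohort(calls[0, ], cells = c("a", "b"))
  expect_equal(empty$n_cnvs, 0)
  expect_equal(sum(empty$class_counts), 0)
  expect_equal(empty$per_cell$n_cnvs, c(0, 0))
})

test_that("carrier fractions count cells matching either query arm", {
  g <- grch38_genome()
  iso <- iso20_karyotype(g)
  p_loss <- data.frame(cell = "c1", chrom = "chr20", start = 0, end = 25e6,
                       size_mb = 25, direction = "loss", mean_copy = 1,
                       n_bins = 25L, cnv_class = "segmental",
                       start_terminal = TRUE, end_terminal = FALSE)
  q_gain <- transform(p_loss, cell = "c2", start = 30e6, end = 64.44e6,
                      direction = "gain", mean_copy = 3)
  other <- transform(p_loss, cell = "c3", chrom = "chr5")
  calls <- rbind(p_loss, q_gain, other)

  mos <- mosaicism_fraction(calls, cells = c("c1", "c2", "c3", "c4"), iso)
  expect_equal(mos$n_carriers, 2)                    # either arm suffices
  expect_equal(mos$n_cells, 4)                       # cells without calls count
  expect_equal(mos$fraction, 0.5)
  expect_setequal(mos$carriers, c("c1", "c2"))

  # invariant to cell order and duplicate matching calls
  mos2 <- mosaicism_fraction(rbind(calls, p_loss),
                             cells = c("c4", "c3", "c2", "c1"), iso)
  expect_equal(mos2$n_carriers, 2)
  expect_error(mosaicism_fraction(calls, character(), iso), "empty cohort")
})

test_that("bulk mixture predictions are linear in the carrier fraction", {
  expect_equal(bulk_expected_copy(0, 1), 2)
  expect_equal(bulk_expected_copy(1, 1), 1)
  expect_equal(bulk_expected_copy(40 / 56, 1), 2 - 40 / 56)
  expect_equal(round(bulk_expected_copy(40 / 56, 1), 1), 1.3)
  # linear in f, monotone in carrier copy
  f <- seq(0, 1, by = 0.1)
  expect_equal(diff(bulk_expected_copy(f, 3)), rep(0.1, 10))
  expect_true(all(bulk_expected_copy(0.5, 1:4) == seq(1.5, 3, by = 0.5)))
  expect_error(bulk_expected_copy(1.2, 1), "\\[0, 1\\]")
})
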
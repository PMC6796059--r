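#!/usr/bin/env Rscript
# Simulate the study cohort: 56 single cells from a mosaic iso(20q) line
# (40/56 carriers), with WGA overdispersion at mixed quality tiers, plus a
# pooled bulk library. Per-cell bin counts (large) go to scratch/; the
# truth table and the resolved configuration go to results/.

suppressPackageStartupMessages(library(scmosaic))

seed <- 20190423L
out_scratch <- "scratch/simulated_cohort"
dir.create("results", showWarnings = FALSE)
dir.create(out_scratch, showWarnings = FALSE, recursive = TRUE)

genome <- grch38_genome()
grid <- make_bin_grid(genome, 0.5e6)
cfg <- sim_config(genome = genome,
                  tier_proportions = c(high = 0.16, mid = 0.55, low = 0.29),
                  seed = seed)
truth <- simulate_population(cfg, 56, grid)
truth_path <- write_truth_set(truth, out_scratch)

set.seed(seed + 1)
bulk <- simulate_bulk(truth, 2e6, grid)
write_bin_counts(bulk, file.path(out_scratch, "bulk_counts.tsv"))

file.copy(truth_path, "results/simulated_truth.tsv", overwrite = TRUE)

tiers <- table(vapply(truth$specs, `[[`, character(1), "quality_tier"))
carriers <- sum(vapply(truth$specs, `[[`, logical(1), "carrier"))
n_extra <- sum(vapply(truth$specs, function(s)
  if (is.null(s$extra_cnvs)) 0L else nrow(s$extra_cnvs), integer(1)))
cat(sprintf("simulated 56 cells: %d iso20 carriers, %d extra CNVs\n",
            carriers, n_extra))
cat("quality tiers:", paste(names(tiers), tiers, sep = "=", collapse = ", "),
    "\n")
cat("per-cell counts under", out_scratch, "\n")
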
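---
title: "Detecting low-level mosaicism from single-cell shallow sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting low-level mosaicism from single-cell shallow sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmosaic)
```

## The problem

Cultured pluripotent stem-cell lines accumulate copy-number variants
(CNVs) that spread through the culture as mosaic subpopulations. Bulk
assays see only the population average: a one-copy arm loss carried by
70% of cells shows up as copy 1.3, and a CNV carried by a few percent of
cells disappears entirely. Sequencing many single cells at shallow depth
(a few million reads each, after whole-genome amplification) resolves the
per-cell karyotype at megabase resolution and lets the carrier fraction of
each aberration be counted directly.

`scmosaic` implements the complete in-silico part of such an experiment:
binned read counts → GC normalization → outlier smoothing → circular
binary segmentation (CBS) → absolute copy scaling → per-sample bin-size
quality control → CNV calling → fragile-site breakpoint annotation →
cohort-level mosaicism statistics. A companion simulator generates
single-cell and bulk counts with known ground truth so that every stage,
and the pipeline end to end, is testable without sequencing data.

## The per-cell model

Reads are counted into fixed bins of 0.5, 1 or 2.5 Mb (0-based half-open
coordinates; bins overlapping "difficult to sequence" regions by ≥ 50%
are excluded). For a cell with per-bin integer copy $c_i$, observed
counts are modelled as multinomial with relative rates

$$ r_i = c_i\,\bigl(1 + \beta\,(g_i - 0.40)\bigr)\, a_i,
   \qquad a_i \sim \Gamma(1/d,\, d), $$

where $g_i$ is the bin GC fraction, $\beta$ a linear GC amplification
bias, and $a_i$ a multiplicative whole-genome-amplification (WGA) noise
factor with mean 1 and variance $d$ (marginally, counts are negative
binomial). The pipeline inverts this model step by step:

1. **GC normalization** (`gc_normalize`). A lowess fit (span 0.3) of
   $\log_2(\text{count}+0.5)$ on GC over usable bins is subtracted and
   the result recentred so the genome median ratio is 1. The 0.5
   pseudocount keeps zero-count bins defined; zero-count bins at extreme
   GC (< 0.28 or > 0.68) are masked as amplification dropouts. A local
   rather than parametric fit is used because CNVs occupying < 30% of
   bins barely perturb it. At least 100 usable positive bins are
   required.

2. **Outlier smoothing** (`smooth_outliers`). Isolated single-bin
   excursions beyond 3 MAD-based standard deviations from the running
   median (window 10 bins) are winsorized to the threshold. Both
   neighbours must be unremarkable, so runs of ≥ 2 deviating bins — real
   CNV signal — are never eroded, and the operation is idempotent.

3. **Segmentation** (`segment_cbs`). Recursive CBS per chromosome on
   log2 values: the arc maximizing a two-sample t-like statistic is
   tested by permutation (default 10,000 permutations, $\alpha = 0.05$,
   with early stopping once significance is impossible); a split is
   accepted only if every resulting piece keeps ≥ 5 bins. Ties go to the
   earliest, shortest arc. The permutation generator is driven by the R
   seed, making "default parameters" reproducible. The scan and
   permutation loop are implemented in C++ (`src/cbs.cpp`).

4. **Segment medians** (`apply_segment_medians`). Bin ratios are
   replaced by their segment's median normalized ratio; the pre-median
   per-bin values are retained for quality control.

5. **Copy scaling** (`fit_copy_scaling`). A scaling factor $s$ (copies
   per unit median-normalized ratio) is scanned over [1.5, 3] in steps
   of 0.001, minimizing the segment-weighted sum of squares
   $\sum_k n_k\,(s m_k - \mathrm{round}(s m_k))^2$ over segment medians
   $m_k$. Ties break towards $s = 2$ (diploid-modal assumption). Copies
   are deliberately *not* rounded afterwards — in a mosaic bulk sample
   the informative signal is precisely the fractional copy number. The
   search interval excludes degenerate near-zero solutions; for
   non-diploid-modal genomes it is configurable.

## Bin-size quality control

WGA noise varies hugely between cells. Following the clustering
criterion of the experimental protocol this pipeline reproduces, each
cell is scored at all three bin sizes by the fraction of usable bins
whose continuous copy value lies within ±0.25 (closed window) of an
integer copy in {1, 2, 3}; the smallest bin size whose fraction
*strictly* exceeds its threshold (> 0.80 at 0.5 Mb, > 0.62 at 1 Mb,
> 0.58 at 2.5 Mb) is used for calling, and a cell passing at none fails
QC. Per-bin (pre-segment-median) copies are scored — segment medians
would cluster trivially. The fractions are computed post-smoothing; the
protocol text does not fix this, and the choice is recorded here.

## CNV calling

On the chosen bin size, maximal runs of consecutive usable bins
deviating from the per-chromosome baseline (2 for autosomes; 1 for X and
Y in an XY line — deviations, not absolute copies, so a male X loss is
callable) by at least +0.65 (gains at 0.5/1 Mb), +0.55 (gains at
2.5 Mb) or −0.65 (losses, all sizes) become calls when the run has ≥ 8
usable bins *and* spans ≥ 8 Mb (≥ 20 Mb at 2.5 Mb bins). Masked bins
inside a run neither break it nor count toward the 8-bin minimum. Calls
covering ≥ 95% of a chromosome's usable bins are whole-chromosome
(trisomy/monosomy); endpoints at the first/last usable bin edge are
terminal. An expected karyotype (e.g. the iso(20q): 20p loss + 20q gain)
is subtracted by reciprocal-overlap matching (≥ 0.5, same chromosome and
direction); what remains are the cell's *additional* CNVs. A cell
counts as an expected-karyotype carrier if either arm-event matches —
the published analysis is ambiguous on cells where only one arm was
called, and this package resolves the ambiguity permissively and
records it.

## Fragile sites and cohort statistics

Each non-terminal breakpoint (the call's outer bin edge, so resolution
is ±1 bin) is assigned to its nearest catalogued fragile site: `within`
if inside the interval, `proximal` if ≤ 2.5 Mb away, else `none`;
terminal endpoints are chromosome ends, not breakpoints, and are
excluded from the denominator. The cohort layer counts carrier
fractions over *analysed* (QC-passing) cells, tabulates class counts
and per-cell burden (≥ 4 aberrations: complex; ≥ 10: chaotic), groups
recurrent segmental aberrations across cells by reciprocal overlap, and
converts carrier fractions to bulk copy predictions via the mixture
expectation $(1-f)\,c_{\text{base}} + f\,c_{\text{carrier}}$.

The package bundles two small plain-text reference tables:
`table1_cnvs.tsv`, a transcription of the published per-cell call set of
a 56-cell iso(20q) cohort (13 cells carrying 50 additional CNVs; 60
non-terminal breakpoints, 24 within fragile sites), and
`fragile_sites_synthetic.bed`, a *synthetic* fragile-site catalogue: one
interval per site named in that table, positioned to be consistent with
its recorded assignments. The real HumanCFS catalogue is deliberately
not redistributed; any BED4 file can be supplied in its place.

## The simulator and what it does (not) emulate

`simulate_population()` draws per-cell totals from a truncated normal
(3.92 ± 1.33 million reads), gives exactly `round(f · n)` cells the
carrier karyotype, adds Poisson-distributed extra CNVs (log-uniform
8–100 Mb, a 16% minority whole-chromosome; placement avoids chr20, chrY
and centromere-spanning intervals so truth stays unambiguous), and
assigns quality tiers. Tier dispersions (0.004 / 0.02 / 0.06 / 0.3 at
the 0.5 Mb grid) were derived once from the count model: with per-bin
mean $\mu$ the copy-value CV is $\sqrt{1/\mu + d}$, and summing $k$ fine
bins dilutes $d$ by $1/k$, which places the four tiers on the expected
sides of the 0.80 / 0.62 / 0.58 clustering thresholds at 0.5 / 1 /
2.5 Mb for ~3.9 M reads. Counts are simulated once on the 0.5 Mb grid
and aggregated to coarser grids, as real reads would be.

The simulator emulates the *statistical* structure the pipeline assumes
— GC bias, gamma overdispersion, multinomial sampling, exclusion zones —
not real WGA artefact structure: no spatially correlated amplification
waves, no chimeric amplicons, no mappability gradients beyond the binary
exclusion mask, and GC is a smooth synthetic track rather than measured
sequence composition. Passing end-to-end tests therefore demonstrates
correctness of the inference given the model, not robustness to every
real-data pathology.

## Numerical choices and edge cases

* Exclusion zones in the packaged GRCh38-like genome model are 5
  Mb-aligned (centromere windows, acrocentric p-arms, chrY
  heterochromatin) so no bin at any of the three sizes is partially
  excluded and fine-to-coarse aggregation is exact.
* The CBS split statistic uses the piece's global variance, so it is
  invariant under adding a constant to all log2 values; near-constant
  pieces (sd < 1e-12) never split. Permutation p-values use the
  (1 + exceedances)/(1 + permutations) convention.
* The min-bins rule constrains *segment* sizes, not event sizes: a
  sufficiently strong 4-bin step can still induce a split via a 5-bin
  arc straddling it. No segment below `min_bins` is ever produced, and
  sub-8-bin events can never become calls.
* A chromosome with fewer usable bins than `min_bins` forms a single
  segment with a warning; a sample with fewer than 100 usable positive
  bins is rejected outright.
* SSE ties in copy scaling (exactly degenerate flat profiles) resolve
  to the candidate nearest 2, then the smaller value.
* Cells whose pipeline errors are marked failed with a reason and do not
  abort the cohort run; they are excluded from the analysed denominator,
  as QC failures are.

## Problem sizes used in the tests

The packaged test suite exercises the full pipeline at the cohort scale
the method targets — 56 cells, three bin sizes, whole GRCh38-scale
genome — with CBS at 2,000 permutations, and the segmentation oracle
comparison on 200 two-level signals of 100 bins plus 200 pure-noise
profiles at 300 permutations. Unit tests run on one-to-three-chromosome
toy genomes where expected values are computable by enumeration or in
closed form. These sizes were chosen so the full suite completes in
minutes on a single core while keeping every statistical check
adequately powered.

## Known limitations

* Breakpoint resolution is one bin (0.5–2.5 Mb); sub-resolution events
  such as recurrent ~1 Mb amplicons are out of scope by design.
* Cells are modelled as single genomes: no within-cell subclonal
  fraction deconvolution.
* The copy-scaling search assumes a diploid-modal genome unless the
  interval is reconfigured; tetraploid cells would be mis-scaled.
* Only the clustering-based QC metric is implemented; read-level QC
  (duplication rates, MAPD) belongs upstream.
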
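---
title: "Detecting a lymphoid deletion signature in array CGH cohorts"
author: "acghsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a lymphoid deletion signature in array CGH cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acghsig)
```

## The problem

Chronic myeloid leukemia (CML) progresses from a chronic phase into a myeloid
or lymphoid blast crisis. Oligonucleotide array CGH of such cohorts measures,
at each of ~10^5 probes, the fluorescence ratio (FR) of test over pooled
reference DNA: ~1.0 at a diploid locus, below 1 for genomic loss, above 1 for
gain, attenuated towards 1 when only a fraction of cells carries the event.
Lymphoid blast crisis is characterized by a recurrent *deletion signature*:
near-universal losses within the antigen-receptor loci (IGH at 14q32.33,
TCRA/D at 14q11.2, TCRG at 7p14.1) and IKZF1 at 7p12, accompanied in a subset
of samples by concomitant segmental losses of 7p12-14 and 9p13-24.1.

`acghsig` implements the complete analysis that detects such a signature —
per-sample noise estimation, probe calling, a recurrence screen with CNV
masking, a two-class permutation SAM, clustering and region-level
classification — together with a synthetic cohort generator that plants the
signature with known truth, so every stage can be validated end to end.

## Working on the simple-ratio scale

All statistics operate on the simple ratio, not its logarithm. A deletion of
`c` copies present in a fraction `f` of cells has expected ratio

$$\mathrm{FR} = \frac{2 + c\,f}{2},$$

so effects are linear in the clonal fraction and events carried by independent
subclones of one sample compose additively in `c*f` before conversion to a
ratio (`expected_ratio()`). Additive Gaussian noise on this scale, with a
per-sample SD, is the package's noise model throughout.

## Per-sample noise: iterative sigma clipping with a consistency factor

`robust_sd()` alternates median centring, rescaled SD estimation and
rejection of points beyond `k_reject = 3` estimated SDs, until the retained
set stabilizes. Two numerical choices matter:

* **Gaussian consistency.** The SD of a normal sample truncated at ±3σ is
  0.9866σ, and iterating the clip drives the raw retained-set SD to ~0.985σ
  even on perfectly clean data. The estimator therefore multiplies the
  retained-set SD by $1/\sqrt{1 - 2k\,\varphi(k)/(2\Phi(k)-1)}$ (the analogue
  of the MAD's 1.4826), which makes it unbiased under normality. This is not
  cosmetic: calls are made at ±4 SD, where a 1.5% downward bias in the SD
  inflates the false-call rate by ~30%. The correction can be disabled
  (`consistency = FALSE`). A side effect is that on pristine data the robust
  SD can exceed the plain SD by up to the ~1.4% correction factor; whenever
  outliers are actually present it sits far below it.
* **Re-admission.** Rejection is recomputed from the full sample at every
  iteration, so the procedure converges to a fixed point rather than a
  monotonically shrinking set; constant vectors converge in one iteration
  with SD 0 and a degeneracy warning.

Calls (`call_matrix()`) are centred on the robust centre rather than on 1.0
exactly, absorbing residual normalization offsets. The preliminary screen uses
`k = 4`; region-level display calls use `k = 3`.

## The recurrence screen

`recurrent_adjacent_loci()` looks, within each sample, for runs of at least
`min_adjacent = 2` genome-adjacent probes called in the *same* direction
(mixed-sign adjacent outliers are noise; missing cells break runs; runs never
span a chromosome boundary). A window qualifies when at least
`min_samples = 3` samples support it, counted over the whole analysed cohort;
consecutive qualifying windows merge into maximal loci and the unmerged
window count is retained as a diagnostic. `apply_cnv_mask()` then removes any
locus overlapping (≥ 1 bp) a merged mask of known copy-number-variable
regions — polymorphic germline CNVs recur across classes and would otherwise
dominate a recurrence screen. Sex chromosomes are dropped before any
statistics (`drop_sex_chromosomes()`) because the design uses a sex-mismatched
pooled reference that leaves X/Y ratios off-centre by construction.

## Two-class SAM

`sam_twoclass()` implements the two-class unpaired Significance Analysis of
Microarrays from scratch. For probe *i*,

$$d_i = \frac{\bar x_{i2} - \bar x_{i1}}{s_i + s_0},\qquad
s_i = \sqrt{\tfrac{1}{n_1}+\tfrac{1}{n_2}}
      \sqrt{\frac{\sum_1 (x-\bar x_{i1})^2 + \sum_2 (x-\bar x_{i2})^2}
            {n_1+n_2-2}},$$

with missing cells excluded per probe and class sizes recomputed. The fudge
factor `s0` is chosen by the standard percentile search (0th-100th in steps
of 5) minimizing the coefficient of variation of the within-window MAD of
`d` across s-quantile windows (`choose_s0()`); a fixed `s0` can be supplied.
The permutation null (`permutation_null()`) recomputes `d` under label
arrangements — all `choose(n, n2)` of them when at most 10,000 (complement
arrangements included), otherwise `B = 1000` sampled uniformly under the
configured seed — and averages sorted permuted statistics into the expected
order statistics `dbarE`. The bulk computation reduces each permutation to a
handful of matrix products, so B = 1000 on a 10,000-probe, 74-sample matrix
takes seconds.

`fdr_table()` applies asymmetric cutpoints: at threshold delta the upper cut
is the smallest observed `d` whose gap over `dbarE` reaches delta, the lower
cut the largest `d` at least delta below it; everything beyond a cut is
called, and the FDR is the summarized count of permuted values beyond the
cuts divided by the number called (capped at 1). Two selection rules are
distinct operations, as in SAM practice: `select_fdr_zero()` returns the
called set at the smallest delta with estimated FDR exactly 0, and
`top_by_delta_gap()` ranks probes by `|d - dbarE|` at their rank (ties broken
by `|d|`, then genome address).

**Choice of false-count summary.** The per-permutation false-call counts can
be summarized by their mean, median or 90th percentile (`fdr_convention`).
The default is the **mean** — the original SAM averaging rule — and the
choice is deliberate: an FDR of exactly 0 should mean that permutations
essentially never produce a value beyond the cutpoints. With the median, the
most extreme observed order statistic exceeds the median of the permutation
maxima in about half of *null* datasets, so "FDR = 0" sets of one or two
noise probes appear in roughly 40% of pure-noise cohorts; with the mean, a
single exceedance in any of the B permutations keeps the estimate positive,
and the FDR = 0 set stays empty on null data (0 of 20 null cohorts in the
acceptance suite). The median and 90th-percentile summaries remain available
for comparison with other implementations.

No correction for the proportion of true nulls is applied; the delta-table
FDR is reported raw.

## Clustering and the region signature

`hierarchical_cluster()` clusters sample columns of the selected-probe
submatrix (average linkage, Euclidean distance; probe-wise median imputation
of missing cells). `write_newick()` serializes the dendrogram with branch
lengths equal to merge-height differences, so cophenetic structure is fully
preserved and any Newick parser recovers the same partitions.

`region_deletion_flag()` flags a sample as deleted in a region when at least
`min_fraction = 0.5` of the region's probes carry call −1 (all probes
missing gives `no_data`). The default region set
(`default_signature_regions()`) names the four signature regions with
gene-level primary members (IGH, TCRA/D, TCRG, IKZF1) and the two broader
secondary members (7p12-14 excluding the gene loci, and 9p — both the
9p13-24.1 and the narrower 9p21-24 extent are shipped, as the literature uses
both). A sample carries the *concomitant loss* exactly when every
secondary-role region is deleted (`classify_concomitant()`), which is
monotone in the flags by construction. `cohort_summary()` reports per-region
deletion counts and fractions over a target class. The 0.5 fraction threshold
is configurable; with the generator's fully deleted regions the downstream
tests are insensitive to it.

## What the synthetic cohort emulates

`simulation_config()` defaults encode the study conditions the package is
validated against:

* **Cohort**: 92 samples — 78 CML (38 chronic phase, 6 accelerated, 10
  lymphoid and 15 myeloid blast crisis, 2 mixed-lineage, 7 unclassified) and
  14 controls. The published per-stage counts sum to 71 CML of 78; the seven
  unaccounted hybridizations are assigned to the chronic phase, consistent
  with the seven patients contributing paired chronic/blast samples.
* **Grid**: ~105,000 probes allocated to chromosomes by length
  (largest-remainder rounding), evenly spaced with jitter. The desk-scale
  `demo_simulation_config()` keeps array-like density by restricting the
  genome to the signature chromosomes (7, 9, 14) plus a neutral autosome and
  the sex chromosomes, with 10,000 probes — the problem size used by the
  examples, the test suite and the acceptance script.
* **Noise**: per-sample SD drawn uniformly from 0.057-0.187, the printed
  range of per-sample FR standard deviations; Gaussian, independent across
  probes. Probe-to-probe autocorrelation is not characterized in the source
  data and is assumed absent.
* **Signature**: planted only in lymphoid-class samples (BCL, BCmix) —
  primary regions in every lymphoid sample, the secondary 7p/9p pair jointly
  in `n_concomitant = 7` of them, mirroring the 7-of-12 concomitant subset.
  Deletions are planted as complete loss of the region in the carrier clone
  (`copy_change = -2`) at clonal fraction U(0.8, 1). Complete loss is the
  natural model for the antigen-receptor loci, where V(D)J recombination
  removes the intervening segments on both alleles of a clonal lymphoid
  population, and it makes region-level recovery depend on the clonal
  fraction rather than on zygosity: a heterozygous deletion deviates by at
  most 0.5, which is *below* the ±3 SD call threshold for samples in the
  upper part of the 0.057-0.187 noise range (3 × 0.187 = 0.561) — such
  events are intrinsically uncallable per probe at that noise level, a
  limitation of ±k·SD calling worth keeping in mind with real data.
  Per-region copy change and clonal-fraction bounds are configurable.
* **CNV polymorphisms**: a fixed set of loci applied to samples of *all*
  classes at stated population frequencies (one adjacent to IGH, mimicking
  the CNV-like behaviour seen next to true signature loci).
* **Sex chromosomes**: crude off-centre ratios per sex, standing in for the
  sex-mismatched reference; the pipeline drops them, the generator does not.

The generator does **not** emulate two-channel intensities, dye bias or dye
swaps (the FR matrix represents already-merged ratios), GC waves, spatial
artifacts, or paired longitudinal sampling of one genome. Passing tests on
this cohort therefore demonstrate the statistical machinery — calling,
screening, SAM, classification — under honest noise levels, not robustness
to array-specific systematic error, which real data would add on top.

## Numerical choices and degenerate inputs

* FR values serialize at 6 significant digits; all downstream comparisons use
  tolerances, never string equality. Intervals are 0-based half-open on disk
  and in memory.
* The delta grid defaults to 50 evenly spaced values from 0 to the largest
  observed |gap| (the endpoint included exactly).
* Ties in the delta-gap ranking break by `|d|`, then genome address, then
  probe id; the s0 percentile search breaks ties toward the smaller
  percentile; a flat scatter vector returns the common value as `s0`.
* Degenerate inputs fail loudly and early: fewer than 3 values for
  `robust_sd()`, one-class designs, regions overlapping no probe, duplicate
  probe or sample ids, malformed intervals (with the offending line), empty
  delta grids. A zero-SD sample produces all-zero calls with a warning rather
  than an error, and expected ratios below 0 (deep composite losses) are
  clipped to 0 and counted in the truth set.
* `paired_reference_mode()` divides pooled-reference ratio columns; under the
  noiseless model this equals a physical co-hybridization of the two samples,
  with noise it compounds the two columns' noise, and a reference-only
  aberration shows up as its reciprocal — both documented artefacts.

## Known limitations

* ±k·SD per-probe calling has no spatial pooling: subclonal or heterozygous
  events in noisy samples fall below the threshold (see above). Segmentation
  methods (CBS, HMM) are out of scope here.
* The permutation FDR is the raw SAM estimate; with few samples in one class
  the discreteness of the permutation distribution limits resolution.
* Region coordinates in the default set are approximate, build-agnostic
  placeholders; analyses of real data should supply region definitions
  matching the probe annotation build.

## A worked run

```{r demo, eval = FALSE}
cfg <- demo_pipeline_config(outdir = "acghsig_demo", seed = 1)
manifest <- run_pipeline(cfg)
manifest$counts
manifest$results$summary
```

The run directory contains every artifact (probe table, FR matrix, QC, screen
loci before/after masking, SAM tables, the dendrogram in Newick, signature
flags and the cohort summary) plus `manifest.yaml` recording parameters and
md5 digests; a rerun with the same seeds reproduces the digests byte for
byte.
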
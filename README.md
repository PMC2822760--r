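# acghsig

Deletion-signature discovery in array CGH cohorts.

## What this package is for

Array comparative genomic hybridization (aCGH) measures, at each of ~10^5
genomic probes, the fluorescence ratio (FR) of test over reference DNA —
about 1.0 for a diploid locus, below 1 for genomic loss, attenuated towards 1
when only a fraction of cells carries the aberration. In chronic myeloid
leukemia (CML), the lymphoid form of blast crisis carries a characteristic
*deletion signature*: near-universal losses within the antigen-receptor loci
(IGH at 14q32.33, TCRA/D at 14q11.2, TCRG at 7p14.1) and IKZF1 at 7p12,
accompanied in a subset of samples by concomitant segmental loss of 7p12-14
and 9p13-24.1.

`acghsig` provides the full analysis path for detecting such a signature in a
probes-by-samples FR matrix, for analysts working with simple-ratio aCGH
cohorts:

1. **Noise QC** — per-sample outlier-resistant SD by iterative sigma clipping
   with a Gaussian-consistency factor (`robust_sd()`, `sample_qc()`);
2. **Calling** — ternary gain/normal/loss calls at `centre ± k·SD`
   (`call_matrix()`, screen at k = 4, region display calls at k = 3);
3. **Recurrence screen** — runs of ≥ 2 genome-adjacent same-direction calls
   supported by ≥ 3 samples, masked against known copy-number-variant regions
   (`recurrent_adjacent_loci()`, `apply_cnv_mask()`);
4. **Two-class SAM** — a from-scratch permutation Significance Analysis of
   Microarrays for the lymphoid/myeloid dichotomy, with the regularized
   statistic

   d_i = (x̄_i2 − x̄_i1) / (s_i + s0),
   s_i = sqrt[(1/n1 + 1/n2) · (SS_i1 + SS_i2) / (n1 + n2 − 2)],

   expected order statistics from the permutation null, the delta/FDR table,
   the FDR = 0 selection and the top-k "enhanced delta gap" ranking
   (`sam_twoclass()`, `select_fdr_zero()`, `top_by_delta_gap()`);
5. **Clustering and signature calling** — hierarchical clustering of samples
   on the selected probes, per-sample region deletion flags, concomitant
   7p/9p classification and a per-class cohort summary
   (`hierarchical_cluster()`, `classify_concomitant()`, `cohort_summary()`);
6. **Synthetic cohorts** — a generator that plants clonal-fraction-attenuated
   deletions, class-specific signature regions and class-agnostic CNV
   polymorphisms on a jittered probe grid, with a complete truth set
   (`simulate_cohort()`), so the whole pipeline is testable against known
   ground truth.

`run_pipeline()` orchestrates all stages from one configuration and writes
every artifact plus a run manifest with parameter values and md5 digests;
reruns with the same seeds are byte-identical.

## Worked example

A desk-scale synthetic study cohort: 74 samples (12 lymphoid blast crisis vs
62 chronic-phase/myeloid/control) on a 10,000-probe grid over the signature
chromosomes, signature deletions planted in the lymphoid samples only, the
secondary 7p/9p pair in 7 of 12:

```r
library(acghsig)

cfg <- pipeline_config(
  simulate = demo_simulation_config(
    n_probes = 10000,
    class_counts = c(CP = 33, BCL = 10, BCM = 15, BCmix = 2, control = 14),
    seed = 1),
  sam = list(class_a = c("BCL", "BCmix"), class_b = c("CP", "BCM", "control"),
             n_permutations = 1000, seed = 1001),
  outdir = "acghsig_demo")
manifest <- run_pipeline(cfg)
manifest$results$summary
#>           region n_deleted n_no_data n_class  fraction
#> 1            IGH        12         0      12 1.0000000
#> 2          TCRAD        12         0      12 1.0000000
#> 3           TCRG        12         0      12 1.0000000
#> 4          IKZF1        12         0      12 1.0000000
#> 5 7p_concomitant         7         0      12 0.5833333
#> 6 9p_concomitant         7         0      12 0.5833333
#> 7    concomitant         7         0      12 0.5833333
```

Reading the output: every primary region (IGH, TCRA/D, TCRG, IKZF1) is
flagged deleted in all 12 lymphoid samples (fraction 1.0), and exactly the 7
planted carriers show the full concomitant 7p/9p loss (7/12 = 0.583) — the
region-level calls recover the planted truth exactly. On this run the
preliminary ±4 SD screen reports 13 recurrent loci (5 after CNV masking,
the difference being the planted polymorphic CNV loci), SAM finds 619 probes
at FDR = 0 — all of them planted signature probes — and the 2-cluster cut of
the top-22 probe clustering separates lymphoid from non-lymphoid samples
perfectly (Jaccard 1.0).

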
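# mirkd

Whole-blood small RNA (miR-ome) analysis for Kawasaki disease, rebuilt as a
tested, desk-scale R pipeline. Kawasaki disease is an acute childhood
vasculitis; profiling microRNAs in matched acute and convalescent whole-blood
samples identifies miRs (notably miR-145 and its star strand) whose levels
rise during the acute phase and whose predicted targets concentrate in the
TGF-β signalling pathway. Raw sequencing data for such studies are often
unavailable, so `mirkd` ships a first-class synthetic-data generator with
planted ground truth: every downstream stage is testable end to end without
any download.

The package is aimed at analysts who want a small, fully inspectable
implementation of the classic small RNA discovery stack:

1. **Simulation** — paired acute/convalescent FASTQ libraries from a mini
   two-chromosome reference: negative-binomial counts with planted fold
   changes, 22-nt-modal inserts, 5'/3' isomiR offsets, ligated 3' adapters,
   ncRNA contamination, unmappable junk, and truth sidecars.
2. **Preprocessing** — 3' adapter trimming (≤ 2 mismatches over a full
   overlap, scaled for terminal overlaps), the inclusive 17–27 nt length
   window, per-base Phred ≥ 10, and collapsing to unique reads.
3. **Annotation** — hierarchical zero-mismatch classification
   (genome → ncRNA exclusion → miR arm with seed containment and ±3 nt end
   offsets → precursor → novel candidate), isomiR tables with dominant-read
   calls, and the miR × library count matrix.
4. **Differential expression** — the negative-binomial conditional exact
   test with median-of-ratios size factors, method-of-moments dispersions
   with an `a0/q + a1` trend and conservative maximum rule,
   Benjamini–Hochberg adjustment, and variance-stabilized fold changes:
   for counts *k* with dispersion α, the test conditions on the row total
   *K* and scores every split (*a*, *K−a*) between conditions with NB
   probabilities whose means and variances are the condition-summed
   *s<sub>j</sub>q̂₀* and *s<sub>j</sub>q̂₀ + α(s<sub>j</sub>q̂₀)²*;
   p is the total probability of splits no more likely than the observed one.
5. **Pathway enrichment** — union predicted-target set at miTG score ≥ 0.7,
   pathways with ≥ 10 genes, one-sided Fisher (hypergeometric upper tail)
   against the pathway-database universe.
6. **Clinical statistics** — 2^−ΔCt qRT-PCR abundance normalized to RNU48,
   exact tie-adjusted Wilcoxon signed-rank and Mann–Whitney tests, Spearman
   correlation, the matched-pairs power simulation, and the RNase-protection
   vesicle fraction (1 − level(Triton+RNase)/level(RNase)).

## Worked example

```r
library(mirkd)

cfg <- sim_config(n_pairs = 4, n_loci = 20, library_size = 1500, seed = 8)
pl  <- run_small_rna_pipeline(cfg)

head(pl$filter_stats, 3)
#>   library  no_adapter too_short too_long low_quality qualified total
#> 1 P01_acut         46        82       33          14      1585  1760
#> 2 P01_conv         42        83       52          23      1349  1549
#> 3 P02_acut         34        77       44           7      1021  1183

de <- run_diffexp(pl$counts, pl$samples)
head(tidy(de), 2)
#>   mir_id      mean_norm_a mean_norm_b fold_change vst_log2fc      p_raw     p_adj
#> 1 miR-sim-19       113.         28.7        3.95       1.95  0.00000114 0.0000296
#> 2 miR-sim-19*       11.4         3.54       3.23       1.48  0.00429    0.0557
```

`miR-sim-19` carries a planted log2 fold change of +2 (a true 4-fold
acute elevation); the pipeline recovers it — and its star arm — at the top
of the table, estimated at 3.9-fold with BH-adjusted p = 3×10⁻⁵. The filter
tallies mirror the proportions such libraries report (~86% of reads
qualified). Dominant-read and unique-read summaries come from
`summarize_isomirs()` / `unique_read_counts()`, enrichment from
`run_enrichment()`, and plots from `autoplot()`, `plot_filter_stats()` and
`plot_insert_lengths()`.

The study's sample-size justification is reproduced by simulation:

```r
power_paired_wilcoxon(n_pairs = 12, effect_size = 1, alpha = 0.05,
                      reps = 50000, seed = 1)
#>   power   mc_se  reps n_pairs effect_size alpha
#> 1 0.850 0.00160 50000      12           1  0.05
```

i.e. ~85% power for 12 matched pairs at a standardized effect of 1, the
conventional justification for a 12-subject paired design.

## Package layout

- `R/sim-config.R`, `R/reference.R`, `R/simulate.R` — synthetic study
  generator (reference bundle, truth counts, FASTQ synthesis).
- `R/preprocess.R` — trimming, filtering, collapsing.
- `R/exact-index.R`, `R/annotate.R` — zero-mismatch matching and the
  classification hierarchy.
- `R/diffexp.R` — size factors, dispersions, exact test, BH, fold changes.
- `R/enrichment.R` — miTG-thresholded target sets and Fisher tests.
- `R/clinstats.R` — qRT-PCR, rank tests, power simulation, vesicle fraction.
- `vignettes/mirome-pipeline.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations).
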
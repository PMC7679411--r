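# crest

**C**ontext-specific **R**egulatory **E**nhancer and **S**ignature
**T**oolkit — an R package for identifying context-specific transcription
factor target genes in tumors with constitutive NRF2 activation
(KEAP1-mutant lung cancers and similar settings).

## The problem

NRF2 is normally a transient stress-response activator. In tumors where
KEAP1 is lost, NRF2 is persistently stabilized and rewires the enhancer
landscape, driving target genes that transient NRF2 activation never
touches. Telling these *context-specific* targets apart from *canonical*
cytoprotective targets takes four coordinated analyses, which this package
implements as composable, tested stages:

1. **Gene-set classification** from differential-expression contrasts.
   With knockdown contrasts in NRF2-activated lines and inducer (e.g. DEM)
   contrasts in NRF2-normal lines, responsive genes are selected at
   BH-adjusted *p* < α (default 0.05) **with** the matching direction of
   change. The common downstream set is the intersection of the knockdown
   responders; the inducible set is the union of induction responders; then

   `canonical = common ∩ inducible`, `specific = common \ inducible`.

2. **NRF2-dependent enhancer calling** from paired H3K27ac coverage. For
   each H3K27ac peak overlapping a TF binding peak, signals from
   depth-normalized control and knockdown tracks give

   `log2((kd + ψ) / (control + ψ))`,  ψ = pseudocount (default 1),

   and the deposition is *TF-dependent* when the ratio is strictly below
   −0.5. A classified gene is a **direct target** when a dependent peak is
   assigned to it (nearest-TSS within 100 kb) and TF binding lies in the
   same window.

3. **Cofactor colocalization** ranking by base-pair Jaccard
   `J(A, B) = |A ∩ B| / |A ∪ B|` (bases) against the reference set of TF
   peaks carrying H3K27ac, with a length- and chromosome-preserving
   permutation null, `p = (k + 1) / (n_perm + 1)`.

4. **Signature activity scoring** of tumor cohorts: the per-sample NRF2
   activity score is the mean z-score of a six-gene signature (NQO1,
   SLC7A11, GCLC, GCLM, TXNRD1, NR0B1); cohorts are stratified into
   activity groups and query genes compared across strata by one-way ANOVA
   with Bonferroni pairwise tests, plus χ², Pearson and Mann–Whitney
   helpers for the accompanying clinical tables.

A seeded synthetic-data module plants every structure the pipeline infers
(gene classes, dependent enhancers, cofactor Jaccards, latent cohort
activity), so the whole analysis runs end-to-end with known ground truth
and no downloads.

## Worked example

```r
library(crest)

cfg <- sim_config(seed = 11)                 # default study conditions
man <- write_simulation(cfg, "sim")          # BED/bedGraph/TSV inputs
rep <- run_end_to_end(pipeline_config_from_simulation(man, "out", seed = 11))
rep
#> pipeline run report
#>   gene classes: 123 common = 87 canonical + 36 specific
#>   enhancers: 200 called, dependent fraction 0.500
#>   direct targets: 77 canonical, 21 specific
#>   top cofactor: GATA3
#>   activity: 503 samples, query ANOVA p = 2.58e-42
```

Reading the report: the classifier recovered the planted 123 common
downstream genes and split them into 87 canonical and 36 context-specific;
100/200 TF-bound H3K27ac peaks lost signal on knockdown (dependent
fraction 0.50); nearest-TSS assignment called 77 canonical and 21 specific
genes direct targets — including the planted "NOTCH3-like" gene whose
dependent enhancer sits 10 kb upstream of its TSS; the cofactor with the
largest planted Jaccard ranks first; and the query gene differs strongly
across the three activity strata of the 503-sample cohort. Per-stage
tables (`gene_classes.tsv`, `enhancers.tsv`, `direct_targets.tsv`,
`cofactor_ranking.tsv`, `activity_scores.tsv`, `correlation_filter.tsv`)
are written to `out/`, and a rerun with the same config is byte-identical.

Individual stages are plain functions (`read_bed`, `call_enhancers`,
`rank_cofactors`, `activity_score`, `mann_whitney`, ...) and work on real
BED/bedGraph/TSV inputs the same way; see the methods vignette
(`vignettes/crest-methods.Rmd`) for the modelling details and parameter
guidance.

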
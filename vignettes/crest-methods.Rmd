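---
title: "crest: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crest: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and design decisions
behind `crest`, in the spirit of the long-form methods vignettes of the
Bioconductor differential-analysis packages: what each stage assumes, which
parameters matter and why their defaults are what they are, what the
synthetic-data generators emulate — and, just as importantly, what they do
not, hence what a passing test suite does and does not establish about real
data.

## Coordinate and data model

All on-disk formats (BED, bedGraph) use 0-based half-open coordinates, and
all public tables report in the same convention; in memory intervals live
in `GRanges` objects (1-based closed, as is standard for Bioconductor) and
the converters at the I/O boundary are the only place the two conventions
meet. A genome model (`genome_model()`, a `Seqinfo`) declares chromosome
names and lengths once; every reader validates its input against it and
names the offending chromosome or line on failure. Two strictness choices
are deliberate:

* `read_bedgraph()` rejects overlapping steps instead of summing them.
  Merged coverage tracks are step functions; overlap in the input means an
  upstream merge went wrong, and silent summation would hide it.
* `overlapping_subset()` returns whole intervals, never clipped fragments,
  because downstream stages classify whole H3K27ac depositions.

Base-count operations (`intersect_bases`, `union_bases`, `jaccard_index`)
are computed by a single event sweep over both interval sets laid onto one
coordinate axis. The sweep tracks running coverage counts, so inputs need
not be pre-merged and the results are invariant to fragmentation of either
input. The test suite checks all interval algebra — including the sweep —
against a literal per-base membership oracle on hundreds of random small
genomes, exactly.

## Gene-set classification

A contrast table carries `(gene_id, log2fc, p_adj)` for one perturbation in
one cell context, with `p_adj` Benjamini–Hochberg adjusted
(`bh_adjust()` wraps `stats::p.adjust`). Differential-expression estimation
itself is out of scope: the package consumes the DE tool's output.

Two rules define responsiveness, both strict inequalities:

* significance: `p_adj < alpha` (default `alpha = 0.05`);
* direction: `log2fc < 0` for knockdown contrasts, `> 0` for induction.

The direction requirement matters — "downregulated by knockdown" is a
claim about sign, not only significance. The common downstream set is the
*intersection* of responders across all knockdown tables (a gene absent
from one table counts as non-responsive there); the inducible set is the
*union* across induction tables; `classify_genes()` partitions the common
set into `canonical` (also inducible) and `specific` (not inducible). The
partition identity `|canonical| + |specific| = |common|`, with the two
classes disjoint, holds for any input and is property-tested.

`correlation_filter()` implements the cohort-correlation narrowing of
candidate genes. The literature this models does not pin down the
statistic or cutoff, so both are parameters: Spearman correlation with
threshold 0.3 by default. Rank correlation is robust to the (arbitrary)
expression scale of public cohorts; 0.3 is a conventional "clearly
non-null" floor. Candidates missing from the cohort, or with zero
variance, are reported as skipped with a warning — a missing gene in an
external cohort is an annotation mismatch, not an analysis error.

## Dependent-enhancer calling

Both coverage tracks are first scaled to a common total
(`normalize_track()`, default target 1e6), the same linear normalization
as scaling by total mapped reads. Replicate tracks can be collapsed with
`mean_merge_tracks()` (per-base mean). For each H3K27ac peak overlapping a
TF peak, the whole-peak signals give

```
ratio = log2((kd + pseudocount) / (control + pseudocount))
```

and the peak is dependent iff `ratio < threshold` (default −0.5, strict:
a peak exactly at −0.5 is not called). Quantification is over whole peak
intervals rather than summit windows — peaks are the unit being
classified, and whole-peak sums are additive and fragmentation-stable.
The pseudocount (default 1 normalized signal unit) exists solely to keep
the ratio defined at zero coverage; with both signals zero the ratio is
exactly 0. The calling is monotone: lowering knockdown signal can only
turn a peak dependent, never the reverse, and joint rescaling of both
tracks (followed by renormalization) leaves calls unchanged.

Direct-target calling assigns each called peak to its *nearest* TSS within
a window (default 100 kb), so one enhancer supports exactly one gene; a
classified gene is direct iff it has at least one dependent assigned peak
and TF binding within the window. The 100 kb window is a conventional
generous bound for enhancer-promoter assignment — the motivating example
enhancer sits ~10 kb from its TSS — and is exposed in the configuration,
as the true linking rule used in any given study rarely is published.
Whether the "dependent fraction" should be counted over peaks or bases is
likewise unstated in the motivating work; `crest` reports the fraction of
peak *calls*.

`mann_whitney()` compares signal between gene-class groups: rank-sum with
mid-ranks, exact two-sided p by enumeration when the pooled sample size is
at most 16 with no ties (delegated to `stats::wilcox.test`, whose exact
branch the tests verify against full enumeration for all group sizes up to
7), otherwise the normal approximation with tie and continuity
corrections.

## Cofactor colocalization

The reference set is the TF peaks that carry the enhancer mark
(`reference_set()`). Candidate factors are ranked by *base-pair* Jaccard —
the unit choice follows the genome-arithmetic convention of the BEDTools /
GenometriCorr family; peak-count Jaccard is not implemented because it
conflates peak fragmentation with signal. Ties in the ranking break by
factor name, and the ranking is invariant to catalog order.

Significance uses a Monte-Carlo null that repositions every query interval
uniformly within its own chromosome, preserving lengths and chromosome
assignment. This choice keeps the marginal coverage of the query fixed
while destroying its positional relationship to the reference; it does not
model clustering of peaks along the genome (see *Limitations*). The
p-value is the add-one estimator `(k + 1) / (n_perm + 1)`, which is never
zero and is uniform under the null up to discreteness; `n_perm = 999` by
default. Under a true null the p-values are checked to be approximately
uniform (Kolmogorov–Smirnov at the 0.01 level over 200 seeded replicates
at `n_perm = 99` — smaller `n_perm` there purely to keep the check
inexpensive). When exclusion regions (assay blacklists) are supplied to
the pipeline they are subtracted from peak sets before any analysis.

## Activity scoring and cohort statistics

`zscore_by_gene()` standardizes each gene with the sample (n−1) standard
deviation; zero-variance genes become `NaN` and only raise an error when a
downstream signature actually requests them. The activity score is the
unweighted mean of the signature genes' z-scores (default signature: NQO1,
SLC7A11, GCLC, GCLM, TXNRD1, NR0B1), so it is invariant to per-gene affine
rescaling of the input matrix and has cohort mean zero by construction.
Z-scores are computed against all samples of the supplied cohort — if a
reference subpopulation is preferred, subset before scoring.

`stratify()` cuts samples into `n_groups` ordinal strata (default 3 —
low/intermediate/high is the smallest design that exposes a trend) of
sizes differing by at most one, ties resolved by stable sample-id order
and remainder samples placed in the lower strata. Group comparison is the
classical one-way ANOVA decomposition with pairwise pooled-variance
t-tests multiplied by the number of pairs (Bonferroni); identical
constant groups are rejected with an explicit zero-within-variance error
rather than returning an infinite F. The 2×2 chi-square uses the closed
form with optional Yates correction (off by default; the correction term
is capped at |ad−bc| so the corrected statistic can never overshoot), and
`pearson_r()` reports the product-moment correlation with the t-transform
p-value. All four are tested against independently coded textbook
formulas to 1e-9 on random instances.

## What the synthetic data emulates

`sim_config()` fixes the default study conditions; every generator derives
an independent RNG stream from the master seed and identical configs give
byte-identical output files.

* **Contrasts** (`make_contrasts`): 10,000 genes; 87 canonical genes down
  in all three knockdown tables and up in at least one of two induction
  tables; 36 specific genes down in all knockdown tables and never
  induction-responsive (the first of them is the designated NOTCH3-like
  gene); 500 inducible-only genes exercise the union logic without
  entering the common set; the rest are null. Responsive p-values are
  drawn from Beta(0.1, 20) truncated below alpha (a sharply
  significance-concentrated shape), non-responsive ones uniform and
  floored above alpha; responsive |log2fc| centers on 2. `flip_rate`
  optionally flips each per-table call with fixed probability to emulate
  call noise.
* **Epigenome** (`make_epigenome`): a 2 × 1 Mb genome with 200 TF-bound
  H3K27ac peaks of 500–2000 bp, placed with uniform jitter inside disjoint
  ~10 kb slots. Slotted placement (rather than fully uniform positions)
  guarantees non-overlap and makes every peak's nearest TSS the gene it
  was planted for, so ground truth is exact; the geometry keeps each
  gene's TSS ~3 kb from its own peak and ≥ 3.8 kb from any neighbor. Half
  the peaks are dependent with true knockdown/control ratio 0.4 (true
  log2 ratio ≈ −1.32, comfortably below the −0.5 threshold); coverage is
  Poisson-sampled per 50 bp bin around a mean control total of 100 per
  peak over a background of 1× (the mean-100 level matches a deeply
  covered ChIP peak and gives the caller a realistic but not trivial
  noise margin); `noise = FALSE` gives exact levels for exact tests. 77
  of the canonical and 21 of the specific genes sit at dependent peaks
  (the NOTCH3-like gene with its peak 10 kb upstream, flanked by empty
  slots so the assignment is unambiguous); the remaining classified genes
  sit at independent peaks; leftover peaks belong to unclassified filler
  genes.
* **Cofactors** (`make_cofactor_catalog`): each factor copies a fraction
  `min(1, 2j)` of reference bases and adds disjoint filler so the realized
  base-pair Jaccard equals the target `j` up to integer rounding. The
  default four factors carry well-separated targets 0.60/0.40/0.20/0.05.
* **Cohort** (`make_cohort`): 503 samples with latent activity
  `~ N(0, 1)`; each signature gene is `a·activity + N(0, σ²)` and the
  query gene `b·activity + N(0, σ²)` with `a = b = σ = 1`; extra genes are
  pure noise.

**What passing tests do not show.** The generators plant clean,
well-separated structure: independent Poisson noise, no copy-number or
GC coverage artifacts, no peak clustering or correlated binding, no
batch effects or dropout in the cohort, balanced class sizes. Recovery at
the planted conditions demonstrates that the *rules are implemented
correctly and are robust to the modeled noise* — it does not certify
sensitivity/specificity on real ChIP-seq, where signal-to-noise, peak
width distributions and confounders differ. Parameters were chosen once
to reflect the emulated designs and are not tuned to the test outcomes.

## Numerical and degenerate-input choices

* All cutoffs (`alpha`, dependency threshold) are strict `<` comparisons.
* `nearest_tss()` breaks ties by the lexicographically smaller gene id.
* Track normalization requires equal totals to 1e-6 relative before
  enhancer calling; zero-total tracks are errors, not silently skipped.
* Jaccard of two empty sets is an error (undefined), not 0.
* Permutation p-values are never 0 (add-one estimator).
* `stratify()` with all-tied scores falls back to stable sample-id order.
* Pipeline reruns with identical config and inputs are byte-identical;
  timestamps appear nowhere in output tables.

## Interface notes

The package is R-native: configuration is the `pipeline_config()` object
rather than a YAML file, and the pipeline stages (`simulate`,
classify/call/coloc/score, end-to-end run) are exported functions rather
than shell subcommands — a shell wrapper would add a dependency without
adding capability for an audience working in R. `run_end_to_end()` writes
every intermediate as tab-separated text with headers, logs the seed and
per-stage counts to `run.log`, and on failure leaves a `FAILED` marker
naming the stage and cause beside any partial outputs.

## Known limitations

* The permutation null ignores chromatin-driven clustering of peaks;
  against a clustered reference it is anti-conservative for queries that
  cluster the same way. A shuffling null that preserves inter-peak gap
  structure would be the next refinement.
* Signal quantification over whole peaks makes calls depend on the peak
  caller's width conventions; summit-window quantification is not
  implemented.
* Peak-to-gene assignment by nearest TSS cannot represent skipped-gene
  enhancer interactions; the window parameter only bounds, it does not
  model, contact frequency.
* The activity score weights all signature genes equally; a degenerate
  signature gene (zero variance) is an error rather than being dropped.
* BigWig/BAM inputs are not parsed; convert to bedGraph/BED upstream.
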
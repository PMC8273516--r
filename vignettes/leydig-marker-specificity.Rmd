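---
title: "Calling population-specific Leydig cell markers from bulk and single-cell RNA-seq"
author: "LeydigMarkers authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling population-specific Leydig cell markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LeydigMarkers)
```

# The problem

Mouse testes contain two successive androgen-producing Leydig cell
populations: fetal Leydig cells (FLCs) and adult Leydig cells (ALCs). Bulk
RNA-seq of purified populations measures their transcriptomes deeply but
cannot tell whether a gene enriched in FLCs versus ALCs is *specific* to
Leydig cells — it may be expressed in Sertoli, germ, endothelial or
interstitial cells too. Single-cell RNA-seq resolves cell types but is
shallow. This package implements the integration of both: a gene is called
an FLC (or ALC) **specific marker** only when

1. it is differentially expressed in the right direction in the bulk
   FLC-versus-ALC contrast,
2. it passes single-cell pairwise marker criteria between the FLC and ALC
   clusters, and
3. it also passes the one-vs-rest marker criteria against every other
   testicular cluster.

Every stage of that chain — RPKM quantification, negative-binomial
differential expression, droplet cell calling, Wilcoxon marker statistics,
splicing-table summarization, enrichment statistics — is implemented here
and validated on synthetic data with planted ground truth.

# The statistical model, stage by stage

## Bulk quantification

RPKM is `1e9 * count / (length_bp * total)`, with the per-sample column sum
of the count table as the "million mapped reads" denominator (the original
pipeline's exact denominator is not recoverable; the column sum is the
reproducible choice and the divergence risk is confined to genes near the
expressed-gene boundary). A gene is *expressed* in a population when its
mean RPKM across that population's replicates is at least 1; the mean (not
per-sample) formulation is our documented choice because one expressed-gene
count is reported per population. Biotype proportions are taken among genes
with mean RPKM strictly above zero.

## Bulk differential expression

A deliberately transparent two-group negative-binomial Wald pipeline,
rather than a wrapped DESeq2 call: median-of-ratios size factors (rescaled
to geometric mean 1), exclusion of genes with fewer than 10 raw reads in
total across all six samples (the community reading of that low-count
rule), `log2FC = log2((m_B + 0.5) / (m_A + 0.5))` on normalized group means
with a 0.5-normalized-unit pseudocount so single-sided zeros stay finite,
and a delta-method standard error from the NB variance
`mu + alpha * mu^2`.

Two numerical choices matter at triplicate scale and were set by measuring
calibration on planted-null and planted-effect simulations:

* **Dispersion moderation.** The gene-wise method-of-moments dispersion
  pooled within groups has only four residual degrees of freedom; raw, it
  both collapses to the floor (inflating Wald statistics on null genes)
  and overshoots several-fold (destroying power on real effects). We
  squeeze it toward the across-gene median with `prior_df = 4`
  pseudo-degrees of freedom. No mean-dispersion trend is fitted; the
  target is a single constant, keeping the estimator simple and monotone.
* **t reference.** The Wald statistic is referred to a t distribution with
  `nA + nB - 2 + prior_df` degrees of freedom instead of the standard
  normal, the usual small-sample correction for a plug-in variance. On
  2,000 planted-null genes in 20 simulations this keeps the fraction of
  genes at adjusted p < 0.01 at zero (bound: 1%), while planted
  |log2FC| = 3 effects at baseline means of 200 or more are recovered with
  probability 1.

Benjamini–Hochberg adjusts across tested genes. Classification uses the
study thresholds: adjusted p < 0.01 with fold change < 0.5 (FLC-enriched,
because the ratio convention is ALC over FLC) or > 2 (ALC-enriched), all
strict inequalities. Fold-change direction is pinned by the published
marker tables, in which FLC-specific genes print negative log2 fold
changes.

DE genes can be grouped into expression-pattern clusters (default k = 15)
by Ward (`ward.D2`) hierarchical clustering of row-z-scored expression with
Euclidean distance; genes with zero variance cannot be z-scored and are
assigned to the nearest centroid afterwards, flagged. Genes are processed
in `gene_id` order, which makes the assignment deterministic.

## Droplet cell calling

The threshold between cell-containing and empty barcodes is the local
minimum of the UMI-count density between the knee and the inflection of
the ranked-barcode curve. On the log10(total UMI) versus log10(rank) curve,
tied UMI values are collapsed to one point; because the collapsed
abscissae are grossly uneven (log-rank spacing collapses toward both ends),
the curve is resampled by linear interpolation onto an even 512-point grid
before a centered moving average (window: 5% of grid points) smooths it.
The knee is the grid point of most negative signed curvature
$y''/(1+y'^2)^{3/2}$; the inflection is the steepest descent at larger
rank. Two robustness guards reflect common droplet-QC practice: barcodes
below 100 total UMI are excluded from the landmark search, and the
half-window margins of the grid (where the asymmetric moving average
biases the curve) are not eligible as landmarks. A curve whose minimum
curvature is shallower than 1 in magnitude — a straight power law, say —
raises "no knee detectable" rather than returning an arbitrary point.

The density itself is the base `density()` Gaussian KDE on the **raw** UMI
scale with bandwidth 500 and a 4,096-point grid spanning `[0, max UMI]`
(the stated bandwidth is only meaningful on raw counts). Among grid-local
minima inside `[inflection, knee]` the one with smallest density wins,
ties going to the smaller UMI; if the window contains no local minimum the
geometric mean of the two landmarks is used and flagged. Cells are
barcodes **strictly above** the threshold — the threshold sits in a density
valley, not on a real barcode. Per-cell QC cutoffs (minimum UMI,
mitochondrial fraction) are exposed as explicit configuration rather than
hard-coded, since the source protocols differ between stages and one
printed mitochondrial bound is implausible as printed.

## Single-cell marker statistics

Counts are normalized as `ln(1 + 1e4 * count / cell_total)`. For a focal
group against a reference group, per gene: `pct.1` and `pct.2` are the
fractions of cells with nonzero counts inside and outside the focal group;
the effect size is
`avg_logfc = ln(mean_in(e^x - 1) + 1) - ln(mean_out(e^x - 1) + 1)`
(natural log of de-normalized group means — the convention under which the
printed 0.5 threshold is meaningful). A gene is tested only when
`max(pct.1, pct.2) >= 0.25` and, for positive markers, `avg_logfc >= 0.25`
(the prefilter semantics of the cited tool's `min.pct`/`thresh.use`). The
test is the two-sided Mann–Whitney–Wilcoxon rank-sum with normal
approximation, tie correction and continuity correction (`wilcox.test`);
exact enumeration is reserved for test oracles at tiny n. Adjustment is
Bonferroni over the full gene universe by default (the cited tool's
convention for "adj. p-value"; BH available), with untested genes carrying
p = adjusted p = 1. The marker pass criteria are adjusted p < 0.01,
avg_logfc > 0.5, pct.1 > 0.5, pct.2 < 0.25, all strict.

Pairwise markers run both orientations of FLC versus ALC; one-vs-rest runs
each cluster against all remaining cells pooled, skipping clusters of
fewer than 3 cells with a warning. Whether one-vs-rest uses a merged
two-stage matrix or per-stage matrices is the caller's choice: the label
table is an input.

## The specificity integration

For population P with declared bulk direction (FLC maps to the
fold-change-below-0.5 class, ALC to the above-2 class):

* **enriched** = passes pairwise marker criteria for P **and** bulk class
  matches P's direction;
* **specific** = enriched **and** passes one-vs-rest for P's cluster.

Every candidate failing a filter keeps a machine-readable
`exclusion_reason`: `no_bulk_enrichment` (single-cell pass, bulk
discordant — the *Thbs2*-style exclusion), `low_sc_expression` (bulk
concordant but in-population detection never above 0.5 — the *Mc2r*-style
exclusion), `fails_sc_criteria`, `absent_in_modality` (a gene missing from
one modality's universe is dropped with that reason rather than silently),
or `expressed_elsewhere` (enriched but not one-vs-rest specific). Bulk and
single-cell gene universes are joined by gene symbol with exact string
match, since the two references typically differ by annotation version and
symbols are the lingua franca of the published tables; a symbol collision
is resolved toward the id with the higher base mean.

## Splicing summarization

rMATS-format tables (one per event type: SE, RI, A5SS, A3SS, MXE;
junction-count dialect by default) are filtered at FDR <= 0.05
(inclusive), and each significant event is assigned to a population by the
sign of its inclusion-level difference under a declared sample-1
orientation — the attribution rule is configuration, not inference,
because the tables themselves do not state it; exact zeros stay unassigned
with a warning. The summary reports event-type counts and proportions per
population, distinct spliced gene sets (including the genes spliced in
both populations), and the overlap of each population's DE genes with its
spliced genes.

## Enrichment statistics

Over-representation uses the upper-tail hypergeometric probability
P(X >= k) with BH adjustment across sets; term lists are flat GMT inputs
(no ontology graph is modeled — term databases are external and
version-dependent). Pre-ranked GSEA uses the classic weighted
Kolmogorov–Smirnov running sum on genes with ranking score above 1
(mean RPKM is the intended ranking), hit increments proportional to
score^1 (the weighting exponent is configurable; 1 is the cited tool's
"weighted" default), gene-label permutation for the null (phenotype
permutation is impossible without sample-level inputs), NES by same-sign
null normalization, and the standard pooled-null FDR q, reported at
q < 0.25.

# The synthetic-data generator

The generator is the package's validation instrument; its defaults *are*
the study conditions and are not tuned per test:

* **Bulk**: two conditions (FLC, ALC) in triplicate; gene-wise NB counts
  with dispersion 0.05 and log-normal size factors (sdlog 0.1); null genes
  draw baseline means log-normal(log 150, 1); genes with a planted effect
  draw the *lower*-group mean uniformly in [200, 2000] and multiply the
  up-regulated group by 2^3 — markers are strongly expressed in their own
  population, the regime the triplicate design can resolve.
* **Single cell**: six clusters over two stages (FLC 151 and ALC 148
  cells, echoing the reported Leydig cluster sizes, plus Sertoli-like,
  interstitial and germ clusters); per-cell multinomial counts over
  cluster profiles with log-normal library sizes around 8,000 UMI. A
  planted marker's profile weight is set so its expected detection equals
  0.9 in-cluster and 0.02 elsewhere at the mean library size.
* **Trap genes**: `trap_low_expression` genes carry the full bulk effect
  but in-cluster detection 0.3 (they must be excluded with reason
  `low_sc_expression`); `trap_no_bulk_enrichment` genes have full
  single-cell specificity but identical bulk means (reason
  `no_bulk_enrichment`). The traps make the exclusion logic — not just the
  recall — part of the acceptance surface.
* **Barcodes**: 500 cell barcodes log-normal around 8,000 UMI (sdlog
  0.25) pooled with 50,000 empties around 200 (sdlog 0.5); a
  configuration whose modes are not separable (ambient >= cell/5) is
  flagged, not rejected.
* **Splicing**: per-population significant event counts defaulting to the
  reported totals (1,380 FLC / 591 ALC) with intron retention skewed to
  the fetal side (742 vs 34); 10% of each population's DE genes receive a
  significant event.

All generators are pure functions of (configuration, seed); per-stage
child seeds are derived deterministically from the master seed and the
stage name.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: ambient-RNA contamination, doublets, batch
effects, transcript-level coverage biases, mean-dispersion trends,
correlated genes, or annotation-version mismatches between modalities. The
generator exists to verify that the decision logic recovers a known truth
under its own model assumptions, not to claim the thresholds are optimal
for any real dataset.

# Worked example

```{r pipeline, eval = TRUE}
cfg <- pipelineConfig(seed = 1, run_barcodes = FALSE,
                      run_enrichment = FALSE, run_splicing = FALSE)
res <- runPipeline(cfg)
res$summary$specific_counts
evaluateCalls(res$calls, res$truth)[c("recall", "trap_specific")]
```

The published marker tables ship with the package and anchor the
fold-change arithmetic:

```{r tables, eval = TRUE}
tab <- markerReferenceTable("ALC")
head(cbind(tab[, c("gene", "log2_fold_change", "fold_change")],
           recomputed = round(log2fcToFc(tab$log2_fold_change), 3)))
```

# Problem sizes and determinism

The validation suite runs the full pipeline on 20 seeded replicates of the
default configuration (2,000 genes, 949 cells), the null-calibration
suites on 20 replicates of 2,000 planted-null genes (bulk) and 200 null
genes across 80 cells (single cell), and barcode calling on 200 seeded
profiles of 50,500 barcodes — sizes chosen so the whole suite documents
the method at the scale the study design actually has, while remaining
quick enough to run routinely. Every random draw flows from one master
seed through stage-named child seeds, so reruns are byte-identical.

# Known limitations

* The NB Wald pipeline intentionally omits trend-fitted dispersion
  shrinkage, log-fold-change shrinkage, independent filtering and outlier
  refitting; on real data its numbers will differ from a full DESeq2 run,
  and the package's claims rest on synthetic truth and internal
  consistency, not on reproducing deposited-dataset outputs.
* Knee/inflection definitions are not uniquely determined by a ranked
  curve; ours (curvature minimum, steepest log-log descent) are chosen for
  robustness and testability and are stable between the ambient and cell
  modes on bimodal profiles, but a profile without a shoulder is
  deliberately an error, not a guess.
* Marker specificity is only as good as the input cluster labels; the
  package consumes labels, it does not cluster cells.
* Mouse-only: no claim is made that these markers transfer across
  species.
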
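# otsubtypes

Integrative multi-omics subtyping of oligodendroglial tumours (OT), as a
tested, reusable R package. Diffuse gliomas are stratified by the 1p/19q
whole-arm co-deletion and *IDH* mutation; this workflow refines that
stratification from bulk molecular profiles and probes the aggressive,
OPC-like (oligodendrocyte-precursor-like) subtype of co-deleted tumours
and its MYC-pathway activation. It is aimed at computational biologists
who want each stage of such an analysis as an auditable, testable
function rather than a one-off script.

## What it implements

* **Resampled consensus clustering** per omic: for each K in 2..8, the
  consensus matrix entry M_K(i,j) is the fraction of subsampling
  iterations (1,000 by default, 80% of samples each) in which samples i
  and j co-clustered under hierarchical clustering — Pearson
  dissimilarity (1 − r) with Ward linkage for expression and miRNA,
  Euclidean with unsquared-input Ward for methylation. K is selected
  from the areas A(K) under the CDFs of consensus values via the
  relative increase Δ(K) = (A(K) − A(K−1))/A(K−1), with both a fixed
  threshold rule and a plateau (curve-shape) rule.
* **Contamination screening**: tumours clustering with normal-brain
  controls in a preliminary run are flagged and removed.
* **Cluster-of-clusters integration**: per-omic partitions are encoded
  as binary class indicators (NA when a sample lacks that omic) and the
  same consensus engine clusters samples on them.
* **1p/19q co-deletion from expression**: per-sample mean gene-centred
  expression of 1p and 19q features, split by exact 1-D within-variance
  minimization; the lower class is co-deleted.
* **MYC-pathway event calls**: MYC gain / MAX loss from gain-normal-loss
  (GNL) copy-number data under an "all positions" rule; MYC exon 3
  hypomethylation (beta < 0.5 at cg00163372); mir34b/c promoter
  hypermethylation (beta > mean + 2·SD at cg22879515); CIMP status from
  island-CpG consensus clustering at K = 2.
* **Moderated-t differential expression** (empirical-Bayes variance
  shrinkage with a method-of-moments scaled-F prior fit), top-N
  signature selection, hypergeometric gene-set enrichment, and the MYC
  activity score (mean centred expression of MYC targets).
* **Mutual exclusivity** of lesions by one-sided binomial tests against
  the independence null Binomial(n, pA·pB).
* **Survival**: Kaplan–Meier / log-rank comparisons, cross-cohort
  pooling, and a radiotherapy-stratified five-year analysis with a
  3-month landmark.
* **Synthetic multi-omics cohort generator** with ground truth
  (subtype-structured expression, normal-contamination mixtures,
  negative-binomial miRNA counts, logit-normal methylation with CIMP
  and single-CpG events, arm-level GNL segments, subtype-dependent
  exponential survival), so the whole pipeline is testable without
  controlled-access data.

See `vignettes/multiomics-subtyping.Rmd` for the models, parameter
choices and limitations.

## Worked example

```r
library(otsubtypes)

cf <- cohort_config(n_per_subtype = c(C1 = 35, C2 = 25, C3 = 30, C4 = 15, C5 = 15),
                    n_contaminated = 21, n_normal_controls = 9, seed = 42)
cohort <- generate_cohort(cf)
res <- run_pipeline(cohort, n_iter = 1000, seed = 42)
```

The pipeline first flags tumours that cluster with the normal controls
(here all 21 planted contaminated samples, no false positives):

```
flagged contaminated tumours: 21
```

then clusters each omic; the mRNA consensus result prints the CDF areas
and their relative increases:

```
consensus_result: K in {2,3,4,5,6,7,8}, selected K = 4
          2     3     4     5     6     7     8
area  0.417 0.635 0.753 0.780 0.792 0.801 0.809
delta 0.417 0.525 0.185 0.036 0.015 0.011 0.010
```

(at these sizes the two smallest co-deleted subtypes, 15 samples each,
merge — the Δ curve collapses after K = 4). The integrated partition
agrees with the planted subtypes at adjusted Rand index 0.902, and the
per-omic classifications associate strongly, e.g.

```
mRNA vs miRNA classes: chi-square = 342.4 , p = 2.51e-68
```

Event calling and the MYC activity score reproduce the planted
coupling: samples with at least one MYC-deregulation event score about
one log2 unit higher than samples without,

```
     group  n     q1 median      q3   mean
1 no_event 98 -0.336 -0.185 -0.0984 -0.170
2    event 22  0.639  0.758  0.7994  0.755
score t-test p = 3.41e-28
```

while the exclusivity test correctly finds *no* exclusivity under the
default independent-events configuration (observed 3 co-occurrences vs
0.87 expected, binomial p = 0.99).

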
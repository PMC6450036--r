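---
title: "Marker-based annotation of scRNA-seq clusters: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based annotation of scRNA-seq clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markercall)
library(dplyr)
```

## The problem

Unsupervised clustering of single-cell RNA-seq data yields groups of cells
with no biological identity attached. `markercall` labels those clusters
automatically using prior knowledge: a compendium of marker genes curated
per cell type. The package deliberately consumes, rather than computes, the
upstream artifacts — deduplicated counts, cluster assignments, doublet
scores, motif hit tables, co-expression modules — so each stage has a single
well-defined contract.

## The annotation model

**Cluster profiles.** A cluster is summarized by the per-gene *median* of
its cells' normalized expression. The median was preferred over arithmetic,
geometric or harmonic means because it is robust to the extreme
zero-inflation and occasional high outliers of droplet data; for even-sized
clusters the midpoint of the two central values is used. Normalization is
counts-per-library-size followed by `log2(x + 1)`; RPKM input (full-length
protocols) is log-transformed with a pseudo-count of 1 directly, since it
arrives already length- and depth-normalized.

**Marker weighting.** A marker listed for many cell types carries little
evidence. Simply discarding multi-type markers would inflate type II error,
so they are down-weighted instead. With `f(g)` the number of cell types
listing gene `g`:

$$w(g) = 1 + \sqrt{\frac{\max(f) - f(g)}{\max(f) - \min(f)}} \in [1, 2].$$

When every gene has the same frequency the ratio is 0/0; with no frequency
signal, no down-weighting is warranted, so every gene receives the
specific-marker weight 2. Anything in (1, 2] would preserve ranking — the
choice only fixes the degenerate scale.

**CTA score.** For cell type $j$ with $N$ markers and cluster medians
$Z_i$:

$$S_{j,k} = \Big(\sum_{i=1}^{N} Z_i \, w_i\Big) \Big/ \sqrt[3]{N}.$$

$Z$ is taken to be the cluster median profile — it is the only
cluster-level expression quantity the procedure constructs. Markers absent
from the matrix's gene axis contribute $Z = 0$ but still count in $N$: the
marker count is a property of the compendium, not of the assay, and an
unmeasured marker should penalize, not silently shrink, the denominator.
The score is linear in the profile, so any positive rescaling of the
normalized values (e.g. a different library-size target) changes no
winner.

**Significance and the Unknown rule.** Expressed means median > 0. The
overlap between a cluster's expressed genes and a type's markers is tested
with a one-sided hypergeometric tail whose universe is the matrix's gene
axis after QC — the only finite gene universe available. P-values are
BH-adjusted *across the cell types within one cluster* (the fallback rule
is applied per cluster, so the cluster is the natural family). The
top-ranking type by CTA becomes the label unless its adjusted p exceeds
0.05 — strictly; equality keeps the label. CTA ties are broken by smaller
p-value, then alphabetically, purely for determinism.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_reads` | 1000 | minimum library depth (counts) per retained cell |
| `doublet_fraction` | 0.05 | top fraction of doublet scores removed |
| `min_cells` | 10 | minimum cluster size entering analysis |
| `scale` | 10000 | target library size before `log2(x+1)` |
| `fdr_cutoff` | 0.05 | adjusted-p threshold for accepting a label |
| `alpha` | 0.01 | Bonferroni family-wise rate for gene-set activity |
| `min_size`, `max_size` | 10, 500 | admissible gene-set sizes |
| `top_n` | 200 | motif-ranking truncation for regulon tests |
| `threshold` | 0.05 | KDE tail significance for motif support |

The library-size target of 10000 is the common scRNA-seq convention; any
positive value yields identical winners (see linearity above), it only sets
the numeric range. Doublet removal takes `ceiling(fraction * n_cells)`
cells — "top 5%" is ambiguous at non-integer boundaries and at score ties,
so the count is rounded up and ties at the cut are resolved by barcode
order. The depth filter is applied before the doublet cut; the order is not
fixed by the procedure's description, and depth is the cheaper, more
conservative filter to run first.

## Gene-set activity and regulons

Gene-set activity reuses the expressed = median > 0 rule per cluster and
tests each admissible set with the same one-sided hypergeometric tail,
controlling family-wise error by Bonferroni at α = 0.01 over the *tested*
(size-admissible) sets — sets excluded by the size window were never
hypotheses. Ortholog restriction (for mouse samples against human-curated
collections) maps genes through a strictly one-to-one table *before* the
size filter, because mapping changes effective set sizes.

For regulons, motif scanners emit several redundant hits per gene in the
±10 kb promoter window; hits are rescored by summing per (motif, gene) and
genes ranked by the combined score, truncated to the top 200. A TF module's
**recovery AUC** along a motif's ranking is the mean over positions
t = 1..200 of the fraction of module members within the top t — the
cumulative-recovery definition of the SCENIC family, normalized so AUC ∈
[0, 1]. The AUCs over *all* motifs form the genomic background for that
module. Because these backgrounds are frequently non-Gaussian, a z-score is
avoided: a Gaussian-kernel density (Silverman bandwidth) is fitted to the
background and integrated from the observed AUC upward by trapezoidal
quadrature; a motif with tail mass < 0.05 supports the module. A degenerate
(zero-spread) background falls back to the empirical tail fraction. One
regulon row is emitted per supported motif, its targets being the module
members inside that motif's top-200 list; a union over motifs is
recoverable from the rows.

## The synthetic generators

`simulate_markers()` / `simulate_counts()` emulate a small droplet sample
with planted truth: each cluster is assigned a cell type; that type's
markers draw Poisson counts at `marker_mean = 5` and are zeroed per cell
with `dropout_prob = 0.3`; all other genes draw Poisson at
`background_mean = 0.1`. Defaults — 5 types × 20 markers, 8 clusters × 50
cells, 2000 background genes — keep a full pipeline run in seconds while
exercising every code path. Per cell, all means are scaled so the expected
depth matches a uniform draw from `library_depth_range = (1200, 1600)`:
cells then clear the 1000-read floor, while background genes stay mostly
unexpressed at the median, which is the regime the annotation model
assumes. Poisson-with-dropout was chosen over a negative binomial because
the statistics under test depend only on medians and the expressed/zero
boundary; overdispersion would not change what the tests can detect. The
generators do **not** model ambient RNA, batch effects, doublet mixtures or
gene-length bias — passing recovery tests demonstrates correctness of the
scoring machinery under its own assumptions, not robustness on real tissue.

`simulate_motif_fixture()` plants module members at the top of their own
motif's ranking among 50 motifs over a 1000-gene pool, with decoy motifs
scoring random genes; planted support is detected while ≥ 90% of decoys
stay non-significant.

## Numerical choices and degenerate inputs

* All hypergeometric tails use exact `phyper` upper tails (`P(X ≥ k)`);
  tests cross-check them against brute-force enumeration over all overlap
  outcomes for universes up to 20 genes.
* BH adjustment is the standard step-up, cross-checked against an
  independent re-implementation on random vectors.
* Every writer serializes numbers at 6 significant digits, making pipeline
  reruns byte-identical — determinism is asserted, not hoped for.
* Empty marker tables, missing doublet scores, zero-depth cells, ambiguous
  gene aliases and non-one-to-one ortholog maps are hard errors naming the
  offending records; an all-zero profile yields p = 1 everywhere and an
  "Unknown" label rather than an error.

## Limitations

Annotation is per cluster, not per cell; heterogeneous clusters get a
single label and their minority population is invisible at this
granularity. The sensitivity statistic is operationalized as the
expressed-fraction among clusters called as the type — how often a marker
"identifies its type uniquely" admits several readings, and penalizing
expression in other types would be an equally defensible alternative. The
cell-type universe is whatever the supplied compendium contains; no
ontology reconciles synonymous or nested type names.

## Problem sizes used in the test suite

Unit fixtures use universes of ≤ 20 genes (where exact enumeration is the
oracle), the default synthetic preset (2100 genes × 400 cells) for
end-to-end recovery, 1000-case property sweeps for BH and AUC monotonicity,
and a 50-motif fixture for regulon recovery — sizes chosen so the whole
suite documents the method at interactive speed while still covering every
branch.
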
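---
title: "Methods: subgenome homoeolog expression bias at single-cell resolution"
author: "triadbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgenome homoeolog expression bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadbias)
```

## The problem

*Brassica rapa* (Chinese cabbage) carries the footprint of a whole-genome
triplication: its genes partition into three subgenomes — least fractionated
(LF), moderately fractionated 1 (MF1) and moderately fractionated 2 (MF2) —
plus a set of ungrouped genes (UG) that cannot be assigned to any subgenome.
Many ancestral genes survive as a **1:1:1 homoeolog triad**, one copy per
subgenome; others as duplets (two subgenomes), monads (one), or UG. After
triplication the three copies of a triad need not be expressed equally, and
the direction and strength of that asymmetry can differ between cell types.
This package quantifies that asymmetry from clustered single-cell RNA-seq
counts: per cell cluster, each triad is placed on the 2-simplex of relative
homoeolog contributions and assigned one of seven bias categories.

## The model

### Pseudobulk expression

Raw UMI counts $x_{cg}$ (cell $c$, gene $g$) are library-size normalized,

$$y_{cg} = \log\!\left(1 + s\,\frac{x_{cg}}{\sum_g x_{cg}}\right),
  \qquad s = 10^4 \text{ (CP10K)},$$

and averaged over the cells of each cluster $k$ to give the pseudobulk
profile $\bar y_{kg}$. The classification unit is the cluster, mirroring a
per-cluster reporting of category percentages; cells only enter through the
cluster mean. Classification on the mean of log-normalized values is the
default; the quantity is smooth and monotone in expression, and because
every category centroid is a symmetric configuration of the three
coordinates (center, vertex, or edge midpoint), a monotone transform of the
three homoeolog means does not move a triad that sits on a centroid, so the
choice mainly affects triads far from every centroid.

### Relative contribution and the seven categories

For a triad with homoeolog means $e = (e_{LF}, e_{MF1}, e_{MF2})$ the
relative contribution is $r_i = e_i / \sum_j e_j$, a point on the
2-simplex. The seven categories are fixed points of that simplex:

| category | centroid $(LF, MF1, MF2)$ |
|---|---|
| Balanced | $(1/3, 1/3, 1/3)$ |
| LF / MF1 / MF2 dominant | $(1,0,0)$, $(0,1,0)$, $(0,0,1)$ |
| LF / MF1 / MF2 suppressed | $(0,\tfrac12,\tfrac12)$, $(\tfrac12,0,\tfrac12)$, $(\tfrac12,\tfrac12,0)$ |

A triad is assigned the category whose centroid is nearest in plain
Euclidean distance, the convention of the wheat homoeolog-bias literature
this analysis follows. No log-ratio transform is applied before the
distance; the centroids contain zeros, which an ilr/clr transform cannot
represent. The minimum distance between two centroids is
$\sqrt{6}/6 \approx 0.408$ (Balanced to any suppressed centroid), so a
point within $0.20$ of a centroid is always classified to it.

**Ties.** Points exactly equidistant from two centroids have measure zero
but can be constructed; they resolve deterministically to the earlier
category in the table (Balanced first), so reruns are identical.

**Expression filter.** A triad enters the per-cluster classification only
when the summed mean normalized expression of its three homoeologs reaches
`min_total_expr` (default 0.5). The source analysis states no inclusion
threshold; the default excludes triads whose relative contributions are
dominated by sampling noise while keeping any triad with roughly half a
normalized unit of signal. Raising the filter can only remove assigned
triads. Homoeologs entirely absent from the profile (e.g. removed by gene
QC because they were never detected) count as zero expression — an
undetected copy is exactly what a "suppressed" homoeolog looks like.

### Composition statistics

Per cluster, a gene is *expressed* when it has at least `min_count` (1) raw
counts in at least `min_cells` (1) cells of the cluster; the most permissive
rule is the default because the source data's expressed-gene totals were
published without a stated criterion, and both knobs are exposed. From the
expressed sets the package reports subgenome shares of expressed genes per
cluster, expressed fractions per homoeolog-group class, and genome-wide
subgenome percentages (printed to one decimal, rounded half away from
zero, matching how such percentages are typically typeset; exact fractions
are always returned alongside).

The per-cluster comparison of expression across subgenomes is a one-way
fixed-effects ANOVA whose unit of observation is one expressed gene's mean
normalized expression in that cluster — the quantity a per-cluster
expression box plot displays. Cell-level nesting is deliberately not
modeled; the three LF/MF1/MF2-vs-UG contrasts are pooled-variance t tests
on the ANOVA residual.

### Marker genes

Cluster-enriched genes use the two-sided Wilcoxon rank-sum test of each
gene, cluster vs rest, with one-directional gates applied first: detection
fraction `min_pct` (default 0.25, on the larger of the in/out fractions,
with an in-only option) and log2 fold-change of at least 0.58
($\approx \log_2 1.5$, a round effect size only in log2 units) computed as
$\log_2\frac{\bar y_{in} + 1}{\bar y_{out} + 1}$ on mean normalized
expression. P-values use the normal approximation with tie and continuity
correction — at matrix scale the exact test adds nothing but cost; the test
suite checks the approximation against both `wilcox.test` and an exhaustive
permutation enumeration (6-vs-6 complete separation: absolute error
< 0.02). Benjamini–Hochberg adjustment is applied across all tests
performed.

## The synthetic data generator

Real data at the original accession is not required anywhere: the generator
emits a complete dataset (10x-style triplet, homoeology table, cluster
labels, ground truth) with known per-(triad, cluster) categories.

* **Genome partition.** Defaults follow the published partition — LF 16270,
  MF1 11633, MF2 9653, UG 3464 genes; 2215 triads and 6720 duplets — and a
  `scale` argument floors everything except monads, which are re-derived so
  that $3T + 2D + M + UG$ equals the gene total exactly. Duplets are split
  as evenly as possible over the three subgenome pairs and monads absorb
  each subgenome's remainder; the split is a free choice (the printed
  figures constrain only totals) and is validated for feasibility.
* **Categories.** Each cluster's triad categories realize the published
  mean per-cluster category proportions (Balanced 33.19%, LF dominant
  16.46%, MF1 dominant 12.06%, MF2 dominant 11.31%, LF suppressed 7.24%,
  MF1 suppressed 9.33%, MF2 suppressed 10.41%) by largest-remainder quota,
  shuffled across triads. Quota allocation (rather than i.i.d. multinomial
  draws) is the default because the generator's job is a known ground
  truth: with i.i.d. draws the realized composition differs from the
  nominal mixture by multinomial noise (~2.5 SE deviations occur in a third
  of runs somewhere among seven categories), which a mixture-recovery check
  would then measure instead of the pipeline. `mixture_sampling =
  "multinomial"` restores i.i.d. draws.
* **Simplex spread.** The relative-contribution triple of a triad in a
  cluster is Dirichlet with mean at the category centroid and concentration
  `dominance_strength`; zero centroid components are floored at $10^{-3}$
  before scaling so the Dirichlet is well defined. Root-mean-square distance
  from the centroid scales as $1/\sqrt{\text{strength}+1}$: strength 200
  (default) gives realistic scatter (~0.06), 5000 keeps essentially all
  draws within 0.05 of their centroid.
* **Counts.** Gene $\times$ cluster means: non-triad genes get a baseline
  drawn log-uniformly from `nb_mean_log_range` (default $[\log 0.05,
  \log 5]$ counts/cell — conventional scRNA-seq magnitudes; the source
  data's expression distribution is unpublished, so these are not fitted);
  triad homoeologs split $3\times$ a baseline by the drawn triple; a
  `marker_frac` fraction of non-triad genes (triads are exempt so the bias
  ground truth stays exact) get a `marker_log2fc` fold-change in one home
  cluster. Cells draw counts from a negative binomial with shared
  dispersion (default 0.1; 0 gives Poisson), per-cell lognormal size
  factors with $E[\text{sf}] = 1$ (sdlog 0.3) so normalization is
  non-trivial, and optional independent zero-inflation. A fixed seed makes
  outputs byte-identical across runs.

**What the generator does not emulate:** batch effects, doublets, ambient
RNA, trajectories, spatial structure, gene–gene correlation, or the true
expression-level distribution of the tissue. Passing the recovery tests
therefore shows the pipeline is correct and well calibrated on clean
NB-world data, not that the biological category calls on real tissue are
right — on real data the classification inherits all upstream noise the
simulation omits. One visible artifact: because dominant/suppressed
centroids set homoeolog means exactly to zero, simulated triads have a
*lower* expressed fraction than other gene classes, whereas real triads
show the highest expressed proportion.

## Numerical choices and degenerate inputs

* QC removes cells first (detected-gene window 200–11000, mitochondrial
  fraction > 5%, chloroplast fraction > 30%, with user-supplied organelle
  id sets), then genes detected in fewer than 3 surviving cells; removing
  everything is an error that reports the per-rule tallies. The filter is
  idempotent in practice and tested as such.
* Zero-total cells make CP10K undefined; `normalize_counts` refuses them
  rather than guessing (they cannot survive QC).
* A zero-sum expression triple has no relative contribution;
  `relative_contribution` errors and `classify_all` excludes such triads
  via the expression filter instead.
* Constant ANOVA responses (zero between- and within-group variance) are
  reported as $F = 0$, $p = 1$ rather than `NaN`.
* Percentages are displayed with one decimal, half away from zero; exact
  fractions are always carried in the same table.

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
desk scale, chosen to make every statistical check sharp at interactive
runtimes: a 1/50-scale genome with 3 clusters × 40 cells for mechanical
checks; a 12-cluster, 200-triad, 250-cells-per-cluster simulation at
concentration 5000 for category recovery (2400 triad-cluster decisions);
2000 genes × 200 exchangeable cells for null calibration of the rank-sum
test; 10000 random simplex points against the exhaustive nearest-centroid
search; and the full published gene counts (41020 genes) for the genome
composition arithmetic. The analysis scripts under `analysis/` use a
1/10-scale genome with 12 clusters × 100 cells.

## Known limitations

* The published per-cluster expressed-gene totals and subgenome shares of
  the real tissue depend on the original accession and unstated criteria;
  the package reproduces the *procedures*, and its recomputed genome
  percentage for MF1 (28.4% = 11633/41020) deviates from one printed value
  (29.4%) that is arithmetically inconsistent with the printed counts.
* Classification on pseudobulk means ignores within-cluster heterogeneity;
  a cluster mixing two opposite biases reports their average.
* The Wilcoxon p-values are asymptotic; for clusters with very few cells
  the permutation distribution is coarse (clusters under 3 cells are
  skipped outright).
* `min.pct` gating on the max of in/out fractions is one of two defensible
  readings of the convention; the in-only variant is a flag.
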
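---
title: "Mapping leukemic cells onto a normal hematopoietic hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping leukemic cells onto a normal hematopoietic hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hematree)
```

`hematree` answers two related questions about a leukemic bone-marrow
sample: *which normal cell type does each blast population resemble most*,
and *how is the cellular hierarchy of the marrow distorted relative to
normal hematopoiesis*. This vignette documents the models and the design
decisions behind them.

## The reference model

Normal bone-marrow mononuclear cells (BMMCs) are organized on a curated
differentiation tree rooted at HSC/MPP. Edges are *solid* where
differentiation proceeds continuously inside the marrow (myeloid,
erythroid, dendritic and B arms) and *dashed* where mature cells are
recruited from outside (T/NK cells, some memory B cells). The package
ships a full 38-type tree (`bmmc_tree()`) and an 11-type miniature
(`miniature_tree()`) used as the synthetic default; users can supply their
own via `read_tree_config()`. Tree validation enforces a single root,
acyclicity, and the rule that dashed edges only point into recruited
(T/NK or memory-B) populations.

The expression reference is built at the *subcluster* level rather than
the cell or cell-type level: within every annotated cell type, cells are
partitioned into metacell-like groups with a target median of 100 cells,
and the arithmetic mean of their log-normalized profiles becomes one row
of the reference matrix **B** (restricted to the highly variable gene
set). Subclusters are the right granularity here because they smooth
droplet noise without erasing within-type substructure (donor and state
variation), and because ~100-cell means are stable enough to correlate
across heavy downsampling (`robustness_downsample()` quantifies this on
any atlas). Rows of **B** belonging to the root type form matrix **C**.

### Preprocessing defaults

| parameter | default | rationale |
|---|---|---|
| min expressed genes / cell | 300 | droplet QC floor |
| total counts / cell | 500–30,000 | empty droplets / multiplets |
| mitochondrial fraction | ≤ 10% (prefix `MT-`) | dying cells |
| doublets | external flags, dropped | detection is out of scope |
| normalization | counts per 10⁴, `log1p` | standard workflow |
| variable genes | 3000, binned dispersion | mean-dependence removed in 20 bins |
| PCA | 30 dims, values clipped at ±10 | standard workflow; clip caps outlier leverage |
| clustering | Louvain, SNN Jaccard, k = 20, resolution 1 | standard workflow |

QC is applied per input matrix. Filtering reports the *first* failing rule
per cell in a fixed order (genes, low counts, high counts, mito, doublet),
which makes QC reports reproducible and comparable across runs.

### Max-min k-means subclustering

`choose_k()` realizes the target-median objective as
`k = max(1, floor(n / target + 0.5))`. Seeding is deterministic
farthest-first traversal: the first seed is the cell nearest the subset
centroid, each next seed maximizes its minimum distance to the chosen
seeds (ties by cell id), followed by Lloyd iterations to an assignment
fixpoint. This "max-min" reading — farthest-first seeding, plain k-means
refinement — was chosen over the variance-weighted MaxMin k-means of the
clustering literature because it is deterministic (no restarts), simple,
and empirically lands the median subcluster size within a few percent of
the target on homogeneous populations (the acceptance suite checks a
10,000-cell blob). Distances are Euclidean in the PCA embedding. Empty
clusters are repaired by reseeding with the worst-fit cell, so every
subcluster is nonempty by construction.

## The LIKE score

For a query subcluster centroid $a$ and reference centroid $b$ (both
log-normalized means over the shared gene space):

$$\mathrm{sim}(a,b) = \frac{a \cdot b}{\lVert a\rVert\,\lVert b\rVert},
\qquad d(a,b) = 1 - \mathrm{sim}(a,b)$$

$$\mathrm{like}(a,b) = \mathrm{sim}(a,b)\,\sin\theta \quad \text{(non-T/NK)},
\qquad \mathrm{like}(a,b) = \mathrm{sim}(a,b) \quad \text{(T/NK)}$$

where $\cos\theta = \mathrm{sim}(a, \bar c)$ positions the query relative
to the mean HSC/MPP centroid $\bar c$. Because all profiles are
non-negative, every similarity, distance and score lies in $[0,1]$.

Two design decisions deserve explanation:

**The definition of θ.** The root adjustment could plausibly be (i) the
angle between the query and the root centroid, or (ii) the angular offset
of the query from the root-to-reference axis, measured at the root. Both
are implemented (`mode = "query_vs_root"` — the default — and
`mode = "axis_offset"`). The default is preferred because it is a
per-query quantity: it scales all non-T/NK scores by a common factor and
therefore never reorders them, making the assignment robust to the exact
choice. The axis-offset variant is exposed for exploration, never used
silently.

**The T/NK bypass is per query.** sin θ exists to discount scores of
queries that sit close to the undifferentiated root — such profiles
resemble everything, and their match confidence should be low. T/NK cells
are excluded because they do not arise by intramedullary differentiation,
so "position along the differentiation process from HSC/MPP" is
meaningless for them. The package therefore first determines the nearest
counterpart by raw cosine similarity; if that counterpart is T/NK the raw
similarity is kept as the score, otherwise all scores are scaled by the
query's sin θ. Applying the bypass per *reference row* instead (keeping
raw similarity on T/NK rows for every query) degenerates: any non-T/NK
query whose sin θ is below its T/NK similarity — including every
HSC/MPP-like query, for which sin θ → 0 — would be mis-assigned to T/NK
regardless of the data. The per-query rule preserves the two intended
properties simultaneously: the assignment equals the raw-similarity
argmax (sin θ is a common factor) and the reported score is
root-adjusted. Declared T-lineage queries (T-ALL) are refused outright:
T-cell maturation is extramedullary and the score is undefined for them.

Ties at the argmax are broken by higher raw similarity, then lexicographic
reference row id, so results are deterministic.

## Aberration inference

Sample composition is estimated by summing member cells of subclusters per
assigned type. Relative ratios against the normal composition use additive
smoothing, $(q_t + \varepsilon)/(p_t + \varepsilon)$ with
$\varepsilon = 10^{-4}$, because rare types can legitimately be absent
from one side; ε is recorded in the output. A type is flagged
*proliferation* above the fold-change threshold (default 1.25, the same
threshold used for bulk score calls) and *suppression* below its
reciprocal. The *initiating site* is defined operationally as a
proliferation-flagged node none of whose ancestors along solid edges is
itself flagged; dashed edges never propagate initiation, since recruited
populations do not descend from marrow progenitors in situ. Tree layouts
are deterministic (radial, leaves in configuration order) with node radii
on a log scale, $1 + \log_2(\mathrm{ratio})/2$, clamped to $[0.25, 4]$ so
a normal type draws at unit radius.

## Bulk scoring

Per cell type, an L1-penalized least-squares model with a 0/1 subcluster
membership response is fitted on the gene-standardized centroid matrix
over a 100-point log-spaced λ grid, with λ chosen at the minimum mean
10-fold cross-validation error (folds stratified by membership, seeded; a
1-SE rule and a logistic variant are exposed as options). Squared-error
loss with a membership response is the simplest model family consistent
with "one model per cell type" scoring, and the resulting scores are used
comparatively — against a normal panel — rather than as calibrated
probabilities, so the linear family suffices. Standardization parameters
are frozen at training and reapplied to bulk samples (log-CPM scaled), so
scoring is exactly `intercept + Σ coef · z(g)` with absent genes
contributing zero.

Normalization subtracts the per-type mean of a designated normal panel.
Fold changes on scores need a positive scale, so scores are shifted so
that the normal-panel minimum maps to 1 before the 1.25 rule is applied —
a convention of this package; the threshold itself is configurable. When
comparing cohorts quantified differently, `normalize_between()` maps query
columns onto the pooled quantile distribution of a reference cohort (the
mean of its sorted columns, interpolated at tied ranks); it deliberately
normalizes *onto a frozen target* rather than jointly, so that adding
query samples never changes the reference scale.

## The synthetic cohort generator

The generator is the package's test bed and defines the study conditions
under which its guarantees are verified. Per cell type it builds a mean
expression profile from (i) a shared lognormal baseline (sdlog 1), (ii) a
genome-wide lognormal type program (sdlog 0.8) reflecting the fact that
real cell types differ across thousands of genes, (iii) 25 disjoint marker
genes boosted by 2 log2 units (markers are exempted from the type program
so their fold-change guarantee is exact), and (iv) a blend of 30% of the
parent profile along solid edges, producing the expression gradients a
differentiation continuum shows. Counts are negative-binomial (per-gene
size jittered around 10) with lognormal library sizes (median 2500 counts)
and mild per-donor batch factors (sdlog 0.08, 4 donors). Leukemic samples
expand one blast type to a set fraction, with the blast mean blended
toward the root profile by a `shift` parameter and mildly perturbed.
Pseudobulk samples are Dirichlet mixtures of the type means with lognormal
noise. All generators are pure functions of (config, seed).

What the generator does **not** emulate: ambient RNA, doublet structure,
dropout beyond NB sampling, donor-specific composition differences,
transcriptional bursting, or platform effects. Passing tests on this
generator therefore demonstrate correctness of the algorithms under a
realistic noise model, not performance on any particular real cohort.

## Problem sizes and numerical choices

The test and acceptance suites run at sizes chosen to exercise the
defaults faithfully while staying desk-scale: the shared fixture is the
generator default (11 types × 500 cells, 2000 genes), the subcluster-size
check uses a 10,000-cell blob in 30 dimensions, and the normal-vs-normal
calibration splits an 11,000-cell cohort in half (≥ 5000 cells per side),
builds the atlas on one half and annotates the other; per-type relative
ratios then average 1.00 ± a few per mil. Parameter-recovery checks
(self-projection ≥ 95%, a 70% planted blast recovered within 5 points,
per-type Spearman ≥ 0.9 between LASSO scores and true pseudobulk
fractions over 5 seeds) run on the same fixture.

Numerical details worth knowing: PCA uses an exact eigendecomposition of
the gene-gene covariance with a fixed sign convention (largest-magnitude
loading positive); k-nearest neighbors are exact (blocked brute force);
cosines against the root are clipped into $[-1, 1]$ before
$\sin\theta = \sqrt{1 - \cos^2\theta}$; constant genes are excluded from
HVG selection with a floating-point tolerance; the Wilcoxon marker test
uses the normal approximation with tie correction and Benjamini–Hochberg
adjustment within each cluster; glmnet's coordinate-descent path may
transiently drop a variable, so coefficient-sparsity monotonicity along λ
holds up to small active-set fluctuations.

## Limitations

The sin θ adjustment can inflate differences between adjacent
differentiation stages near the root, and collinearity between progenitor
signatures is reduced but not eliminated — both properties inherent to the
score. T-lineage disease cannot be scored (by design). The atlas bundle
stores full-precision TSV matrices; very large atlases are better kept in
binary stores by the user. The generator's defaults produce well-separated
types; performance on real data with subtler boundaries should be
validated against orthogonal annotations.
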
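# hematree

Hierarchy-based mapping of leukemic cells onto a normal hematopoietic
reference.

## The problem

Acute leukemias (AML, BCP-ALL) expand blast populations that still resemble
a normal hematopoietic cell type — GMP-like, HSC/MPP-like, pro-B-like — and
identifying that normal counterpart, together with how the whole cellular
hierarchy of the bone marrow is distorted, is central to understanding the
cell-of-origin and monitoring treatment. `hematree` implements a complete
workflow for this question, for people analysing bone-marrow mononuclear
cell (BMMC) transcriptomes:

1. **Reference construction.** Normal BMMC scRNA-seq counts are quality
   filtered, log-normalized, reduced to 30 PCs over 3000 highly variable
   genes, clustered (Louvain on a shared-nearest-neighbor graph,
   resolution 1), and partitioned within each annotated cell type into
   metacell-like *subclusters* of a target median size of 100 cells with a
   max-min (farthest-first) seeded k-means. Subcluster centroid profiles
   form the reference matrix **B**; the subset belonging to the root
   HSC/MPP type forms matrix **C**. Cell types live on a curated
   differentiation tree (solid edges: continuous intramedullary
   differentiation; dashed edges: recruited mature cells such as T/NK).

2. **Projection with the LIKE score.** Query subcluster centroids (matrix
   **A**) are compared with every reference subcluster by cosine
   similarity, `sim(a, b) = a·b / (‖a‖‖b‖)`, `d = 1 − sim`. The likelihood
   score adjusts the similarity by the query's angular position relative to
   the HSC/MPP root: `like(a, b) = sim(a, b) · sin θ`, with
   `cos θ = sim(a, c̄)` for the mean root centroid `c̄`. T/NK cells do not
   arise by intramedullary differentiation, so a query whose nearest
   counterpart is T/NK keeps the raw similarity as its score. Each query
   subcluster is assigned the cell type of its maximizing reference row,
   suffixed `-like`.

3. **Lineage aberrations.** Per-cell-type composition of the query is
   divided by the normal composition to give *relative ratios* (ratio > 1:
   proliferation; < 1: suppression; fold change > 1.25 flags aberrancy).
   Flags are placed on the tree, the root-proximal flagged node along solid
   edges is reported as the initiating site, and tree/radar layouts are
   produced for plotting.

4. **Bulk deconvolution.** One LASSO model per cell type (squared-error
   loss, 0/1 subcluster membership response, 10-fold cross-validated λ) is
   trained on the gene-standardized subcluster centroids and used to score
   bulk RNA-seq samples; scores are normalized by subtracting the normal
   panel mean and aberrant types called at fold change > 1.25.

A negative-binomial synthetic cohort generator (typed mean profiles with
marker boosts and expression gradients along the tree, lognormal library
sizes, donor batch shifts, leukemic blast expansion, pseudobulk mixtures)
makes the whole pipeline testable with known ground truth — no downloads
required.

## Worked example

```r
library(hematree)

cfg  <- synthetic_config(seed = 1)          # 11-type tree, 500 cells/type
ref  <- simulate_reference_cohort(cfg)
ref$counts
#> CountMatrix: 5500 cells x 2000 genes (48.0% nonzero)

built <- run_build_ref(ref$counts, ref$truth$cell_types, cfg$tree,
                       n_hvg = 1500, verbose = FALSE)
built$atlas
#> ReferenceAtlas: 55 subclusters, 11 cell types, 1500 genes

# a leukemic sample: 60% blasts expanded from GMP, shifted toward the root
leuk <- simulate_leukemia_sample(ref$truth, blast_type = "GMP",
                                 blast_fraction = 0.6, shift = 0.3,
                                 n_cells = 2000, seed = 2)
ann <- run_annotate(leuk$counts, built$atlas, n_hvg = 1500, verbose = FALSE)
head(ann$like$table[, c("subcluster", "assigned_type", "best_score", "sin_theta")])
#>   subcluster assigned_type best_score sin_theta
#> 1     C0|s01      GMP-like  0.4225119 0.4291102
#> 2     C0|s02      GMP-like  0.5215876 0.7902256
#> 3     C0|s03      GMP-like  0.5332297 0.6170533
#> ...

round(ann$composition$fractions, 3)
#> CD14 Mono   CLP   CMP   Ery   GMP GMP-Mono HSC/MPP   MEP pre-B pre-pro-B  T/NK
#>     0.044 0.036 0.039 0.047 0.580    0.050   0.043 0.038 0.046     0.040 0.038

abr <- run_aberration(ann$composition, built$atlas)
abr$aberration
#> AberrationProfile: 11 cell types (epsilon = 0.0001)
#>   flags: proliferation=1, suppression=10
#>   initiating sites: GMP
```

The 60% planted GMP blast population is recovered at 58%, GMP is the only
proliferation-flagged type, and the initiating site is located at GMP. The
per-type LASSO scores track true pseudobulk mixing fractions:

```r
models <- run_deconv_train(built$atlas, seed = 1)
bulk   <- simulate_bulk_cohort(ref$truth, n_samples = 6, seed = 3)
scores <- run_deconv_score(bulk$bulk, models)
cor(scores$raw[, "GMP"], bulk$fractions[, "GMP"], method = "spearman")
#> [1] 0.943
```

Plots: `render_plots("circle_tree" | "tree" | "radar" | "marker_dot", ...)`
return ggplot objects (optionally written to file).

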
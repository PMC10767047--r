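# spatglia

Spatiotemporal analysis of glial-cell activation in spot-based (Visium-style)
spatial transcriptomics of amyloid-pathology mouse brain.

In amyloid models such as 5XFAD, microglia and astrocytes switch into
disease-associated states (DAM, DAA) as plaques accumulate, and the switch is
not spatially uniform: white matter (WM) activates months before the gray
matter (GM) does. Demonstrating that pattern from spot-level transcriptomics
takes a chain of methods — anatomical clustering of spots, region-wise
differential expression, signature scoring, integration with fluorescence
plaque images, and pseudotime over microglial gene signatures. `spatglia`
implements that chain end to end for analysts working with 10x-style spot
matrices, together with a seeded synthetic-data generator that emulates the
2 genotype × 2 age × 2 replicate study design with a WM-early / GM-late
activation field, so every stage can be verified against known ground truth.

## What is inside

* **Synthetic study generator** (`simulate_study`, `simulate_plaque_sample`,
  `simulate_activation_gradient`, `render_plaque_image`) — hex-lattice
  tissue with seven anatomical regions, negative-binomial counts
  (`mean = baseline · fold^activation`, variance `m + m²/θ`), DAM/DAA/
  homeostatic programs driven by an age- and genotype-dependent activation
  field, and a paired plaque-like fluorescence image with known derangements
  and landmarks.
* **Preprocessing and clustering** — `LogNormalize`-style depth
  normalization `ln(1 + 10⁴·x/total)`, vst-flavoured highly-variable-gene
  selection, covariate regression + z-scoring, PCA (top 30 components),
  SNN-Jaccard graph + Louvain at resolution 0.2, one-vs-rest Wilcoxon
  markers (logFC > 0.3), replicate Pearson-correlation QC.
* **Differential expression** — two-part hurdle test (logistic detection +
  Gaussian positive part, combined LR ~ χ²₂), BH adjustment, per-cluster
  AD-vs-WT gene lists at FDR < 0.05 and logFC > 0.25, cross-cluster
  intersections, and a pseudobulk + label-shuffle robustness check.
* **Signature scoring** — binned-control module scores (24 bins, 100
  controls per gene) for the 8-gene DAM set (*Lpl, Cst7, Axl, Itgax, Spp1,
  Cd9, Ccl6, Csf1*), the 7-gene DAA set and arbitrary GMT sets, with
  cluster/group comparisons and spatial export.
* **Image linkage** — Otsu masking + Gaussian smoothing, rigid → affine
  (optionally demons) registration with landmark RMSE reporting, 32 × 32
  patch extraction at spots, a training-free 10-feature bank (pluggable
  extractor), latent PCA (`ImageLatent_1` = plaque-intensity axis) and
  per-gene OLS association with top-k selection.
* **Trajectory** — PCA on the 28-gene microglial panel, principal tree
  (k-means + MST + edge projection), root selection by late-disease-group
  enrichment, geodesic pseudotime, branch decomposition, spatial maps and
  expression-vs-pseudotime window curves.
* **Enrichment** — exact hypergeometric over-representation of gene lists
  against GMT collections.

## Worked example

```r
library(spatglia)

## simulate a small version of the study (4 samples at 3 months)
ds <- simulate_study(seed = 1, n_rows = 24, n_cols = 18, n_genes = 600,
                     n_region_markers = 15,
                     samples = c("WT_3M_r1", "WT_3M_r2",
                                 "AD_3M_r1", "AD_3M_r2"))
ds
#> spot_dataset: 600 genes x 1728 spots, 4 sample(s)

## cluster spots and annotate clusters by their majority truth region
pip <- cluster_pipeline(ds, n_hvg = 400, n_pcs = 20, seed = 1)
majority_region(pip$clusters, ds$truth$region)
#>              0              1              2              3              4
#>       "border"     "thalamus" "cortex_inner"  "hippocampus" "cortex_outer"
#>              5              6
#>           "WM"     "striatum"

## DAM signature scores: WM is already activated at 3 months, GM is not
sc <- module_score(pip$normalized, dam_genes(), seed = 1)
by_grp <- score_by_group(sc, ds$truth$region, ds$meta$genotype, ds$meta$age)
subset(by_grp$tests, cluster %in% c("WM", "cortex_inner"))
#>        cluster age  mean_diff            p
#> 2 cortex_inner  3M 0.00134481 6.418680e-01
#> 7           WM  3M 0.52993026 1.304712e-21

## region-wise differential expression (AD vs WT) in the WM
wm <- ds$truth$region == "WM"
de <- hurdle_test(pip$normalized[, wm], ds$meta$genotype[wm],
                  contrast = c("AD", "WT"))
head(de[order(de$p_adj), ], 5)
#>       gene      logFC        p_raw        p_adj   pct_A     pct_B
#> 14    Ctsb  0.9805056 2.322421e-22 1.393453e-19 1.00000 0.9479167
#> 2     Cst7  0.6218366 2.894530e-14 8.683590e-12 1.00000 1.0000000
#> 15    Gfap  0.5359737 2.791345e-13 5.582691e-11 1.00000 1.0000000
#> 21    Ctss -0.6293464 7.615642e-11 1.142346e-08 0.78125 0.9791667
#> 27 Tmem119 -0.6078538 1.273887e-10 1.528665e-08 0.93750 0.9687500
```

Reading the output: the seven Louvain clusters map one-to-one onto the
ground-truth anatomical regions; the DAM score difference between AD and WT
3-month mice is large and highly significant in the WM cluster
(+0.53, p ≈ 10⁻²¹) but absent in the inner cortex (+0.001, p = 0.64) —
the WM-early pattern; and the WM DE table recovers disease markers going up
(*Ctsb*, *Cst7*, *Gfap*) while homeostatic microglial genes go down
(*Ctss*, *Tmem119*).

## Vignette

`vignettes/spatglia-methods.Rmd` documents the models, the parameter choices
and their rationale, the design decisions taken where the methods were
underdetermined, and what passing the synthetic-recovery suite does and does
not demonstrate about real tissue.
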
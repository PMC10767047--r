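---
title: "spatglia: models and methods"
author: "spatglia authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatglia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`spatglia` reimplements, as a tested pipeline, the spatiotemporal analysis of
glial-cell activation in spot-based (Visium-style) spatial transcriptomics of
an amyloid-pathology (5XFAD-like) mouse brain: region clustering of spots,
region-wise differential expression, disease-associated microglia (DAM) and
astrocyte (DAA) signature scoring, registration of a paired fluorescence
image with image-latent/gene association, and microglial-signature pseudotime
with spatial mapping. Because the real deposited data are not required, the
package ships a seeded synthetic-data generator that emulates the study
design — 2 genotypes (WT/AD) x 2 ages (3M/7M) x 2 replicates, with
white-matter-early / gray-matter-late activation — so every stage of the
pipeline can be exercised and scored against a known ground truth.

# The synthetic study

## Tissue and counts

A sample is a rectangular offset lattice (odd rows shifted by half a spacing,
mirroring Visium hex packing). Horizontal bands assign the seven anatomical
regions (outer/inner cortex, hippocampus, WM, thalamus, striatum) and the
outermost ring of spots is a border/meninges analog. The default sample is
50 x 40 = 2,000 spots; the default study is 8 samples and 2,500 genes.

Counts are negative binomial. The expected count of gene $g$ in spot $s$ is

$$\mu_{gs} = b_g \prod_p f_p^{\,a_{ps}}, \qquad
  X_{gs} \sim \mathrm{NB}(\mu_{gs} \cdot \ell_s,\ \theta)$$

where $b_g$ is the gene's baseline mean, each expression *program* $p$
carries a fold $f_p$ reached at activation 1, $a_{ps} \in [0,1]$ is the
per-spot activation of that program, $\ell_s$ is a log-normal library factor
(sd 0.2) and $\theta$ is the NB size (variance $\mu + \mu^2/\theta$).

Choices a reader should know about, with their reasons:

* **NB size 6 for the study generator.** Visium spots pool roughly 5–10
  cells, so spot-level counts are markedly less overdispersed than
  single-cell counts; size values in the mid single digits are typical of NB
  fits to spot data. (The generic `gene_program()` default remains the more
  conservative size 2.)
* **Baseline means are log-normal** (median ≈ 1.2 counts, capped at 60), and
  the 42 named signature genes (DAM, DAA, microglial panel) draw baselines
  from a spread distribution clipped to [3, 25] rather than one shared value.
  The spread matters: signature scoring draws its control genes from
  expression-matched bins, and in a desk-scale gene universe a shared
  baseline would place every disease-responsive gene in the same bin, so the
  controls themselves would carry the disease signal and cancel it — an
  artifact a genome-scale universe does not have. Spreading the baselines
  restores the realistic situation in which each bin is dominated by
  unrelated genes.
* **Region identity** is encoded by 40 marker genes per region at fold 4,
  the synthetic analog of the strong regional expression differences that
  make anatomical clusters recoverable from expression alone.

## The activation field

Disease activation per (region class, genotype, age) encodes the
WM-early / GM-late claim the pipeline must recover:

| group | WM | GM | border |
|---|---|---|---|
| WT (any age) | 0 | 0 | 0.4 |
| AD 3M | 0.8 | 0 | 0.4 |
| AD 7M | 1.0 | 0.8 | 0.4 |

The border level is shared by all mice: border-associated macrophages express
much of the DAM signature in healthy tissue too. GM activation at 3M is zero
by design — the generator's contract is that the 3-month GM is at fold parity
with WT, which is exactly what the recovery test asks the scoring stage to
confirm (WM difference detected, GM difference not detected). An
`activation_field()` is monotone in age within each region by construction.

The activation drives three programs at once: the DAM program (the 8 DAM
markers plus the reactive microglial panel genes, fold 2 by default), the DAA
program (7 genes, fold 2) and a homeostatic-microglia program whose fold is
0.6 — homeostatic markers such as *P2ry12* and *Tmem119* fall as microglia
activate.

## The plaque image

`render_plaque_image()` builds a fluorescence-like image from a driver gene:
each spot's log1p count is splatted at its pixel position, convolved with a
Gaussian PSF, and divided by the identically blurred unit-amplitude splat.
The division is a Nadaraya–Watson kernel-regression estimate; without it the
image would be a spot-*density* field (bright wherever spots are dense,
dark at the tissue edge) rather than an *intensity* field, which is what a
fluorescence micrograph of continuous tissue actually is. The in-tissue 10th
percentile is then subtracted so the background is dim and the plaque foci
bright, as in amyloid immunofluorescence; outside-tissue pixels are zero.
Gaussian read noise (sd 0.02) is added last and the image clipped to [0, 1].
A known derangement (any transform chain) can be applied, in which case five
landmark pairs linking the reference and deranged frames are returned for
registration scoring.

The single-section plaque sample (`simulate_plaque_sample()`) drives one
gene (`Driver`, baseline 20, fold 6, NB size 12) with a smooth field made of
8 Gaussian foci with radii of 2–4 spot spacings; 20 bystander genes follow
the field weakly (fold 1.3) and the rest of the 500-gene universe is flat.
Fold 6 reflects how strongly plaque-induced genes respond in the immediate
neighbourhood of amyloid deposits; foci of a few spot spacings reflect
plaque-field extents at 7 months.

## The activation-gradient benchmark

Trajectory inference is scored on a dedicated gradient simulation
(`simulate_activation_gradient()`): 500 spots carry a latent activation
$a \in [0,1]$ laid out as a smooth diagonal spatial gradient; the 16
reactive panel genes scale as $5^a$, the 12 homeostatic genes as $0.3^a$,
both from baseline 50 at NB size 8, and spots whose noisy activation
exceeds 0.6 are labelled AD-7M (the "late" group). The high baseline and
moderate dispersion are the spot-level regime for this panel — *Cst3*,
*Apoe*, *Fth1*, *B2m* and peers are among the most abundant transcripts in
brain spots — and a ~5-fold homeostatic-to-DAM swing is in line with the
reported magnitude of DAM induction once diluted into a multi-cell spot.

# Pipeline methods

## Normalization, variable genes, scaling, PCA

`log_normalize()` is depth normalization with a natural log:
$\ln(1 + 10^4 \, x_{gs} / \sum_g x_{gs})$. `select_hvg_vst()` fits a
loess trend (span 0.3, degree 2) of $\log_{10}$ variance on $\log_{10}$ mean,
standardizes counts by the trend-predicted sd, clips at $\sqrt{n}$, and ranks
genes by the variance of the clipped values. `scale_and_regress()`
residualizes each gene on the covariates (per-spot total counts, and the
mitochondrial fraction when `mt-` genes exist) by least squares, then
z-scores with the population sd (ddof 0) and clips at ±10 — the sd convention
and clip value are stated because "scaling" alone underdetermines them.
`embed_pca()` eigendecomposes the gene–gene covariance; components are
ordered by explained variance and the sign of each component is fixed so its
largest-|loading| gene loads positively, making embeddings reproducible
across platforms.

## Clustering

`cluster_spots()` builds an exact k-nearest-neighbour graph (k = 20,
Euclidean in the top 30 PCs), re-weights by shared-neighbour Jaccard
similarity $s/(2k - s)$ pruned below 1/15, and runs Louvain at resolution
0.2 (`igraph::cluster_louvain`). The kNN size, weight scheme and prune value
are package decisions — the clustering method and resolution are the
pipeline's fixed parameters, but no published value exists for the rest.
Louvain node order depends on the RNG, so the run is seeded and final labels
are re-indexed by decreasing cluster size. Cluster-to-region annotation for
synthetic data is by majority ground-truth label (`majority_region()`); the
original visual atlas comparison has no computational analog.

## Differential expression

`hurdle_test()` is a two-part model per gene: a logistic regression of
detection (expression > 0) and a Gaussian regression of the positive
log-normalized values, each with a group term plus (by default) the
per-spot detection rate as covariate. The combined statistic is the sum of
the two likelihood-ratio statistics referred to $\chi^2_2$ — one group
coefficient per component. Logistic separation (a group with 0% or 100%
detection) is handled by clamping fitted probabilities to
$[10^{-6}, 1-10^{-6}]$; a component whose group term cannot be estimated
(e.g. fewer than two positive spots in a group) contributes a zero LR; genes
that are never detected get p = 1. Log fold change is
$\ln\!\big((\overline{\mathrm{expm1}\,x_A} + 1)/(\overline{\mathrm{expm1}\,x_B} + 1)\big)$
— natural log with a +1 pseudocount on de-logged means, the convention under
which the usual marker thresholds (0.25 for genotype contrasts within a
cluster, 0.3 for cluster-vs-cluster markers) are stated. FDR control is
Benjamini–Hochberg (`stats::p.adjust`).

`pseudobulk_and_shuffle()` sums raw counts per sample within a cluster and
contrasts groups by a Student t-test on log2 CPM. With 2–4 samples per group
this is a descriptive robustness device, not an inferential claim: the
reported quantity is the count of genes below the nominal threshold under
the true labelling versus random label shuffles.

## Signature scoring

`module_score()` implements binned-control scoring: genes are cut into 24
equal-frequency bins by mean log-normalized expression; each signature gene
draws 100 control genes from its bin (with replacement when a bin is
smaller, which happens in desk-scale universes); the spot score is the mean
signature expression minus the mean of the drawn controls. The draw is
seeded and recorded, so scores are exactly reproducible. A constant matrix
scores exactly zero.

## Image registration and latent association

`preprocess_image()` converts to grayscale, Otsu-masks the tissue, and
returns a sigma-5 Gaussian-smoothed copy. `register_images()` estimates the
fixed-to-moving coordinate map by multi-resolution (3-level pyramid)
Nelder-Mead minimization of mean-squared error, in a rigid stage (rotation +
translation, about the image centre) followed by a full affine stage seeded
from the rigid result; an optional nonlinear stage is a Gaussian-regularized
demons refinement returning a dense displacement field (a deliberate
simplification of symmetric diffeomorphic registration — adequate for the
residual deformations left after the affine stage at this image scale). If
the optimizer hits its iteration cap the best-so-far transform is returned
with a warning. With landmarks supplied, the landmark RMSE (pixels) is
reported. For the synthetic images the PSF already exceeds the 5-pixel
preprocessing blur, so registration is run on the grayscale directly —
re-blurring an already smooth image slightly biases the scale estimate
because Gaussian smoothing does not commute with scaling.

`extract_patches()` takes 32 x 32 patches at spot centres with the half-open
convention [c−16, c+16) and zero padding. `patch_features()` is a
training-free 10-feature bank (mean, sd, 10/50/90% quantiles,
gradient-magnitude mean and sd, and Gaussian-response means at sigma 1, 2,
4) behind a pluggable extractor interface; an external CNN embedding can be
substituted without touching the downstream logic. The bank is deliberately
intensity-centric: eight of ten features respond monotonically to local
intensity, so the first principal component of the z-scored features —
`ImageLatent_1`, sign-fixed to correlate positively with patch mean — is the
local-plaque-intensity axis. `associate_genes()` regresses each gene's
log-normalized expression on the z-scored latent; the coefficient is the OLS
slope, genes are ranked by it in descending order, and the top 100 form the
selected set. Ranking by the signed slope (not |slope|) mirrors the use of
the latent as "plaque accumulation": the genes of interest are the
positively tracking ones.

## Trajectory inference

`panel_embedding()` restricts to the 28-gene microglial panel (log-normalize,
z-score, PCA, 10 components). `learn_principal_graph()` is a deterministic
principal-tree learner: k-means centroids (k = clamp(⌈n/50⌉, 5, 100), 10
restarts), a Euclidean minimum spanning tree over the centroids, and
projection of every spot to the nearest point on any tree edge. This is a
reimplementation of the principal-graph idea with the same
topology-recovery contract as SimplePPT-style learners, not a port.
`select_root()` operationalizes the study's manual orientation step: per
node, the fraction of projected spots in the late disease group (AD, 7M);
the root is the leaf with the minimal late fraction, ties to the smallest
node id with a warning. Pseudotime is the tree geodesic from the root to
each projection point, hence nonnegative, monotone along root-to-leaf paths
and 1-Lipschitz along the tree. Branches are root-to-leaf paths; trunk spots
belong to every branch through their edge and are flagged shared. The
correspondence between branches and the study's three named trajectories is
a reporting step — `rank_branches_by_gene()` ranks branches by a query
marker (e.g. *Axl*, *Lpl*) — not an algorithmic one, and the learner may
yield a different branch count on other data.

## Over-representation

`hypergeometric_ora()` is the exact upper-tail hypergeometric test
$P(X \ge k)$ over user-supplied gene sets (GMT), BH-adjusted across sets.
The universe defaults to the assayed genes of the dataset at hand; no live
annotation databases are touched.

# Verification scale and determinism

Everything stochastic is seeded, and the generators are bit-reproducible
under a fixed seed. The test suite checks exact oracles (enumerated Wilcoxon,
brute-force BH, exhaustive hypergeometric for N ≤ 12, closed-form OLS slopes,
bit-exact MTX roundtrips) and then property-style recovery at the study's
design scale: clustering on five full 16,000-spot datasets; DE calibration on
2,000 null genes and power on fold-2 spikes with 200 spots per group; the
WM-early pattern, the pseudotime gradient and the pseudobulk-shuffle check on
20 seeded replicates each (a detection per run is a two-sided Wilcoxon at
alpha 0.01, with ground-truth regions standing in for clusters — clustering
accuracy is scored separately); registration on one 256 x 256 derangement and
image-latent association on one 500-gene section. These sizes are the
package's verification scale: large enough for stable properties, small
enough to re-run routinely.

# What passing does and does not show

The generator emulates the statistical skeleton of the study — region-marked
NB counts, an age- and genotype-dependent activation field, a paired
intensity image, library-size variation. It does not emulate segmentation
artifacts, spatial autocorrelation beyond region blocks and plaque foci,
batch or slide effects, cell-type mixtures within spots, zero-inflation
beyond NB, or atlas-level anatomy. Passing the recovery suite therefore
shows the pipeline is correct and well calibrated on data satisfying its own
assumptions; it does not by itself validate biological conclusions on real
tissue. Known limitations worth restating: the hurdle test assumes
independent spots (no spatial correlation in errors); the registration
metric is plain MSE, so strong intensity nonstationarity between modalities
would need the mutual-information variant the interface leaves room for;
and the principal-tree learner is deterministic but greedy — on data without
a dominant trajectory its topology can be unstable across seeds.
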
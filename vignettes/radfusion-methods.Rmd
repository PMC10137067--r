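---
title: "Multi-view radiomics fusion subtyping and radiogenomics association: methods"
author: "radfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view radiomics fusion subtyping and radiogenomics association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`radfusion` implements a radiogenomics analysis for contrast-enhanced CT
(CE-CT) of hepatocellular carcinoma and similar solid tumours. The method
has three arms:

1. **Multi-view radiomics.** From each patient's arterial- and
   venous-phase volumes, four volumes of interest (VOIs) are built: the
   tumour in each phase and a 10 mm peritumoral shell in each phase. Each
   VOI yields 100 features (18 first-order, 14 shape, 68 gray-level
   texture features over GLCM / GLRLM / GLSZM / GLDM).
2. **Fused imaging-feature subtyping.** Per-view patient similarity
   networks are integrated by similarity network fusion (SNF), the fused
   network is clustered spectrally, and the number of clusters is chosen
   by consensus clustering over subsampled re-runs. For two subtypes the
   label `FIFS1` is anchored to the better-prognosis arm.
3. **Radiogenomics association.** Prognostic radiomics features (PRFs)
   are identified by a differential-then-prognostic cascade; signed
   co-expression modules are built from matched expression data, filtered
   for subtype association, prognosis and PRF correlation; pathway
   enrichment scores of the retained modules are paired with PRFs by
   correlation under one FDR pass; and a nearest shrunken centroid (NSC)
   classifier transfers the subtypes to expression-only cohorts.

A synthetic-cohort generator plants all the structure the analysis
assumes, so every stage is verifiable at desk scale.

# The synthetic cohort: what it emulates and what it does not

`generateCohort()` draws, per patient:

* **Features**: i.i.d. standard normal noise per view, with a mean shift
  of `textureEffectSD` (default 1.5 SD) on a fraction (default 30%) of
  the texture features, applied to subtype-2 patients with a random sign
  per feature. Cross-view dependence arises only through the shared
  latent subtype — the simplest structure under which fusing views helps.
  Columns are z-scored, mirroring the analysis contract.
* **Expression**: negative-binomial counts (default dispersion 0.1)
  around log-normal baseline means, with an "immune" module (100 genes)
  elevated log2-fold 2 in subtype 1 and a "cell-cycle" module (80 genes)
  elevated in subtype 2.
* **Survival**: exponential event times with a subtype-2 log hazard of
  `log(1/0.146)` by default, and uniform administrative censoring whose
  horizon is solved numerically so the expected censored fraction matches
  `censoringRate` (default 0.3). Times are rounded up to whole days, so
  ties occur and the Efron correction in the Cox fit is exercised.
* **Clinical**: a log-normal AFP-like marker elevated in subtype 2 and an
  ordinal grade-like covariate skewed toward high grade in subtype 2.

The default cohort size is 30 with subtype proportions 16/30 and 14/30,
the discovery-scale configuration the pipeline targets.
`generateVolumes()` additionally produces two-phase image volumes with
ellipsoidal lesions: subtype-1 lesions are low-intensity with
heterogeneous voxel noise (high co-occurrence contrast after
discretization), subtype-2 lesions high-intensity with a smooth gradient
(low contrast), and the venous phase adds a constant enhancement offset.

What the generator does **not** emulate: CT physics and reconstruction,
scanner batch effects, spatially correlated image noise, realistic
gene-gene correlation beyond the planted modules, and non-proportional
hazards. Passing tests therefore demonstrate the correctness and
calibration of the machinery under its stated assumptions, not
performance on real CE-CT cohorts.

# Preprocessing and the feature registry

Volumes are resampled to 1 x 1 x 1 mm (trilinear for intensities, nearest
neighbour for masks) and VOI intensities are discretized with a fixed bin
width of 25: `level = floor((I - min)/25) + 1`, with the minimum taken
inside the mask so that texture features are invariant to a constant
intensity offset. The peritumoral shell contains voxels at Euclidean
distance in `(0, 10]` mm of the tumour, minus the tumour and an optional
exclusion mask (e.g. beyond the liver parenchyma); distances use physical
spacing.

Registry conventions that the tooling literature leaves open, fixed here
and tested against brute-force oracles:

* GLCM and GLRLM use the 13 unique 3D directions at voxel distance 1,
  symmetric accumulation, features computed per direction then averaged;
  directions contributing no voxel pair are skipped.
* GLSZM zones are 26-connected components of constant level; GLDM
  dependence is 1 plus the number of equal-level in-mask 26-neighbours
  (tolerance alpha = 0), counting the centre so small-dependence
  emphases stay finite.
* The 22 GLCM features are the standard set minus the deprecated sum
  average and the expensive maximal-correlation coefficient, keeping the
  total texture count at 68.
* Surface area is computed by exposed-voxel-face counting rather than a
  marching-cubes mesh: deterministic and exactly testable, but
  systematically larger than mesh-based areas (a unit voxel has area 6,
  not that of a sphere-like mesh). `MeshVolume` equals `VoxelVolume`
  under this voxel model. Axis lengths come from the eigenvalues of the
  voxel-centre covariance (`4 * sqrt(lambda)`).
* Zero-variance conventions: skewness and kurtosis of a constant region
  are 0; division-by-zero features return their limit (e.g. GLCM
  correlation of a constant region is 1).

# Fusion and model selection

Per view, the affinity is the scaled-exponential kernel
`W(i,j) = exp(-d^2(i,j) / (mu * eps_ij))` with
`eps_ij = (knn_i + knn_j + d(i,j))/3`, Euclidean distance on z-scored
columns, `mu = 0.5`, and `k = min(20, floor(n/3))` neighbours — the
common default of 20 is degenerate at n = 30. SNF then iterates
`P_v <- S_v (mean of the other views' P) S_v^T` for 20 rounds, where
`S_v` is the row-normalized k-NN kernel; each iterate is symmetrized and
renormalized so half the row mass sits on the diagonal. The outputs are
averaged, symmetrized and row-normalized. With a single view the
normalized input is returned; note that fusing m identical copies of a
view is *not* an identity operation — the iteration smooths the network
along its k-NN graph — but the result is exactly independent of m.

Spectral clustering uses the normalized Laplacian embedding (k smallest
eigenvectors, rows renormalized) with seeded k-means, 50 restarts, labels
numbered by first occurrence so restarts cannot permute them.

**Choosing k.** Consensus clustering re-runs the entire pipeline
(affinity, fusion, clustering) on 1000 subsamples of 80% of patients —
resampling the pipeline rather than re-clustering one fused network is
the conservative reading of consensus-based model selection for a fusion
method. The consensus entry (i,j) is the co-clustering fraction over
co-samplings. The per-k CDFs of the consensus entries are summarized two
ways: the delta-area vector (reported as a diagnostic) and the
**proportion of ambiguous clustering** (PAC: mass in the (0.1, 0.9)
window), which is the selection criterion — `chosenK` minimizes PAC,
ties going to the smallest k. A fixed relative-delta-area threshold was
considered and rejected: the area under the consensus CDF grows
mechanically with k (every additional split moves co-clustering mass to
zero), so "largest k with relative area gain above a threshold" always
drifts to the largest k tested, even on perfectly separated two-cluster
data. PAC is the standard quantitative form of the usual
consensus-matrix/CDF inspection and recovers the planted k = 2 crisply.

The silhouette of an assignment is computed on the dissimilarity
`1 - P/max_offdiag(P)` of the symmetrized fused network (the raw feature
space is also possible by passing a similarity matrix directly);
singleton clusters contribute 0. The view-ablation table re-runs the
whole procedure per combination pattern (all four views; tumour-only;
venous-only; arterial-only pairs) and reports chosen k, silhouette and
log-rank p.

# Survival analysis

Kaplan-Meier, log-rank and Cox proportional hazards stand on the
`survival` package. Fixed conventions: Efron tie handling (day-resolution
times tie frequently; Breslow is switchable), Wald 95% intervals
`exp(coef +/- 1.96 SE)`, two-sided p values. Constant covariates and
non-converged fits are rejected rather than silently reported. The
log-rank statistic equals the Cox score test on a group indicator in the
untied case, which is tested.

# Expression statistics

Counts are normalized by median-of-ratios size factors (checked against
the reference implementation in a test). Differential expression uses
Welch's t-test on `log2(normalized + 1)` with fold changes from group
means (pseudocount 1) and Benjamini-Hochberg adjustment; a gene is
significant iff `|log2FC| > 1` and adjusted `p < 0.05`. This documented
substitution keeps the thresholds — the analytically meaningful part —
while replacing the negative-binomial shrinkage machinery of specialised
DE packages with a desk-verifiable test; it is not numerically identical
to them. `FIFS1` is the reference level, recorded in the output metadata.

Single-sample gene-set scores are the rank-based running-sum statistic
(weight 0.25) rather than a kernel-density variant: per sample, the score
is the summed difference between the weighted in-set rank ECDF and the
out-of-set ECDF, rescaled by the global max-min. Only ranks enter, so
scores are invariant to monotone transforms of a sample's expression.
Immune/stromal-style scores are obtained by calling the same scorer on
user-supplied gene sets — there is no separate code path.
Over-representation uses the exact hypergeometric upper tail with BH
across sets.

# Co-expression modules

Signed adjacency `((1 + cor)/2)^beta` with beta = 8, topological overlap
smoothing, average-linkage clustering of `1 - TOM`, a **static cut** and
a minimum module size of 30 (smaller branches go to the unassigned
"grey" pool). The static cut replaces dynamic-hybrid tree cutting: it is
deterministic and exactly testable, at the cost of not adapting to
branch shape. The cut height default is 0.97: at beta = 8 even unrelated
genes sit near TOM dissimilarity 0.99, so a cut above that level merges
everything; 0.97 separates planted modules (which merge far below it)
from the noise regime across the generator's conditions. Module
eigengenes are first principal components of standardized member
expression, unit variance, sign-oriented to correlate positively with
their members. Networks are built on the most-variable 5000 genes by MAD
(configurable) when the input is larger.

# The PRF cascade and the association network

Stage 1 keeps features whose z-scored values differ between subtypes
(two-sample Student's t-test, p < 0.05); stage 2 keeps stage-1 survivors
whose univariate Cox p is below 0.05. Retained PRFs are annotated with
view, phase, region, class and the subtype with the higher mean.
PRF-related modules must pass all three of: subtype correlation
(p < 0.05), eigengene prognosis (Cox p < 0.05), and correlation with at
least one PRF (p < 0.05). Pathway-feature pairs are Pearson correlations
between per-patient pathway scores (restricted to the retained modules)
and PRF values, with **one** BH pass across the full pathway x PRF grid
— per-feature adjustment would understate the multiplicity the network
figure implies — retaining pairs with q < 0.05. The association network
keeps the top five pairs per PRF by |r| (ties by pathway name), and the
top PRF-related gene is the member gene with the largest |r| among those
with p < 0.05.

# The subtype classifier

Candidate genes are the intersection of significant DE genes with
PRF-related-module membership. The NSC classifier shrinks standardized
centroid offsets `d_ik = (xbar_ik - xbar_i)/(m_k (s_i + s_0))` by soft
thresholding over a grid of 30 values from 0 to `max |d_ik|`; the
threshold is chosen by stratified 10-fold cross-validation as the
largest value attaining the minimal error (fewest genes at lowest
error). Priors are empirical class frequencies. Prediction minimizes the
standardized squared distance to shrunken centroids minus twice the log
prior; ties go deterministically to the first class; genes missing in an
external cohort are imputed at the overall centroid with a warning.
External validation re-anchors two predicted arms to prognosis, compares
them by Kaplan-Meier/log-rank and reports row-z-scored,
hierarchically-ordered immune gene-set scores.

# Numerical choices and degenerate inputs

* Empty masks, empty peritumoral shells, missing phases: patients are
  skipped with a warning during extraction; empty masks error in the
  low-level functions.
* Z-scoring: constant columns are reported and left unscaled; a
  single-patient table cannot be z-scored and is returned raw with a
  warning.
* Consensus pairs never co-sampled are `NA`, flagged, and excluded from
  the CDF; a single repetition is allowed but flagged as low coverage.
* Disconnected fused networks with more components than k are labelled
  by component with a warning.
* The pipeline fans one global seed out to fixed per-stage offsets so
  stage RNG streams never overlap, and writes a manifest with an MD5
  hash of the configuration.

# Problem sizes used by the tests

The test-suite and the acceptance script use the generator's study
conditions: discovery cohorts of n = 30 (16/14), external cohorts of
n = 150, n = 2000 for large-sample Cox consistency (100 repetitions),
20 seeds for calibration rates, 10 seeds for classifier transfer, 1000
consensus repetitions at 80% subsampling, and 50 random 5 x 5 x 3 arrays
for the texture oracles. Image-based tests use 24-26 voxel grids with
4-5 mm lesions so that full multi-view extraction stays fast.

# Known limitations

* Face-counting surface areas and voxel-centre diameters differ from
  mesh-based radiomics tools; comparisons across toolkits should expect
  systematic shape-feature offsets.
* The DE test and the gene-set scorer are documented substitutions, not
  numerical clones of the specialised packages they stand in for.
* The static module cut can absorb weakly correlated genes into large
  modules on real data; planted-structure recovery is the tested claim.
* With more PRFs than patients the PRF matrix spans the sample space and
  module filter criterion (c) loses specificity; the cascade is designed
  for the discovery-scale setting (tens of features passing stage 2).
* The generator's feature noise is i.i.d.; real radiomics features are
  strongly inter-correlated within classes, which typically makes
  subtype recovery easier than the i.i.d. case at matched effect size,
  but can also inflate apparent PRF counts.
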
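# radfusion

Multi-view radiomics feature fusion, subtyping and radiogenomics
association analysis in R.

## The problem

Contrast-enhanced CT of hepatocellular carcinoma images the same lesion
in an arterial and a portal venous phase, and the tissue around a tumour
carries signal of its own. `radfusion` treats the four resulting volumes
of interest — tumour and 10 mm peritumoral shell in each phase — as four
*views* of one patient, extracts a fixed registry of 100 radiomics
features per view (18 first-order, 14 shape, 68 gray-level texture
features over GLCM/GLRLM/GLSZM/GLDM), and asks three questions:

1. Do the fused views define reproducible imaging subtypes with distinct
   prognosis?
2. Which features are *prognostic radiomics features* (PRFs): different
   between subtypes **and** associated with survival?
3. What transcriptomic programs do the PRFs track — which co-expression
   modules, pathways and genes correlate with them — and can an
   expression-only cohort be assigned to the imaging subtypes?

The package is aimed at methodologists and analysts building or
stress-testing radiogenomics pipelines: every stage is driven by a
synthetic-cohort generator with planted ground truth, so each claim the
pipeline makes is checkable.

## The model in brief

Per view, patients are connected by the scaled-exponential kernel
`W(i,j) = exp(-d²(i,j)/(μ ε_ij))` with local scale
`ε_ij = (mean_{l∈kNN(i)} d(i,l) + mean_{l∈kNN(j)} d(j,l) + d(i,j))/3`.
Similarity network fusion iterates
`P_v ← S_v · (Σ_{u≠v} P_u/(m−1)) · S_vᵀ` (S_v the row-normalized k-NN
kernel, 20 iterations) and averages the views; spectral clustering of
the fused network with consensus model selection (1000 subsampled
re-runs at 80%, k chosen by minimal proportion of ambiguous clustering)
yields subtypes `FIFS1` (better prognosis, by convention) and `FIFS2`.
PRFs pass a two-sample t-test (p < 0.05) and a univariate Cox fit
(p < 0.05). Signed co-expression modules (`((1+cor)/2)^8`, TOM, static
cut, minimum size 30) are filtered for subtype association, prognosis
and PRF correlation; module pathway scores (rank-based single-sample
enrichment) are paired with PRFs under one Benjamini-Hochberg pass
(q < 0.05); and a nearest shrunken centroid classifier with stratified
10-fold CV carries the subtypes to expression-only cohorts.

## Worked example

```r
library(radfusion)

# simulate a 30-patient discovery cohort with two planted subtypes
coh <- generateCohort(cohortConfig(seed = 7))
coh
#> SyntheticCohort: 30 patients, 1000 genes
#>   planted subtype sizes: 16 / 14

# fuse the four per-view similarity networks and pick k by consensus
views <- lapply(paste0("type", 1:4), function(v)
  featureValues(subsetViews(cohortFeatures(coh), v)))
names(views) <- paste0("type", 1:4)
cons <- consensusSelectK(views, kRange = 2:5, nReps = 200, seed = 7)
cons
#> ConsensusResult: k in {2, 3, 4, 5}; chosen k = 2 (200 reps, 80% subsampling)

fused <- snfFuse(lapply(views, affinityMatrix))
subtypes <- orientSubtypes(
  spectralCluster(fused, chosenK(cons), seed = 7), cohortSurvival(coh))
subtypes
#> SubtypeAssignment (k = 2): FIFS1 = 16, FIFS2 = 14

logrankTest(cohortSurvival(coh), subtypeLabels(subtypes))$p
#> [1] 0.000135248
```

The consensus procedure recovers the two planted subtypes exactly
(16/14, matching the generator's truth), and the split separates
survival (log-rank p ≈ 1.4e-4) because the generator plants a higher
hazard in subtype 2.

```r
prf <- identifyPRFs(cohortFeatures(coh), subtypes, cohortSurvival(coh))
head(prf[, c("feature", "view", "phase", "region",
             "higher_subtype", "hr", "cox_p")], 3)
#>             feature  view  phase region higher_subtype        hr       cox_p
#> 1      ClusterShade type1 artery  tumor          FIFS2 2.4281197 0.001663757
#> 2   ClusterTendency type1 artery  tumor          FIFS1 0.5812684 0.040186238
#> 3 DifferenceEntropy type1 artery  tumor          FIFS2 2.1194460 0.001665980
```

Each PRF row reads like a hazard table: `hr` is the per-SD hazard ratio
of the (z-scored) feature, and `higher_subtype` marks the arm with the
larger mean. `runPipeline(pipelineConfig(seed = 7), outDir = "run")`
executes the whole chain — subtyping, PRFs, differential expression,
modules, the pathway-feature association network and the classifier —
and writes each stage's table plus a manifest under `run/`.

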
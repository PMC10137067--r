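Package: radfusion
Title: Multi-View Radiomics Feature Fusion, Subtyping and Radiogenomics
    Association
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-view contrast-enhanced CT radiomics analysis of
    hepatocellular carcinoma and similar solid tumours. Implements volume-of-
    interest preprocessing (isotropic resampling, peritumoral dilation, fixed
    bin-width discretization), a 100-feature-per-VOI registry of first-order,
    shape and gray-level texture features (GLCM, GLRLM, GLSZM, GLDM), fused
    imaging-feature subtyping via similarity network fusion with consensus
    clustering model selection, survival analysis of the resulting subtypes,
    differential expression and single-sample gene-set scoring, signed
    co-expression modules with eigengenes, a prognostic-radiomics-feature
    association cascade linking imaging features to pathways and genes, and a
    nearest shrunken centroid classifier for transferring subtypes to
    expression-only cohorts. A synthetic-cohort generator with planted
    subtype, expression-module and survival effects makes every stage
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    survival,
    cluster,
    igraph,
    jsonlite,
    RNifti,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
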
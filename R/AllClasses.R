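#' @import methods
#' @importFrom stats sd var quantile median cor cor.test t.test p.adjust
#'   phyper prcomp hclust cutree as.dist kmeans rnorm rbinom rexp runif
#'   rlnorm rnbinom uniroot pnorm pchisq pt setNames dist ecdf coef
#'   relevel mad
#' @importFrom utils head write.csv
NULL

## ---------------------------------------------------------------------------
## Image containers
## ---------------------------------------------------------------------------

#' 3D image volume on a regular grid
#'
#' A minimal container for a scalar 3D image: a numeric array plus the
#' physical voxel spacing (mm) and origin (mm). Voxel indices are treated as
#' 0-based when converted to physical coordinates; all distances are computed
#' in physical millimetres using the spacing.
#'
#' @slot values 3D numeric array of intensities.
#' @slot spacing numeric(3), voxel size in mm along each axis; strictly
#'   positive.
#' @slot origin numeric(3), physical coordinate of voxel (0,0,0) in mm.
#' @export
setClass("ImageVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("ImageVolume", function(object) {
  msg <- NULL
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite values")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ImageVolume
#'
#' @param values 3D numeric array.
#' @param spacing voxel spacing in mm (length 3).
#' @param origin physical origin in mm (length 3).
#' @return An [ImageVolume-class] object.
#' @examples
#' vol <- imageVolume(array(rnorm(27), c(3, 3, 3)))
#' @export
imageVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Volume-of-interest mask
#'
#' A binary voxel mask on the same grid as its companion [ImageVolume-class].
#' The view type records which of the four multi-view VOIs the mask
#' represents: tumour in the arterial phase (`type1`), tumour in the portal
#' venous phase (`type2`), peritumoral shell in the arterial phase (`type3`)
#' or peritumoral shell in the venous phase (`type4`).
#'
#' @slot mask 3D logical array; voxels inside the VOI are `TRUE`.
#' @slot viewType character, one of `"type1".."type4"` or `""` when not yet
#'   assigned.
#' @export
setClass("VOIMask",
  representation(mask = "array", viewType = "character"),
  prototype(viewType = ""))

setValidity("VOIMask", function(object) {
  msg <- NULL
  if (length(dim(object@mask)) != 3L)
    msg <- c(msg, "'mask' must be a 3D array")
  if (!is.logical(object@mask))
    msg <- c(msg, "'mask' must be logical")
  if (!object@viewType %in% c("", "type1", "type2", "type3", "type4"))
    msg <- c(msg, "'viewType' must be one of type1..type4")
  if (is.null(msg)) TRUE else msg
})

#' Construct a VOIMask
#'
#' @param mask 3D logical (or 0/1) array.
#' @param viewType optional view label (`"type1".."type4"`).
#' @return A [VOIMask-class] object.
#' @export
voiMask <- function(mask, viewType = "") {
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  new("VOIMask", mask = mask, viewType = viewType)
}

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat("ImageVolume ", paste(d, collapse = " x "),
      " | spacing (mm): ", paste(format(object@spacing), collapse = " x "),
      "\n", sep = "")
  cat("  intensity range: [", format(min(object@values)), ", ",
      format(max(object@values)), "]\n", sep = "")
})

setMethod("show", "VOIMask", function(object) {
  cat("VOIMask ", paste(dim(object@mask), collapse = " x "),
      if (nzchar(object@viewType)) paste0(" [", object@viewType, "]"),
      " | ", sum(object@mask), " voxels set\n", sep = "")
})

## ---------------------------------------------------------------------------
## MultiViewFeatureTable
## ---------------------------------------------------------------------------

#' Patients-by-features table over multiple VOI views
#'
#' The central radiomics container: one row per patient, one column per
#' (view, class, feature) triple. A complete view carries exactly 100
#' features (18 first-order + 14 shape + 68 texture). Columns may be z-scored
#' across patients, in which case `standardized` is `TRUE` and every
#' non-constant column has mean 0 and unit SD.
#'
#' @slot values numeric matrix, patients in rows (rownames = patient ids).
#' @slot featureInfo data.frame with one row per column of `values` and
#'   columns `view`, `class`, `feature`.
#' @slot standardized logical scalar.
#' @export
setClass("MultiViewFeatureTable",
  representation(values = "matrix", featureInfo = "data.frame",
                 standardized = "logical"),
  prototype(standardized = FALSE))

setValidity("MultiViewFeatureTable", function(object) {
  msg <- NULL
  fi <- object@featureInfo
  if (nrow(fi) != ncol(object@values))
    msg <- c(msg, "featureInfo rows must match value columns")
  if (!all(c("view", "class", "feature") %in% names(fi)))
    msg <- c(msg, "featureInfo needs columns view, class, feature")
  if (is.null(rownames(object@values)))
    msg <- c(msg, "values must have patient-id rownames")
  if (!is.null(msg)) return(msg)
  reg <- featureRegistry()
  for (v in unique(fi$view)) {
    n <- sum(fi$view == v)
    if (n != nrow(reg))
      msg <- c(msg, sprintf("view %s has %d features; expected %d", v, n,
                            nrow(reg)))
  }
  if (isTRUE(object@standardized)) {
    sds <- apply(object@values, 2, sd)
    keep <- sds > 0
    m <- colMeans(object@values[, keep, drop = FALSE])
    if (any(abs(m) > 1e-8) ||
        any(abs(sds[keep] - 1) > 1e-8))
      msg <- c(msg, "standardized table must have z-scored columns")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a MultiViewFeatureTable
#'
#' @param values patients x features numeric matrix with patient-id rownames.
#' @param featureInfo data.frame with columns `view`, `class`, `feature`.
#' @param standardized logical; are columns z-scored?
#' @return A [MultiViewFeatureTable-class].
#' @export
multiViewFeatureTable <- function(values, featureInfo,
                                  standardized = FALSE) {
  colnames(values) <- paste(featureInfo$view, featureInfo$class,
                            featureInfo$feature, sep = "|")
  new("MultiViewFeatureTable", values = values,
      featureInfo = as.data.frame(featureInfo), standardized = standardized)
}

#' @describeIn MultiViewFeatureTable-class feature value matrix
#'   (patients x features).
#' @param x,object a `MultiViewFeatureTable`.
#' @export
featureValues <- function(x) x@values

#' @describeIn MultiViewFeatureTable-class per-column metadata
#'   (view/class/feature).
#' @export
featureInfo <- function(x) x@featureInfo

#' @describeIn MultiViewFeatureTable-class patient identifiers.
#' @export
patientIds <- function(x) rownames(x@values)

#' Subset a feature table to a set of views
#'
#' Used to form the combination patterns compared in the view-ablation
#' analysis (e.g. tumour-only or single-phase inputs).
#'
#' @param x a [MultiViewFeatureTable-class].
#' @param views character vector of view labels to keep.
#' @return A `MultiViewFeatureTable` restricted to `views`.
#' @export
subsetViews <- function(x, views) {
  stopifnot(length(views) >= 1L, all(views %in% x@featureInfo$view))
  keep <- x@featureInfo$view %in% views
  multiViewFeatureTable(x@values[, keep, drop = FALSE],
                        x@featureInfo[keep, , drop = FALSE],
                        standardized = x@standardized)
}

setMethod("show", "MultiViewFeatureTable", function(object) {
  cat("MultiViewFeatureTable: ", nrow(object@values), " patients x ",
      ncol(object@values), " features (",
      length(unique(object@featureInfo$view)), " views)",
      if (object@standardized) ", z-scored", "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Fusion / subtyping containers
## ---------------------------------------------------------------------------

#' Fused patient-similarity network
#'
#' Output of similarity network fusion: a non-negative patient-by-patient
#' matrix whose rows sum to one after the final normalization, together with
#' the Frobenius-norm change of the averaged network at each message-passing
#' iteration.
#'
#' @slot matrix n x n numeric matrix with patient-id dimnames.
#' @slot trace numeric vector of per-iteration Frobenius deltas.
#' @export
setClass("FusedNetwork",
  representation(matrix = "matrix", trace = "numeric"))

setValidity("FusedNetwork", function(object) {
  msg <- NULL
  P <- object@matrix
  if (nrow(P) != ncol(P)) msg <- c(msg, "matrix must be square")
  if (any(P < 0)) msg <- c(msg, "matrix must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-8))
    msg <- c(msg, "rows must sum to 1 within 1e-8")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn FusedNetwork-class the fused matrix.
#' @param x a `FusedNetwork`.
#' @export
fusedMatrix <- function(x) x@matrix

setMethod("show", "FusedNetwork", function(object) {
  cat("FusedNetwork on ", nrow(object@matrix), " patients; ",
      length(object@trace), " fusion iterations (final delta ",
      format(utils::tail(object@trace, 1), digits = 3), ")\n", sep = "")
})

#' Consensus clustering result
#'
#' Per-k consensus matrices from subsampled re-runs of the full fusion
#' pipeline, their empirical CDFs, the delta-area vector used for model
#' selection and the chosen number of clusters.
#'
#' @slot consensus named list (one per k) of n x n matrices with entries in
#'   \[0,1\]; pairs never co-sampled are `NA` and flagged.
#' @slot cdf named list of functions (empirical CDFs of the upper-triangle
#'   consensus entries).
#' @slot area numeric vector of areas under the CDFs, named by k.
#' @slot deltaArea numeric vector: absolute area for the smallest k, relative
#'   increase for larger k.
#' @slot pac numeric vector, proportion of ambiguous clustering per k
#'   (consensus entries in the (0.1, 0.9) window); the selection criterion.
#' @slot chosenK integer, selected number of clusters (minimal PAC, ties to
#'   the smallest k).
#' @slot nReps,subsampleFraction resampling settings.
#' @slot lowCoverage logical, `TRUE` when some pair was never co-sampled.
#' @export
setClass("ConsensusResult",
  representation(consensus = "list", cdf = "list", area = "numeric",
                 deltaArea = "numeric", pac = "numeric",
                 chosenK = "integer", nReps = "integer",
                 subsampleFraction = "numeric", lowCoverage = "logical"))

setValidity("ConsensusResult", function(object) {
  msg <- NULL
  for (M in object@consensus) {
    v <- M[!is.na(M)]
    if (any(v < -1e-12 | v > 1 + 1e-12))
      msg <- c(msg, "consensus entries must lie in [0,1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ConsensusResult-class selected cluster number.
#' @param x a `ConsensusResult`.
#' @export
chosenK <- function(x) x@chosenK

#' @describeIn ConsensusResult-class consensus matrix for a given k.
#' @param k number of clusters.
#' @export
consensusMatrix <- function(x, k) x@consensus[[as.character(k)]]

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult: k in {", paste(names(object@consensus),
      collapse = ", "), "}; chosen k = ", object@chosenK, " (",
      object@nReps, " reps, ", object@subsampleFraction * 100,
      "% subsampling)\n", sep = "")
  if (object@lowCoverage)
    cat("  note: some patient pairs were never co-sampled\n")
})

#' Patient subtype assignment
#'
#' Cluster labels for every patient. For two clusters the naming convention
#' is prognostic: `FIFS1` is the better-prognosis arm (see
#' [orientSubtypes()]), so the labels are invariant to arbitrary label swaps
#' by the clustering backend.
#'
#' @slot labels named integer vector (names = patient ids, values in 1..k).
#' @slot k integer, number of clusters.
#' @export
setClass("SubtypeAssignment",
  representation(labels = "integer", k = "integer"))

setValidity("SubtypeAssignment", function(object) {
  msg <- NULL
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by patient id")
  if (anyNA(object@labels))
    msg <- c(msg, "every patient must be labelled")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SubtypeAssignment
#' @param labels named integer vector of cluster labels.
#' @param k number of clusters (default `max(labels)`).
#' @return A [SubtypeAssignment-class].
#' @export
subtypeAssignment <- function(labels, k = max(labels)) {
  lab <- setNames(as.integer(labels), names(labels))
  new("SubtypeAssignment", labels = lab, k = as.integer(k))
}

#' @describeIn SubtypeAssignment-class named integer labels.
#' @param x a `SubtypeAssignment`.
#' @export
subtypeLabels <- function(x) x@labels

#' @describeIn SubtypeAssignment-class labels as `FIFS1`, `FIFS2`, ... factor.
#' @export
subtypeNames <- function(x) {
  factor(paste0("FIFS", x@labels), levels = paste0("FIFS", seq_len(x@k)))
}

setMethod("show", "SubtypeAssignment", function(object) {
  tb <- table(subtypeNames(object))
  cat("SubtypeAssignment (k = ", object@k, "): ",
      paste(names(tb), tb, sep = " = ", collapse = ", "), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Synthetic cohort
## ---------------------------------------------------------------------------

#' Synthetic radiogenomics cohort
#'
#' Bundles the objects the analysis consumes for one simulated cohort:
#' multi-view radiomics features, gene expression counts, survival, clinical
#' covariates and the ground truth used to verify each stage.
#'
#' @slot features a [MultiViewFeatureTable-class] (4 views x 100 features).
#' @slot counts genes x patients integer matrix.
#' @slot survival data.frame with `patient_id`, `time_days`, `event`,
#'   `endpoint`.
#' @slot clinical data.frame with `patient_id`, `afp`, `grade`.
#' @slot truth list: `subtype` (named integer), `geneModule` (named
#'   character), `affectedFeatures` (data.frame of planted feature effects),
#'   and generator settings.
#' @export
setClass("SyntheticCohort",
  representation(features = "MultiViewFeatureTable", counts = "matrix",
                 survival = "data.frame", clinical = "data.frame",
                 truth = "list"))

setValidity("SyntheticCohort", function(object) {
  msg <- NULL
  ids <- patientIds(object@features)
  if (!setequal(names(object@truth$subtype), ids))
    msg <- c(msg, "truth subtype labels must cover all patients")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (any(object@survival$time_days <= 0))
    msg <- c(msg, "survival times must be positive")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort: ", nrow(object@features@values), " patients, ",
      nrow(object@counts), " genes\n  planted subtype sizes: ",
      paste(table(object@truth$subtype), collapse = " / "), "\n", sep = "")
})

#' @describeIn SyntheticCohort-class the feature table.
#' @param x a `SyntheticCohort`.
#' @export
cohortFeatures <- function(x) x@features

#' @describeIn SyntheticCohort-class the count matrix.
#' @export
cohortCounts <- function(x) x@counts

#' @describeIn SyntheticCohort-class the survival table.
#' @export
cohortSurvival <- function(x) x@survival

#' @describeIn SyntheticCohort-class the clinical table.
#' @export
cohortClinical <- function(x) x@clinical

#' @describeIn SyntheticCohort-class the ground-truth list.
#' @export
cohortTruth <- function(x) x@truth

## ---------------------------------------------------------------------------
## Nearest shrunken centroid model
## ---------------------------------------------------------------------------

#' Nearest shrunken centroid model
#'
#' Stores everything needed to reproduce training and to predict: the raw and
#' shrunken class centroids, pooled within-class standard deviations, the
#' fudge factor, class priors, the chosen shrinkage threshold and the full
#' cross-validation profile.
#'
#' @slot genes character vector of gene ids (model feature space).
#' @slot overallCentroid numeric, per-gene overall mean.
#' @slot centroids genes x classes matrix of shrunken centroids at the chosen
#'   threshold.
#' @slot sdPooled numeric, per-gene pooled within-class SD.
#' @slot s0 numeric scalar fudge (median of `sdPooled`).
#' @slot priors named numeric, class priors.
#' @slot threshold numeric, chosen shrinkage Delta.
#' @slot cvProfile data.frame: `threshold`, `cv_error`, `n_active`.
#' @slot classes character vector of class labels.
#' @export
setClass("ShrunkenCentroidModel",
  representation(genes = "character", overallCentroid = "numeric",
                 centroids = "matrix", sdPooled = "numeric", s0 = "numeric",
                 priors = "numeric", threshold = "numeric",
                 cvProfile = "data.frame", classes = "character"))

setValidity("ShrunkenCentroidModel", function(object) {
  msg <- NULL
  if (!all(diff(object@cvProfile$threshold) >= 0))
    msg <- c(msg, "cvProfile thresholds must be increasing")
  if (!all(diff(object@cvProfile$n_active) <= 0))
    msg <- c(msg, "active-gene count must be non-increasing in threshold")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ShrunkenCentroidModel-class genes with a nonzero shrunken
#'   offset at the chosen threshold.
#' @param x a `ShrunkenCentroidModel`.
#' @export
activeGenes <- function(x) {
  off <- x@centroids - x@overallCentroid
  x@genes[rowSums(abs(off)) > 0]
}

setMethod("show", "ShrunkenCentroidModel", function(object) {
  cat("ShrunkenCentroidModel: ", length(object@classes), " classes, ",
      length(object@genes), " genes (", length(activeGenes(object)),
      " active at Delta = ", format(object@threshold, digits = 4), ")\n",
      sep = "")
})
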
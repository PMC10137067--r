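## The fixed 100-feature-per-VOI registry: 18 first-order + 14 shape +
## 68 texture (22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM).

.FIRSTORDER_NAMES <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")

.SHAPE_NAMES <- c(
  "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
  "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
  "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness")

.GLCM_NAMES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MaximumProbability", "SumEntropy", "SumSquares")

.GLRLM_NAMES <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

.GLSZM_NAMES <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

.GLDM_NAMES <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

#' The per-VOI radiomics feature registry
#'
#' Returns the fixed registry of the 100 features extracted from every
#' volume of interest: 18 first-order intensity statistics, 14 3D shape
#' descriptors and 68 texture features split over the four gray-level
#' matrices (22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM).
#'
#' @return data.frame with columns `class` (one of `first-order`, `shape`,
#'   `glcm`, `glrlm`, `glszm`, `gldm`) and `feature`.
#' @examples
#' table(featureRegistry()$class)
#' @export
featureRegistry <- function() {
  data.frame(
    class = rep(c("first-order", "shape", "glcm", "glrlm", "glszm", "gldm"),
                c(18L, 14L, 22L, 16L, 16L, 14L)),
    feature = c(.FIRSTORDER_NAMES, .SHAPE_NAMES, .GLCM_NAMES, .GLRLM_NAMES,
                .GLSZM_NAMES, .GLDM_NAMES),
    stringsAsFactors = FALSE)
}

#' View-type metadata for the four multi-view VOIs
#'
#' Maps the four view types to their phase and region: tumour in the
#' arterial phase (type1), tumour in the portal venous phase (type2),
#' peritumoral shell in the arterial phase (type3) and peritumoral shell in
#' the venous phase (type4).
#'
#' @return data.frame with columns `view`, `phase`, `region`.
#' @export
viewTypes <- function() {
  data.frame(view = paste0("type", 1:4),
             phase = c("artery", "venous", "artery", "venous"),
             region = c("tumor", "tumor", "peritumor", "peritumor"),
             stringsAsFactors = FALSE)
}
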
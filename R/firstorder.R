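#' First-order intensity statistics of a VOI
#'
#' Computes the 18 first-order features describing the distribution of voxel
#' intensities inside the mask. `Entropy` and `Uniformity` are computed on
#' the fixed-bin-width discretized histogram; everything else uses the raw
#' intensities. Percentiles use linear interpolation. Conventions for
#' degenerate (constant) regions: `Variance = 0`, `Skewness = 0`,
#' `Kurtosis = 0`.
#'
#' @param volume an [ImageVolume-class].
#' @param mask a non-empty [VOIMask-class].
#' @param params a [discretizationParams()] list (bin width for
#'   entropy/uniformity).
#' @return Named numeric vector of length 18.
#' @examples
#' vol <- imageVolume(array(1:8, c(2, 2, 2)))
#' msk <- voiMask(array(TRUE, c(2, 2, 2)))
#' firstOrderFeatures(vol, msk)[c("Mean", "Range")]
#' @export
firstOrderFeatures <- function(volume, mask,
                               params = discretizationParams()) {
  stopifnot(is(volume, "ImageVolume"), is(mask, "VOIMask"))
  if (!any(mask@mask)) stop("mask is empty")
  x <- volume@values[mask@mask]
  n <- length(x)
  vv <- prod(volume@spacing)
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  rob <- x[x >= q[1] & x <= q[4]]
  lev <- floor((x - min(x)) / params$binWidth)
  p <- tabulate(lev + 1L) / n
  p <- p[p > 0]
  c(Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = mu,
    Median = median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

#' 3D shape descriptors of a VOI
#'
#' Computes the 14 shape features from the voxel representation of the mask.
#' Surface area is obtained by counting exposed voxel faces (deterministic
#' and exactly testable), so values differ from marching-cubes mesh tools;
#' `MeshVolume` consequently equals `VoxelVolume` under this voxel model.
#' Axis lengths derive from the eigenvalues of the physical-coordinate
#' covariance of the voxel centres (`4 * sqrt(lambda)`), and the maximum
#' diameters are largest voxel-centre distances overall and within axial,
#' coronal and sagittal planes. For a single-voxel mask `Elongation` and
#' `Flatness` take their isotropic limit 1.
#'
#' @param mask a non-empty [VOIMask-class].
#' @param spacing voxel spacing in mm (length 3).
#' @return Named numeric vector of length 14.
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
#' shapeFeatures(voiMask(m), c(1, 1, 1))["SurfaceVolumeRatio"]  # 6
#' @export
shapeFeatures <- function(mask, spacing) {
  stopifnot(is(mask, "VOIMask"), length(spacing) == 3L)
  m <- mask@mask
  if (!any(m)) stop("mask is empty")
  dims <- dim(m)
  n <- sum(m)
  vol <- n * prod(spacing)

  ## exposed faces along each axis
  faceArea <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                spacing[1] * spacing[2])
  pad <- array(FALSE, dims + 2L)
  pad[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- m
  sa <- 0
  for (a in 1:3) {
    sh <- c(0L, 0L, 0L); sh[a] <- 1L
    ## neighbours in -a and +a directions
    minus <- pad[seq_len(dims[1]) + 1L - sh[1], seq_len(dims[2]) + 1L - sh[2],
                 seq_len(dims[3]) + 1L - sh[3], drop = FALSE]
    plus <- pad[seq_len(dims[1]) + 1L + sh[1], seq_len(dims[2]) + 1L + sh[2],
                seq_len(dims[3]) + 1L + sh[3], drop = FALSE]
    sa <- sa + faceArea[a] * (sum(m & !minus) + sum(m & !plus))
  }

  idx <- which(m, arr.ind = TRUE)
  xyz <- sweep(idx - 1, 2, spacing, `*`)
  ## population covariance of voxel centres
  cv <- crossprod(sweep(xyz, 2, colMeans(xyz))) / n
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  axes <- 4 * sqrt(ev)

  ## boundary voxels are enough for diameters
  interior <- m
  for (a in 1:3) {
    sh <- c(0L, 0L, 0L); sh[a] <- 1L
    minus <- pad[seq_len(dims[1]) + 1L - sh[1], seq_len(dims[2]) + 1L - sh[2],
                 seq_len(dims[3]) + 1L - sh[3], drop = FALSE]
    plus <- pad[seq_len(dims[1]) + 1L + sh[1], seq_len(dims[2]) + 1L + sh[2],
                seq_len(dims[3]) + 1L + sh[3], drop = FALSE]
    interior <- interior & minus & plus
  }
  bidx <- which(m & !interior, arr.ind = TRUE)
  if (nrow(bidx) == 0L) bidx <- idx
  bxyz <- sweep(bidx - 1, 2, spacing, `*`)
  maxPairDist <- function(pts) {
    if (nrow(pts) < 2L) return(0)
    sqrt(max(dist(pts)^2))
  }
  d3 <- maxPairDist(bxyz)
  planeDiameter <- function(sliceAxis, keepAxes) {
    mx <- 0
    for (s in unique(bidx[, sliceAxis])) {
      pts <- bxyz[bidx[, sliceAxis] == s, keepAxes, drop = FALSE]
      mx <- max(mx, maxPairDist(pts))
    }
    mx
  }
  d2slice <- planeDiameter(3L, 1:2)   # axial (x-y) plane
  d2col <- planeDiameter(2L, c(1, 3)) # coronal (x-z) plane
  d2row <- planeDiameter(1L, 2:3)     # sagittal (y-z) plane

  c(MeshVolume = vol,
    VoxelVolume = vol,
    SurfaceArea = sa,
    SurfaceVolumeRatio = sa / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / sa,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d2slice,
    Maximum2DDiameterColumn = d2col,
    Maximum2DDiameterRow = d2row,
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}
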
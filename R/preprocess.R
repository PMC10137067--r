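#' Discretization and resampling parameters
#'
#' Bundles the two preprocessing constants applied before texture
#' extraction: images are resampled to an isotropic grid (default 1 x 1 x 1
#' mm) and intensities inside the VOI are discretized with a fixed bin width
#' (default 25 intensity units).
#'
#' @param binWidth positive bin width for gray-level discretization.
#' @param resampleSpacing target voxel spacing in mm (length 3, positive).
#' @return A named list with class `DiscretizationParams`.
#' @export
discretizationParams <- function(binWidth = 25, resampleSpacing = c(1, 1, 1)) {
  if (!is.numeric(binWidth) || length(binWidth) != 1L || binWidth <= 0)
    stop("'binWidth' must be a single positive number")
  if (length(resampleSpacing) != 3L || any(resampleSpacing <= 0))
    stop("'resampleSpacing' must be 3 positive values")
  structure(list(binWidth = binWidth,
                 resampleSpacing = as.numeric(resampleSpacing)),
            class = "DiscretizationParams")
}

## interpolate a 3D array onto a new grid; 0-based voxel-centre coordinates
.resample_array <- function(values, spacing, newSpacing, method) {
  dims <- dim(values)
  newDims <- pmax(1L, as.integer(floor((dims - 1) * spacing / newSpacing +
                                         1e-9)) + 1L)
  g <- lapply(1:3, function(a) {
    x <- (seq_len(newDims[a]) - 1) * newSpacing[a] / spacing[a]
    pmin(pmax(x, 0), dims[a] - 1)
  })
  if (method == "nearest") {
    idx <- lapply(1:3, function(a) pmin(round(g[[a]]) + 1L, dims[a]))
    return(values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  i0 <- lapply(1:3, function(a) pmin(floor(g[[a]]) + 1L, dims[a]))
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1L, dims[a]))
  f <- lapply(1:3, function(a) g[[a]] - (i0[[a]] - 1L))
  out <- array(0, newDims)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx == 0) 1 - f[[1]] else f[[1]]
    wy <- if (cy == 0) 1 - f[[2]] else f[[2]]
    wz <- if (cz == 0) 1 - f[[3]] else f[[3]]
    w <- outer(outer(wx, wy), wz)
    ix <- if (cx == 0) i0[[1]] else i1[[1]]
    iy <- if (cy == 0) i0[[2]] else i1[[2]]
    iz <- if (cz == 0) i0[[3]] else i1[[3]]
    out <- out + w * values[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Resample a volume and its mask to a target spacing
#'
#' Interpolates the image onto an isotropic grid (trilinear for intensities,
#' nearest-neighbour for the mask) so that texture offsets correspond to
#' equal physical distances in every direction. A volume already on the
#' target grid is returned unchanged.
#'
#' @param volume an [ImageVolume-class].
#' @param mask a [VOIMask-class] on the same grid.
#' @param params a [discretizationParams()] list; `resampleSpacing` is the
#'   target spacing.
#' @return list with elements `volume` and `mask` on the new grid.
#' @export
resampleIsotropic <- function(volume, mask, params = discretizationParams()) {
  stopifnot(is(volume, "ImageVolume"), is(mask, "VOIMask"))
  if (!identical(dim(volume@values), dim(mask@mask)))
    stop("volume and mask grids differ")
  target <- params$resampleSpacing
  if (any(!is.finite(target)) || any(target <= 0))
    stop("degenerate target spacing")
  if (isTRUE(all.equal(volume@spacing, target)))
    return(list(volume = volume, mask = mask))
  v <- .resample_array(volume@values, volume@spacing, target, "trilinear")
  m <- .resample_array(mask@mask, volume@spacing, target, "nearest")
  list(volume = imageVolume(v, spacing = target, origin = volume@origin),
       mask = voiMask(m, viewType = mask@viewType))
}

#' Peritumoral shell by morphological dilation
#'
#' Computes the peritumoral region as all voxels whose Euclidean distance
#' (in physical mm) to the tumour is in `(0, radiusMm]`, minus the tumour
#' itself and minus an optional exclusion mask (e.g. tissue beyond the liver
#' parenchyma, large vessels or air cavities).
#'
#' @param tumor a non-empty [VOIMask-class].
#' @param spacing voxel spacing in mm (length 3).
#' @param radiusMm dilation radius in mm (default 10).
#' @param exclusion optional [VOIMask-class] of voxels to remove, or `NULL`.
#' @param viewType view label for the returned mask.
#' @return A [VOIMask-class] for the peritumoral shell.
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
#' sum(dilatePeritumor(voiMask(m), c(1, 1, 1), radiusMm = 2)@mask)  # 32
#' @export
dilatePeritumor <- function(tumor, spacing, radiusMm = 10, exclusion = NULL,
                            viewType = "") {
  stopifnot(is(tumor, "VOIMask"))
  if (radiusMm < 0) stop("'radiusMm' must be non-negative")
  if (!any(tumor@mask)) stop("tumor mask is empty")
  dims <- dim(tumor@mask)
  out <- array(FALSE, dims)
  if (radiusMm > 0) {
    ## work on the tumour bounding box padded by the radius
    idx <- which(tumor@mask, arr.ind = TRUE)
    rvox <- ceiling(radiusMm / spacing)
    lo <- pmax(apply(idx, 2, min) - rvox, 1)
    hi <- pmin(apply(idx, 2, max) + rvox, dims)
    sub <- tumor@mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sd_ <- dim(sub)
    off <- expand.grid(dx = -rvox[1]:rvox[1], dy = -rvox[2]:rvox[2],
                       dz = -rvox[3]:rvox[3])
    d2 <- (off$dx * spacing[1])^2 + (off$dy * spacing[2])^2 +
      (off$dz * spacing[3])^2
    off <- off[d2 <= radiusMm^2 + 1e-9, , drop = FALSE]
    dil <- array(FALSE, sd_)
    for (r in seq_len(nrow(off))) {
      dx <- off$dx[r]; dy <- off$dy[r]; dz <- off$dz[r]
      tx <- max(1, 1 + dx):min(sd_[1], sd_[1] + dx)
      ty <- max(1, 1 + dy):min(sd_[2], sd_[2] + dy)
      tz <- max(1, 1 + dz):min(sd_[3], sd_[3] + dz)
      dil[tx, ty, tz] <- dil[tx, ty, tz] |
        sub[tx - dx, ty - dy, tz - dz, drop = FALSE]
    }
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- dil
  }
  out <- out & !tumor@mask
  if (!is.null(exclusion)) {
    stopifnot(is(exclusion, "VOIMask"))
    out <- out & !exclusion@mask
  }
  voiMask(out, viewType = viewType)
}

#' Fixed-bin-width gray-level discretization
#'
#' Maps intensities inside the mask to integer gray levels
#' `floor((I - min) / binWidth) + 1`, where `min` is the minimum intensity
#' within the mask. Voxels outside the mask are `NA`. The number of levels
#' `Ng` (the maximum level) is attached as an attribute.
#'
#' @param volume an [ImageVolume-class].
#' @param mask a non-empty [VOIMask-class].
#' @param params a [discretizationParams()] list.
#' @return Integer 3D array of levels with attribute `Ng`.
#' @export
discretizeVolume <- function(volume, mask, params = discretizationParams()) {
  stopifnot(is(volume, "ImageVolume"), is(mask, "VOIMask"))
  if (!any(mask@mask)) stop("mask is empty")
  v <- volume@values
  inm <- mask@mask
  lev <- array(NA_integer_, dim(v))
  lev[inm] <- as.integer(floor((v[inm] - min(v[inm])) / params$binWidth)) + 1L
  attr(lev, "Ng") <- max(lev[inm])
  lev
}

#' Simple global-threshold segmentation helper
#'
#' Produces a mask of voxels with intensity in `[lower, upper]`. Supplied
#' reference masks remain authoritative; this helper only supports quick
#' threshold-based lesion segmentation.
#'
#' @param volume an [ImageVolume-class].
#' @param lower,upper intensity bounds (inclusive).
#' @return A [VOIMask-class].
#' @export
thresholdSegment <- function(volume, lower, upper = Inf) {
  voiMask(volume@values >= lower & volume@values <= upper)
}

## ---------------------------------------------------------------------------
## NIfTI I/O
## ---------------------------------------------------------------------------

#' Read / write volumes and masks as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} keeping the `ImageVolume` spacing in sync
#' with the NIfTI `pixdim`.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readVolumeNifti` returns an [ImageVolume-class];
#'   `readMaskNifti` a [VOIMask-class].
#' @export
readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  imageVolume(array(as.numeric(img), dim(img)),
              spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname readVolumeNifti
#' @param volume an [ImageVolume-class] to write.
#' @export
writeVolumeNifti <- function(volume, path) {
  img <- RNifti::asNifti(volume@values, pixdim = volume@spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname readVolumeNifti
#' @param viewType view label to attach to the mask read from disk.
#' @export
readMaskNifti <- function(path, viewType = "") {
  img <- RNifti::readNifti(path)
  voiMask(array(as.numeric(img) > 0.5, dim(img)), viewType = viewType)
}

#' @rdname readVolumeNifti
#' @param mask a [VOIMask-class] to write (stored as 0/1).
#' @param spacing voxel spacing recorded in the header.
#' @export
writeMaskNifti <- function(mask, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(mask@mask), dim(mask@mask)),
                         pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
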
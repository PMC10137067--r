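## Multi-view feature extraction: four VOIs per patient, 100 features each.

## z-score columns; constant columns are left untouched and reported
.zscore_columns <- function(mat) {
  sds <- apply(mat, 2, sd)
  mns <- colMeans(mat)
  keep <- is.finite(sds) & sds > 0
  out <- mat
  out[, keep] <- sweep(sweep(mat[, keep, drop = FALSE], 2, mns[keep]), 2,
                       sds[keep], `/`)
  attr(out, "constantColumns") <- colnames(mat)[!keep]
  out
}

#' Extract one VOI's full 100-feature vector
#'
#' Convenience wrapper computing the first-order, shape and texture blocks
#' of the registry for a single volume/mask pair (already on the working
#' grid).
#'
#' @param volume an [ImageVolume-class].
#' @param mask a non-empty [VOIMask-class] on the same grid.
#' @param params a [discretizationParams()] list.
#' @return data.frame with columns `class`, `feature`, `value` (100 rows, in
#'   registry order).
#' @export
extractVoiFeatures <- function(volume, mask,
                               params = discretizationParams()) {
  fo <- firstOrderFeatures(volume, mask, params)
  sh <- shapeFeatures(mask, volume@spacing)
  lev <- discretizeVolume(volume, mask, params)
  tx <- textureFeatures(lev)
  out <- rbind(
    data.frame(class = "first-order", feature = names(fo),
               value = unname(fo)),
    data.frame(class = "shape", feature = names(sh), value = unname(sh)),
    tx)
  rownames(out) <- NULL
  out
}

#' Extract the multi-view feature table for a cohort of imaged patients
#'
#' For each patient the four VOIs are built from the arterial and venous
#' phase volumes and the tumour mask: tumour-arterial (type1),
#' tumour-venous (type2), peritumour-arterial (type3) and peritumour-venous
#' (type4), the peritumoral shell coming from a Euclidean dilation of the
#' tumour ([dilatePeritumor()]) minus the tumour and any exclusion mask.
#' Volumes are resampled to the target spacing first; each VOI then yields
#' the 100 registry features. Patients with a missing phase, an empty
#' tumour mask or an empty peritumoral shell are skipped with a warning.
#'
#' @param patients named list; each element a list with components
#'   `arterial` and `venous` ([ImageVolume-class]), `tumor`
#'   ([VOIMask-class]) and optionally `exclusion` ([VOIMask-class] or
#'   `NULL`).
#' @param params a [discretizationParams()] list.
#' @param radiusMm peritumoral dilation radius in mm.
#' @param standardize z-score every column across patients (constant
#'   columns are reported via the `constantColumns` attribute and left
#'   unscaled).
#' @return A [MultiViewFeatureTable-class] with 400 columns.
#' @export
extractMultiview <- function(patients, params = discretizationParams(),
                             radiusMm = 10, standardize = TRUE) {
  reg <- featureRegistry()
  vt <- viewTypes()
  rows <- list()
  for (pid in names(patients)) {
    p <- patients[[pid]]
    if (is.null(p$arterial) || is.null(p$venous) || is.null(p$tumor)) {
      warning("patient ", pid, ": missing phase or tumour mask; skipped")
      next
    }
    vals <- tryCatch({
      byPhase <- lapply(list(artery = p$arterial, venous = p$venous),
        function(vol) {
          rs <- resampleIsotropic(vol, p$tumor, params)
          excl <- if (!is.null(p$exclusion))
            resampleIsotropic(vol, p$exclusion, params)$mask else NULL
          peri <- dilatePeritumor(rs$mask, rs$volume@spacing,
                                  radiusMm = radiusMm, exclusion = excl)
          if (!any(peri@mask)) stop("empty peritumoral shell")
          list(volume = rs$volume, tumor = rs$mask, peri = peri)
        })
      unlist(lapply(seq_len(nrow(vt)), function(k) {
        ph <- byPhase[[vt$phase[k]]]
        msk <- if (vt$region[k] == "tumor") ph$tumor else ph$peri
        extractVoiFeatures(ph$volume, msk, params)$value
      }))
    }, error = function(e) {
      warning("patient ", pid, ": ", conditionMessage(e), "; skipped")
      NULL
    })
    if (!is.null(vals)) rows[[pid]] <- vals
  }
  if (!length(rows)) stop("no patient could be extracted")
  mat <- do.call(rbind, rows)
  fi <- data.frame(view = rep(vt$view, each = nrow(reg)),
                   class = rep(reg$class, nrow(vt)),
                   feature = rep(reg$feature, nrow(vt)),
                   stringsAsFactors = FALSE)
  colnames(mat) <- paste(fi$view, fi$class, fi$feature, sep = "|")
  const <- character(0)
  if (standardize) {
    if (nrow(mat) < 2L) {
      warning("cannot z-score with fewer than 2 patients; returning raw ",
              "values")
      standardize <- FALSE
    } else {
      z <- .zscore_columns(mat)
      const <- attr(z, "constantColumns")
      if (length(const))
        warning(length(const), " constant column(s) left unscaled")
      standardize <- length(const) == 0L
      mat <- z
      attr(mat, "constantColumns") <- NULL
    }
  }
  out <- multiViewFeatureTable(mat, fi, standardized = standardize)
  attr(out, "constantColumns") <- const
  out
}
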
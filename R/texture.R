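## Gray-level texture matrices and their features.
##
## All four families operate on a 3D integer level array (NA outside the
## VOI) as produced by discretizeVolume(). Conventions, fixed because the
## underlying tooling literature leaves them open:
##  - GLCM/GLRLM: the 13 unique 3D direction offsets at voxel distance 1,
##    symmetric accumulation, features computed per direction then averaged.
##  - GLSZM: zones are 26-connected components of constant level.
##  - GLDM: dependence = 1 + number of in-mask 26-neighbours with exactly
##    equal level (alpha = 0); the centre voxel counts itself.
##  - Division-by-zero features return their limit value (e.g. Correlation
##    of a constant region is 1).

## the 13 unique direction offsets (up to sign) of the 26-neighbourhood
.DIRECTIONS_13 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) |
    (g$dz == 0 & g$dy == 0 & g$dx > 0)
  as.matrix(g[keep, ])
})

## 26 signed offsets
.DIRECTIONS_26 <- rbind(.DIRECTIONS_13, -.DIRECTIONS_13)

## B[v] = A[v + d], NA where v + d falls off the grid
.shift_arr <- function(A, d) {
  dims <- dim(A)
  out <- array(A[1][NA], dims)
  rng <- lapply(1:3, function(a) {
    lo <- max(1, 1 - d[a]); hi <- min(dims[a], dims[a] - d[a])
    if (lo > hi) integer(0) else lo:hi
  })
  sx <- rng[[1]]; sy <- rng[[2]]; sz <- rng[[3]]
  if (!length(sx) || !length(sy) || !length(sz)) return(out)
  out[sx, sy, sz] <- A[sx + d[1], sy + d[2], sz + d[3], drop = FALSE]
  out
}

.ng_of <- function(levels) {
  ng <- attr(levels, "Ng")
  if (is.null(ng)) ng <- max(levels, na.rm = TRUE)
  as.integer(ng)
}

.degenerate_p <- function(levels, ng) {
  ## single-voxel (or otherwise pair-free) VOI: unit mass on the observed
  ## level's diagonal cell
  l <- levels[!is.na(levels)][1]
  P <- matrix(0, ng, ng)
  P[l, l] <- 1
  P
}

## ---------------------------------------------------------------------------
## GLCM
## ---------------------------------------------------------------------------

#' Gray-level co-occurrence matrix features
#'
#' Builds a symmetric GLCM at voxel distance 1 for each of the 13 unique 3D
#' directions, computes the 22 registry features per direction and averages
#' them over directions (directions yielding no voxel pair are skipped).
#'
#' @param levels integer 3D level array with `NA` outside the VOI, as
#'   returned by [discretizeVolume()].
#' @return Named numeric vector of the 22 GLCM features.
#' @export
glcmFeatures <- function(levels) {
  ng <- .ng_of(levels)
  feats <- NULL
  for (r in seq_len(nrow(.DIRECTIONS_13))) {
    d <- .DIRECTIONS_13[r, ]
    nb <- .shift_arr(levels, d)
    ok <- !is.na(levels) & !is.na(nb)
    if (!any(ok)) next
    i <- levels[ok]; j <- nb[ok]
    cnt <- matrix(0, ng, ng)
    tab <- tabulate((i - 1L) * ng + j, nbins = ng * ng)
    cnt <- matrix(tab, ng, ng, byrow = TRUE)
    P <- cnt + t(cnt)                 # symmetric accumulation
    P <- P / sum(P)
    feats <- rbind(feats, .glcm_from_p(P, ng))
  }
  if (is.null(feats))
    feats <- rbind(.glcm_from_p(.degenerate_p(levels, ng), ng))
  colMeans(feats)
}

.glcm_from_p <- function(P, ng) {
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  ## difference and sum distributions
  pd <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), 0)
  ps <- vapply(2:(2 * ng), function(k) sum(P[(i + j) == k]), 0)
  k_d <- 0:(ng - 1)
  da <- sum(k_d * pd)
  ent2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- ent2(P)
  hx <- ent2(px)
  pxy <- outer(px, px)
  nz <- P > 0 & pxy > 0
  hxy1 <- -sum(P[nz] * log2(pxy[nz]))
  hxy2 <- ent2(pxy)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 > hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = ent2(pd),
    DifferenceVariance = sum((k_d - da)^2 * pd),
    Id = sum(pd / (1 + k_d)),
    Idm = sum(pd / (1 + k_d^2)),
    Idmn = sum(pd / (1 + k_d^2 / ng^2)),
    Idn = sum(pd / (1 + k_d / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (ng > 1) sum(pd[-1] / k_d[-1]^2) else 0,
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MaximumProbability = max(P),
    SumEntropy = ent2(ps),
    SumSquares = sig2)
}

## ---------------------------------------------------------------------------
## GLRLM
## ---------------------------------------------------------------------------

#' Gray-level run-length matrix features
#'
#' Runs are maximal sequences of consecutive in-mask voxels with equal level
#' along one of the 13 directions; out-of-mask voxels break runs. The 16
#' registry features are computed per direction and averaged.
#'
#' @inheritParams glcmFeatures
#' @return Named numeric vector of the 16 GLRLM features.
#' @export
glrlmFeatures <- function(levels) {
  ng <- .ng_of(levels)
  np <- sum(!is.na(levels))
  feats <- NULL
  for (r in seq_len(nrow(.DIRECTIONS_13))) {
    d <- .DIRECTIONS_13[r, ]
    P <- .glrlm_matrix(levels, d, ng)
    feats <- rbind(feats, .size_family_features(P, np, "run"))
  }
  colMeans(feats)
}

.glrlm_matrix <- function(levels, d, ng) {
  nxt <- .shift_arr(levels, d)
  cont <- !is.na(levels) & !is.na(nxt) & levels == nxt
  prv <- .shift_arr(levels, -d)
  contPrev <- !is.na(levels) & !is.na(prv) & levels == prv
  start <- !is.na(levels) & !contPrev
  ## run length by chasing the continuation chain
  rl <- array(1, dim(levels))
  repeat {
    nxt_rl <- .shift_arr(rl, d)
    newRl <- ifelse(cont, 1 + ifelse(is.na(nxt_rl), 0, nxt_rl), 1)
    if (identical(newRl, rl)) break
    rl <- newRl
  }
  lv <- levels[start]; ln <- rl[start]
  maxlen <- max(ln)
  matrix(tabulate((lv - 1L) * maxlen + ln, nbins = ng * maxlen),
         ng, maxlen, byrow = TRUE)
}

## shared features of the (gray level i) x (size j) count-matrix families:
## GLRLM (j = run length), GLSZM (j = zone size), GLDM (j = dependence).
.size_family_features <- function(P, np, kind) {
  ns <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / ns
  mui <- sum(i * p); muj <- sum(j * p)
  pg <- rowSums(P); pz <- colSums(P)
  base <- c(
    small = sum(P / j^2) / ns,
    large = sum(P * j^2) / ns,
    gln = sum(pg^2) / ns,
    glnn = sum(pg^2) / ns^2,
    szn = sum(pz^2) / ns,
    sznn = sum(pz^2) / ns^2,
    pct = ns / np,
    glv = sum((i - mui)^2 * p),
    szv = sum((j - muj)^2 * p),
    ent = { q <- p[p > 0]; -sum(q * log2(q)) },
    lgl = sum(P / i^2) / ns,
    hgl = sum(P * i^2) / ns,
    slgl = sum(P / (i^2 * j^2)) / ns,
    shgl = sum(P * i^2 / j^2) / ns,
    llgl = sum(P * j^2 / i^2) / ns,
    lhgl = sum(P * i^2 * j^2) / ns)
  names(base) <- switch(kind,
    run = c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
            "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "GrayLevelVariance", "RunVariance", "RunEntropy",
            "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
            "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"),
    zone = c("SmallAreaEmphasis", "LargeAreaEmphasis",
             "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
             "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
             "ZoneEntropy", "LowGrayLevelZoneEmphasis",
             "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
             "SmallAreaHighGrayLevelEmphasis",
             "LargeAreaLowGrayLevelEmphasis",
             "LargeAreaHighGrayLevelEmphasis"),
    dep = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
            "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
            "DependenceNonUniformity", "DependenceNonUniformityNormalized",
            "DependencePercentage", "GrayLevelVariance",
            "DependenceVariance", "DependenceEntropy",
            "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
            "SmallDependenceLowGrayLevelEmphasis",
            "SmallDependenceHighGrayLevelEmphasis",
            "LargeDependenceLowGrayLevelEmphasis",
            "LargeDependenceHighGrayLevelEmphasis"))
  base
}

## ---------------------------------------------------------------------------
## GLSZM
## ---------------------------------------------------------------------------

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of constant level inside the VOI; the
#' matrix counts zones by (level, size). A single matrix is built (no
#' direction averaging).
#'
#' @inheritParams glcmFeatures
#' @return Named numeric vector of the 16 GLSZM features.
#' @export
glszmFeatures <- function(levels) {
  ng <- .ng_of(levels)
  np <- sum(!is.na(levels))
  zones <- .glszm_zones(levels)
  maxsz <- max(zones$size)
  P <- matrix(tabulate((zones$level - 1L) * maxsz + zones$size,
                       nbins = ng * maxsz), ng, maxsz, byrow = TRUE)
  .size_family_features(P, np, "zone")
}

## label 26-connected constant-level zones; returns per-zone level and size
.glszm_zones <- function(levels) {
  dims <- dim(levels)
  assigned <- array(FALSE, dims)
  assigned[is.na(levels)] <- TRUE
  idx <- which(!assigned)
  lv <- integer(0); sz <- integer(0)
  coordOf <- function(lin) arrayInd(lin, dims)
  for (v in idx) {
    if (assigned[v]) next
    level <- levels[v]
    assigned[v] <- TRUE
    frontier <- coordOf(v)
    size <- 1L
    while (nrow(frontier)) {
      cand <- NULL
      for (r in seq_len(nrow(.DIRECTIONS_26))) {
        nb <- sweep(frontier, 2, .DIRECTIONS_26[r, ], `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
        cand <- rbind(cand, nb[ok, , drop = FALSE])
      }
      lin <- unique(cand[, 1] + (cand[, 2] - 1L) * dims[1] +
                      (cand[, 3] - 1L) * dims[1] * dims[2])
      lin <- lin[!assigned[lin] & levels[lin] == level]
      if (!length(lin)) break
      assigned[lin] <- TRUE
      size <- size + length(lin)
      frontier <- arrayInd(lin, dims)
    }
    lv <- c(lv, level); sz <- c(sz, size)
  }
  list(level = lv, size = sz)
}

## ---------------------------------------------------------------------------
## GLDM
## ---------------------------------------------------------------------------

#' Gray-level dependence matrix features
#'
#' The dependence of a voxel is one plus the number of in-mask 26-neighbours
#' with exactly the same level (alpha = 0); the matrix counts voxels by
#' (level, dependence).
#'
#' @inheritParams glcmFeatures
#' @return Named numeric vector of the 14 GLDM features.
#' @export
gldmFeatures <- function(levels) {
  ng <- .ng_of(levels)
  np <- sum(!is.na(levels))
  dep <- array(1L, dim(levels))
  for (r in seq_len(nrow(.DIRECTIONS_26))) {
    nb <- .shift_arr(levels, .DIRECTIONS_26[r, ])
    eq <- !is.na(levels) & !is.na(nb) & levels == nb
    dep <- dep + eq
  }
  inm <- !is.na(levels)
  maxd <- max(dep[inm])
  P <- matrix(tabulate((levels[inm] - 1L) * maxd + dep[inm],
                       nbins = ng * maxd), ng, maxd, byrow = TRUE)
  f <- .size_family_features(P, np, "dep")
  ## the GLDM registry keeps 14 of the family statistics
  f[c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "GrayLevelVariance",
      "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
      "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis")]
}

## ---------------------------------------------------------------------------
## Combined texture vector
## ---------------------------------------------------------------------------

#' All 68 texture features of a discretized VOI
#'
#' @param levels integer 3D level array with `NA` outside the VOI (attribute
#'   `Ng` respected when present).
#' @return data.frame with columns `class`, `feature`, `value` in registry
#'   order (22 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM).
#' @export
textureFeatures <- function(levels) {
  if (all(is.na(levels))) stop("mask is empty")
  out <- rbind(
    data.frame(class = "glcm", feature = .GLCM_NAMES,
               value = unname(glcmFeatures(levels)[.GLCM_NAMES])),
    data.frame(class = "glrlm", feature = .GLRLM_NAMES,
               value = unname(glrlmFeatures(levels)[.GLRLM_NAMES])),
    data.frame(class = "glszm", feature = .GLSZM_NAMES,
               value = unname(glszmFeatures(levels)[.GLSZM_NAMES])),
    data.frame(class = "gldm", feature = .GLDM_NAMES,
               value = unname(gldmFeatures(levels)[.GLDM_NAMES])))
  rownames(out) <- NULL
  out
}
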
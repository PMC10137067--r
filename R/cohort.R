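## Synthetic radiogenomics cohort generator. The generator plants the
## statistical structure the analysis assumes -- two latent subtypes that
## differ on texture features, a subtype-elevated immune module and a
## subtype-elevated cell-cycle module in negative-binomial expression
## counts, higher hazard in subtype 2, and AFP-like / grade-like clinical
## covariates -- and records every planted effect as ground truth.

#' Synthetic cohort configuration
#'
#' Defaults mirror the discovery-cohort conditions the analysis targets: 30
#' patients split 16/14 across two subtypes, a subtype-2 log hazard of
#' `log(1/0.146)`, and two planted expression modules (an immune module
#' elevated in subtype 1 and a cell-cycle module elevated in subtype 2,
#' both at log2 effect 2).
#'
#' @param nPatients cohort size.
#' @param seed integer seed; identical configs with identical seeds
#'   generate identical cohorts.
#' @param subtypeProportions simplex vector of subtype proportions.
#' @param textureEffectSD mean shift (in SD units of the feature noise)
#'   planted on affected texture features.
#' @param affectedFeatureFraction fraction of the 100 features per view
#'   that receive the shift (drawn from the texture block, capped at 68).
#' @param nGenes number of genes.
#' @param moduleSpec named list of planted modules; each element a list
#'   with `size`, `subtype` (which subtype is elevated) and `log2fc`.
#' @param nbDispersion negative-binomial dispersion (1/size).
#' @param subtype2LogHazard planted log hazard ratio of subtype 2 vs 1.
#' @param censoringRate target fraction of administratively censored
#'   patients (uniform censoring horizon solved to match).
#' @param makeVolumes also allow [generateVolumes()] on this config.
#' @param volumeDim,lesionRadiusMm image grid (voxels) and ellipsoidal
#'   lesion radii (mm) used by [generateVolumes()].
#' @return Named list with class `CohortConfig`.
#' @export
cohortConfig <- function(nPatients = 30L, seed = 1L,
    subtypeProportions = c(16, 14) / 30, textureEffectSD = 1.5,
    affectedFeatureFraction = 0.3, nGenes = 1000L,
    moduleSpec = list(
      immune = list(size = 100L, subtype = 1L, log2fc = 2),
      cellcycle = list(size = 80L, subtype = 2L, log2fc = 2)),
    nbDispersion = 0.1, subtype2LogHazard = log(1 / 0.146),
    censoringRate = 0.3, makeVolumes = FALSE,
    volumeDim = c(36L, 36L, 24L), lesionRadiusMm = c(7, 6, 5)) {
  if (nPatients < 1 || nPatients != round(nPatients))
    stop("invalid config: 'nPatients' must be a positive integer")
  if (nGenes < 1 || nGenes != round(nGenes))
    stop("invalid config: 'nGenes' must be a positive integer")
  if (abs(sum(subtypeProportions) - 1) > 1e-8 || any(subtypeProportions <= 0))
    stop("invalid config: proportions must be positive and sum to 1")
  if (textureEffectSD < 0) stop("invalid config: negative effect size")
  if (affectedFeatureFraction < 0 || affectedFeatureFraction > 1)
    stop("invalid config: 'affectedFeatureFraction' must be in [0,1]")
  if (nbDispersion <= 0) stop("invalid config: 'nbDispersion' must be > 0")
  if (censoringRate < 0 || censoringRate >= 1)
    stop("invalid config: 'censoringRate' must be in [0,1)")
  for (m in moduleSpec)
    if (m$size < 1) stop("invalid config: module sizes must be >= 1")
  if (sum(vapply(moduleSpec, function(m) m$size, 0)) > nGenes)
    stop("invalid config: modules exceed 'nGenes'")
  structure(list(nPatients = as.integer(nPatients), seed = as.integer(seed),
                 subtypeProportions = subtypeProportions,
                 textureEffectSD = textureEffectSD,
                 affectedFeatureFraction = affectedFeatureFraction,
                 nGenes = as.integer(nGenes), moduleSpec = moduleSpec,
                 nbDispersion = nbDispersion,
                 subtype2LogHazard = subtype2LogHazard,
                 censoringRate = censoringRate, makeVolumes = makeVolumes,
                 volumeDim = as.integer(volumeDim),
                 lesionRadiusMm = lesionRadiusMm),
            class = "CohortConfig")
}

## largest-remainder apportionment of n patients to proportions
.apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## censoring horizon tau with E[fraction censored] = target under
## exponential event times and U(0, tau) censoring
.censor_horizon <- function(rates, target) {
  f <- function(tau) mean((1 - exp(-rates * tau)) / (rates * tau)) - target
  uniroot(f, lower = 1e-6, upper = 1e9, tol = 1e-8)$root
}

#' Generate a synthetic radiogenomics cohort
#'
#' Draws the multi-view feature table (i.i.d. standard normal per view
#' plus subtype mean shifts on the affected texture features, then
#' z-scored), negative-binomial expression counts with the planted module
#' effects, exponential survival with the planted subtype-2 log hazard and
#' uniform administrative censoring, and AFP-like / grade-like clinical
#' covariates. All planted structure is returned in the `truth` slot.
#'
#' @param config a [cohortConfig()] list.
#' @return A [SyntheticCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(seed = 7))
#' cohortTruth(coh)$subtype[1:5]
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  n <- config$nPatients
  ids <- sprintf("P%03d", seq_len(n))
  nSub <- length(config$subtypeProportions)
  counts_k <- .apportion(n, config$subtypeProportions)
  subtype <- sample(rep(seq_len(nSub), counts_k))
  names(subtype) <- ids

  ## ---- features: 4 views x 100 registry features -----------------------
  reg <- featureRegistry()
  vt <- viewTypes()
  texIdx <- which(reg$class %in% c("glcm", "glrlm", "glszm", "gldm"))
  nAff <- min(round(config$affectedFeatureFraction * nrow(reg)),
              length(texIdx))
  blocks <- list(); planted <- list()
  for (v in vt$view) {
    M <- matrix(rnorm(n * nrow(reg)), n, nrow(reg))
    aff <- sort(sample(texIdx, nAff))
    sgn <- sample(c(-1, 1), nAff, replace = TRUE)
    if (nAff > 0 && config$textureEffectSD > 0)
      M[subtype == 2L, aff] <- M[subtype == 2L, aff] +
        rep(sgn * config$textureEffectSD, each = sum(subtype == 2L))
    blocks[[v]] <- M
    if (nAff > 0)
      planted[[v]] <- data.frame(view = v, class = reg$class[aff],
                                 feature = reg$feature[aff],
                                 shift_subtype2 = sgn * config$textureEffectSD,
                                 stringsAsFactors = FALSE)
  }
  mat <- do.call(cbind, blocks)
  rownames(mat) <- ids
  fi <- data.frame(view = rep(vt$view, each = nrow(reg)),
                   class = rep(reg$class, nrow(vt)),
                   feature = rep(reg$feature, nrow(vt)),
                   stringsAsFactors = FALSE)
  zs <- .zscore_columns(mat)
  attr(zs, "constantColumns") <- NULL
  features <- multiViewFeatureTable(zs, fi, standardized = TRUE)

  ## ---- expression counts ----------------------------------------------
  nG <- config$nGenes
  genes <- sprintf("g%04d", seq_len(nG))
  moduleOf <- rep("grey", nG)
  at <- 1L
  for (mn in names(config$moduleSpec)) {
    sz <- config$moduleSpec[[mn]]$size
    moduleOf[at:(at + sz - 1L)] <- mn
    at <- at + sz
  }
  names(moduleOf) <- genes
  baseMu <- exp(rnorm(nG, log(100), 1))
  lfcMat <- matrix(0, nG, n)
  for (mn in names(config$moduleSpec)) {
    ms <- config$moduleSpec[[mn]]
    lfcMat[moduleOf == mn, subtype == ms$subtype] <- ms$log2fc
  }
  mu <- baseMu * 2^lfcMat
  cnt <- matrix(rnbinom(nG * n, mu = mu, size = 1 / config$nbDispersion),
                nG, n, dimnames = list(genes, ids))

  ## ---- survival --------------------------------------------------------
  lambda0 <- log(2) / 730     # ~2-year median survival in the better arm
  rate <- lambda0 * exp(config$subtype2LogHazard * (subtype == 2L))
  tev <- rexp(n, rate)
  if (config$censoringRate > 0) {
    tau <- .censor_horizon(rate, config$censoringRate)
    cen <- runif(n, 0, tau)
  } else {
    cen <- rep(Inf, n)
  }
  time <- pmax(1, ceiling(pmin(tev, cen)))
  event <- as.integer(tev <= cen)
  survivalTab <- data.frame(patient_id = ids, time_days = time,
                            event = event, endpoint = "OS",
                            stringsAsFactors = FALSE)

  ## ---- clinical --------------------------------------------------------
  afp <- rlnorm(n, meanlog = log(20) + log(5) * (subtype == 2L), sdlog = 1)
  gradeProbs <- rbind(c(0.5, 0.4, 0.1), c(0.1, 0.4, 0.5))
  grade <- vapply(subtype, function(s)
    sample(1:3, 1, prob = gradeProbs[s, ]), 0L)
  clinical <- data.frame(patient_id = ids, afp = afp, grade = grade,
                         stringsAsFactors = FALSE)

  truth <- list(subtype = subtype, geneModule = moduleOf,
                affectedFeatures = if (length(planted))
                  do.call(rbind, c(planted, make.row.names = FALSE))
                  else NULL,
                plantedLogHazard = config$subtype2LogHazard,
                volumeContrastHigherIn = 1L, config = config)
  new("SyntheticCohort", features = features, counts = cnt,
      survival = survivalTab, clinical = clinical, truth = truth)
}

#' Generate synthetic two-phase CT volumes with lesion masks
#'
#' Builds, for each patient, arterial and venous phase volumes with an
#' ellipsoidal lesion on a liver-like background. Subtype-1 lesions carry
#' low-intensity heterogeneous voxel noise (high texture contrast after
#' discretization); subtype-2 lesions carry a high-intensity smooth
#' gradient (low contrast). The venous phase adds a constant enhancement
#' offset. Deterministic given the config seed.
#'
#' @param config a [cohortConfig()] with `makeVolumes = TRUE`.
#' @return Named list (one element per patient) of lists with components
#'   `arterial`, `venous` ([ImageVolume-class]), `tumor`
#'   ([VOIMask-class]) and `subtype`.
#' @export
generateVolumes <- function(config = cohortConfig(makeVolumes = TRUE)) {
  stopifnot(inherits(config, "CohortConfig"))
  if (!isTRUE(config$makeVolumes))
    stop("config has makeVolumes = FALSE")
  dims <- config$volumeDim
  rad <- config$lesionRadiusMm
  if (any(rad <= 0)) stop("geometry error: lesion radius must be positive")
  if (any(2 * rad + 4 > dims))
    stop("geometry error: volume smaller than lesion")
  set.seed(config$seed + 1L)
  n <- config$nPatients
  ids <- sprintf("P%03d", seq_len(n))
  counts_k <- .apportion(n, config$subtypeProportions)
  subtype <- sample(rep(seq_along(counts_k), counts_k))
  ctr <- (dims + 1) / 2
  ax <- lapply(1:3, function(a) seq_len(dims[a]) - ctr[a])
  out <- list()
  for (i in seq_len(n)) {
    r <- rad * runif(3, 0.85, 1.15)
    r <- pmin(r, (dims - 4) / 2)
    E <- outer(outer((ax[[1]] / r[1])^2, (ax[[2]] / r[2])^2, `+`),
               (ax[[3]] / r[3])^2, `+`)
    lesion <- E <= 1
    if (!any(lesion)) stop("geometry error: empty lesion mask")
    bg <- array(rnorm(prod(dims), 90, 3), dims)
    vol <- bg
    if (subtype[i] == 1L) {
      vol[lesion] <- rnorm(sum(lesion), 60, 18)
    } else {
      ramp <- outer(outer(ax[[1]], rep(1, dims[2])), rep(1, dims[3])) /
        max(abs(ax[[1]]))
      vol[lesion] <- 120 + 8 * ramp[lesion] + rnorm(sum(lesion), 0, 2)
    }
    venous <- vol + 15 + array(rnorm(prod(dims), 0, 1), dims)
    out[[ids[i]]] <- list(
      arterial = imageVolume(vol),
      venous = imageVolume(venous),
      tumor = voiMask(lesion),
      subtype = subtype[i])
  }
  attr(out, "subtype") <- setNames(subtype, ids)
  out
}
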
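## Nearest shrunken centroid subtype classifier: candidate-gene
## preselection, training with 10-fold stratified CV over a shrinkage
## grid, prediction, and external-cohort validation.

#' Candidate genes for the subtype classifier
#'
#' Intersection of the significant differentially expressed genes with the
#' membership of the PRF-related co-expression modules.
#'
#' @param de data.frame from [differentialExpression()].
#' @param moduleGenes character vector of gene ids belonging to
#'   PRF-related modules.
#' @return Character vector of candidate gene ids.
#' @export
candidateGenes <- function(de, moduleGenes) {
  hits <- de$gene[de$significant]
  out <- intersect(hits, moduleGenes)
  if (!length(out))
    stop("no overlap between DE genes and module genes; consider looser ",
         "DE thresholds or larger modules")
  out
}

## raw statistics shared by training and CV: centroids, pooled SD, d_ik
.nsc_stats <- function(X, y) {
  ## X: genes x samples, y: factor
  classes <- levels(y)
  n <- ncol(X); K <- length(classes)
  if (n <= K)
    stop("need more samples than classes to pool within-class variance")
  nk <- table(y)
  xbar <- rowMeans(X)
  cent <- vapply(classes, function(cl) rowMeans(X[, y == cl, drop = FALSE]),
                 numeric(nrow(X)))
  ## pooled within-class SD
  ss <- 0
  for (cl in classes) {
    d <- X[, y == cl, drop = FALSE] - cent[, cl]
    ss <- ss + rowSums(d^2)
  }
  si <- sqrt(ss / (n - K))
  s0 <- median(si)
  mk <- sqrt(1 / nk - 1 / n)
  dik <- vapply(classes, function(cl)
    (cent[, cl] - xbar) / (mk[cl] * (si + s0)), numeric(nrow(X)))
  list(classes = classes, nk = nk, xbar = xbar, cent = cent, si = si,
       s0 = s0, mk = mk, dik = dik)
}

## shrunken centroids at threshold delta
.nsc_shrink <- function(st, delta) {
  dik <- sign(st$dik) * pmax(abs(st$dik) - delta, 0)
  cent <- st$xbar + sweep(dik * (st$si + st$s0), 2, st$mk, `*`)
  list(dik = dik, cent = cent)
}

## discriminant prediction given shrunken centroids
.nsc_discriminant <- function(Xnew, cent, si, s0, priors, classes) {
  scores <- vapply(classes, function(cl) {
    colSums((Xnew - cent[, cl])^2 / (si + s0)^2) - 2 * log(priors[cl])
  }, numeric(ncol(Xnew)))
  scores <- matrix(scores, ncol = length(classes),
                   dimnames = list(colnames(Xnew), classes))
  lab <- classes[apply(scores, 1, which.min)]  # ties -> first class
  list(labels = setNames(lab, colnames(Xnew)), scores = scores)
}

#' Train a nearest shrunken centroid classifier
#'
#' Standardized class-centroid offsets
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` are soft-thresholded at
#' each candidate Delta and the misclassification error estimated by
#' stratified k-fold cross-validation. The chosen threshold is the largest
#' Delta attaining the minimal CV error (fewest genes at lowest error).
#' The grid is 30 evenly spaced values from 0 to `max |d_ik|`.
#'
#' @param expr genes x samples matrix (candidate genes only).
#' @param labels class labels (two or more classes).
#' @param thresholds optional explicit threshold grid.
#' @param folds number of CV folds (default 10; reduced with a warning if
#'   a class is smaller).
#' @param seed integer seed for fold assignment.
#' @return A [ShrunkenCentroidModel-class].
#' @export
trainNSC <- function(expr, labels, thresholds = NULL, folds = 10L,
                     seed = 1L) {
  X <- as.matrix(expr)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  if (min(table(y)) < 2L) stop("each class needs >= 2 samples")
  if (min(table(y)) < folds) {
    folds <- max(2L, min(table(y)))
    warning("reducing folds to ", folds, " (smallest class size)")
  }
  st <- .nsc_stats(X, y)
  if (is.null(thresholds))
    thresholds <- seq(0, max(abs(st$dik)), length.out = 30L)
  thresholds <- sort(thresholds)
  priors <- table(y) / length(y)

  ## stratified folds
  foldOf <- withr_seed(seed, {
    f <- integer(ncol(X))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
  cvErr <- numeric(length(thresholds))
  for (fd in seq_len(folds)) {
    tr <- foldOf != fd
    if (nlevels(droplevels(y[tr])) < nlevels(y))
      stop("a fold lost a class; stratification failed")
    stTr <- .nsc_stats(X[, tr, drop = FALSE], y[tr])
    priorsTr <- table(y[tr]) / sum(tr)
    for (ti in seq_along(thresholds)) {
      sh <- .nsc_shrink(stTr, thresholds[ti])
      pr <- .nsc_discriminant(X[, !tr, drop = FALSE], sh$cent, stTr$si,
                              stTr$s0, priorsTr, stTr$classes)
      cvErr[ti] <- cvErr[ti] + sum(pr$labels != as.character(y[!tr]))
    }
  }
  cvErr <- cvErr / ncol(X)
  nActive <- vapply(thresholds, function(d)
    sum(rowSums(abs(.nsc_shrink(st, d)$dik)) > 0), 0L)
  best <- max(which(cvErr == min(cvErr)))   # largest Delta, fewest genes
  sh <- .nsc_shrink(st, thresholds[best])
  genes <- rownames(X)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(X)))
  new("ShrunkenCentroidModel", genes = genes, overallCentroid = st$xbar,
      centroids = sh$cent, sdPooled = st$si, s0 = st$s0,
      priors = setNames(as.numeric(priors), names(priors)),
      threshold = thresholds[best],
      cvProfile = data.frame(threshold = thresholds, cv_error = cvErr,
                             n_active = nActive),
      classes = st$classes)
}

#' Predict with a nearest shrunken centroid model
#'
#' Assigns each sample to the class minimizing the standardized squared
#' distance to the shrunken centroid penalized by the log prior. Genes
#' absent from `expr` are imputed at the overall centroid with a warning;
#' ties go deterministically to the first class.
#'
#' @param model a [ShrunkenCentroidModel-class].
#' @param expr genes x samples matrix covering (ideally) the model genes.
#' @return list with `labels` (named character) and `scores` (samples x
#'   classes discriminant matrix).
#' @export
predictNSC <- function(model, expr) {
  X <- as.matrix(expr)
  act <- activeGenes(model)
  if (!length(act)) stop("model has no active genes")
  missing <- setdiff(model@genes, rownames(X))
  if (length(missing)) {
    warning(length(missing), " model gene(s) missing; imputed at the ",
            "overall centroid")
    imp <- matrix(model@overallCentroid[match(missing, model@genes)],
                  nrow = length(missing), ncol = ncol(X),
                  dimnames = list(missing, colnames(X)))
    X <- rbind(X, imp)
  }
  X <- X[model@genes, , drop = FALSE]
  .nsc_discriminant(X, model@centroids, model@sdPooled, model@s0,
                    model@priors, model@classes)
}

#' Validate predicted subtypes on an external cohort
#'
#' Compares survival between predicted arms (Kaplan-Meier + log-rank),
#' scores the supplied immune gene sets per patient with [ssgseaScores()],
#' z-scores each pathway row and orders rows by hierarchical clustering.
#' For two predicted arms the labels are prognosis-anchored so that
#' `FIFS1` is the better-survival arm.
#'
#' @param predicted named vector of predicted class labels.
#' @param survivalData data.frame with `patient_id`, `time_days`, `event`.
#' @param immuneSets named list of immune-related gene sets.
#' @param expr genes x patients expression matrix.
#' @return list: `labels` (possibly re-anchored), `logrank` (list from
#'   [logrankTest()] or NULL when degenerate), `km` (per-arm KM tables),
#'   `scoreMatrix` (row-z-scored, row-ordered), `rowOrder`.
#' @export
validateExternal <- function(predicted, survivalData, immuneSets, expr) {
  ids <- names(predicted)
  sv <- survivalData[match(ids, survivalData$patient_id), ]
  lab <- factor(predicted)
  degenerate <- nlevels(droplevels(lab)) < 2L
  lr <- NULL
  if (degenerate) {
    warning("only one predicted class; reporting descriptive output")
  } else {
    if (nlevels(lab) == 2L) {
      asg <- orientSubtypes(subtypeAssignment(
        setNames(as.integer(lab), ids), k = 2L), sv)
      lab <- subtypeNames(asg)
    }
    lr <- logrankTest(sv, lab)
  }
  km <- lapply(split(seq_along(ids), lab), function(ix)
    kmEstimate(sv[ix, , drop = FALSE]))
  S <- ssgseaScores(expr[, ids, drop = FALSE], immuneSets)
  Z <- t(scale(t(S)))
  Z[!is.finite(Z)] <- 0               # constant score rows
  ord <- if (nrow(Z) >= 2L) hclust(dist(Z), method = "average")$order
         else seq_len(nrow(Z))
  list(labels = setNames(as.character(lab), ids), logrank = lr, km = km,
       scoreMatrix = Z[ord, , drop = FALSE], rowOrder = rownames(Z)[ord])
}
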
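## The prognostic-radiomics-feature (PRF) cascade and the
## module -> pathway -> feature -> gene association network.

## Pearson correlation matrix with two-sided t-test p values; equivalent to
## cor.test per pair but vectorized
.cor_with_p <- function(X, Y) {
  n <- nrow(X)
  R <- cor(X, Y)
  tt <- abs(R) * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(-tt, df = n - 2)
  P[abs(R) >= 1] <- 0
  list(r = R, p = P)
}

#' Identify prognostic radiomics features
#'
#' Two-stage cascade on z-scored feature eigenvalues: (1) a two-sample
#' Student's t-test between the two subtypes keeps features with p < 0.05;
#' (2) a univariate Cox fit per surviving feature keeps those with
#' p < 0.05. Retained features are annotated with their view, phase,
#' region, class and the subtype with the higher mean. Zero-variance
#' features are excluded with a message.
#'
#' @param features a [MultiViewFeatureTable-class] (z-scored).
#' @param subtypes a [SubtypeAssignment-class] with k = 2.
#' @param survivalData data.frame with `patient_id`, `time_days`, `event`.
#' @param alphaDiff,alphaCox stage thresholds (default 0.05 each).
#' @return data.frame (feature_key, view, phase, region, class, feature,
#'   higher_subtype, diff_p, hr, ci_lower, ci_upper, cox_p), one row per
#'   PRF. The full per-feature cascade table is attached as attribute
#'   `cascade`.
#' @export
identifyPRFs <- function(features, subtypes, survivalData,
                         alphaDiff = 0.05, alphaCox = 0.05) {
  stopifnot(is(features, "MultiViewFeatureTable"),
            is(subtypes, "SubtypeAssignment"))
  if (subtypes@k != 2L) stop("the cascade expects two subtypes")
  X <- featureValues(features)
  lab <- subtypeLabels(subtypes)[rownames(X)]
  if (anyNA(lab)) stop("subtype labels misaligned with feature table")
  sv <- survivalData[match(rownames(X), survivalData$patient_id), ]
  fi <- featureInfo(features)
  vt <- viewTypes()
  fi$phase <- vt$phase[match(fi$view, vt$view)]
  fi$region <- vt$region[match(fi$view, vt$view)]
  n <- ncol(X)
  diffP <- rep(NA_real_, n)
  hi <- rep(NA_integer_, n)
  sds <- apply(X, 2, sd)
  usable <- sds > 0
  if (any(!usable))
    message(sum(!usable), " zero-variance feature(s) excluded from the ",
            "cascade")
  for (j in which(usable)) {
    x1 <- X[lab == 1L, j]; x2 <- X[lab == 2L, j]
    if (sd(x1) == 0 && sd(x2) == 0) { usable[j] <- FALSE; next }
    diffP[j] <- t.test(x1, x2, var.equal = TRUE)$p.value
    hi[j] <- if (mean(x1) >= mean(x2)) 1L else 2L
  }
  stage1 <- usable & !is.na(diffP) & diffP < alphaDiff
  coxP <- hr <- lo <- up <- rep(NA_real_, n)
  for (j in which(stage1)) {
    fit <- tryCatch(suppressWarnings(coxFit(sv, X[, j, drop = FALSE])),
                    error = function(e) NULL)
    if (is.null(fit)) next
    coxP[j] <- fit$p[1]; hr[j] <- fit$hr[1]
    lo[j] <- fit$ci_lower[1]; up[j] <- fit$ci_upper[1]
  }
  keep <- stage1 & !is.na(coxP) & coxP < alphaCox
  cascade <- data.frame(feature_key = colnames(X), view = fi$view,
                        phase = fi$phase, region = fi$region,
                        class = fi$class, feature = fi$feature,
                        diff_p = diffP, stage1 = stage1, cox_p = coxP,
                        stringsAsFactors = FALSE)
  out <- data.frame(feature_key = colnames(X)[keep], view = fi$view[keep],
                    phase = fi$phase[keep], region = fi$region[keep],
                    class = fi$class[keep], feature = fi$feature[keep],
                    higher_subtype = paste0("FIFS", hi[keep]),
                    diff_p = diffP[keep], hr = hr[keep],
                    ci_lower = lo[keep], ci_upper = up[keep],
                    cox_p = coxP[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cascade") <- cascade
  out
}

#' Filter modules to those related to prognostic radiomics features
#'
#' Keeps co-expression modules that are (a) significantly correlated with
#' the subtype indicator, (b) prognostic by a univariate Cox fit of their
#' eigengene, and (c) correlated with at least one PRF (Pearson p < 0.05).
#' All three flags are returned per module.
#'
#' @param eigengenes modules x samples matrix (samples = patients).
#' @param subtypes a [SubtypeAssignment-class].
#' @param survivalData data.frame with `patient_id`, `time_days`, `event`.
#' @param prfTable output of [identifyPRFs()].
#' @param features the [MultiViewFeatureTable-class] holding the PRF
#'   values.
#' @param alpha per-criterion threshold (default 0.05).
#' @return data.frame (module, subtype_p, cox_p, n_prf_correlated,
#'   pass_subtype, pass_cox, pass_prf, kept).
#' @export
filterPrfModules <- function(eigengenes, subtypes, survivalData, prfTable,
                             features, alpha = 0.05) {
  if (!nrow(eigengenes)) stop("empty module set")
  ids <- colnames(eigengenes)
  lab <- subtypeLabels(subtypes)[ids]
  ind <- as.numeric(lab == 1L)
  sv <- survivalData[match(ids, survivalData$patient_id), ]
  X <- featureValues(features)[ids, prfTable$feature_key, drop = FALSE]
  rows <- lapply(rownames(eigengenes), function(m) {
    e <- eigengenes[m, ]
    pSub <- cor.test(e, ind)$p.value
    pCox <- tryCatch(suppressWarnings(coxFit(sv, matrix(e,
      dimnames = list(NULL, m)))$p[1]), error = function(err) NA_real_)
    pPrf <- if (ncol(X)) vapply(seq_len(ncol(X)), function(j)
      cor.test(e, X[, j])$p.value, 0) else numeric(0)
    nSig <- sum(pPrf < alpha)
    data.frame(module = m, subtype_p = pSub, cox_p = pCox,
               n_prf_correlated = nSig,
               pass_subtype = pSub < alpha,
               pass_cox = !is.na(pCox) && pCox < alpha,
               pass_prf = nSig >= 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$kept <- out$pass_subtype & out$pass_cox & out$pass_prf
  rownames(out) <- NULL
  out
}

#' Pathway-feature correlation pairs
#'
#' Pearson correlation between every per-patient pathway enrichment score
#' and every PRF eigenvalue, Benjamini-Hochberg adjusted once across the
#' whole pathway x PRF grid; pairs with `q < fdr` are retained. Constant
#' score vectors are skipped with a warning.
#'
#' @param pathwayScores pathways x patients score matrix (e.g. from
#'   [ssgseaScores()] on the PRF-related-module pathways).
#' @param prfValues patients x PRFs numeric matrix.
#' @param fdr retention threshold on adjusted p (default 0.05).
#' @param pathwayModules optional named vector pathway -> module label.
#' @return data.frame (module, pathway, prf, r, p, q), retained pairs
#'   only; the unfiltered grid is attached as attribute `allPairs`.
#' @export
pathwayFeaturePairs <- function(pathwayScores, prfValues, fdr = 0.05,
                                pathwayModules = NULL) {
  S <- as.matrix(pathwayScores)
  X <- as.matrix(prfValues)
  if (ncol(S) != nrow(X)) stop("patients misaligned")
  keepPath <- apply(S, 1, sd) > 0
  if (any(!keepPath))
    warning("skipping ", sum(!keepPath), " constant score vector(s)")
  S <- S[keepPath, , drop = FALSE]
  cp <- .cor_with_p(t(S), X)
  all <- data.frame(
    module = if (!is.null(pathwayModules))
      unname(pathwayModules[rep(rownames(S), ncol(X))])
      else NA_character_,
    pathway = rep(rownames(S), ncol(X)),
    prf = rep(colnames(X), each = nrow(S)),
    r = as.vector(cp$r), p = as.vector(cp$p), stringsAsFactors = FALSE)
  all$q <- p.adjust(all$p, method = "BH")
  out <- all[all$q < fdr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "allPairs") <- all
  out
}

#' Bipartite PRF-pathway association network
#'
#' Keeps the `topN` pairs of each PRF by `|r|` (ties broken by pathway
#' name) and assembles the bipartite graph with edge weight `|r|`, PRF
#' nodes carrying their subtype and pathway nodes their module colour.
#'
#' @param pairs data.frame from [pathwayFeaturePairs()].
#' @param topN edges kept per PRF (default 5; `Inf` keeps all).
#' @param prfSubtypes optional named vector PRF -> subtype label.
#' @return An \pkg{igraph} bipartite graph.
#' @export
buildAssociationNetwork <- function(pairs, topN = 5, prfSubtypes = NULL) {
  kept <- do.call(rbind, lapply(split(pairs, pairs$prf), function(d) {
    d <- d[order(-abs(d$r), d$pathway), , drop = FALSE]
    head(d, n = if (is.finite(topN)) topN else nrow(d))
  }))
  g <- igraph::graph_from_data_frame(
    data.frame(from = kept$prf, to = kept$pathway,
               weight = abs(kept$r), r = kept$r),
    directed = FALSE)
  igraph::V(g)$type <- igraph::V(g)$name %in% kept$pathway
  mod <- kept$module[match(igraph::V(g)$name, kept$pathway)]
  igraph::V(g)$module <- mod
  if (!is.null(prfSubtypes))
    igraph::V(g)$subtype <- unname(prfSubtypes[igraph::V(g)$name])
  g
}

#' Top correlated gene per prognostic radiomics feature
#'
#' For each retained pathway-feature pair, correlates the expression of
#' every measured member gene of the pathway with the PRF eigenvalue and
#' reports, per PRF, the gene with the largest `|r|` among those with
#' p < 0.05.
#'
#' @param expr genes x patients expression matrix.
#' @param pairs data.frame from [pathwayFeaturePairs()].
#' @param prfValues patients x PRFs matrix.
#' @param geneSets named list pathway -> gene ids.
#' @return data.frame (gene, prf, pathway, module, r, p); at most one row
#'   per PRF. Pathways without measured genes are skipped with a warning.
#' @export
prfRelatedGenes <- function(expr, pairs, prfValues, geneSets) {
  expr <- as.matrix(expr)
  X <- as.matrix(prfValues)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pw <- pairs$pathway[i]; f <- pairs$prf[i]
    genes <- intersect(geneSets[[pw]], rownames(expr))
    if (!length(genes)) {
      warning("pathway ", pw, " has no measured gene; skipped")
      next
    }
    cp <- .cor_with_p(t(expr[genes, , drop = FALSE]),
                      X[, f, drop = FALSE])
    rows[[paste(f, pw)]] <- data.frame(gene = genes, prf = f,
      pathway = pw, module = pairs$module[i], r = as.vector(cp$r),
      p = as.vector(cp$p), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(gene = character(0),
    prf = character(0), pathway = character(0), module = character(0),
    r = numeric(0), p = numeric(0)))
  all <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(all, all$prf), function(d) {
    d <- d[d$p < 0.05, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d[which.max(abs(d$r)), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}
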
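## Signed weighted co-expression network: adjacency, topological overlap,
## module detection, eigengenes, module-trait correlation.

#' Co-expression network parameters
#'
#' @param beta soft-thresholding power for the signed adjacency (default 8,
#'   the value reaching scale-free topology on the motivating data).
#' @param minModuleSize smallest retained module (default 30); smaller
#'   branches are sent to the unassigned ("grey") pool.
#' @param cutHeight static tree-cut height on the 1 - TOM dendrogram
#'   (default 0.97).
#' @return Named list with class `CoexpressionParams`.
#' @export
coexpressionParams <- function(beta = 8, minModuleSize = 30L,
                               cutHeight = 0.97) {
  if (beta <= 0) stop("'beta' must be positive")
  if (minModuleSize < 2L) stop("'minModuleSize' must be >= 2")
  if (cutHeight <= 0 || cutHeight > 1) stop("'cutHeight' must be in (0,1]")
  structure(list(beta = beta, minModuleSize = as.integer(minModuleSize),
                 cutHeight = cutHeight), class = "CoexpressionParams")
}

#' Signed weighted adjacency
#'
#' `a_ij = ((1 + cor(g_i, g_j)) / 2)^beta` on pairwise Pearson correlation
#' across samples; `a_ii = 1`. Signed: anti-correlated genes get adjacency
#' near 0 rather than near 1.
#'
#' @param expr genes x samples numeric matrix with gene-id rownames.
#' @param params a [coexpressionParams()] list.
#' @return genes x genes adjacency matrix in \[0, 1\].
#' @export
signedAdjacency <- function(expr, params = coexpressionParams()) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need >= 3 samples")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(expr)[sds == 0], 5), collapse = ", "))
  A <- ((1 + cor(t(expr))) / 2)^params$beta
  diag(A) <- 1
  A
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and connectivity
#' `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`. Credits shared network
#' neighbours so that weakly connected but co-embedded genes cluster
#' together.
#'
#' @param adjacency square symmetric matrix with entries in \[0, 1\].
#' @return TOM similarity matrix in \[0, 1\] with unit diagonal.
#' @export
tomSimilarity <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (max(abs(A - t(A))) > 1e-10) stop("adjacency must be symmetric")
  if (any(A < 0) || any(A > 1 + 1e-12)) stop("entries must be in [0,1]")
  diag(A) <- 0
  L <- A %*% A                 # l_ij over u != i,j given zero diagonal
  k <- rowSums(A)
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, a static cut at
#' `cutHeight`, and a size filter: branches below `minModuleSize` genes are
#' sent to the unassigned "grey" pool. This deterministic static cut is a
#' documented simplification of dynamic-hybrid tree cutting. Modules are
#' named "M1", "M2", ... in decreasing size order.
#'
#' @param tom TOM similarity matrix from [tomSimilarity()].
#' @param params a [coexpressionParams()] list.
#' @return Named character vector gene -> module label ("grey" =
#'   unassigned).
#' @export
detectModules <- function(tom, params = coexpressionParams()) {
  d <- as.dist(1 - tom)
  hc <- hclust(d, method = "average")
  raw <- cutree(hc, h = params$cutHeight)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= params$minModuleSize]
  lab <- rep("grey", length(raw))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep])]
    for (i in seq_along(keep))
      lab[raw == as.integer(keep[i])] <- paste0("M", i)
  } else {
    warning("no module reaches the minimum size; all genes unassigned")
  }
  setNames(lab, rownames(as.matrix(tom)))
}

#' Module eigengenes
#'
#' First principal component of the standardized member-gene expression of
#' each module, scaled to unit variance and sign-oriented so that the
#' average correlation with member genes is positive. A single-gene module
#' yields that gene standardized.
#'
#' @param expr genes x samples matrix.
#' @param modules named character vector gene -> module ("grey" ignored).
#' @return list with `eigengenes` (modules x samples matrix) and
#'   `varExplained` (named numeric).
#' @export
moduleEigengenes <- function(expr, modules) {
  expr <- as.matrix(expr)
  mods <- setdiff(unique(modules), "grey")
  if (!length(mods)) stop("no (non-grey) modules")
  E <- matrix(NA_real_, length(mods), ncol(expr),
              dimnames = list(mods, colnames(expr)))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(modules)[modules == m]
    X <- expr[genes, , drop = FALSE]
    Xs <- t(scale(t(X)))               # standardize each gene
    if (nrow(Xs) == 1L) {
      e <- as.numeric(Xs)
      ve[m] <- 1
    } else {
      pc <- prcomp(t(Xs), center = FALSE, scale. = FALSE)
      e <- pc$x[, 1]
      ve[m] <- pc$sdev[1]^2 / sum(pc$sdev^2)
    }
    ## orient: average correlation with member genes positive
    if (mean(cor(e, t(Xs))) < 0) e <- -e
    E[m, ] <- e / sd(e)
  }
  list(eigengenes = E, varExplained = ve)
}

#' Module-trait correlation
#'
#' Pearson correlation (with two-sided p) between every module eigengene
#' and every phenotype column, e.g. 0-1 subtype indicators.
#'
#' @param eigengenes modules x samples matrix.
#' @param traits samples x phenotypes numeric matrix/data.frame.
#' @return data.frame (module, trait, r, p).
#' @export
moduleTraitCorrelation <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (ncol(eigengenes) != nrow(traits))
    stop("samples misaligned between eigengenes and traits")
  if (any(apply(traits, 2, sd) == 0)) stop("constant trait column")
  rows <- list()
  for (m in rownames(eigengenes)) for (tr in colnames(traits)) {
    ct <- cor.test(eigengenes[m, ], traits[, tr])
    rows[[paste(m, tr)]] <- data.frame(module = m, trait = tr,
      r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep the most variable genes
#'
#' Pre-filter for network construction: retains the `n` genes with the
#' largest median absolute deviation across samples.
#'
#' @param expr genes x samples matrix.
#' @param n number of genes to keep (default 5000).
#' @return Filtered matrix.
#' @export
filterVariableGenes <- function(expr, n = 5000L) {
  expr <- as.matrix(expr)
  if (nrow(expr) <= n) return(expr)
  madv <- apply(expr, 1, stats::mad)
  expr[order(-madv)[seq_len(n)], , drop = FALSE]
}
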
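## Expression statistics: normalization, differential expression at the
## fixed thresholds, rank-based single-sample gene-set scoring, and
## over-representation testing.

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: each sample's median ratio of counts
#' to the per-gene geometric mean, computed over genes expressed in every
#' sample.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return Named positive numeric vector (one factor per sample).
#' @export
sizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (ncol(counts) == 1L)
    return(setNames(1, colnames(counts)))
  allPos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allPos))
    stop("no gene is expressed in all samples; consider adding a ",
         "pseudocount before normalization")
  lg <- log(counts[allPos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(s) exp(median(s - geo)))
  setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#'
#' @param counts genes x samples matrix.
#' @param sf size factors (default [sizeFactors()]).
#' @return Matrix of normalized counts.
#' @export
normalizeCounts <- function(counts, sf = sizeFactors(counts)) {
  sweep(as.matrix(counts), 2, sf, `/`)
}

#' Differential expression between two groups
#'
#' Normalizes by median-of-ratios, computes the log2 fold change from group
#' means with a pseudocount of 1, tests each gene with Welch's t-test on
#' `log2(normalized + 1)`, and adjusts p values by Benjamini-Hochberg. A
#' gene is flagged significant iff `|log2FC| > 1` and adjusted `p < 0.05`.
#' The first factor level (or `reference`) is the reference group, so
#' positive fold changes mean higher expression in the other group.
#'
#' @param counts genes x samples integer matrix.
#' @param groupLabels two-group factor/vector aligned to columns.
#' @param reference optional reference level.
#' @param lfcThreshold,alpha significance thresholds.
#' @return data.frame (gene, log2fc, p, padj, significant) with attribute
#'   `reference`.
#' @export
differentialExpression <- function(counts, groupLabels, reference = NULL,
                                   lfcThreshold = 1, alpha = 0.05) {
  counts <- as.matrix(counts)
  g <- factor(groupLabels)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (!is.null(reference)) g <- stats::relevel(g, ref = reference)
  if (any(table(g) < 2L)) stop("each group needs >= 2 samples")
  norm <- normalizeCounts(counts)
  lx <- log2(norm + 1)
  ref <- g == levels(g)[1]
  m1 <- rowMeans(norm[, ref, drop = FALSE])
  m2 <- rowMeans(norm[, !ref, drop = FALSE])
  lfc <- log2(m2 + 1) - log2(m1 + 1)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    x <- lx[i, ref]; y <- lx[i, !ref]
    if (sd(x) == 0 && sd(y) == 0) return(if (mean(x) == mean(y)) 1 else 0)
    t.test(y, x)$p.value
  }, 0)
  padj <- p.adjust(p, method = "BH")
  gene <- rownames(counts)
  if (is.null(gene)) gene <- paste0("g", seq_len(nrow(counts)))
  out <- data.frame(gene = gene, log2fc = lfc, p = p, padj = padj,
                    significant = abs(lfc) > lfcThreshold & padj < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- levels(g)[1]
  out
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file path.
#' @return `readGMT` returns a named list of character vectors.
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname readGMT
#' @param sets named list of gene-id vectors.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

## restrict sets to the measured universe, dropping empty ones with warning
.filter_sets <- function(sets, universe) {
  out <- lapply(sets, intersect, y = universe)
  empty <- lengths(out) == 0
  if (any(empty))
    warning("dropping ", sum(empty), " gene set(s) with no measured gene: ",
            paste(names(out)[empty], collapse = ", "))
  out <- out[!empty]
  if (!length(out)) stop("all gene sets are empty after intersection")
  out
}

#' Rank-based single-sample gene-set enrichment scores
#'
#' For each sample, genes are ranked by expression (average ranks on
#' ties); the set score is the sum over all rank positions of the
#' difference between the weighted in-set empirical CDF (ranks raised to
#' `weight`) and the unweighted out-of-set CDF. Scores are rescaled by the
#' global (max - min) across the matrix. Because only ranks enter, the
#' score is invariant to any strictly monotone transform of a sample's
#' expression values.
#'
#' @param expr genes x samples numeric matrix (normalized expression).
#' @param sets named list of gene-id vectors.
#' @param weight rank-weighting exponent (default 0.25).
#' @return Sets x samples score matrix with attribute `method = "ssgsea"`.
#' @export
ssgseaScores <- function(expr, sets, weight = 0.25) {
  expr <- as.matrix(expr)
  genes <- rownames(expr)
  if (is.null(genes)) stop("expr needs gene-id rownames")
  sets <- .filter_sets(sets, genes)
  n <- nrow(expr)
  S <- matrix(NA_real_, length(sets), ncol(expr),
              dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")   # higher expr = higher rank
    ord <- order(r, decreasing = TRUE)
    rSorted <- r[ord]
    gSorted <- genes[ord]
    for (s in seq_along(sets)) {
      inset <- gSorted %in% sets[[s]]
      w <- abs(rSorted)^weight
      wIn <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
      nOut <- n - sum(inset)
      pOut <- if (nOut > 0) cumsum(!inset) / nOut else rep(0, n)
      S[s, j] <- sum(wIn - pOut)
    }
  }
  rng <- max(S) - min(S)
  if (rng > 0) S <- S / rng
  attr(S, "method") <- "ssgsea"
  S
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric test of each gene set against a hit
#' list, with Benjamini-Hochberg adjustment across sets.
#'
#' @param hits character vector of significant gene ids (subset of
#'   `universe`).
#' @param sets named list of gene-id vectors.
#' @param universe character vector of all measured gene ids.
#' @return data.frame (set, set_size, overlap, p, padj).
#' @export
overrepresentationTest <- function(hits, sets, universe) {
  hits <- unique(hits)
  if (!length(hits)) stop("empty hit list")
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  sets <- .filter_sets(sets, universe)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    x <- length(intersect(hits, sets[[nm]]))
    ## P(X >= x) for X ~ Hypergeom(universe, set, draws = hits)
    p <- phyper(x - 1, K, length(universe) - K, length(hits),
                lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = x, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out
}
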
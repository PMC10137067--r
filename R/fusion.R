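## Fused imaging-feature subtyping: per-view affinities, similarity network
## fusion, spectral clustering, consensus model selection and the
## combination-pattern ablation.

#' Fusion hyperparameters
#'
#' @param kNeighbors number of nearest neighbours for the local kernel
#'   scale and the sparse kernel. Default `min(20, floor(n/3))`, chosen at
#'   call time when `n` is known; the common default of 20 is degenerate
#'   for a 30-patient cohort.
#' @param mu kernel bandwidth multiplier in (0, 1].
#' @param tIterations number of message-passing iterations.
#' @return Named list with class `FusionParams`.
#' @export
fusionParams <- function(kNeighbors = NULL, mu = 0.5, tIterations = 20L) {
  if (!is.null(kNeighbors) && (kNeighbors < 1 || kNeighbors != round(kNeighbors)))
    stop("'kNeighbors' must be a positive integer")
  if (mu <= 0 || mu > 1) stop("'mu' must be in (0, 1]")
  if (tIterations < 1) stop("'tIterations' must be >= 1")
  structure(list(kNeighbors = kNeighbors, mu = mu,
                 tIterations = as.integer(tIterations)),
            class = "FusionParams")
}

.resolve_k <- function(params, n) {
  k <- params$kNeighbors
  if (is.null(k)) k <- min(20L, floor(n / 3))
  k <- as.integer(k)
  if (k >= n) stop("kNeighbors must be smaller than the number of patients")
  max(1L, k)
}

#' Scaled-exponential patient affinity matrix for one view
#'
#' Builds the patient-by-patient similarity network for a single view:
#' `W(i,j) = exp(-d(i,j)^2 / (mu * eps_ij))` with the local scale
#' `eps_ij = (mean_{l in kNN(i)} d(i,l) + mean_{l in kNN(j)} d(j,l) +
#' d(i,j)) / 3`, Euclidean distance on the (z-scored) feature columns.
#'
#' @param viewFeatures patients x features numeric matrix with patient-id
#'   rownames.
#' @param params a [fusionParams()] list.
#' @return Symmetric non-negative matrix with patient-id dimnames.
#' @export
affinityMatrix <- function(viewFeatures, params = fusionParams()) {
  n <- nrow(viewFeatures)
  if (n < 3L) stop("need at least 3 patients")
  k <- .resolve_k(params, n)
  D <- as.matrix(dist(viewFeatures))
  ## mean distance to the k nearest neighbours (self excluded)
  knnMean <- vapply(seq_len(n), function(i) {
    dr <- D[i, -i]
    mean(sort(dr)[seq_len(k)])
  }, 0)
  eps <- (outer(knnMean, knnMean, `+`) + D) / 3
  eps[eps <= 0] <- .Machine$double.eps
  W <- exp(-D^2 / (params$mu * eps))
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(D)
  W
}

## full-kernel row normalization: half the mass off-diagonal, half on it;
## rows sum to exactly 1
.snf_normalize <- function(W) {
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

## sparse k-NN kernel, rows normalized over the neighbourhood
.snf_sparse <- function(W, k) {
  n <- nrow(W)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    ord <- order(W[i, -i], decreasing = TRUE)
    nb <- seq_len(n)[-i][ord[seq_len(min(k, n - 1L))]]
    nb <- c(i, nb)
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  S
}

#' Similarity network fusion
#'
#' Iteratively integrates per-view affinity networks by message passing:
#' each view's full kernel is updated through its own sparse k-NN kernel
#' and the average of the other views' status matrices,
#' `P_v <- S_v (sum_{u != v} P_u / (m - 1)) S_v^T`, then renormalized, for
#' `tIterations` rounds. Low-weight edges are suppressed by the sparse
#' kernels while edges supported across views are reinforced. With a single
#' view the normalized input is returned unchanged.
#'
#' @param affinities list of affinity matrices over the same patients (same
#'   dimnames, same order).
#' @param params a [fusionParams()] list.
#' @return A [FusedNetwork-class].
#' @export
snfFuse <- function(affinities, params = fusionParams()) {
  stopifnot(length(affinities) >= 1L)
  ids <- rownames(affinities[[1]])
  for (W in affinities)
    if (!identical(rownames(W), ids) || !identical(colnames(W), ids))
      stop("affinity matrices refer to different patient sets")
  n <- nrow(affinities[[1]])
  k <- .resolve_k(params, n)
  m <- length(affinities)
  P <- lapply(affinities, .snf_normalize)
  if (m == 1L) {
    out <- (P[[1]] + t(P[[1]])) / 2
    out <- out / rowSums(out)
    return(new("FusedNetwork", matrix = out, trace = numeric(0)))
  }
  S <- lapply(affinities, .snf_sparse, k = k)
  trace <- numeric(params$tIterations)
  avgPrev <- Reduce(`+`, P) / m
  for (it in seq_len(params$tIterations)) {
    Pnew <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, P[-v]) / (m - 1)
      Q <- S[[v]] %*% others %*% t(S[[v]])
      Q <- (Q + t(Q)) / 2
      Pnew[[v]] <- .snf_normalize(Q)
    }
    P <- Pnew
    avg <- Reduce(`+`, P) / m
    trace[it] <- sqrt(sum((avg - avgPrev)^2))
    avgPrev <- avg
  }
  out <- Reduce(`+`, P) / m
  out <- (out + t(out)) / 2
  out <- out / rowSums(out)
  dimnames(out) <- list(ids, ids)
  new("FusedNetwork", matrix = out, trace = trace)
}

## symmetrized similarity from a fused network
.sym_similarity <- function(network) {
  P <- fusedMatrix(network)
  (P + t(P)) / 2
}

#' Spectral clustering of a fused network
#'
#' Normalized-Laplacian spectral embedding (the `k` smallest eigenvectors
#' of `L_sym = I - D^{-1/2} W D^{-1/2}`, rows renormalized) followed by
#' seeded k-means with 50 restarts. Deterministic given `seed`. If the
#' network has more connected components than `k`, a warning is issued and
#' patients are labelled by component (the smallest components are merged
#' into the last label).
#'
#' @param network a [FusedNetwork-class] (or a symmetric similarity
#'   matrix).
#' @param k number of clusters, `2 <= k < n`.
#' @param seed integer seed for the k-means restarts.
#' @return A [SubtypeAssignment-class].
#' @export
spectralCluster <- function(network, k, seed = 1L) {
  W <- if (is(network, "FusedNetwork")) .sym_similarity(network)
       else (network + t(network)) / 2
  n <- nrow(W)
  if (k < 2L || k >= n) stop("need 2 <= k < n")
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > k) {
    warning("network has ", comp$no, " components for k = ", k,
            "; labelling by component")
    sizes <- sort(table(comp$membership), decreasing = TRUE)
    big <- as.integer(names(sizes)[seq_len(k - 1L)])
    lab <- match(comp$membership, big)
    lab[is.na(lab)] <- k
    return(subtypeAssignment(setNames(lab, ids), k = k))
  }
  d <- rowSums(W)
  d[d <= 0] <- .Machine$double.eps
  Dh <- 1 / sqrt(d)
  Lsym <- diag(n) - (Dh * W) * rep(Dh, each = n)
  ev <- eigen(Lsym, symmetric = TRUE)
  U <- ev$vectors[, n - seq_len(k) + 1L, drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- withr_seed(seed, kmeans(U, centers = k, nstart = 50, iter.max = 100))
  ## stable label order: clusters numbered by first occurrence, so ties in
  ## k-means restarts cannot permute the labelling
  lab <- as.integer(factor(km$cluster, levels = unique(km$cluster)))
  subtypeAssignment(setNames(lab, ids), k = k)
}

## run an expression with a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Silhouette score on a fused similarity network
#'
#' Converts the symmetrized fused network to a dissimilarity
#' `d(i,j) = 1 - P(i,j) / max_offdiag(P)` and computes the mean silhouette
#' width of the given labels (singleton clusters contribute 0, the standard
#' convention).
#'
#' @param network a [FusedNetwork-class] or symmetric similarity matrix.
#' @param labels a [SubtypeAssignment-class] or integer vector.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouetteFromSimilarity <- function(network, labels) {
  W <- if (is(network, "FusedNetwork")) .sym_similarity(network)
       else (network + t(network)) / 2
  lab <- if (is(labels, "SubtypeAssignment")) subtypeLabels(labels)
         else labels
  if (length(unique(lab)) < 2L)
    stop("silhouette undefined for a single cluster")
  off <- W
  diag(off) <- NA
  mx <- max(off, na.rm = TRUE)
  D <- 1 - W / mx
  diag(D) <- 0
  sil <- cluster::silhouette(as.integer(lab), dmatrix = D)
  mean(sil[, "sil_width"])
}

#' Consensus clustering over subsampled fusion runs for model selection
#'
#' For each of `nReps` repetitions a fraction of patients is subsampled
#' without replacement and the entire pipeline (per-view affinity, fusion,
#' spectral clustering) is re-run for every candidate `k`. The consensus
#' matrix entry (i,j) is the fraction of co-samplings in which i and j were
#' clustered together. The empirical CDF of the upper-triangle entries is
#' summarized by its area and by the proportion of ambiguous clustering
#' (PAC: entries in the (0.1, 0.9) window). `chosenK` minimizes PAC (ties
#' to the smallest k), the quantitative form of the usual
#' consensus-matrix/CDF inspection: for a well-supported k the consensus
#' entries concentrate near 0 and 1, while over-split k leave ambiguous
#' mid-range mass. The delta-area vector (absolute area for the smallest
#' k, relative increase for larger k) is reported as a diagnostic. Pairs
#' never co-sampled are `NA`, flagged, and excluded from the CDF.
#'
#' @param featuresByView named list of patients x features matrices (one
#'   per view, same patients in the same order).
#' @param kRange candidate cluster numbers.
#' @param nReps number of subsample repetitions.
#' @param fraction subsampling fraction.
#' @param params a [fusionParams()] list.
#' @param seed integer seed governing subsampling and clustering restarts.
#' @return A [ConsensusResult-class].
#' @export
consensusSelectK <- function(featuresByView, kRange = 2:5, nReps = 1000L,
                             fraction = 0.8, params = fusionParams(),
                             seed = 1L) {
  n <- nrow(featuresByView[[1]])
  ids <- rownames(featuresByView[[1]])
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ns <- max(2L, floor(fraction * n))
  if (ns < max(kRange) + 2L)
    stop("subsample too small for the largest k")
  if (nReps < 1L) stop("nReps must be >= 1")
  kRange <- sort(unique(as.integer(kRange)))
  co <- matrix(0, n, n)          # co-sample counts
  hit <- lapply(kRange, function(k) matrix(0, n, n))
  names(hit) <- as.character(kRange)
  subsets <- withr_seed(seed, lapply(seq_len(nReps), function(r)
    sort(sample.int(n, ns))))
  for (r in seq_len(nReps)) {
    sub <- subsets[[r]]
    co[sub, sub] <- co[sub, sub] + 1
    aff <- lapply(featuresByView, function(X)
      affinityMatrix(X[sub, , drop = FALSE], params))
    fused <- snfFuse(aff, params)
    for (k in kRange) {
      lab <- subtypeLabels(spectralCluster(fused, k,
                                           seed = seed + 7L * r + k))
      same <- outer(lab, lab, `==`)
      key <- as.character(k)
      hit[[key]][sub, sub] <- hit[[key]][sub, sub] + same
    }
  }
  consensus <- lapply(hit, function(H) {
    M <- H / co
    M[co == 0] <- NA
    diag(M) <- ifelse(diag(co) > 0, 1, NA)
    dimnames(M) <- list(ids, ids)
    M
  })
  lowCoverage <- any(co[upper.tri(co)] == 0)
  grid <- seq(0, 1, length.out = 201L)
  cdfs <- list(); area <- numeric(0); pac <- numeric(0)
  for (key in names(consensus)) {
    v <- consensus[[key]][upper.tri(consensus[[key]])]
    v <- v[!is.na(v)]
    f <- ecdf(v)
    cdfs[[key]] <- f
    area[key] <- mean(f(grid))
    pac[key] <- mean(v > 0.1 & v < 0.9)
  }
  delta <- numeric(length(area))
  names(delta) <- names(area)
  delta[1] <- area[1]
  if (length(area) > 1)
    delta[-1] <- diff(area) / head(area, -1)
  chosen <- as.integer(names(pac)[which.min(pac)])
  if (nReps < 10L)
    warning("low-coverage consensus: only ", nReps, " repetition(s)")
  new("ConsensusResult", consensus = consensus, cdf = cdfs, area = area,
      deltaArea = delta, pac = pac, chosenK = chosen,
      nReps = as.integer(nReps), subsampleFraction = fraction,
      lowCoverage = lowCoverage)
}

#' Anchor two-cluster labels to prognosis
#'
#' Renames the arms of a two-cluster assignment so that label 1 (reported
#' as `FIFS1`) is the better-prognosis arm: the arm with the larger
#' restricted mean survival time. Assignments with `k != 2` are returned
#' unchanged.
#'
#' @param assignment a [SubtypeAssignment-class].
#' @param survivalData data.frame with `patient_id`, `time_days`, `event`.
#' @return A [SubtypeAssignment-class] with prognosis-anchored labels.
#' @export
orientSubtypes <- function(assignment, survivalData) {
  if (assignment@k != 2L) return(assignment)
  lab <- subtypeLabels(assignment)
  sv <- survivalData[match(names(lab), survivalData$patient_id), ]
  fit <- survival::survfit(survival::Surv(sv$time_days, sv$event) ~ lab)
  sm <- summary(fit, rmean = max(sv$time_days))$table
  rmean <- sm[, "rmean"]
  if (rmean[1] < rmean[2]) lab <- 3L - lab
  subtypeAssignment(lab, k = 2L)
}

#' Ablation over view combination patterns
#'
#' Re-runs the full subtyping pipeline on each combination pattern of views
#' (CP1 = all four views, CP2 = tumour arterial + venous, CP3 = venous
#' tumour + peritumour, CP4 = arterial tumour + peritumour), selecting k by
#' consensus, clustering the full cohort, and scoring each pattern by
#' fused-similarity silhouette and by the log-rank p value of the split.
#'
#' @param featuresByView named list of per-view feature matrices (names
#'   `type1..type4`).
#' @param survivalData data.frame with `patient_id`, `time_days`, `event`.
#' @param patterns named list of view subsets; default the four canonical
#'   patterns.
#' @param kRange,nReps,fraction,params,seed passed to [consensusSelectK()].
#' @return data.frame (pattern, chosen_k, silhouette, logrank_p), sorted by
#'   decreasing silhouette.
#' @export
ablateCombinationPatterns <- function(featuresByView, survivalData,
    patterns = list(CP1 = paste0("type", 1:4), CP2 = c("type1", "type2"),
                    CP3 = c("type2", "type4"), CP4 = c("type1", "type3")),
    kRange = 2:5, nReps = 100L, fraction = 0.8, params = fusionParams(),
    seed = 1L) {
  if (!length(patterns)) stop("empty pattern list")
  rows <- lapply(names(patterns), function(pn) {
    vs <- patterns[[pn]]
    if (!length(vs) || !all(vs %in% names(featuresByView)))
      stop("pattern ", pn, " names unknown views")
    fv <- featuresByView[vs]
    cons <- consensusSelectK(fv, kRange = kRange, nReps = nReps,
                             fraction = fraction, params = params,
                             seed = seed)
    fused <- snfFuse(lapply(fv, affinityMatrix, params = params), params)
    lab <- spectralCluster(fused, chosenK(cons), seed = seed)
    sil <- silhouetteFromSimilarity(fused, lab)
    sv <- survivalData[match(names(subtypeLabels(lab)),
                             survivalData$patient_id), ]
    lr <- logrankTest(sv, subtypeLabels(lab))
    data.frame(pattern = pn, chosen_k = chosenK(cons), silhouette = sil,
               logrank_p = lr$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$silhouette), , drop = FALSE]
}
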
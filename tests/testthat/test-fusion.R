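# small helpers shared by the fusion tests
two_block_features <- function(n1 = 8, n2 = 8, gap = 4, p = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * p, gap / 2), n1, p),
             matrix(rnorm(n2 * p, -gap / 2), n2, p))
  rownames(X) <- sprintf("P%02d", seq_len(n1 + n2))
  X
}

test_that("the affinity kernel matches its closed form and contracts", {
  # 3 patients on a line at 0, 1, 10 with k = 1, mu = 0.5
  X <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), "f"))
  prm <- fusionParams(kNeighbors = 1, mu = 0.5)
  W <- affinityMatrix(X, prm)
  knn <- c(1, 1, 9)                       # nearest-neighbour distance each
  epsAB <- (knn[1] + knn[2] + 1) / 3
  expect_equal(W["a", "b"], exp(-1 / (0.5 * epsAB)))
  epsAC <- (knn[1] + knn[3] + 10) / 3
  expect_equal(W["a", "c"], exp(-100 / (0.5 * epsAC)))
  expect_gt(W["a", "b"], W["a", "c"])
  expect_equal(max(abs(W - t(W))), 0)

  # duplicated patients have the maximal off-diagonal affinity in their row
  Xd <- two_block_features(seed = 2)
  Xd[2, ] <- Xd[1, ]
  Wd <- affinityMatrix(Xd, fusionParams(kNeighbors = 3))
  off <- Wd[1, -1]
  expect_equal(unname(which.max(off)), 1L)

  expect_error(affinityMatrix(Xd, fusionParams(kNeighbors = 16)),
               "smaller")
})

test_that("fusion normalizes rows, ignores copies, and is equivariant", {
  X <- two_block_features(seed = 3)
  W <- affinityMatrix(X)
  single <- snfFuse(list(W))
  expect_true(all(abs(rowSums(fusedMatrix(single)) - 1) < 1e-8))

  f2 <- snfFuse(list(W, W))
  f3 <- snfFuse(list(W, W, W))
  expect_equal(fusedMatrix(f2), fusedMatrix(f3), tolerance = 1e-12)
  expect_true(all(abs(rowSums(fusedMatrix(f2)) - 1) < 1e-8))

  # fused network preserves the two-block structure of its inputs
  P <- fusedMatrix(f2)
  blk <- rep(1:2, each = 8)
  within <- mean(P[outer(blk, blk, `==`) & row(P) != col(P)])
  between <- mean(P[outer(blk, blk, `!=`)])
  expect_gt(within, 5 * between)

  # permutation equivariance
  W2 <- affinityMatrix(X + matrix(rnorm(length(X), sd = 0.1), nrow(X)))
  dimnames(W2) <- dimnames(W)
  perm <- sample(nrow(X))
  fP <- fusedMatrix(snfFuse(list(W[perm, perm], W2[perm, perm])))
  f0 <- fusedMatrix(snfFuse(list(W, W2)))
  expect_equal(fP, f0[perm, perm], tolerance = 1e-12)

  Wbad <- W; rownames(Wbad)[1] <- "zz"
  expect_error(snfFuse(list(W, Wbad)), "different patient sets")
})

test_that("spectral clustering recovers exact blocks deterministically", {
  n <- 10
  W <- matrix(0, 2 * n, 2 * n,
              dimnames = list(sprintf("P%02d", 1:(2 * n)),
                              sprintf("P%02d", 1:(2 * n))))
  W[1:n, 1:n] <- 1; W[(n + 1):(2 * n), (n + 1):(2 * n)] <- 1
  lab <- subtypeLabels(spectralCluster(W, 2, seed = 9))
  expect_equal(adj_rand_index(lab, rep(1:2, each = n)), 1)
  lab2 <- subtypeLabels(spectralCluster(W, 2, seed = 9))
  expect_identical(lab, lab2)
})

test_that("fused subtyping recovers planted subtypes across seeds", {
  aris <- vapply(1:5, function(s) {
    coh <- generateCohort(cohortConfig(seed = s))
    fv <- lapply(paste0("type", 1:4), function(v)
      featureValues(subsetViews(cohortFeatures(coh), v)))
    fused <- snfFuse(lapply(fv, affinityMatrix))
    lab <- subtypeLabels(spectralCluster(fused, 2, seed = s))
    adj_rand_index(lab, cohortTruth(coh)$subtype)
  }, 0)
  expect_gte(median(aris), 0.8)
})

test_that("silhouette behaves on exact, random, and singleton labellings", {
  n <- 6
  W <- matrix(0, 2 * n, 2 * n)
  W[1:n, 1:n] <- 1; W[(n + 1):(2 * n), (n + 1):(2 * n)] <- 1
  diag(W) <- 1
  expect_equal(silhouetteFromSimilarity(W, rep(1:2, each = n)), 1)
  expect_error(silhouetteFromSimilarity(W, rep(1L, 2 * n)), "single")

  # structureless similarity with random labels stays near zero
  set.seed(11)
  s <- replicate(10, {
    A <- matrix(runif(144, 0.4, 0.6), 12); A <- (A + t(A)) / 2; diag(A) <- 1
    silhouetteFromSimilarity(A, sample(rep(1:2, 6)))
  })
  expect_lt(max(abs(s)), 0.2)

  # singleton cluster contributes zero, not an error
  sil <- silhouetteFromSimilarity(W, c(2L, rep(1L, n - 1), rep(3L, n)))
  expect_true(is.finite(sil))
})

test_that("consensus selection returns crisp k = 2 on duplicated
           archetypes and flags degenerate settings", {
  arch <- rbind(matrix(rep(c(3, rep(0, 5)), 8), 8, byrow = TRUE),
                matrix(rep(c(-3, rep(0, 5)), 8), 8, byrow = TRUE))
  rownames(arch) <- sprintf("P%02d", 1:16)
  cons <- consensusSelectK(list(v = arch), kRange = 2:3, nReps = 40,
                           seed = 3)
  expect_equal(chosenK(cons), 2L)
  v <- consensusMatrix(cons, 2)
  v <- v[upper.tri(v)]; v <- v[!is.na(v)]
  expect_true(all(v %in% c(0, 1)))
  # consensus matrices are symmetric with unit diagonal where co-sampled
  M <- consensusMatrix(cons, 2)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 1, na.rm = TRUE))

  expect_warning(consensusSelectK(list(v = arch), kRange = 2,
                                  nReps = 1, seed = 1), "low-coverage")
  expect_error(consensusSelectK(list(v = arch[1:5, ]), kRange = 2:4,
                                nReps = 5, fraction = 0.8), "subsample")
})

test_that("two-cluster labels are anchored to prognosis", {
  set.seed(12)
  n <- 40
  lab <- rep(1:2, each = n / 2)
  sv <- data.frame(patient_id = sprintf("P%02d", 1:n),
                   time_days = ceiling(rexp(n, ifelse(lab == 2, 1 / 100,
                                                      1 / 1000))),
                   event = 1L)
  a1 <- subtypeAssignment(setNames(lab, sv$patient_id), 2)
  a2 <- subtypeAssignment(setNames(3L - lab, sv$patient_id), 2)
  o1 <- subtypeLabels(orientSubtypes(a1, sv))
  o2 <- subtypeLabels(orientSubtypes(a2, sv))
  expect_identical(o1, o2)        # invariant to the arbitrary label swap
  # the longer-surviving arm is labelled 1 (reported as FIFS1)
  expect_equal(unique(o1[lab == 1]), 1L)
})

test_that("the view-combination ablation returns one scored row per
           pattern", {
  coh <- generateCohort(cohortConfig(seed = 6))
  fv <- lapply(paste0("type", 1:4), function(v)
    featureValues(subsetViews(cohortFeatures(coh), v)))
  names(fv) <- paste0("type", 1:4)
  tab <- ablateCombinationPatterns(fv, cohortSurvival(coh),
                                   patterns = list(CP2 = c("type1",
                                                           "type2")),
                                   kRange = 2:3, nReps = 20, seed = 2)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$pattern, "CP2")
  expect_true(all(c("chosen_k", "silhouette", "logrank_p") %in%
                    names(tab)))
  expect_error(ablateCombinationPatterns(fv, cohortSurvival(coh),
                                         patterns = list()), "empty")
})
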
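sep_expr <- function(n = 60, p = 40, shift = 2, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n / 2))
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(paste0("g", 1:p), paste0("s", 1:n)))
  X[1:20, y == "B"] <- X[1:20, y == "B"] + shift
  list(X = X, y = y)
}

test_that("candidate genes are the DE / module-membership overlap", {
  de <- data.frame(gene = paste0("g", 1:10),
                   significant = c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_setequal(candidateGenes(de, paste0("g", c(2, 4, 6, 8))),
                  paste0("g", c(2, 4, 6)))
  expect_setequal(candidateGenes(de, paste0("g", 1:10)),
                  paste0("g", 1:6))
  expect_error(candidateGenes(de, paste0("g", 7:10)), "no overlap")
})

test_that("shrunken centroid arithmetic matches hand computation on a
           4-gene toy", {
  # two classes, three samples each; values chosen for clean arithmetic
  X <- rbind(g1 = c(1, 2, 3, 7, 8, 9),
             g2 = c(5, 5, 5, 5, 5, 5) + c(0.1, -0.1, 0, 0.1, -0.1, 0),
             g3 = c(2, 4, 6, 2, 4, 6),
             g4 = c(0, 0, 1, 3, 3, 4))
  colnames(X) <- paste0("s", 1:6)
  y <- factor(rep(c("A", "B"), each = 3))
  model <- suppressWarnings(trainNSC(X, y, thresholds = 0, folds = 3,
                                     seed = 1))
  # hand: overall centroid, class centroids, pooled SD, m_k, d_ik
  xbar <- rowMeans(X)
  centA <- rowMeans(X[, 1:3]); centB <- rowMeans(X[, 4:6])
  si <- sqrt((rowSums((X[, 1:3] - centA)^2) +
                rowSums((X[, 4:6] - centB)^2)) / (6 - 2))
  s0 <- median(si)
  mk <- sqrt(1 / 3 - 1 / 6)
  dA <- (centA - xbar) / (mk * (si + s0))
  # at Delta = 0 the shrunken centroids equal the raw class centroids
  expect_equal(model@centroids[, "A"], centA, tolerance = 1e-12)
  expect_equal(model@centroids[, "B"], centB, tolerance = 1e-12)
  expect_equal(model@sdPooled, si, tolerance = 1e-12)
  expect_equal(model@s0, s0, tolerance = 1e-12)
  # re-derive d_ik and verify the reconstruction identity
  expect_equal(xbar + mk * (si + s0) * dA, centA, tolerance = 1e-12)
})

test_that("full shrinkage collapses centroids and priors drive
           prediction", {
  fx <- sep_expr()
  st <- radfusion:::.nsc_stats(fx$X, fx$y)
  big <- max(abs(st$dik)) + 1
  model <- trainNSC(fx$X, fx$y, thresholds = c(0, big), folds = 5,
                    seed = 2)
  sh <- radfusion:::.nsc_shrink(st, big)
  expect_true(all(abs(sh$cent[, 1] - st$xbar) < 1e-12))
  expect_true(all(abs(sh$cent[, 2] - st$xbar) < 1e-12))
  # active genes are monotone non-increasing along the threshold grid
  m2 <- trainNSC(fx$X, fx$y, folds = 5, seed = 2)
  expect_true(all(diff(m2@cvProfile$n_active) <= 0))
  # a separable design reaches zero CV error at some threshold
  expect_equal(min(m2@cvProfile$cv_error), 0)
})

test_that("prediction is deterministic, centroid-faithful, and imputes
           missing genes", {
  fx <- sep_expr(seed = 3)
  model <- trainNSC(fx$X, fx$y, folds = 5, seed = 3)
  pr <- predictNSC(model, fx$X)
  expect_lte(mean(pr$labels != as.character(fx$y)),
             min(model@cvProfile$cv_error) + 0.1)

  # a sample placed exactly at a shrunken centroid is assigned its class
  probe <- matrix(model@centroids[, "A"],
                  dimnames = list(model@genes, "probe"))
  expect_equal(unname(predictNSC(model, probe)$labels), "A")

  expect_warning(pr2 <- predictNSC(model, fx$X[-1, ]), "imputed")
  expect_equal(pr2$labels, pr$labels)

  # equidistant sample with equal priors ties to the first class
  st <- radfusion:::.nsc_stats(fx$X, fx$y)
  mid <- (model@centroids[, "A"] + model@centroids[, "B"]) / 2
  eq <- model
  eq@priors <- c(A = 0.5, B = 0.5)
  tie <- predictNSC(eq, matrix(mid, dimnames = list(model@genes, "m")))
  expect_equal(unname(tie$labels), "A")
})

test_that("external validation anchors labels to prognosis and scores
           immune sets", {
  coh <- generateCohort(cohortConfig(nPatients = 80, seed = 44))
  tr <- cohortTruth(coh)
  predicted <- setNames(paste0("FIFS", tr$subtype), names(tr$subtype))
  expr <- log2(normalizeCounts(cohortCounts(coh)) + 1)
  immune <- names(tr$geneModule)[tr$geneModule == "immune"][1:40]
  other <- names(tr$geneModule)[tr$geneModule == "grey"][1:40]
  rep_ <- validateExternal(predicted, cohortSurvival(coh),
                           list(immune = immune, background = other),
                           expr)
  expect_lt(rep_$logrank$p, 0.05)
  lab <- rep_$labels
  # planted immune activity is higher in the better-prognosis arm (FIFS1)
  zImm <- rep_$scoreMatrix["immune", ]
  expect_gt(mean(zImm[lab == "FIFS1"]), mean(zImm[lab == "FIFS2"]))
  # degenerate one-class prediction falls back to description
  expect_warning(one <- validateExternal(
    setNames(rep("FIFS1", 80), names(predicted)), cohortSurvival(coh),
    list(immune = immune), expr), "one predicted class")
  expect_null(one$logrank)
})
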
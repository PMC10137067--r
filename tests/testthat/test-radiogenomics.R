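# shared fixture: planted cohort with fused subtypes
prf_fixture <- function(seed = 9) {
  coh <- generateCohort(cohortConfig(seed = seed))
  fv <- lapply(paste0("type", 1:4), function(v)
    featureValues(subsetViews(cohortFeatures(coh), v)))
  fused <- snfFuse(lapply(fv, affinityMatrix))
  lab <- orientSubtypes(spectralCluster(fused, 2, seed = seed),
                        cohortSurvival(coh))
  list(coh = coh, lab = lab)
}

test_that("the PRF cascade keeps planted features and is order-stable", {
  fx <- prf_fixture()
  prf <- identifyPRFs(cohortFeatures(fx$coh), fx$lab,
                      cohortSurvival(fx$coh))
  expect_gt(nrow(prf), 0)
  expect_true(all(prf$diff_p < 0.05 & prf$cox_p < 0.05))
  expect_true(all(prf$higher_subtype %in% c("FIFS1", "FIFS2")))
  # annotations follow the view map: type2 = venous tumour etc.
  t2 <- prf[prf$view == "type2", ]
  if (nrow(t2)) {
    expect_true(all(t2$phase == "venous"))
    expect_true(all(t2$region == "tumor"))
  }
  # a planted feature with a 1.5 SD shift is mostly recovered
  planted <- cohortTruth(fx$coh)$affectedFeatures
  plantedKeys <- paste(planted$view, planted$class, planted$feature,
                       sep = "|")
  expect_gt(mean(plantedKeys %in% prf$feature_key), 0.15)
  # and the retained set is dominated by planted columns
  expect_gt(mean(prf$feature_key %in% plantedKeys), 0.5)

  # shuffling feature column order never changes the retained PRF set
  ftab <- cohortFeatures(fx$coh)
  set.seed(2)
  perm <- sample(400)
  reordered <- multiViewFeatureTable(featureValues(ftab)[, perm],
                                     featureInfo(ftab)[perm, ],
                                     standardized = TRUE)
  prf2 <- identifyPRFs(reordered, fx$lab, cohortSurvival(fx$coh))
  expect_setequal(prf2$feature_key, prf$feature_key)
})

test_that("stage-2 of the cascade is calibrated under permuted survival", {
  rates <- vapply(1:5, function(s) {
    fx <- prf_fixture(seed = 30 + s)
    sv <- cohortSurvival(fx$coh)
    set.seed(s)
    svPerm <- sv
    perm <- sample(nrow(sv))
    svPerm$time_days <- sv$time_days[perm]
    svPerm$event <- sv$event[perm]
    prf <- identifyPRFs(cohortFeatures(fx$coh), fx$lab, svPerm)
    casc <- attr(prf, "cascade")
    nrow(prf) / sum(casc$stage1)
  }, 0)
  expect_lt(mean(rates), 0.12)
})

test_that("module filtering demands subtype link, prognosis, and a PRF
           correlate", {
  fx <- prf_fixture(seed = 12)
  sv <- cohortSurvival(fx$coh)
  ftab <- cohortFeatures(fx$coh)
  prf <- identifyPRFs(ftab, fx$lab, sv)
  ids <- patientIds(ftab)

  # module built as a copy of a prognostic, subtype-linked PRF passes all
  prfVal <- featureValues(ftab)[, prf$feature_key[1]]
  set.seed(1)
  noiseEig <- rnorm(length(ids))
  eg <- rbind(copy = prfVal, noise = noiseEig)
  colnames(eg) <- ids
  flags <- filterPrfModules(eg, fx$lab, sv, prf, ftab)
  expect_true(flags$kept[flags$module == "copy"])
  expect_false(flags$kept[flags$module == "noise"])

  # orthogonalizing against every PRF removes criterion (c); use a small
  # PRF table so the projection leaves residual variance (with more PRFs
  # than patients any vector lies in their span)
  prf5 <- prf[seq_len(min(5, nrow(prf))), , drop = FALSE]
  P <- featureValues(ftab)[, prf5$feature_key, drop = FALSE]
  mixed <- prfVal + rnorm(length(prfVal))
  resid <- residuals(lm(mixed ~ P))
  eg2 <- rbind(orth = as.numeric(resid))
  colnames(eg2) <- ids
  flags2 <- filterPrfModules(eg2, fx$lab, sv, prf5, ftab)
  expect_false(flags2$pass_prf[1])
  expect_error(filterPrfModules(eg2[0, , drop = FALSE], fx$lab, sv, prf5,
                                ftab), "empty")
})

test_that("pathway-feature pairs apply one BH pass over the full grid", {
  set.seed(8)
  n <- 30
  prfVals <- matrix(rnorm(n * 3), n,
                    dimnames = list(NULL, paste0("f", 1:3)))
  scores <- rbind(copy = prfVals[, 1] * 2 + 1,
                  noise = rnorm(n))
  colnames(scores) <- paste0("s", 1:n)
  pairs <- pathwayFeaturePairs(scores, prfVals)
  hit <- pairs[pairs$pathway == "copy" & pairs$prf == "f1", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$r, 1, tolerance = 1e-12)

  # single pathway x single feature: adjusted p equals raw p
  one <- pathwayFeaturePairs(scores["copy", , drop = FALSE],
                             prfVals[, 1, drop = FALSE])
  all1 <- attr(one, "allPairs")
  expect_equal(all1$q, all1$p)

  # constant score vectors are skipped with a warning
  expect_warning(pathwayFeaturePairs(rbind(flat = rep(1, n),
                                           copy = prfVals[, 1]),
                                     prfVals), "constant")

  # independent noise: BH keeps the retained fraction near zero
  retained <- vapply(1:5, function(s) {
    set.seed(40 + s)
    S <- matrix(rnorm(40 * n), 40, n,
                dimnames = list(paste0("p", 1:40), NULL))
    X <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
    nrow(pathwayFeaturePairs(S, X)) / 400
  }, 0)
  expect_lte(mean(retained), 0.05 + 2 * sqrt(0.05 * 0.95 / (5 * 400)))
})

test_that("the association network truncates per PRF and round-trips", {
  pairs <- data.frame(
    module = "M1",
    pathway = paste0("pw", 1:7),
    prf = "f1",
    r = seq(0.9, 0.3, length.out = 7),
    p = rep(1e-4, 7), q = rep(1e-3, 7), stringsAsFactors = FALSE)
  g <- buildAssociationNetwork(pairs, topN = 5)
  expect_equal(igraph::ecount(g), 5L)
  gAll <- buildAssociationNetwork(pairs, topN = Inf)
  expect_equal(igraph::ecount(gAll), 7L)
  # bipartite: PRF nodes vs pathway nodes
  expect_equal(sum(!igraph::V(g)$type), 1L)

  tmp <- tempfile(fileext = ".graphml")
  igraph::write_graph(g, tmp, format = "graphml")
  g2 <- igraph::read_graph(tmp, format = "graphml")
  e1 <- apply(igraph::as_edgelist(g), 1, paste, collapse = "~")
  e2 <- apply(igraph::as_edgelist(g2), 1, paste, collapse = "~")
  expect_setequal(e1, e2)
  unlink(tmp)
})

test_that("the top PRF-related gene is found by correlation", {
  set.seed(14)
  n <- 30
  prfVals <- matrix(rnorm(n), n, dimnames = list(NULL, "f1"))
  expr <- rbind(gHit = prfVals[, 1],
                gA = rnorm(n), gB = rnorm(n))
  colnames(expr) <- paste0("s", 1:n)
  pairs <- data.frame(module = "M1", pathway = "pw1", prf = "f1",
                      r = 0.9, p = 1e-5, q = 1e-4,
                      stringsAsFactors = FALSE)
  sets <- list(pw1 = c("gHit", "gA", "gB"))
  tab <- prfRelatedGenes(expr, pairs, prfVals, sets)
  expect_equal(tab$gene, "gHit")
  expect_equal(tab$r, 1, tolerance = 1e-12)
  expect_true(all(c("gene", "prf", "pathway", "module", "r", "p") %in%
                    names(tab)))
  expect_warning(prfRelatedGenes(expr, transform(pairs, pathway = "pwX"),
                                 prfVals, sets), "no measured gene")
})
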
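## End-to-end orchestration: synthetic cohort (or user tables) -> fused
## subtyping -> PRF cascade -> DE / co-expression modules -> association
## network -> classifier. Each stage draws its seed from the global seed
## plus a fixed stage offset so that stage RNG streams never overlap.

.STAGE_OFFSETS <- c(synth = 1000L, fifs = 2000L, prf = 3000L, de = 4000L,
                    modules = 5000L, assoc = 6000L, classify = 7000L)

#' Pipeline configuration
#'
#' Collects every stage parameter with the registry defaults: 10 mm
#' peritumoral radius, bin width 25, 1000 consensus repetitions at 80%
#' subsampling, signed network power 8 with minimum module size 30, DE
#' thresholds |log2FC| > 1 at adjusted p < 0.05, and 10 CV folds. Unknown
#' arguments are rejected.
#'
#' @param seed global seed fanned out to the stages.
#' @param cohort a [cohortConfig()] describing the synthetic cohort, or a
#'   ready [SyntheticCohort-class].
#' @param kRange,nReps,fraction consensus-clustering settings.
#' @param fusion a [fusionParams()] list.
#' @param coexpression a [coexpressionParams()] list.
#' @param lfcThreshold,alpha DE thresholds.
#' @param folds classifier CV folds.
#' @param topN association-network edges per PRF.
#' @param nVariableGenes gene pre-filter for the network stage.
#' @return Named list with class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, cohort = cohortConfig(seed = seed),
                           kRange = 2:5, nReps = 1000L, fraction = 0.8,
                           fusion = fusionParams(),
                           coexpression = coexpressionParams(),
                           lfcThreshold = 1, alpha = 0.05, folds = 10L,
                           topN = 5, nVariableGenes = 5000L) {
  if (fraction <= 0 || fraction > 1)
    stop("invalid config: 'fraction' must be in (0, 1]")
  if (nReps < 1L) stop("invalid config: 'nReps' must be >= 1")
  structure(list(seed = as.integer(seed), cohort = cohort, kRange = kRange,
                 nReps = as.integer(nReps), fraction = fraction,
                 fusion = fusion, coexpression = coexpression,
                 lfcThreshold = lfcThreshold, alpha = alpha,
                 folds = as.integer(folds), topN = topN,
                 nVariableGenes = as.integer(nVariableGenes)),
            class = "PipelineConfig")
}

.stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  cat(format(Sys.time(), "%H:%M:%S"), " stage ", name, " done\n",
      sep = "", file = log, append = TRUE)
  res
}

#' Run the full radiogenomics pipeline
#'
#' Executes cohort generation (or intake), fused subtyping with consensus
#' model selection, the PRF cascade, differential expression,
#' co-expression modules with the PRF-related filter, the pathway-feature
#' association network with its top genes, and the expression classifier.
#' Stage outputs are written as CSV under `outDir` together with a
#' manifest (parameter hash, seeds, session info) and a log. Reruns with
#' the same config are identical for all deterministic stages.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory (created if missing); `NULL` keeps
#'   everything in memory only.
#' @return Invisible list with every stage result.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  sd_ <- config$seed + .STAGE_OFFSETS
  log <- if (is.null(outDir)) nullfile() else {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    file.path(outDir, "run.log")
  }

  cohort <- .stage("synth", log, {
    if (is(config$cohort, "SyntheticCohort")) config$cohort
    else generateCohort(config$cohort)
  })
  feats <- cohortFeatures(cohort)
  sv <- cohortSurvival(cohort)

  fifs <- .stage("fifs", log, {
    byView <- lapply(paste0("type", 1:4), function(v)
      featureValues(subsetViews(feats, v)))
    names(byView) <- paste0("type", 1:4)
    cons <- consensusSelectK(byView, kRange = config$kRange,
                             nReps = config$nReps,
                             fraction = config$fraction,
                             params = config$fusion, seed = sd_["fifs"])
    fused <- snfFuse(lapply(byView, affinityMatrix,
                            params = config$fusion), config$fusion)
    lab <- spectralCluster(fused, chosenK(cons), seed = sd_["fifs"])
    if (chosenK(cons) == 2L) lab <- orientSubtypes(lab, sv)
    list(consensus = cons, fused = fused, subtypes = lab,
         silhouette = silhouetteFromSimilarity(fused, lab),
         logrank = logrankTest(sv[match(names(subtypeLabels(lab)),
                                        sv$patient_id), ],
                               subtypeLabels(lab)))
  })
  subtypes <- fifs$subtypes

  prf <- .stage("prf", log, identifyPRFs(feats, subtypes, sv))

  de <- .stage("de", log, differentialExpression(
    cohortCounts(cohort), subtypeNames(subtypes),
    lfcThreshold = config$lfcThreshold, alpha = config$alpha))

  mods <- .stage("modules", log, {
    norm <- normalizeCounts(cohortCounts(cohort))
    lx <- log2(norm + 1)
    lx <- filterVariableGenes(lx, config$nVariableGenes)
    lx <- lx[apply(lx, 1, sd) > 0, , drop = FALSE]
    A <- signedAdjacency(lx, config$coexpression)
    modules <- detectModules(tomSimilarity(A), config$coexpression)
    eg <- moduleEigengenes(lx, modules)
    list(expr = lx, modules = modules, eigengenes = eg$eigengenes,
         varExplained = eg$varExplained)
  })

  assoc <- .stage("assoc", log, {
    kept <- filterPrfModules(mods$eigengenes, subtypes, sv, prf,
                             feats, alpha = config$alpha)
    prfMods <- kept$module[kept$kept]
    if (!length(prfMods) || !nrow(prf))
      return(list(moduleFilter = kept, pairs = NULL, network = NULL,
                  genes = NULL))
    sets <- lapply(prfMods, function(m)
      names(mods$modules)[mods$modules == m])
    names(sets) <- prfMods
    scores <- ssgseaScores(mods$expr, sets)
    prfVals <- featureValues(feats)[, prf$feature_key, drop = FALSE]
    pairs <- pathwayFeaturePairs(scores, prfVals, fdr = config$alpha,
                                 pathwayModules = setNames(prfMods,
                                                           prfMods))
    net <- if (nrow(pairs)) buildAssociationNetwork(pairs, config$topN,
      prfSubtypes = setNames(prf$higher_subtype, prf$feature_key))
      else NULL
    genes <- if (nrow(pairs)) prfRelatedGenes(mods$expr, pairs, prfVals,
                                              sets) else NULL
    list(moduleFilter = kept, pairs = pairs, network = net, genes = genes)
  })

  classifier <- .stage("classify", log, {
    kept <- assoc$moduleFilter
    prfMods <- kept$module[kept$kept]
    modGenes <- names(mods$modules)[mods$modules %in% prfMods]
    if (!length(modGenes) || !any(de$significant)) NULL
    else {
      cand <- candidateGenes(de, modGenes)
      trainNSC(mods$expr[cand, , drop = FALSE], subtypeNames(subtypes),
               folds = config$folds, seed = sd_["classify"])
    }
  })

  result <- list(cohort = cohort, fifs = fifs, prf = prf, de = de,
                 modules = mods, assoc = assoc, classifier = classifier)
  if (!is.null(outDir)) .write_pipeline_outputs(result, config, outDir)
  invisible(result)
}

.write_pipeline_outputs <- function(result, config, outDir) {
  lab <- result$fifs$subtypes
  write.csv(data.frame(patient_id = names(subtypeLabels(lab)),
                       subtype = as.character(subtypeNames(lab))),
            file.path(outDir, "subtypes.csv"), row.names = FALSE)
  write.csv(result$prf, file.path(outDir, "prf_table.csv"),
            row.names = FALSE)
  write.csv(result$de, file.path(outDir, "differential_expression.csv"),
            row.names = FALSE)
  write.csv(data.frame(gene = names(result$modules$modules),
                       module = result$modules$modules),
            file.path(outDir, "modules.csv"), row.names = FALSE)
  if (!is.null(result$assoc$pairs))
    write.csv(result$assoc$pairs,
              file.path(outDir, "pathway_feature_pairs.csv"),
              row.names = FALSE)
  if (!is.null(result$assoc$genes))
    write.csv(result$assoc$genes,
              file.path(outDir, "prf_related_genes.csv"),
              row.names = FALSE)
  if (!is.null(result$assoc$network))
    igraph::write_graph(result$assoc$network,
                        file.path(outDir, "association_network.graphml"),
                        format = "graphml")
  cfgJson <- jsonlite::toJSON(config[setdiff(names(config), "cohort")],
                              auto_unbox = TRUE, force = TRUE, digits = NA)
  cfgPath <- file.path(outDir, "config.json")
  writeLines(cfgJson, cfgPath)
  manifest <- list(
    package_version = as.character(utils::packageVersion("radfusion")),
    r_version = R.version.string,
    seed = config$seed,
    stage_seeds = as.list(config$seed + .STAGE_OFFSETS),
    config_md5 = unname(tools::md5sum(cfgPath)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(outDir, "manifest.json"))
  invisible(outDir)
}
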
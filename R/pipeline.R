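#' Simulate a full biomarker study
#'
#' One call producing every input of the analysis pipeline: a clinical
#' cohort, latent cell populations, a planted-effect specification on
#' causal features chosen from the realizable feature space, paired
#' pre/post immunome matrices, and per-patient variant summaries.
#'
#' @param nPatients cohort size.
#' @param nCausal number of causal marker-combination features.
#' @param effectSize Cohen's-d-scale latent shift per causal feature.
#' @param seed integer run seed; all stages derive their streams from it.
#' @param panel a [PanelDefinition][PanelDefinition-class].
#' @param profile a [cohortProfile()]; defaults to the standard profile
#'   with `nPatients` patients.
#' @param populationsPerTube,concentration,noiseSd,lod,dropoutRate
#'   passed to [generateImmunome()].
#' @param direction per-causal-feature association sign(s) with MPR;
#'   default alternates +1/-1.
#' @param postShift per-causal-feature post-treatment shift.
#' @param detectionBand expected-detection band from which causal
#'   features are picked (see [pickCausalFeatures()]).
#' @return A list: `cohort`, `panel`, `effects`, `pre`, `post`,
#'   `populations`, `variants`.
#' @export
simulateStudy <- function(nPatients = 300, nCausal = 5, effectSize = 1.0,
                          seed = 1, panel = examplePanel(nTubes = 6),
                          profile = NULL, populationsPerTube = 80,
                          concentration = 50, noiseSd = 0.15, lod = 0.1,
                          dropoutRate = 0.02, direction = NULL,
                          postShift = 0,
                          detectionBand = c(0.65, 0.84)) {
  if (is.null(profile)) profile <- cohortProfile(nPatients = nPatients)
  cohort <- generateCohort(profile, seed)
  populations <- makePopulations(panel, populationsPerTube, seed = seed)
  effects <- if (nCausal > 0) {
    causal <- pickCausalFeatures(populations, panel, nCausal,
                                 detectionBand = detectionBand,
                                 concentration = concentration, lod = lod)
    if (is.null(direction)) direction <- rep_len(c(1, -1), nCausal)
    effectSpec(causal, direction = direction, effectSize = effectSize,
               postShift = postShift)
  } else effectSpec(character(0))
  imm <- generateImmunome(cohort, panel, effects, seed = seed,
                          populations = populations,
                          concentration = concentration, noiseSd = noiseSd,
                          lod = lod, dropoutRate = dropoutRate)
  variants <- generateMutationData(cohort, seed)
  list(cohort = cohort, panel = panel, effects = effects,
       pre = imm$pre, post = imm$post, populations = populations,
       variants = variants)
}

#' Split samples into training, test set 1 and test set 2
#'
#' Test set 2 holds the samples without an MPR assessment (no resection,
#' e.g. radiographical progression); the remaining MPR-evaluable samples
#' are split into training and test set 1, stratified by MPR status. The
#' three sets are pairwise disjoint.
#'
#' @param cohort cohort data.frame.
#' @param trainFraction fraction of evaluable samples assigned to
#'   training.
#' @param seed integer seed.
#' @return A list of patient-id vectors `train`, `test1`, `test2`.
#' @export
makeSplit <- function(cohort, trainFraction = 0.5, seed = 1) {
  set.seed(deriveSeed(seed, "split"))
  evaluable <- !is.na(cohort$viable_percent) & !cohort$egfr_alk_positive
  test2 <- cohort$patient_id[cohort$resection == "none"]
  resp <- classifyResponse(cohort$viable_percent[evaluable],
                           cohort$resection[evaluable],
                           cohort$surgery[evaluable])
  ids <- cohort$patient_id[evaluable]
  train <- character(0)
  for (cl in unique(resp$mpr)) {
    grp <- sample(ids[resp$mpr == cl])
    train <- c(train, grp[seq_len(round(length(grp) * trainFraction))])
  }
  list(train = sort(train), test1 = sort(setdiff(ids, train)),
       test2 = sort(test2))
}

.subsetByPatients <- function(x, patients) {
  x[, colData(x)$patient_id %in% patients]
}

#' Pipeline configuration
#'
#' @param outputDir run directory (created if absent).
#' @param seed global integer seed; every stage derives its stream from
#'   it.
#' @param simulate list of arguments for [simulateStudy()] (used when no
#'   input paths are given).
#' @param paths optional named list of input files (`cohort`,
#'   `abundancePre`, `abundancePost`, `variants`, `panel`); any file
#'   given replaces the corresponding simulated input.
#' @param trainFraction passed to [makeSplit()].
#' @param detectionMinFraction detection filter threshold.
#' @param prevalenceThreshold prevalence split threshold.
#' @param normalization immunome normalization for divergence scoring.
#' @param selection a [selectionConfig()].
#' @param model a [modelConfig()].
#' @param design list `p0`, `p1`, `alpha`, `n` for [designPower()].
#' @param landmarkMonths survival landmark (months).
#' @param ciMethod confidence-interval method for rates.
#' @return A list of class `RunConfig`.
#' @export
pipelineConfig <- function(outputDir = tempfile("immunomprRun"), seed = 1,
                           simulate = list(), paths = list(),
                           trainFraction = 0.5,
                           detectionMinFraction = 0.5,
                           prevalenceThreshold = 0.85,
                           normalization = "rank",
                           selection = selectionConfig(seed = seed),
                           model = modelConfig(seed = seed),
                           design = list(p0 = 0.05, p1 = 0.15,
                                         alpha = 0.05, n = 180),
                           landmarkMonths = 36, ciMethod = "clopper_pearson") {
  cfg <- list(outputDir = outputDir, seed = as.integer(seed),
              simulate = simulate, paths = paths,
              trainFraction = trainFraction,
              detectionMinFraction = detectionMinFraction,
              prevalenceThreshold = prevalenceThreshold,
              normalization = normalization, selection = selection,
              model = model, design = design,
              landmarkMonths = landmarkMonths, ciMethod = ciMethod)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; the
#' `selection` and `model` mappings are passed to [selectionConfig()] and
#' [modelConfig()].
#'
#' @param path YAML file.
#' @return A `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipelineConfig)))]
  if (!is.null(y$selection))
    args$selection <- do.call(selectionConfig, y$selection)
  if (!is.null(y$model)) args$model <- do.call(modelConfig, y$model)
  do.call(pipelineConfig, args)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> feature-space construction ->
#' extreme-cohort selection -> divergence subsampling ranking ->
#' candidate filtering -> penalized additive model fit -> prediction on
#' the held-out sets -> endpoint report, writing all results and a
#' manifest into the run directory. Re-running with the same
#' configuration and seed reproduces every output byte for byte.
#'
#' @param config a [pipelineConfig()] (or the path of a YAML file for
#'   [readRunConfig()]).
#' @return Invisibly, a list with the main in-memory results (`cohort`,
#'   `selection`, `model`, `predictions`, `endpoints`, `manifest`).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outputDir, ...)
  stage <- "setup"
  manifest <- list(package = "immunoMPR",
                   version = as.character(utils::packageVersion("immunoMPR")),
                   seed = config$seed)
  tryCatch({
    stage <- "simulate"
    if (!is.null(config$paths$cohort)) {
      cohort <- readCohort(config$paths$cohort)
      panel <- if (!is.null(config$paths$panel)) readPanel(config$paths$panel)
               else NULL
      pre <- readAbundance(config$paths$abundancePre, panel)
      post <- if (!is.null(config$paths$abundancePost))
        readAbundance(config$paths$abundancePost, panel) else NULL
      variants <- if (!is.null(config$paths$variants))
        readVariants(config$paths$variants) else NULL
    } else {
      sim <- do.call(simulateStudy,
                     c(config$simulate, list(seed = config$seed)))
      cohort <- sim$cohort; panel <- sim$panel
      pre <- sim$pre; post <- sim$post; variants <- sim$variants
      manifest$causalFeatures <- sim$effects@features
    }
    writeCohort(cohort, out("cohort.csv"))
    writeAbundance(pre, out("abundance_pre.csv"))
    if (!is.null(post)) writeAbundance(post, out("abundance_post.csv"))
    if (!is.null(variants)) writeVariants(variants, out("variants.csv"))
    if (!is.null(panel)) writePanel(panel, out("panel.yaml"))

    stage <- "split"
    split <- makeSplit(cohort, config$trainFraction, config$seed)
    manifest$split <- lapply(split, length)

    stage <- "features"
    train <- .subsetByPatients(pre, split$train)
    fs <- if (!is.null(panel))
      buildFeatureSpace(train, panel, config$detectionMinFraction)
    else {
      obs <- observedPhenotypes(train)
      list(experiment = filterByDetection(train[obs, ],
                                          config$detectionMinFraction),
           stageCounts = c(observed = length(obs)))
    }
    trainF <- fs$experiment

    stage <- "select"
    resp <- cohort[match(split$train, cohort$patient_id), ]
    selCfg <- config$selection
    selCfg$seed <- deriveSeed(config$seed, "selection")
    extremes <- selectExtremeCohorts(resp, trainF, selCfg)
    extremeIds <- c(extremes$regression, extremes$progression)
    xExt <- normalizeImmunome(
      .subsetByPatients(trainF, extremeIds), config$normalization)
    armLabels <- ifelse(colData(xExt)$patient_id %in% extremes$regression,
                        "regression", "progression")
    selection <- subsampleRank(xExt, armLabels, selCfg, fs$stageCounts)
    writeSelectionResult(selection, out("selection.csv"))
    retained <- retainedFeatures(selection)

    stage <- "fit"
    respAll <- classifyResponse(cohort$viable_percent, cohort$resection,
                                cohort$surgery)
    mprOf <- function(ids) {
      respAll$mpr[match(ids, cohort$patient_id)]
    }
    trainR <- trainF[retained, ]
    yTrain <- mprOf(colData(trainR)$patient_id)
    prevSplit <- splitByPrevalence(trainR, config$prevalenceThreshold)
    mdlCfg <- config$model
    mdlCfg$seed <- deriveSeed(config$seed, "model")
    cand <- filterCandidates(prevSplit, trainR, yTrain, mdlCfg)
    utils::write.csv(cand, out("candidates.csv"), row.names = FALSE)
    model <- fitGamLasso(cand, trainR, yTrain, mdlCfg)
    writeModel(model, out("model.json"))

    stage <- "predict"
    predFor <- function(ids) {
      if (!length(ids)) return(NULL)
      predictProbability(model, .subsetByPatients(pre, ids))
    }
    pTrain <- predFor(split$train)
    pTest1 <- predFor(split$test1)
    pTest2 <- predFor(split$test2)
    preds <- data.frame(
      sample_id = c(names(pTrain), names(pTest1), names(pTest2)),
      set = rep(c("train", "test1", "test2"),
                c(length(pTrain), length(pTest1), length(pTest2))),
      probability = c(pTrain, pTest1, pTest2), stringsAsFactors = FALSE)
    preds$patient_id <- colData(pre)$patient_id[match(preds$sample_id,
                                                      colnames(pre))]
    .writeCsv(preds, out("predictions.csv"))
    patOf <- function(p) colData(pre)$patient_id[match(names(p),
                                                       colnames(pre))]
    rocTrain <- rocAuc(pTrain, mprOf(patOf(pTrain)))
    rocTest1 <- if (length(pTest1))
      rocAuc(pTest1, mprOf(patOf(pTest1))) else NULL
    .writeCsv(rocTrain$curve, out("roc_train.csv"))
    if (!is.null(rocTest1)) .writeCsv(rocTest1$curve, out("roc_test1.csv"))
    # no ROC for test set 2: those samples have no MPR assessment
    manifest$auc <- list(apparent = model@apparentAuc,
                         crossValidated = model@cvAuc,
                         test1 = if (is.null(rocTest1)) NULL else rocTest1$auc)

    stage <- "endpoints"
    endpoints <- .endpointReport(cohort, variants, preds, config)
    jsonlite::write_json(endpoints, out("endpoints.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    manifest$stageCounts <- c(fs$stageCounts,
                              scored = nrow(importanceTable(selection)),
                              retained = length(retained),
                              candidates = sum(cand$candidate),
                              selected = length(selectedFeatures(model)))
    manifest$config <- .configEcho(config)
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(cohort = cohort, split = split, selection = selection,
                   model = model, predictions = preds,
                   endpoints = endpoints, manifest = manifest))
  }, error = function(e) {
    writeLines(sprintf("pipeline failed at stage '%s': %s", stage,
                       conditionMessage(e)),
               out("FAILED.log"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

.configEcho <- function(config) {
  ech <- config
  ech$selection <- unclass(ech$selection)
  ech$model <- unclass(ech$model)
  ech$outputDir <- NULL  # keep manifests byte-identical across run dirs
  if (is(ech$simulate$panel, "PanelDefinition"))
    ech$simulate$panel <- list(tubes = ech$simulate$panel@tubes,
                               exclusionRules = lapply(
                                 ech$simulate$panel@exclusionRules, as.list))
  if (is(ech$simulate$profile, "CohortProfile"))
    ech$simulate$profile <- list(nPatients = ech$simulate$profile@nPatients)
  unclass(ech)
}

# Endpoint report: rates with CI, exact tests on TPS and TMB subgroup
# tables, response correlation, Kaplan-Meier landmarks with log-rank by
# MPR, design power, and predicted-probability group comparisons.
.endpointReport <- function(cohort, variants, preds, config) {
  resp <- classifyResponse(cohort$viable_percent, cohort$resection,
                           cohort$surgery)
  evaluable <- !is.na(resp$mpr) & !cohort$egfr_alk_positive
  nEval <- sum(evaluable)
  mpr <- resp$mpr & evaluable
  pcr <- resp$category == "pCR" & evaluable
  rep <- list(
    n = nrow(cohort), nEvaluable = nEval,
    mprRate = responseRateCI(sum(mpr), nEval, config$ciMethod),
    pcrRate = responseRateCI(sum(pcr), nEval, config$ciMethod))

  tpsLevels <- c("<1%", "1-49%", ">=50%")
  tpsKnown <- evaluable & cohort$tps_group %in% tpsLevels
  if (sum(tpsKnown) >= 6) {
    tab <- table(factor(cohort$tps_group[tpsKnown], tpsLevels),
                 factor(mpr[tpsKnown], c(TRUE, FALSE)))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      rep$tpsFisher <- list(table = as.data.frame.matrix(tab),
                            p = fisherExact(tab))
    mids <- c(`<1%` = 0.5, `1-49%` = 25, `>=50%` = 75)
    reg <- resp$pathologicalRegression[tpsKnown]
    rep$tpsCorrelation <- correlateResponse(mids[cohort$tps_group[tpsKnown]],
                                            reg)
  }

  if (!is.null(variants)) {
    tmb <- computeTMB(variants$protein_affecting, variants$covered_bases)
    idx <- match(variants$patient_id, cohort$patient_id)
    ok <- evaluable[idx]
    rep$tmb <- list(median = stats::median(tmb$tmb),
                    groups = as.list(table(tmb$tmbGroup[ok])))
    grp <- tmb$tmbGroup[ok]; mprV <- mpr[idx][ok]
    pw <- list()
    for (pair in list(c("<10", "10-15"), c("<10", ">=16"),
                      c("10-15", ">=16"))) {
      sel <- grp %in% pair
      tab <- table(factor(as.character(grp[sel]), pair),
                   factor(mprV[sel], c(TRUE, FALSE)))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        pw[[paste(pair, collapse = " vs ")]] <- fisherExact(tab)
    }
    rep$tmbPairwiseFisher <- pw
  }

  r0 <- evaluable & cohort$resection == "R0"
  if (any(r0)) {
    kmDfs <- kmEstimate(cohort$dfs_time[r0], cohort$dfs_event[r0])
    kmOs <- kmEstimate(cohort$os_time[r0], cohort$os_event[r0])
    rep$survival <- list(
      landmarkMonths = config$landmarkMonths,
      dfsLandmark = kmDfs$landmark(config$landmarkMonths),
      osLandmark = kmOs$landmark(config$landmarkMonths),
      logRankByMpr = if (length(unique(mpr[r0])) == 2L)
        logRank(cohort$os_time[r0], cohort$os_event[r0], mpr[r0]) else NULL)
  }

  rep$designPower <- do.call(designPower, config$design)

  if (!is.null(preds)) {
    grp <- ifelse(preds$set == "test2", "PD",
                  ifelse(resp$mpr[match(preds$patient_id,
                                        cohort$patient_id)], "MPR", "non-MPR"))
    sizes <- table(grp)
    if (length(sizes) >= 2 && sum(sizes >= 2) >= 2)
      rep$probabilityGroups <- compareProbabilityGroups(preds$probability,
                                                        grp)
  }
  rep
}
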
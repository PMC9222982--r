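#' Stratified fold assignment by event status
#'
#' Partitions patients into `k` folds so that within each status class the
#' fold sizes differ by at most one, giving every fold close to the overall
#' event proportion. Deterministic given the seed.
#'
#' @param status status vector (1 = event, 0 = censored).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), one per patient.
#' @export
stratifiedFolds <- function(status, k = 10L, seed = 1L) {
  n <- length(status)
  if (k > n)
    .roiStop("roicox_config_error", "k = %d exceeds the number of patients", k)
  classes <- unique(status)
  if (length(classes) < 2L)
    .roiStop("roicox_config_error", "both status classes must be nonempty")
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (cls in sort(classes)) {
    idx <- which(status == cls)
    if (length(idx) < k)
      .roiWarn("roicox_stratification_warning",
               "status class %s has %d members for %d folds; spreading as evenly as possible",
               format(cls), length(idx), k)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Experiment configuration for the cross-validation harness
#'
#' @param models subset of `CPH`, `CPH_ROI`, `CPH_DL`, `CPH_DL_ROI`.
#' @param nFolds number of CV folds (default 10).
#' @param roiWeight mixing weight lambda for the joint losses (default 0.2).
#' @param l2Weight L2 penalty weight for all models (default 1e-4).
#' @param extractor optional [ExtractorSpec-class] for the deep models
#'   (default: 100/50 rectified-linear with dropout 0.5, built per task).
#' @param epochs,learningRate deep-model training settings.
#' @param seed master seed; fold and per-model initialization seeds are
#'   derived from it deterministically.
#' @param standardize `"fold"` (default, training-fold statistics only,
#'   leakage-safe), `"global"` (statistics from the full task), or
#'   `"none"`.
#' @return a validated configuration list.
#' @export
experimentConfig <- function(models = c("CPH", "CPH_ROI", "CPH_DL", "CPH_DL_ROI"),
                             nFolds = 10L, roiWeight = 0.2, l2Weight = 1e-4,
                             extractor = NULL, epochs = 200L,
                             learningRate = 1e-3, seed = 1L,
                             standardize = c("fold", "global", "none")) {
  known <- c("CPH", "CPH_ROI", "CPH_DL", "CPH_DL_ROI")
  bad <- setdiff(models, known)
  if (length(bad))
    .roiStop("roicox_config_error", "unknown model(s): %s",
             paste(bad, collapse = ", "))
  if (nFolds < 2L)
    .roiStop("roicox_config_error", "nFolds must be at least 2")
  if (roiWeight < 0 || roiWeight > 1)
    .roiStop("roicox_config_error", "roiWeight must lie in [0, 1]")
  list(models = models, nFolds = as.integer(nFolds), roiWeight = roiWeight,
       l2Weight = l2Weight, extractor = extractor,
       epochs = as.integer(epochs), learningRate = learningRate,
       seed = as.integer(seed), standardize = match.arg(standardize))
}

.fitOneModel <- function(model, trainTask, config, seed) {
  switch(model,
    CPH = fitCph(primaryTask(trainTask), l2Weight = config$l2Weight,
                 control = optimizerControl(seed = seed)),
    CPH_ROI = fitCphRoi(trainTask, roiWeight = config$roiWeight,
                        l2Weight = config$l2Weight,
                        control = optimizerControl(seed = seed)),
    CPH_DL = fitDeep(primaryTask(trainTask), spec = config$extractor,
                     epochs = config$epochs,
                     learningRate = config$learningRate,
                     l2Weight = config$l2Weight, seed = seed),
    CPH_DL_ROI = fitDeep(trainTask, spec = config$extractor,
                         epochs = config$epochs,
                         learningRate = config$learningRate,
                         l2Weight = config$l2Weight,
                         roiWeight = config$roiWeight, seed = seed))
}

#' Run the stratified cross-validation protocol on one paired task
#'
#' For each fold: standardize features on the training portion (by
#' default), fit every requested model — the related-outcome models see the
#' auxiliary outcomes of TRAINING patients only — then score the held-out
#' patients from their features alone and evaluate the concordance index on
#' the primary outcome. Folds whose test portion has no permissible pairs
#' are skipped with a warning and recorded as NA.
#'
#' @param paired a [PairedSurvivalTask-class].
#' @param config an [experimentConfig()] list.
#' @param requireQC if TRUE (default), error when the task fails
#'   [qcTask()] default thresholds; set FALSE to override.
#' @return a [CVReport-class].
#' @export
runTask <- function(paired, config = experimentConfig(), requireQC = TRUE) {
  stopifnot(is(paired, "PairedSurvivalTask"))
  if (requireQC && !passedQC(qcTask(paired)))
    .roiStop("roicox_config_error",
             "task fails QC; pass requireQC = FALSE to override")
  nSeeds <- 1L + length(config$models) * config$nFolds
  seeds <- .deriveSeeds(config$seed, nSeeds)
  foldSeed <- seeds[1]
  fold <- stratifiedFolds(eventStatus(paired), config$nFolds, foldSeed)
  rows <- list()
  deepEvents <- sum(eventStatus(paired) == 1)
  si <- 1L
  for (f in seq_len(config$nFolds)) {
    trainIdx <- which(fold != f)
    testIdx <- which(fold == f)
    trainTask <- subsetTask(paired, trainIdx)
    Xtest <- features(paired)[testIdx, , drop = FALSE]
    if (config$standardize == "fold") {
      std <- standardizeFeatures(features(trainTask), Xtest)
      trainTask@X <- std$XTrain
      Xtest <- std$XApply
    } else if (config$standardize == "global") {
      std <- standardizeFeatures(features(paired))
      trainTask@X <- std$XTrain[trainIdx, , drop = FALSE]
      Xtest <- std$XTrain[testIdx, , drop = FALSE]
    }
    tTest <- eventTime(paired)[testIdx]
    eTest <- eventStatus(paired)[testIdx]
    for (mdl in config$models) {
      si <- si + 1L
      modelSeed <- seeds[si]
      fit <- .fitOneModel(mdl, trainTask, config, modelSeed)
      risk <- predictRisk(fit, Xtest)
      res <- tryCatch(concordanceIndex(risk, tTest, eTest),
                      roicox_metric_error = function(e) NULL)
      if (is.null(res)) {
        .roiWarn("roicox_fold_warning",
                 "fold %d skipped for model %s: no permissible pairs", f, mdl)
        rows[[length(rows) + 1L]] <- data.frame(
          model = mdl, fold = f, cIndex = NA_real_, nPermissiblePairs = 0)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          model = mdl, fold = f, cIndex = cIndex(res),
          nPermissiblePairs = res@nPermissiblePairs)
      }
    }
  }
  new("CVReport", results = do.call(rbind, rows), foldAssignment = fold,
      config = config[setdiff(names(config), "extractor")],
      seeds = list(master = config$seed, fold = foldSeed,
                   model = seeds[-1]),
      taskName = taskName(paired))
}

#' Aggregate a CV report
#'
#' @param report a [CVReport-class].
#' @return data.frame with one row per model: mean and median test-fold
#'   C-index (skipped folds excluded) and the number of evaluated folds.
#' @export
cvSummary <- function(report) {
  res <- report@results
  out <- do.call(rbind, lapply(split(res, res$model), function(d) {
    data.frame(model = d$model[1],
               meanCIndex = mean(d$cIndex, na.rm = TRUE),
               medianCIndex = stats::median(d$cIndex, na.rm = TRUE),
               nFolds = sum(!is.na(d$cIndex)))
  }))
  rownames(out) <- NULL
  out[match(intersect(report@config$models, out$model), out$model), ,
      drop = FALSE]
}

#' Mean cross-validated C-index of one model in a report
#'
#' @param report a [CVReport-class].
#' @param model model name.
#' @return scalar mean C-index over evaluated folds.
#' @export
meanCIndex <- function(report, model) {
  s <- cvSummary(report)
  if (!model %in% s$model)
    .roiStop("roicox_config_error", "model %s not present in the report", model)
  s$meanCIndex[s$model == model]
}

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport for '%s' (%d folds, master seed %d)\n",
              object@taskName, object@config$nFolds, object@seeds$master))
  print(cvSummary(object), row.names = FALSE)
})

#' Export per-fold CV results as a tidy data.frame
#'
#' @param report a [CVReport-class].
#' @return data.frame with columns task, model, fold, c_index,
#'   n_permissible_pairs (one row per model x fold).
#' @export
tidyCVResults <- function(report) {
  data.frame(task = report@taskName, model = report@results$model,
             fold = report@results$fold, c_index = report@results$cIndex,
             n_permissible_pairs = report@results$nPermissiblePairs)
}

#' Compare two models across many tasks
#'
#' Tabulates per-task mean C-indices of a baseline and a comparison model,
#' counts wins/losses/ties, and runs the one-sided signed-rank test for the
#' alternative that the comparison model exceeds the baseline. A fully tied
#' comparison is reported as "no difference" rather than an error.
#'
#' @param reports list of [CVReport-class] objects (each must contain both
#'   models).
#' @param baseline,comparison model names.
#' @return list with `table` (per-task means and difference), `wins`,
#'   `losses`, `ties`, `meanImprovement`, and `pValue` (NA with
#'   `noDifference = TRUE` when all tasks tie).
#' @export
summarizeBenchmark <- function(reports, baseline = "CPH",
                               comparison = "CPH_ROI") {
  if (length(reports) < 2L)
    .roiStop("roicox_config_error", "at least two reports are required")
  cA <- vapply(reports, meanCIndex, numeric(1), model = baseline)
  cB <- vapply(reports, meanCIndex, numeric(1), model = comparison)
  tab <- data.frame(task = vapply(reports, function(r) r@taskName, ""),
                    baseline = cA, comparison = cB, difference = cB - cA)
  names(tab)[2:3] <- c(baseline, comparison)
  p <- tryCatch(as.numeric(pairedModelComparison(cA, cB, "greater")),
                roicox_degenerate_test_error = function(e) NA_real_)
  list(table = tab, wins = sum(cB > cA), losses = sum(cB < cA),
       ties = sum(cB == cA), meanImprovement = mean(cB - cA),
       pValue = p, noDifference = is.na(p))
}

#' Run the synthetic benchmark: generate, cross-validate, aggregate
#'
#' For each generator seed: simulate a paired dataset under `genConfig`
#' (optionally with the outcome roles swapped), run the stratified CV
#' protocol with the requested models, and record each model's mean
#' test-fold C-index.
#'
#' @param seeds integer vector of generator seeds (one dataset per seed;
#'   each seed is also the CV master seed for its dataset).
#' @param models models to evaluate.
#' @param swap if TRUE the auxiliary outcome is treated as primary.
#' @param genConfig base [generatorConfig()]; its seed field is replaced
#'   per run.
#' @param ... further arguments to [experimentConfig()].
#' @return data.frame with columns seed, model, meanCIndex.
#' @export
syntheticBenchmark <- function(seeds, models = c("CPH", "CPH_ROI", "CPH_DL",
                                                 "CPH_DL_ROI"),
                               swap = FALSE, genConfig = generatorConfig(),
                               ...) {
  out <- list()
  for (s in seeds) {
    genConfig$seed <- as.integer(s)
    sim <- generateSurvivalData(genConfig)
    task <- if (swap) swapOutcomes(sim$task) else sim$task
    rep <- runTask(task, experimentConfig(models = models, seed = s, ...),
                   requireQC = FALSE)
    sm <- cvSummary(rep)
    out[[length(out) + 1L]] <- data.frame(seed = s, model = sm$model,
                                          meanCIndex = sm$meanCIndex)
  }
  do.call(rbind, out)
}
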
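test_that("stratified folds balance events and partition the cohort", {
  e <- rep(c(1, 0), 10)
  fold <- stratifiedFolds(e, k = 10, seed = 1)
  for (f in 1:10) {
    expect_identical(sum(fold == f & e == 1), 1L)
    expect_identical(sum(fold == f & e == 0), 1L)
  }
  expect_setequal(fold, 1:10)
  expect_identical(length(fold), 20L)

  # 19 events over 10 folds: nine folds get 2, one gets 1
  e2 <- c(rep(1, 19), rep(0, 30))
  fold2 <- stratifiedFolds(e2, k = 10, seed = 4)
  perFold <- table(fold2[e2 == 1])
  expect_identical(sort(as.integer(perFold)), c(1L, rep(2L, 9)))

  expect_identical(stratifiedFolds(e2, 10, seed = 9),
                   stratifiedFolds(e2, 10, seed = 9))
  expect_warning(stratifiedFolds(c(1, rep(0, 20)), k = 5, seed = 1),
                 class = "roicox_stratification_warning")
  expect_error(stratifiedFolds(rep(1, 10), k = 2),
               class = "roicox_config_error")
})

test_that("runTask produces a complete, deterministic report", {
  sim <- generateSurvivalData(smallGenConfig(seed = 2))
  cfg <- experimentConfig(models = "CPH", nFolds = 10, seed = 5)
  rep1 <- runTask(sim$task, cfg)
  expect_s4_class(rep1, "CVReport")
  expect_identical(nrow(rep1@results), 10L)
  expect_true(all(!is.na(rep1@results$cIndex)))
  s <- cvSummary(rep1)
  expect_equal(s$meanCIndex, mean(rep1@results$cIndex))
  expect_equal(s$medianCIndex, median(rep1@results$cIndex))
  expect_equal(meanCIndex(rep1, "CPH"), mean(rep1@results$cIndex))

  # every patient in exactly one test fold
  expect_identical(length(rep1@foldAssignment), 80L)
  expect_setequal(rep1@foldAssignment, 1:10)

  rep2 <- runTask(sim$task, cfg)
  expect_identical(rep1@results, rep2@results)
  expect_identical(rep1@foldAssignment, rep2@foldAssignment)
})

test_that("joint linear model at lambda = 0 reproduces CPH fold-for-fold", {
  sim <- generateSurvivalData(smallGenConfig(seed = 8))
  base <- runTask(sim$task, experimentConfig(models = "CPH", nFolds = 5,
                                             seed = 3))
  joint <- runTask(sim$task, experimentConfig(models = "CPH_ROI",
                                              roiWeight = 0, nFolds = 5,
                                              seed = 3))
  expect_equal(joint@results$cIndex, base@results$cIndex, tolerance = 1e-6)
})

test_that("auxiliary outcomes of test-fold patients never leak into scores", {
  sim <- generateSurvivalData(smallGenConfig(seed = 4))
  cfg <- experimentConfig(models = c("CPH_ROI", "CPH_DL_ROI"), nFolds = 4,
                          epochs = 30, seed = 7)
  ref <- runTask(sim$task, cfg)
  # corrupt the auxiliary outcome of every fold-1 (test) patient; fold 1's
  # own scores come from a model trained without those patients, so its
  # rows must be unchanged
  idx <- which(ref@foldAssignment == 1)
  tAux <- auxTime(sim$task); eAux <- auxStatus(sim$task)
  tAux[idx] <- rev(tAux[idx]) * 3 + 1
  eAux[idx] <- 1 - eAux[idx]
  corrupted <- pairedSurvivalTask(features(sim$task), eventTime(sim$task),
                                  eventStatus(sim$task), tAux, eAux)
  out <- runTask(corrupted, cfg)
  expect_identical(out@foldAssignment, ref@foldAssignment)
  expect_identical(subset(out@results, fold == 1),
                   subset(ref@results, fold == 1))
})

test_that("QC gate blocks undersized tasks unless overridden", {
  tiny <- generateSurvivalData(
    generatorConfig(nPatients = 40L, nFeatures = 5L, nEventsTarget = 25L,
                    seed = 1))$task
  expect_error(runTask(tiny, experimentConfig(models = "CPH", nFolds = 4)),
               class = "roicox_config_error")
  rep <- runTask(tiny, experimentConfig(models = "CPH", nFolds = 4),
                 requireQC = FALSE)
  expect_identical(nrow(rep@results), 4L)
})

test_that("benchmark summaries count wins and surface degeneracy", {
  mkReport <- function(name, cphC, roiC) {
    res <- rbind(
      data.frame(model = "CPH", fold = 1:3, cIndex = cphC,
                 nPermissiblePairs = 50),
      data.frame(model = "CPH_ROI", fold = 1:3, cIndex = roiC,
                 nPermissiblePairs = 50))
    new("CVReport", results = res, foldAssignment = 1L,
        config = list(models = c("CPH", "CPH_ROI"), nFolds = 3L),
        seeds = list(master = 1L), taskName = name)
  }
  # uniform +0.01 improvement: wins = number of tasks
  reports <- lapply(1:6, function(i)
    mkReport(paste0("task", i), 0.6 + i / 100, 0.61 + i / 100))
  out <- summarizeBenchmark(reports, "CPH", "CPH_ROI")
  expect_identical(out$wins, 6L)
  expect_identical(out$losses, 0L)
  expect_equal(out$meanImprovement, 0.01)
  expect_false(out$noDifference)

  # hand tally on a mixed 6-task table
  cph <- c(0.60, 0.65, 0.70, 0.62, 0.64, 0.66)
  roi <- c(0.63, 0.64, 0.70, 0.65, 0.66, 0.69)
  reports2 <- lapply(1:6, function(i)
    mkReport(paste0("t", i), cph[i], roi[i]))
  out2 <- summarizeBenchmark(reports2, "CPH", "CPH_ROI")
  expect_identical(out2$wins, 4L)
  expect_identical(out2$losses, 1L)
  expect_identical(out2$ties, 1L)

  # identical C-index vectors: no wins, degenerate test surfaced
  reports3 <- lapply(1:6, function(i) mkReport(paste0("s", i), cph[i], cph[i]))
  out3 <- summarizeBenchmark(reports3, "CPH", "CPH_ROI")
  expect_identical(out3$wins, 0L)
  expect_true(out3$noDifference)
  expect_true(is.na(out3$pValue))
})

test_that("tidy export carries one row per model and fold", {
  sim <- generateSurvivalData(smallGenConfig(seed = 10))
  rep <- runTask(sim$task, experimentConfig(models = c("CPH"), nFolds = 4,
                                            seed = 2))
  tidy <- tidyCVResults(rep)
  expect_identical(nrow(tidy), 4L)
  expect_identical(names(tidy),
                   c("task", "model", "fold", "c_index",
                     "n_permissible_pairs"))
})
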
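test_that("extractor forward pass: determinism, degenerate dropout, affine case", {
  task <- makeTask(n = 12, p = 4, seed = 2)
  model <- fitDeep(task, spec = extractorSpec(4, c(6, 3)), epochs = 5L,
                   minEvents = 2L, seed = 3L)
  E1 <- extractFeatures(model, features(task))
  E2 <- extractFeatures(model, features(task))
  expect_identical(E1, E2)
  expect_identical(ncol(E1), 3L)

  # dropout probability 0: training and eval passes coincide
  m0 <- fitDeep(task, spec = extractorSpec(4, c(6, 3), dropout = 0),
                epochs = 3L, minEvents = 2L, seed = 3L)
  set.seed(1)
  expect_identical(extractFeatures(m0, features(task), training = TRUE),
                   extractFeatures(m0, features(task)))

  # single linear layer with identity activation is an affine map
  spec <- extractorSpec(2, 2L, dropout = 0, activation = "identity")
  lin <- fitDeep(makeTask(n = 10, p = 2, seed = 4), spec = spec,
                 epochs = 1L, minEvents = 2L, seed = 7L)
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  W <- lin@params$W1; b <- lin@params$b1
  expect_equal(extractFeatures(lin, X),
               sweep(X %*% W, 2, b, "+"), tolerance = 1e-12)

  expect_error(extractFeatures(model, matrix(0, 2, 5)),
               class = "roicox_shape_error")
})

test_that("deep objective with identity extractor equals the linear objective", {
  task <- makeTask(n = 25, p = 3, seed = 6)
  spec <- extractorSpec(3, integer(0), dropout = 0, activation = "identity")
  model <- fitDeep(task, spec = spec, epochs = 1L, minEvents = 2L, seed = 5L)
  expect_equal(deepCoxLoss(model, task),
               cphLoss(model@params$beta, model@params$bias, task, 1e-4),
               tolerance = 1e-8)
  # and prediction reduces to the linear hazard
  expect_equal(predictRisk(model, features(task)),
               linearHazard(features(task), model@params$beta,
                            model@params$bias), tolerance = 1e-12)
})

test_that("deep forward pass matches a hand-composed two-layer oracle", {
  spec <- extractorSpec(2, c(3, 2), dropout = 0)
  task <- makeTask(n = 10, p = 2, seed = 8)
  model <- fitDeep(task, spec = spec, epochs = 2L, minEvents = 2L, seed = 9L)
  X <- features(task)
  P <- model@params
  H1 <- pmax(sweep(X %*% P$W1, 2, P$b1, "+"), 0)
  H2 <- pmax(sweep(H1 %*% P$W2, 2, P$b2, "+"), 0)
  hOracle <- drop(H2 %*% P$beta) + P$bias
  expect_equal(predictRisk(model, X), hOracle, tolerance = 1e-12)

  # composed loss: explicit forward + brute-force risk-set enumeration
  expect_equal(deepCoxLoss(model, task),
               bruteNll(hOracle, eventTime(task), eventStatus(task)) +
                 1e-4 * (sum(P$W1^2) + sum(P$b1^2) + sum(P$W2^2) +
                           sum(P$b2^2) + sum(P$beta^2) + P$bias^2),
               tolerance = 1e-10)
})

test_that("joint deep objective hits its lambda limits and tied-head identity", {
  paired <- makePairedTask(n = 30, p = 3, seed = 3)
  spec <- extractorSpec(3, c(5, 4), dropout = 0)
  model <- fitDeep(paired, spec = spec, epochs = 2L, minEvents = 2L,
                   seed = 11L)

  m0 <- model; m0@config$roiWeight <- 0
  expect_equal(deepRoiLoss(m0, paired),
               deepCoxLoss(m0, primaryTask(paired)), tolerance = 1e-12)
  m1 <- model; m1@config$roiWeight <- 1
  auxTask <- survivalTask(features(paired), auxTime(paired),
                          auxStatus(paired))
  # at lambda = 1 only the auxiliary head C2 is live
  m1aux <- m1; m1aux@params$beta <- m1@params$betaAux
  expect_equal(deepRoiLoss(m1, paired), deepCoxLoss(m1aux, auxTask),
               tolerance = 1e-12)

  # identical outcomes + tied heads: equals the single loss for any lambda
  same <- pairedSurvivalTask(features(paired), eventTime(paired),
                             eventStatus(paired), eventTime(paired),
                             eventStatus(paired))
  tied <- model; tied@params$betaAux <- tied@params$beta
  for (lam in c(0.2, 0.7)) {
    tied@config$roiWeight <- lam
    expect_equal(deepRoiLoss(tied, same),
                 deepCoxLoss(tied, primaryTask(paired)), tolerance = 1e-10)
  }

  noAux <- fitDeep(primaryTask(paired), spec = spec, epochs = 1L,
                   minEvents = 2L)
  expect_error(deepRoiLoss(noAux, paired), class = "roicox_config_error")
})

test_that("training is seeded-reproducible with a sane loss trajectory", {
  task <- makeTask(n = 50, p = 5, seed = 13)
  m1 <- fitDeep(task, spec = extractorSpec(5, c(8, 4)), epochs = 60L,
                minEvents = 5L, seed = 21L)
  m2 <- fitDeep(task, spec = extractorSpec(5, c(8, 4)), epochs = 60L,
                minEvents = 5L, seed = 21L)
  expect_identical(m1@params, m2@params)
  hist <- m1@diagnostics$lossHistory
  expect_true(all(is.finite(hist)))
  # moving-average of the (dropout-noisy) loss decreases over training
  expect_lt(mean(tail(hist, 15)), mean(head(hist, 15)))
})

test_that("lambda = 0 joint deep training reproduces plain deep training", {
  paired <- makePairedTask(n = 40, p = 4, seed = 17)
  spec <- extractorSpec(4, c(6, 3), dropout = 0)
  plain <- fitDeep(primaryTask(paired), spec = spec, epochs = 40L,
                   minEvents = 5L, seed = 33L)
  joint <- fitDeep(paired, spec = spec, epochs = 40L, roiWeight = 0,
                   minEvents = 5L, seed = 33L)
  for (nm in c("W1", "b1", "W2", "b2", "beta", "bias"))
    expect_equal(joint@params[[nm]], plain@params[[nm]], tolerance = 1e-12)
  expect_equal(joint@diagnostics$lossHistory, plain@diagnostics$lossHistory,
               tolerance = 1e-12)
})

test_that("deep models learn linear signal and stay at chance on noise", {
  cs <- csNoise <- numeric(3)
  for (s in 1:3) {
    sim <- generateSurvivalData(smallGenConfig(seed = 100 + s))
    task <- primaryTask(sim$task)
    train <- subsetTask(task, 1:60)
    test <- subsetTask(task, 61:80)
    m <- fitDeep(train, epochs = 120L, seed = s)
    cs[s] <- cIndex(concordanceIndex(predictRisk(m, features(test)),
                                     eventTime(test), eventStatus(test)))
    noise <- generateSurvivalData(smallGenConfig(seed = 200 + s),
                                  betaOverride = rep(0, 10))
    ntask <- primaryTask(noise$task)
    mN <- fitDeep(subsetTask(ntask, 1:60), epochs = 120L, seed = s)
    csNoise[s] <- cIndex(concordanceIndex(
      predictRisk(mN, features(subsetTask(ntask, 61:80))),
      eventTime(ntask)[61:80], eventStatus(ntask)[61:80]))
  }
  expect_gt(mean(cs), 0.6)
  expect_lt(abs(mean(csNoise) - 0.5), 0.15)
  expect_gt(mean(cs), mean(csNoise))
})

test_that("checkpoints round-trip through JSON", {
  paired <- makePairedTask(n = 25, p = 3, seed = 19)
  model <- fitDeep(paired, spec = extractorSpec(3, c(4, 2)), epochs = 10L,
                   minEvents = 2L, seed = 2L)
  f <- withr::local_tempfile(fileext = ".json")
  writeDeepCoxModel(model, f)
  back <- readDeepCoxModel(f)
  expect_equal(back@params, model@params)
  expect_identical(back@spec@widths, model@spec@widths)
  expect_equal(back@config$roiWeight, model@config$roiWeight)
  expect_identical(predictRisk(back, features(paired)),
                   predictRisk(model, features(paired)))
})
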
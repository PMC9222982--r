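test_that("regularized objective adds the stated penalty", {
  task <- makeTask(n = 15, p = 2, seed = 7)
  nll <- negLogPartialLikelihood(
    linearHazard(features(task), c(1, 2), 3), eventTime(task),
    eventStatus(task))
  # penalty 0.0001 * (1 + 4 + 9) = 0.0014
  expect_equal(cphLoss(c(1, 2), 3, task, 1e-4) - nll, 0.0014,
               tolerance = 1e-9)
  expect_equal(cphLoss(c(1, 2), 3, task, 0), nll)
  expect_equal(cphLoss(c(0, 0), 0, task, 1e-4),
               negLogPartialLikelihood(linearHazard(features(task),
                                                    c(0, 0), 0),
                                       eventTime(task), eventStatus(task)))
})

test_that("joint objective reduces to single-outcome losses at the lambda limits", {
  paired <- makePairedTask(n = 25, p = 3, seed = 2)
  b1 <- c(0.3, -0.2, 0.5); b2 <- c(-0.1, 0.4, 0.2)
  primOnly <- cphLoss(b1, 0.1, primaryTask(paired), 1e-4)
  auxTask <- survivalTask(features(paired), auxTime(paired),
                          auxStatus(paired))
  auxOnly <- cphLoss(b2, 0.1, auxTask, 1e-4)
  expect_identical(roiLoss(b1, b2, 0.1, paired, roiWeight = 0), primOnly)
  expect_identical(roiLoss(b1, b2, 0.1, paired, roiWeight = 1), auxOnly)

  # identical outcomes with beta1 = beta2: convex combination is the
  # single loss for any lambda
  same <- pairedSurvivalTask(features(paired), eventTime(paired),
                             eventStatus(paired), eventTime(paired),
                             eventStatus(paired))
  for (lam in c(0.2, 0.5, 0.9))
    expect_equal(roiLoss(b1, b1, 0.1, same, roiWeight = lam), primOnly,
                 tolerance = 1e-12)

  noAux <- pairedSurvivalTask(features(paired), eventTime(paired),
                              eventStatus(paired), auxTime(paired),
                              rep(0, 25))
  err <- tryCatch(roiLoss(b1, b2, 0, noAux, roiWeight = 0.2),
                  error = identity)
  expect_s3_class(err, "roicox_likelihood_error")
  expect_match(conditionMessage(err), "auxiliary")
})

test_that("fitCph agrees with an independent Newton oracle and coxph", {
  task <- makeTask(n = 20, p = 2, seed = 5)
  fit <- fitCph(task)
  oracle <- newtonCoxOracle(task, l2 = 1e-4)
  expect_equal(fit@beta, oracle[1:2], tolerance = 1e-4)
  expect_lt(abs(fit@bias), 1e-3)

  skip_if_not_installed("survival")
  # unpenalized fit against survival::coxph (Breslow ties)
  fit0 <- fitCph(task, l2Weight = 0)
  cph <- survival::coxph(
    survival::Surv(eventTime(task), eventStatus(task)) ~ features(task),
    ties = "breslow")
  expect_equal(unname(fit0@beta), unname(coef(cph)), tolerance = 1e-3)
})

test_that("penalty shrinks coefficients monotonically and kills noise", {
  task <- makeTask(n = 60, p = 4, seed = 8)
  norms <- vapply(c(1e-4, 1e-2, 1, 100), function(l2)
    sqrt(sum(fitCph(task, l2Weight = l2)@beta^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))

  noise <- makeTask(n = 50, p = 3, seed = 12, beta = c(0, 0, 0))
  weakFit <- fitCph(noise, l2Weight = 1e-4)
  strong <- fitCph(noise, l2Weight = 1000)
  expect_lt(max(abs(strong@beta)), 0.05)
  expect_lt(sqrt(sum(strong@beta^2)), 0.5 * sqrt(sum(weakFit@beta^2)))
})

test_that("fits are deterministic given seed and carry diagnostics", {
  task <- makeTask(n = 30, p = 3, seed = 4)
  f1 <- fitCph(task, control = optimizerControl(seed = 42))
  f2 <- fitCph(task, control = optimizerControl(seed = 42))
  expect_identical(f1@beta, f2@beta)
  expect_identical(f1@bias, f2@bias)
  d <- f1@diagnostics
  expect_true(all(c("loss", "gradNorm", "iterations", "converged") %in%
                    names(d)))
  expect_true(d$converged)
  expect_lt(d$gradNorm, 1e-4)
})

test_that("joint fit at lambda = 0 reproduces the single-outcome fit", {
  sim <- generateSurvivalData(smallGenConfig(seed = 3))
  single <- fitCph(primaryTask(sim$task))
  joint <- fitCphRoi(sim$task, roiWeight = 0)
  expect_equal(joint@beta, single@beta, tolerance = 1e-4)
  expect_lt(abs(joint@bias), 1e-3)
})

test_that("identical primary/auxiliary outcomes give symmetric heads", {
  base <- makeTask(n = 50, p = 4, seed = 6)
  same <- pairedSurvivalTask(features(base), eventTime(base),
                             eventStatus(base), eventTime(base),
                             eventStatus(base))
  fit <- fitCphRoi(same, roiWeight = 0.5)
  expect_equal(fit@beta, fit@betaAux, tolerance = 1e-3)
  single <- fitCph(base)
  expect_equal(fit@beta, single@beta, tolerance = 1e-3)
})

test_that("prediction uses primary coefficients only and is rank-stable in bias", {
  paired <- makePairedTask(n = 40, p = 3, seed = 9)
  fit <- fitCphRoi(paired)
  Xnew <- matrix(rnorm(15), 5, 3)
  risk <- predictRisk(fit, Xnew)
  expect_equal(risk, linearHazard(Xnew, fit@beta, fit@bias))

  # auxiliary head never affects prediction
  tampered <- fit
  tampered@betaAux <- rev(fit@betaAux)
  expect_identical(predictRisk(tampered, Xnew), risk)

  # shifting the bias shifts scores by a constant: C-index unchanged
  shifted <- fit
  shifted@bias <- fit@bias + 5
  tm <- rexp(5); e <- rep(1, 5)
  expect_equal(cIndex(concordanceIndex(predictRisk(shifted, Xnew), tm, e)),
               cIndex(concordanceIndex(risk, tm, e)))
})

test_that("model JSON serialization round-trips", {
  paired <- makePairedTask(n = 30, p = 3, seed = 10)
  fit <- fitCphRoi(paired)
  f <- withr::local_tempfile(fileext = ".json")
  writeLinearCoxModel(fit, f)
  back <- readLinearCoxModel(f)
  expect_equal(back@beta, fit@beta)
  expect_equal(back@betaAux, fit@betaAux)
  expect_equal(back@bias, fit@bias)
  expect_identical(back@roiWeight, fit@roiWeight)
})

test_that("degenerate all-events-at-one-time data is rejected", {
  bad <- survivalTask(matrix(rnorm(20), 10), rep(5, 10), rep(1, 10))
  expect_error(fitCph(bad), class = "roicox_likelihood_error")
})
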
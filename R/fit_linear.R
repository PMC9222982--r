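#' Optimizer control settings for the linear Cox fitters
#'
#' The fitters use L-BFGS-B on the analytic gradient of the regularized
#' partial-likelihood objective, run to (componentwise) gradient tolerance.
#'
#' @param maxIterations iteration cap (default 2000).
#' @param gradientTolerance convergence tolerance on the projected gradient
#'   (default 1e-6).
#' @param factr relative objective-change stopping factor for L-BFGS-B, in
#'   units of machine epsilon (default 10, i.e. essentially gradient-driven
#'   termination).
#' @param seed seed for the random coefficient initialization.
#' @return a list of class-free control settings.
#' @export
optimizerControl <- function(maxIterations = 2000L, gradientTolerance = 1e-6,
                             factr = 10, seed = 1L) {
  if (gradientTolerance <= 0)
    .roiStop("roicox_config_error", "gradientTolerance must be positive")
  list(maxIterations = as.integer(maxIterations),
       gradientTolerance = gradientTolerance, factr = factr,
       seed = as.integer(seed))
}

.checkDegenerate <- function(task) {
  tm <- eventTime(task); st <- eventStatus(task)
  if (all(st == 1) && length(unique(tm)) == 1L)
    .roiStop("roicox_likelihood_error",
             "degenerate data: every patient has an event at the same time")
}

.runLbfgs <- function(par0, fn, gr, control) {
  res <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = control$maxIterations,
                                     pgtol = control$gradientTolerance,
                                     factr = control$factr))
  gfinal <- gr(res$par)
  converged <- res$convergence == 0L
  if (!converged)
    .roiWarn("roicox_convergence_warning",
             "optimizer did not converge (code %d): %s",
             res$convergence, res$message)
  list(par = res$par, loss = res$value,
       gradNorm = sqrt(sum(gfinal^2)),
       iterations = unname(res$counts["function"]),
       converged = converged)
}

#' Fit the L2-regularized linear Cox proportional hazards model
#'
#' Minimizes [cphLoss()] (Breslow partial likelihood plus an L2 penalty on
#' coefficients and bias, default weight 1e-4) by quasi-Newton descent with
#' the analytic gradient. Coefficients are initialized uniformly on
#' \[-0.01, 0.01\] from the control seed and the bias at zero; the fit is
#' deterministic given seed and data.
#'
#' @param task a [SurvivalTask-class].
#' @param l2Weight L2 penalty weight (default 1e-4).
#' @param control an [optimizerControl()] list.
#' @return a [LinearCoxModel-class] with `fit diagnostics` (final loss,
#'   gradient norm, iteration count, convergence flag).
#' @export
fitCph <- function(task, l2Weight = 1e-4, control = optimizerControl()) {
  validObject(task)
  .checkDegenerate(task)
  X <- features(task)
  p <- ncol(X)
  tm <- eventTime(task); st <- eventStatus(task)
  if (sum(st) < 1)
    .roiStop("roicox_likelihood_error", "task has no observed events")
  fn <- function(par) {
    h <- drop(X %*% par[seq_len(p)]) + par[p + 1L]
    .coxNll(h, tm, st)$value + l2Weight * sum(par^2)
  }
  gr <- function(par) {
    h <- drop(X %*% par[seq_len(p)]) + par[p + 1L]
    g <- .coxNll(h, tm, st, gradient = TRUE)$grad
    c(drop(crossprod(X, g)), sum(g)) + 2 * l2Weight * par
  }
  set.seed(control$seed)
  par0 <- c(stats::runif(p, -0.01, 0.01), 0)
  res <- .runLbfgs(par0, fn, gr, control)
  new("LinearCoxModel", beta = res$par[seq_len(p)], bias = res$par[p + 1L],
      betaAux = numeric(0), l2Weight = l2Weight, roiWeight = 0,
      diagnostics = list(loss = res$loss, gradNorm = res$gradNorm,
                         iterations = res$iterations,
                         converged = res$converged, seed = control$seed))
}

#' Fit the related-outcome joint linear Cox model
#'
#' Jointly minimizes [roiLoss()] over `(beta1, beta2, b)`: the weighted sum
#' of the primary and auxiliary regularized Cox objectives with a single
#' shared bias. Prediction for new patients ([predictRisk()]) uses the
#' primary coefficients and bias only — the auxiliary outcome is a
#' training-time device.
#'
#' @param paired a [PairedSurvivalTask-class].
#' @param roiWeight mixing weight lambda (default 0.2).
#' @param l2Weight L2 penalty weight (default 1e-4, as for the plain fit).
#' @param control an [optimizerControl()] list.
#' @return a [LinearCoxModel-class] with both `beta` (primary) and
#'   `betaAux` populated.
#' @export
fitCphRoi <- function(paired, roiWeight = 0.2, l2Weight = 1e-4,
                      control = optimizerControl()) {
  validObject(paired)
  if (roiWeight < 0 || roiWeight > 1)
    .roiStop("roicox_config_error", "roiWeight must lie in [0, 1]")
  X <- features(paired)
  p <- ncol(X)
  t1 <- eventTime(paired); e1 <- eventStatus(paired)
  t2 <- auxTime(paired); e2 <- auxStatus(paired)
  if (sum(e1) < 1)
    .roiStop("roicox_likelihood_error", "primary outcome has no observed events")
  if (sum(e2) < 1)
    .roiStop("roicox_likelihood_error", "auxiliary outcome has no observed events")
  i1 <- seq_len(p); i2 <- p + i1; ib <- 2L * p + 1L
  w1 <- 1 - roiWeight; w2 <- roiWeight
  fn <- function(par) {
    b <- par[ib]
    h1 <- drop(X %*% par[i1]) + b
    h2 <- drop(X %*% par[i2]) + b
    w1 * (.coxNll(h1, t1, e1)$value + l2Weight * (sum(par[i1]^2) + b^2)) +
      w2 * (.coxNll(h2, t2, e2)$value + l2Weight * (sum(par[i2]^2) + b^2))
  }
  gr <- function(par) {
    b <- par[ib]
    g1 <- .coxNll(drop(X %*% par[i1]) + b, t1, e1, gradient = TRUE)$grad
    g2 <- .coxNll(drop(X %*% par[i2]) + b, t2, e2, gradient = TRUE)$grad
    c(w1 * (drop(crossprod(X, g1)) + 2 * l2Weight * par[i1]),
      w2 * (drop(crossprod(X, g2)) + 2 * l2Weight * par[i2]),
      w1 * (sum(g1) + 2 * l2Weight * b) + w2 * (sum(g2) + 2 * l2Weight * b))
  }
  set.seed(control$seed)
  par0 <- c(stats::runif(2 * p, -0.01, 0.01), 0)
  res <- .runLbfgs(par0, fn, gr, control)
  new("LinearCoxModel", beta = res$par[i1], bias = res$par[ib],
      betaAux = res$par[i2], l2Weight = l2Weight, roiWeight = roiWeight,
      diagnostics = list(loss = res$loss, gradNorm = res$gradNorm,
                         iterations = res$iterations,
                         converged = res$converged, seed = control$seed))
}

#' @describeIn predictRisk linear model: `X %*% beta + bias` with the
#'   primary coefficients.
#' @export
setMethod("predictRisk", "LinearCoxModel", function(model, X) {
  linearHazard(X, model@beta, model@bias)
})

setMethod("coef", "LinearCoxModel", function(object, ...) object@beta)

setMethod("show", "LinearCoxModel", function(object) {
  kind <- if (length(object@betaAux)) "related-outcome joint Cox" else "linear Cox"
  cat(sprintf("LinearCoxModel (%s): p = %d, bias = %.3g, l2 = %g, lambda = %g\n",
              kind, length(object@beta), object@bias, object@l2Weight,
              object@roiWeight))
  d <- object@diagnostics
  if (length(d))
    cat(sprintf("  loss %.6g, |grad| %.3g, %d evaluations, converged: %s\n",
                d$loss, d$gradNorm, d$iterations, d$converged))
})

#' Serialize / restore a linear Cox model as JSON
#'
#' @param model a [LinearCoxModel-class].
#' @param path file path.
#' @return `writeLinearCoxModel` returns `path` invisibly;
#'   `readLinearCoxModel` returns the model.
#' @export
writeLinearCoxModel <- function(model, path) {
  x <- list(beta = model@beta,
            beta_aux = if (length(model@betaAux)) model@betaAux else NULL,
            bias = model@bias, l2_weight = model@l2Weight,
            roi_weight = model@roiWeight, diagnostics = model@diagnostics)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeLinearCoxModel
#' @export
readLinearCoxModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("LinearCoxModel", beta = as.numeric(x$beta), bias = as.numeric(x$bias),
      betaAux = if (is.null(x$beta_aux)) numeric(0) else as.numeric(x$beta_aux),
      l2Weight = as.numeric(x$l2_weight), roiWeight = as.numeric(x$roi_weight),
      diagnostics = as.list(x$diagnostics))
}
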
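#' Construct an extractor specification
#'
#' @param inputWidth number of input features p.
#' @param widths hidden-layer widths (default `c(100, 50)`); an empty
#'   vector gives the identity extractor so the deep model degenerates to
#'   the linear one.
#' @param dropout dropout probability after each hidden layer (default 0.5).
#' @param activation "relu" (default) or "identity".
#' @return an [ExtractorSpec-class].
#' @export
extractorSpec <- function(inputWidth, widths = c(100L, 50L), dropout = 0.5,
                          activation = "relu") {
  new("ExtractorSpec", inputWidth = as.integer(inputWidth),
      widths = as.integer(widths), dropout = as.numeric(dropout),
      activation = activation)
}

.embedWidth <- function(spec) {
  if (length(spec@widths)) spec@widths[length(spec@widths)] else spec@inputWidth
}

.activate <- function(Z, activation) {
  if (activation == "relu") Z * (Z > 0) else Z
}

# Fan-in-scaled uniform initialization: U(-1/sqrt(fanIn), 1/sqrt(fanIn)).
# All parameters are drawn in a fixed order (extractor layers, primary
# head, then the auxiliary head LAST) so that a lambda = 0 joint fit
# consumes the shared parameters' random numbers identically to a plain fit.
.initDeepParams <- function(spec, aux = FALSE) {
  params <- list()
  fanIn <- spec@inputWidth
  for (l in seq_along(spec@widths)) {
    w <- spec@widths[l]
    s <- 1 / sqrt(fanIn)
    params[[paste0("W", l)]] <- matrix(stats::runif(fanIn * w, -s, s), fanIn, w)
    params[[paste0("b", l)]] <- stats::runif(w, -s, s)
    fanIn <- w
  }
  s <- 1 / sqrt(fanIn)
  params$beta <- stats::runif(fanIn, -s, s)
  params$bias <- 0
  if (aux) params$betaAux <- stats::runif(fanIn, -s, s)
  params
}

# Forward pass through the extractor. In training mode, inverted dropout
# masks are drawn from the current RNG stream; caches hold everything the
# backward pass needs.
.deepForward <- function(params, spec, X, training = FALSE, cache = FALSE) {
  L <- length(spec@widths)
  A <- X
  caches <- if (cache) vector("list", L) else NULL
  keep <- 1 - spec@dropout
  for (l in seq_len(L)) {
    Z <- A %*% params[[paste0("W", l)]]
    Z <- Z + rep(params[[paste0("b", l)]], each = nrow(Z))
    H <- .activate(Z, spec@activation)
    M <- NULL
    if (training && spec@dropout > 0) {
      M <- matrix((stats::runif(length(H)) < keep) / keep, nrow(H), ncol(H))
      H <- H * M
    }
    if (cache) caches[[l]] <- list(A = A, Z = Z, M = M)
    A <- H
  }
  list(E = A, caches = caches)
}

.sumSq <- function(x) sum(unlist(lapply(x, function(v) sum(v^2))))

.extractorParams <- function(params, spec) {
  L <- length(spec@widths)
  params[as.vector(rbind(paste0("W", seq_len(L)), paste0("b", seq_len(L))))]
}

#' Embed patients with a deep model's feature extractor
#'
#' @param model a [DeepCoxModel-class].
#' @param X feature matrix (width = extractor input width).
#' @param training if TRUE, dropout masks are sampled from the current RNG;
#'   if FALSE (default) the pass is deterministic.
#' @return embedding matrix (n x final layer width).
#' @export
extractFeatures <- function(model, X, training = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != model@spec@inputWidth)
    .roiStop("roicox_shape_error", "X has %d columns, extractor expects %d",
             ncol(X), model@spec@inputWidth)
  .deepForward(model@params, model@spec, X, training = training)$E
}

#' Deep Cox objective
#'
#' The negative log partial likelihood of the head scores
#' `h = F(X) beta + b` plus an L2 penalty over all extractor weights and
#' head parameters. Evaluated in deterministic (no-dropout) mode.
#'
#' @param model a [DeepCoxModel-class].
#' @param task a [SurvivalTask-class].
#' @return scalar objective value.
#' @export
deepCoxLoss <- function(model, task) {
  E <- extractFeatures(model, features(task))
  h <- drop(E %*% model@params$beta) + model@params$bias
  pen <- .sumSq(.extractorParams(model@params, model@spec)) +
    sum(model@params$beta^2) + model@params$bias^2
  negLogPartialLikelihood(h, eventTime(task), eventStatus(task)) +
    model@config$l2Weight * pen
}

#' Joint related-outcome deep Cox objective
#'
#' `(1 - lambda) * l(F, C1) + lambda * l(F, C2)` where both Cox heads read
#' the SAME embedding from the SAME extractor and share one bias; each
#' `l(F, C)` is a deep Cox objective as in [deepCoxLoss()].
#'
#' @param model a [DeepCoxModel-class] with an auxiliary head (`betaAux`).
#' @param paired a [PairedSurvivalTask-class].
#' @return scalar objective value.
#' @export
deepRoiLoss <- function(model, paired) {
  if (is.null(model@params$betaAux))
    .roiStop("roicox_config_error", "model has no auxiliary head")
  lam <- model@config$roiWeight
  l2 <- model@config$l2Weight
  E <- extractFeatures(model, features(paired))
  penW <- .sumSq(.extractorParams(model@params, model@spec))
  b <- model@params$bias
  h1 <- drop(E %*% model@params$beta) + b
  h2 <- drop(E %*% model@params$betaAux) + b
  l1 <- negLogPartialLikelihood(h1, eventTime(paired), eventStatus(paired)) +
    l2 * (penW + sum(model@params$beta^2) + b^2)
  l2term <- negLogPartialLikelihood(h2, auxTime(paired), auxStatus(paired)) +
    l2 * (penW + sum(model@params$betaAux^2) + b^2)
  (1 - lam) * l1 + lam * l2term
}

# One full-batch loss + gradient evaluation with the given dropout masks.
# heads: list of list(name, weight, time, status). Returns value and the
# gradient list over all parameters.
.deepLossGrad <- function(params, spec, X, heads, l2) {
  fwd <- .deepForward(params, spec, X, training = TRUE, cache = TRUE)
  E <- fwd$E
  L <- length(spec@widths)
  grads <- list()
  value <- 0
  dE <- matrix(0, nrow(E), ncol(E))
  sumHeadW <- 0
  for (hd in heads) {
    beta <- params[[hd$name]]
    h <- drop(E %*% beta) + params$bias
    nll <- .coxNll(h, hd$time, hd$status, gradient = TRUE)
    value <- value + hd$weight * nll$value
    g <- hd$weight * nll$grad
    grads[[hd$name]] <- drop(crossprod(E, g)) + 2 * hd$weight * l2 * beta
    grads$bias <- (grads$bias %||% 0) + sum(g)
    dE <- dE + tcrossprod(g, beta)
    sumHeadW <- sumHeadW + hd$weight
    value <- value + hd$weight * l2 * (sum(beta^2) + params$bias^2)
  }
  grads$bias <- grads$bias + 2 * sumHeadW * l2 * params$bias
  # extractor penalty appears once in every head's objective
  penW <- .sumSq(.extractorParams(params, spec))
  value <- value + sumHeadW * l2 * penW
  for (l in rev(seq_len(L))) {
    cc <- fwd$caches[[l]]
    dH <- dE
    if (!is.null(cc$M)) dH <- dH * cc$M
    dZ <- if (spec@activation == "relu") dH * (cc$Z > 0) else dH
    grads[[paste0("W", l)]] <- crossprod(cc$A, dZ) +
      2 * sumHeadW * l2 * params[[paste0("W", l)]]
    grads[[paste0("b", l)]] <- colSums(dZ) +
      2 * sumHeadW * l2 * params[[paste0("b", l)]]
    dE <- tcrossprod(dZ, params[[paste0("W", l)]])
  }
  list(value = value, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fitDeepImpl <- function(X, heads, spec, epochs, learningRate, l2Weight,
                         roiWeight, seed, minEvents, aux) {
  nEv <- sum(heads[[1]]$status)
  if (nEv < minEvents)
    .roiStop("roicox_config_error",
             "only %d primary events; at least %d required", nEv, minEvents)
  set.seed(seed)
  params <- .initDeepParams(spec, aux = aux)
  m <- lapply(params, function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lossHistory <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    lg <- .deepLossGrad(params, spec, X, heads, l2Weight)
    if (!is.finite(lg$value))
      .roiStop("roicox_training_error",
               "training diverged (non-finite loss) at epoch %d", epoch)
    lossHistory[epoch] <- lg$value
    for (nm in names(params)) {
      g <- lg$grads[[nm]]
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
      mhat <- m[[nm]] / (1 - b1^epoch)
      vhat <- v[[nm]] / (1 - b2^epoch)
      params[[nm]] <- params[[nm]] - learningRate * mhat / (sqrt(vhat) + eps)
    }
  }
  new("DeepCoxModel", spec = spec, params = params,
      config = list(epochs = epochs, learningRate = learningRate,
                    seed = seed, roiWeight = if (aux) roiWeight else 0,
                    l2Weight = l2Weight),
      diagnostics = list(lossHistory = lossHistory,
                         finalLoss = lossHistory[epochs]))
}

#' @describeIn fitDeep single-outcome deep Cox model (one head).
#' @export
setMethod("fitDeep", "SurvivalTask",
  function(task, spec = NULL, epochs = 200L, learningRate = 1e-3,
           l2Weight = 1e-4, roiWeight = 0.2, seed = 1L, minEvents = 20L) {
    if (is.null(spec)) spec <- extractorSpec(nFeatures(task))
    heads <- list(list(name = "beta", weight = 1, time = eventTime(task),
                       status = eventStatus(task)))
    .fitDeepImpl(features(task), heads, spec, as.integer(epochs),
                 learningRate, l2Weight, roiWeight, as.integer(seed),
                 minEvents, aux = FALSE)
  })

#' @describeIn fitDeep related-outcome deep Cox model: two heads sharing
#'   the extractor and the bias, joint loss weighted by `roiWeight`.
#' @export
setMethod("fitDeep", "PairedSurvivalTask",
  function(task, spec = NULL, epochs = 200L, learningRate = 1e-3,
           l2Weight = 1e-4, roiWeight = 0.2, seed = 1L, minEvents = 20L) {
    if (is.null(spec)) spec <- extractorSpec(nFeatures(task))
    if (sum(auxStatus(task)) < 1)
      .roiStop("roicox_likelihood_error",
               "auxiliary outcome has no observed events")
    heads <- list(
      list(name = "beta", weight = 1 - roiWeight, time = eventTime(task),
           status = eventStatus(task)),
      list(name = "betaAux", weight = roiWeight, time = auxTime(task),
           status = auxStatus(task)))
    .fitDeepImpl(features(task), heads, spec, as.integer(epochs),
                 learningRate, l2Weight, roiWeight, as.integer(seed),
                 minEvents, aux = TRUE)
  })

#' @describeIn predictRisk deep model: deterministic (evaluation-mode)
#'   forward pass through the extractor, scored by the primary head only.
#' @export
setMethod("predictRisk", "DeepCoxModel", function(model, X) {
  E <- extractFeatures(model, X, training = FALSE)
  drop(E %*% model@params$beta) + model@params$bias
})

setMethod("show", "DeepCoxModel", function(object) {
  w <- object@spec@widths
  cat(sprintf("DeepCoxModel: extractor %d -> %s (%s, dropout %.2g), %s head(s)\n",
              object@spec@inputWidth,
              if (length(w)) paste(w, collapse = " -> ") else "identity",
              object@spec@activation, object@spec@dropout,
              if (!is.null(object@params$betaAux)) "2 shared-bias" else "1"))
  cat(sprintf("  trained %d epochs, final loss %.6g\n",
              object@config$epochs, object@diagnostics$finalLoss))
})

#' Save / load a deep Cox model checkpoint
#'
#' The checkpoint is a single JSON document holding the extractor
#' specification, all parameter arrays in a named, ordered layout, and the
#' training configuration; save then load reproduces the model exactly.
#'
#' @param model a [DeepCoxModel-class].
#' @param path file path.
#' @return `writeDeepCoxModel` returns `path` invisibly;
#'   `readDeepCoxModel` returns the model.
#' @export
writeDeepCoxModel <- function(model, path) {
  # parameters are stored as %.17g strings: shortest text that restores
  # IEEE doubles exactly, so the round trip is bitwise
  params <- lapply(model@params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = sprintf("%.17g", p))
    else list(dim = NULL, data = sprintf("%.17g", p))
  })
  x <- list(spec = list(input_width = model@spec@inputWidth,
                        widths = model@spec@widths,
                        dropout = model@spec@dropout,
                        activation = model@spec@activation),
            params = params, config = model@config,
            diagnostics = model@diagnostics)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeDeepCoxModel
#' @export
readDeepCoxModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- extractorSpec(x$spec$input_width, x$spec$widths %||% integer(0),
                        x$spec$dropout, x$spec$activation)
  params <- lapply(x$params, function(p) {
    d <- as.numeric(p$data)
    if (!is.null(p$dim) && length(p$dim)) matrix(d, p$dim[1], p$dim[2]) else d
  })
  cfg <- as.list(x$config)
  diag <- list(lossHistory = as.numeric(x$diagnostics$lossHistory),
               finalLoss = as.numeric(x$diagnostics$finalLoss))
  new("DeepCoxModel", spec = spec, params = params, config = cfg,
      diagnostics = diag)
}
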
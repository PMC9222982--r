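#' SurvivalTask: one cohort, one time-to-event outcome
#'
#' Container for a single survival-analysis task: an `n x p` numeric feature
#' matrix plus, per patient, a strictly positive follow-up time (days) and a
#' status indicator (1 = event observed, 0 = censored at that time).
#'
#' @slot sampleIds character vector of patient identifiers (length n).
#' @slot X numeric matrix, n patients by p features, no missing values.
#' @slot time numeric vector of positive event/censoring times.
#' @slot status numeric vector in \{0, 1\}.
#' @slot name label for the task.
#'
#' @aliases SurvivalTask-class
#' @exportClass SurvivalTask
setClass("SurvivalTask",
  representation(
    sampleIds = "character",
    X = "matrix",
    time = "numeric",
    status = "numeric",
    name = "character"
  )
)

.validSurvivalVectors <- function(n, time, status, what = "") {
  if (length(time) != n || length(status) != n)
    return(sprintf("%stime/status length must equal the number of patients", what))
  if (anyNA(time) || any(!is.finite(time)) || any(time <= 0))
    return(sprintf("%sall times must be finite and strictly positive", what))
  if (anyNA(status) || !all(status %in% c(0, 1)))
    return(sprintf("%sall status indicators must be 0 or 1", what))
  NULL
}

setValidity("SurvivalTask", function(object) {
  n <- nrow(object@X)
  if (!is.numeric(object@X)) return("X must be a numeric matrix")
  if (anyNA(object@X) || any(!is.finite(object@X)))
    return("X must contain no missing or non-finite values")
  if (length(object@sampleIds) != n)
    return("sampleIds length must equal nrow(X)")
  msg <- .validSurvivalVectors(n, object@time, object@status)
  if (!is.null(msg)) return(msg)
  TRUE
})

#' PairedSurvivalTask: one cohort with a primary and an auxiliary outcome
#'
#' Extends [SurvivalTask-class] with a second (auxiliary) outcome recorded on
#' the same patients. The auxiliary outcome is used only during model
#' training; prediction consumes features alone.
#'
#' @slot timeAux numeric vector of positive auxiliary times.
#' @slot statusAux numeric vector in \{0, 1\}.
#'
#' @aliases PairedSurvivalTask-class
#' @exportClass PairedSurvivalTask
setClass("PairedSurvivalTask",
  contains = "SurvivalTask",
  representation(timeAux = "numeric", statusAux = "numeric")
)

setValidity("PairedSurvivalTask", function(object) {
  msg <- .validSurvivalVectors(nrow(object@X), object@timeAux, object@statusAux,
                               what = "auxiliary ")
  if (!is.null(msg)) return(msg)
  TRUE
})

#' TaskQCReport: quality-control summary of a survival task
#'
#' @slot nPatients,nEvents,nCensored counts.
#' @slot ecRatio events divided by censored (`Inf` when nothing is censored).
#' @slot passed logical; TRUE iff all QC thresholds are met.
#' @aliases TaskQCReport-class
#' @exportClass TaskQCReport
setClass("TaskQCReport",
  representation(
    nPatients = "integer", nEvents = "integer", nCensored = "integer",
    ecRatio = "numeric", passed = "logical"
  )
)

#' LinearCoxModel: fitted linear Cox model (plain or with auxiliary head)
#'
#' @slot beta primary log-hazard coefficients (length p).
#' @slot bias shared scalar intercept b. It cancels in the partial
#'   likelihood and is pinned near zero by the L2 penalty.
#' @slot betaAux auxiliary-outcome coefficients (length p, or length 0 for a
#'   plain fit); shares `bias` with the primary head.
#' @slot l2Weight L2 penalty weight.
#' @slot roiWeight mixing weight lambda in \[0, 1\] (0 for plain fits).
#' @slot diagnostics list: final loss, gradient norm, iteration count,
#'   convergence flag, seed.
#' @aliases LinearCoxModel-class
#' @exportClass LinearCoxModel
setClass("LinearCoxModel",
  representation(
    beta = "numeric", bias = "numeric", betaAux = "numeric",
    l2Weight = "numeric", roiWeight = "numeric", diagnostics = "list"
  )
)

setValidity("LinearCoxModel", function(object) {
  if (anyNA(object@beta) || any(!is.finite(object@beta)))
    return("beta must be finite")
  if (length(object@bias) != 1L || !is.finite(object@bias))
    return("bias must be a finite scalar")
  if (length(object@betaAux) > 0L && length(object@betaAux) != length(object@beta))
    return("betaAux must have the same length as beta")
  if (object@roiWeight < 0 || object@roiWeight > 1)
    return("roiWeight must lie in [0, 1]")
  TRUE
})

#' ExtractorSpec: architecture of the deep feature extractor
#'
#' Describes the multilayer perceptron F that maps p input features into an
#' embedding. The default mirrors the two-hidden-layer architecture used
#' throughout: 100 units, dropout 0.5, 50 units, dropout 0.5.
#'
#' @slot inputWidth number of input features p.
#' @slot widths hidden-layer widths in order (may be empty: identity extractor).
#' @slot dropout dropout probability applied after each hidden layer, in \[0, 1).
#' @slot activation "relu" or "identity".
#' @aliases ExtractorSpec-class
#' @exportClass ExtractorSpec
setClass("ExtractorSpec",
  representation(
    inputWidth = "integer", widths = "integer",
    dropout = "numeric", activation = "character"
  )
)

setValidity("ExtractorSpec", function(object) {
  if (object@inputWidth < 1L) return("inputWidth must be positive")
  if (length(object@widths) > 0L && any(object@widths < 1L))
    return("layer widths must be positive")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must lie in [0, 1)")
  if (!object@activation %in% c("relu", "identity"))
    return("activation must be 'relu' or 'identity'")
  TRUE
})

#' DeepCoxModel: deep Cox model (extractor + one or two Cox heads)
#'
#' @slot spec the [ExtractorSpec-class].
#' @slot params named list of parameter arrays: `W1`, `b1`, ... per hidden
#'   layer, head coefficients `beta`, shared scalar `bias`, and optionally
#'   `betaAux` for the auxiliary head (which shares `bias`).
#' @slot config training configuration (epochs, learningRate, seed,
#'   roiWeight, l2Weight).
#' @slot diagnostics list with per-epoch loss history and final state.
#' @aliases DeepCoxModel-class
#' @exportClass DeepCoxModel
setClass("DeepCoxModel",
  representation(
    spec = "ExtractorSpec", params = "list",
    config = "list", diagnostics = "list"
  )
)

setValidity("DeepCoxModel", function(object) {
  w <- object@spec@widths
  embed <- if (length(w)) w[length(w)] else object@spec@inputWidth
  if (length(object@params$beta) != embed)
    return("head coefficient length must equal the embedding width")
  if (!is.null(object@params$betaAux) &&
      length(object@params$betaAux) != embed)
    return("auxiliary head length must equal the embedding width")
  if (length(object@params$bias) != 1L)
    return("bias must be a scalar")
  TRUE
})

#' ConcordanceResult: Harrell concordance index with pair counts
#'
#' @slot cIndex concordance index in \[0, 1\].
#' @slot nConcordant,nDiscordant,nTiedScore,nPermissiblePairs pair counts;
#'   concordant + discordant + tied = permissible, and
#'   cIndex = (concordant + 0.5 tied) / permissible.
#' @aliases ConcordanceResult-class
#' @exportClass ConcordanceResult
setClass("ConcordanceResult",
  representation(
    cIndex = "numeric", nConcordant = "numeric", nDiscordant = "numeric",
    nTiedScore = "numeric", nPermissiblePairs = "numeric"
  )
)

setValidity("ConcordanceResult", function(object) {
  if (object@nConcordant + object@nDiscordant + object@nTiedScore !=
      object@nPermissiblePairs)
    return("pair counts must sum to the number of permissible pairs")
  TRUE
})

#' SyntheticTruth: ground truth of a simulated paired survival dataset
#'
#' @slot betaTrue,betaAuxTrue the true coefficient vectors of the two
#'   outcomes' hazard functions.
#' @slot correlation realized Pearson correlation between them.
#' @slot cutoffs named numeric: the end-of-study censoring cutoff time per
#'   outcome (`primary`, `aux`).
#' @slot seed generator seed.
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    betaTrue = "numeric", betaAuxTrue = "numeric",
    correlation = "numeric", cutoffs = "numeric", seed = "integer"
  )
)

#' CVReport: cross-validation results for one task
#'
#' @slot results data.frame with columns model, fold, cIndex,
#'   nPermissiblePairs (cIndex is NA for folds skipped for lack of events).
#' @slot foldAssignment integer vector: test-fold id per patient.
#' @slot config resolved experiment configuration.
#' @slot seeds list of derived seeds actually used.
#' @slot taskName label of the evaluated task.
#' @aliases CVReport-class
#' @exportClass CVReport
setClass("CVReport",
  representation(
    results = "data.frame", foldAssignment = "integer",
    config = "list", seeds = "list", taskName = "character"
  )
)
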
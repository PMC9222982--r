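#' @name roicox-generics
#' @title Generics for roicox classes
#' @param object,x an roicox object.
#' @param model a fitted model.
#' @param X numeric feature matrix.
#' @param ... passed to methods.
NULL

#' @rdname roicox-generics
#' @export
setGeneric("nPatients", function(object) standardGeneric("nPatients"))

#' @rdname roicox-generics
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))

#' @rdname roicox-generics
#' @export
setGeneric("features", function(object) standardGeneric("features"))

#' @rdname roicox-generics
#' @export
setGeneric("eventTime", function(object) standardGeneric("eventTime"))

#' @rdname roicox-generics
#' @export
setGeneric("eventStatus", function(object) standardGeneric("eventStatus"))

#' @rdname roicox-generics
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname roicox-generics
#' @export
setGeneric("taskName", function(object) standardGeneric("taskName"))

#' @rdname roicox-generics
#' @export
setGeneric("auxTime", function(object) standardGeneric("auxTime"))

#' @rdname roicox-generics
#' @export
setGeneric("auxStatus", function(object) standardGeneric("auxStatus"))

#' Predict relative risk for new patients
#'
#' Risk scores are log relative hazards computed from the features and the
#' PRIMARY coefficients/head only; auxiliary outcome information is never
#' consumed at prediction time. For deep models the forward pass runs in
#' evaluation mode (dropout off), so repeated calls are deterministic.
#'
#' @param model a [LinearCoxModel-class] or [DeepCoxModel-class].
#' @param X numeric matrix of features (same width as at fit time).
#' @return numeric vector of risk scores, one per row of `X`.
#' @export
setGeneric("predictRisk", function(model, X) standardGeneric("predictRisk"))

#' Fit a deep Cox model
#'
#' Gradient-based training (full-batch Adam) of a multilayer feature
#' extractor topped with one Cox regression head (for a [SurvivalTask-class])
#' or two heads sharing a bias (for a [PairedSurvivalTask-class], where the
#' loss is the weighted sum `(1 - roiWeight) * primary + roiWeight * aux`).
#'
#' @param task a survival task (paired for the related-outcome variant).
#' @param spec an [ExtractorSpec-class]; defaults to two hidden layers of
#'   100 and 50 rectified-linear units with dropout 0.5 after each.
#' @param epochs number of full-batch epochs (default 200).
#' @param learningRate Adam step size (default 1e-3).
#' @param l2Weight L2 penalty weight over all extractor weights and head
#'   parameters (default 1e-4).
#' @param roiWeight mixing weight lambda for the auxiliary loss (paired
#'   tasks only; default 0.2).
#' @param seed integer seed controlling initialization and dropout.
#' @param minEvents minimum number of observed primary events required
#'   (default 20).
#' @return a trained [DeepCoxModel-class] with per-epoch loss history in
#'   `diagnostics`.
#' @export
setGeneric("fitDeep", function(task, spec = NULL, epochs = 200L,
                               learningRate = 1e-3, l2Weight = 1e-4,
                               roiWeight = 0.2, seed = 1L, minEvents = 20L)
  standardGeneric("fitDeep"))

#' @rdname roicox-generics
#' @export
setGeneric("cIndex", function(object) standardGeneric("cIndex"))

#' @rdname roicox-generics
#' @export
setGeneric("passedQC", function(object) standardGeneric("passedQC"))
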
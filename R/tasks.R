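#' Construct a survival task
#'
#' @param X numeric matrix, n patients by p features.
#' @param time positive event/censoring times (days).
#' @param status status indicators, 1 = event, 0 = censored.
#' @param sampleIds optional patient identifiers; defaults to `s1..sn`.
#' @param name task label.
#' @return a [SurvivalTask-class].
#' @examples
#' task <- survivalTask(matrix(rnorm(20), 10), time = 1:10,
#'                      status = rep(c(1, 0), 5))
#' nPatients(task)
#' @export
survivalTask <- function(X, time, status, sampleIds = NULL, name = "task") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(nrow(X)))
  new("SurvivalTask", sampleIds = as.character(sampleIds), X = X,
      time = as.numeric(time), status = as.numeric(status), name = name)
}

#' Construct a paired survival task (primary + auxiliary outcome)
#'
#' @inheritParams survivalTask
#' @param timeAux,statusAux the auxiliary outcome, recorded on the same
#'   patients.
#' @return a [PairedSurvivalTask-class].
#' @export
pairedSurvivalTask <- function(X, time, status, timeAux, statusAux,
                               sampleIds = NULL, name = "task") {
  base <- survivalTask(X, time, status, sampleIds, name)
  new("PairedSurvivalTask", base,
      timeAux = as.numeric(timeAux), statusAux = as.numeric(statusAux))
}

#' @describeIn survivalTask number of patients.
#' @param object a task.
#' @export
setMethod("nPatients", "SurvivalTask", function(object) nrow(object@X))

#' @describeIn survivalTask number of features.
#' @export
setMethod("nFeatures", "SurvivalTask", function(object) ncol(object@X))

#' @describeIn survivalTask the feature matrix.
#' @export
setMethod("features", "SurvivalTask", function(object) object@X)

#' @describeIn survivalTask the primary times.
#' @export
setMethod("eventTime", "SurvivalTask", function(object) object@time)

#' @describeIn survivalTask the primary status indicators.
#' @export
setMethod("eventStatus", "SurvivalTask", function(object) object@status)

#' @describeIn survivalTask the patient identifiers.
#' @export
setMethod("sampleIds", "SurvivalTask", function(object) object@sampleIds)

#' @describeIn survivalTask the task label.
#' @export
setMethod("taskName", "SurvivalTask", function(object) object@name)

#' @describeIn survivalTask auxiliary times (paired tasks).
#' @export
setMethod("auxTime", "PairedSurvivalTask", function(object) object@timeAux)

#' @describeIn survivalTask auxiliary status indicators (paired tasks).
#' @export
setMethod("auxStatus", "PairedSurvivalTask", function(object) object@statusAux)

setMethod("show", "SurvivalTask", function(object) {
  cat(sprintf("%s '%s': %d patients x %d features, %d events / %d censored\n",
              class(object), object@name, nPatients(object),
              nFeatures(object), sum(object@status == 1),
              sum(object@status == 0)))
  if (is(object, "PairedSurvivalTask"))
    cat(sprintf("  auxiliary outcome: %d events / %d censored\n",
                sum(object@statusAux == 1), sum(object@statusAux == 0)))
})

#' Subset a task by patient index
#'
#' @param task a [SurvivalTask-class] or [PairedSurvivalTask-class].
#' @param i integer or logical index over patients.
#' @return a task of the same class restricted to the selected patients.
#' @export
subsetTask <- function(task, i) {
  if (is(task, "PairedSurvivalTask")) {
    pairedSurvivalTask(task@X[i, , drop = FALSE], task@time[i],
                       task@status[i], task@timeAux[i], task@statusAux[i],
                       task@sampleIds[i], task@name)
  } else {
    survivalTask(task@X[i, , drop = FALSE], task@time[i], task@status[i],
                 task@sampleIds[i], task@name)
  }
}

#' Swap the primary and auxiliary outcomes of a paired task
#'
#' Useful for evaluating the symmetric direction of a related-outcome pair
#' (auxiliary treated as the prediction target).
#'
#' @param task a [PairedSurvivalTask-class].
#' @return a [PairedSurvivalTask-class] with the outcomes exchanged.
#' @export
swapOutcomes <- function(task) {
  stopifnot(is(task, "PairedSurvivalTask"))
  pairedSurvivalTask(task@X, task@timeAux, task@statusAux,
                     task@time, task@status, task@sampleIds,
                     paste0(task@name, "_swapped"))
}

#' Drop the auxiliary outcome of a paired task
#'
#' @param task a [PairedSurvivalTask-class].
#' @return the primary [SurvivalTask-class].
#' @export
primaryTask <- function(task) {
  survivalTask(task@X, task@time, task@status, task@sampleIds, task@name)
}
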
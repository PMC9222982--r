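#' Drop records and features with missing values
#'
#' Two-stage missingness filter: first remove every row (patient) whose
#' fraction of missing entries exceeds `sampleThreshold`, then drop every
#' remaining column (feature) that still contains any missing value. The
#' result is guaranteed complete, and reapplying the filter is a no-op.
#'
#' @param X numeric matrix, possibly with `NA` entries.
#' @param sampleThreshold maximum tolerated per-row missing fraction
#'   (default 0.2).
#' @return list with elements `X` (complete submatrix), `rows` and `cols`
#'   (kept indices into the input).
#' @export
filterMissing <- function(X, sampleThreshold = 0.2) {
  X <- as.matrix(X)
  if (sampleThreshold < 0 || sampleThreshold > 1)
    .roiStop("roicox_config_error", "sampleThreshold must lie in [0, 1]")
  rowFrac <- rowMeans(is.na(X))
  rows <- which(rowFrac <= sampleThreshold)
  if (!length(rows))
    .roiStop("roicox_empty_error", "all rows removed by the missingness filter")
  Xr <- X[rows, , drop = FALSE]
  cols <- which(colSums(is.na(Xr)) == 0L)
  if (!length(cols))
    .roiStop("roicox_empty_error", "all columns removed by the missingness filter")
  list(X = Xr[, cols, drop = FALSE], rows = rows, cols = cols)
}

#' Standardize features with training-set statistics
#'
#' Centers and scales every column of `XTrain` to mean zero and unit
#' variance (population convention: divide by n), and applies the same
#' training means/scales to `XApply`. Zero-variance columns are mapped to
#' all zeros rather than dividing by zero.
#'
#' @param XTrain training feature matrix (statistics are fit here only).
#' @param XApply optional held-out matrix with the same feature count,
#'   transformed with the training statistics.
#' @return list with `XTrain`, `XApply` (or NULL), `means`, `scales`.
#' @export
standardizeFeatures <- function(XTrain, XApply = NULL) {
  XTrain <- as.matrix(XTrain)
  if (!nrow(XTrain))
    .roiStop("roicox_empty_error", "XTrain must be nonempty")
  if (!is.null(XApply)) {
    XApply <- as.matrix(XApply)
    if (ncol(XApply) != ncol(XTrain))
      .roiStop("roicox_shape_error",
               "XApply has %d features but XTrain has %d",
               ncol(XApply), ncol(XTrain))
  }
  means <- colMeans(XTrain)
  centered <- sweep(XTrain, 2L, means)
  scales <- sqrt(colMeans(centered^2))
  safe <- ifelse(scales > 0, scales, 1)
  out <- sweep(centered, 2L, safe, "/")
  out[, scales == 0] <- 0
  applied <- NULL
  if (!is.null(XApply)) {
    applied <- sweep(sweep(XApply, 2L, means), 2L, safe, "/")
    applied[, scales == 0] <- 0
  }
  list(XTrain = out, XApply = applied, means = means, scales = scales)
}

#' Unsupervised feature selection by mean absolute deviation
#'
#' Ranks columns by the mean absolute deviation around the column mean,
#' `mean(|x - mean(x)|)`, and keeps the `k` largest. No outcome information
#' is used. Ties are broken toward the lower column index, and the original
#' relative column order is preserved among the selected features.
#'
#' @param X numeric feature matrix.
#' @param k number of features to keep (`k <= ncol(X)`).
#' @return list with `X` (n x k matrix) and `cols` (selected indices, in
#'   original order).
#' @export
selectTopMad <- function(X, k) {
  X <- as.matrix(X)
  if (k > ncol(X))
    .roiStop("roicox_config_error", "k = %d exceeds feature count %d",
             k, ncol(X))
  mad <- colMeans(abs(sweep(X, 2L, colMeans(X))))
  keep <- sort(order(mad, seq_along(mad), decreasing = c(TRUE, FALSE),
                     method = "radix")[seq_len(k)])
  list(X = X[, keep, drop = FALSE], cols = keep)
}

#' Quality-control report for a survival task
#'
#' A task passes QC iff it has at least `minPatients` patients, at least
#' `minEvents` observed events, and an event-to-censored ratio of at least
#' `minEC`. When no patient is censored the ratio is `Inf` and the E/C
#' criterion passes.
#'
#' @param task a [SurvivalTask-class].
#' @param minPatients,minEvents,minEC thresholds (defaults 50, 20, 0.2).
#' @return a [TaskQCReport-class].
#' @export
qcTask <- function(task, minPatients = 50L, minEvents = 20L, minEC = 0.2) {
  nEvents <- sum(eventStatus(task) == 1)
  nCens <- sum(eventStatus(task) == 0)
  ec <- if (nCens > 0) nEvents / nCens else Inf
  new("TaskQCReport",
      nPatients = nPatients(task), nEvents = as.integer(nEvents),
      nCensored = as.integer(nCens), ecRatio = ec,
      passed = nPatients(task) >= minPatients && nEvents >= minEvents &&
               ec >= minEC)
}

#' @describeIn qcTask whether the task passed.
#' @param object a [TaskQCReport-class].
#' @export
setMethod("passedQC", "TaskQCReport", function(object) object@passed)

setMethod("show", "TaskQCReport", function(object) {
  cat(sprintf(
    "TaskQCReport: %d patients, %d events, %d censored (E/C = %.3g) -> %s\n",
    object@nPatients, object@nEvents, object@nCensored, object@ecRatio,
    if (object@passed) "PASS" else "FAIL"))
})

#' Serialize a QC report to JSON
#'
#' @param report a [TaskQCReport-class].
#' @param path optional file to write to.
#' @return the JSON string, invisibly if written to file.
#' @export
qcReportJson <- function(report, path = NULL) {
  x <- list(n_patients = report@nPatients, n_events = report@nEvents,
            n_censored = report@nCensored,
            ec_ratio = if (is.finite(report@ecRatio)) report@ecRatio else "Inf",
            passed = report@passed)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
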
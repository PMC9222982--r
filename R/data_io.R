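#' Read a survival task from CSV
#'
#' Expected layout: one header row; an identifier column (default
#' `sample_id`, synthesized if absent); the primary outcome columns named in
#' `primaryCols`; optionally auxiliary outcome columns named in `auxCols`;
#' every remaining column is a numeric feature. Missing values may be coded
#' as empty cells or `NA`. Feature and row order are preserved.
#'
#' @param path CSV file path.
#' @param primaryCols length-2 character: time column, status column.
#' @param auxCols optional length-2 character for the auxiliary outcome;
#'   when supplied a [PairedSurvivalTask-class] is returned.
#' @param idCol identifier column name.
#' @param name task label (defaults to the file name).
#' @return a [SurvivalTask-class] or [PairedSurvivalTask-class].
#' @export
readSurvivalCsv <- function(path, primaryCols = c("time", "event"),
                            auxCols = NULL, idCol = "sample_id",
                            name = NULL) {
  if (!file.exists(path))
    .roiStop("roicox_config_error", "file does not exist: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  need <- c(primaryCols, auxCols)
  missingCols <- setdiff(need, names(df))
  if (length(missingCols))
    .roiStop("roicox_config_error", "missing required column(s): %s",
             paste(missingCols, collapse = ", "))
  ids <- if (idCol %in% names(df)) as.character(df[[idCol]])
         else paste0("s", seq_len(nrow(df)))
  featCols <- setdiff(names(df), c(idCol, need))
  X <- matrix(NA_real_, nrow(df), length(featCols),
              dimnames = list(NULL, featCols))
  for (j in seq_along(featCols)) {
    col <- df[[featCols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      .roiStop("roicox_parse_error",
               "non-numeric feature value '%s' at row %d, column '%s'",
               col[bad[1]], bad[1], featCols[j])
    X[, j] <- num
  }
  .checkOutcome <- function(tm, st, label) {
    if (anyNA(tm) || anyNA(st))
      .roiStop("roicox_validation_error", "%s outcome contains missing values", label)
    if (any(tm <= 0))
      .roiStop("roicox_validation_error",
               "%s time must be strictly positive (row %d)", label,
               which(tm <= 0)[1])
    if (!all(st %in% c(0, 1)))
      .roiStop("roicox_validation_error", "%s status must be 0 or 1", label)
  }
  tm <- as.numeric(df[[primaryCols[1]]]); st <- as.numeric(df[[primaryCols[2]]])
  .checkOutcome(tm, st, "primary")
  if (is.null(name)) name <- sub("\\.csv$", "", basename(path))
  if (is.null(auxCols))
    return(survivalTask(X, tm, st, ids, name))
  ta <- as.numeric(df[[auxCols[1]]]); sa <- as.numeric(df[[auxCols[2]]])
  .checkOutcome(ta, sa, "auxiliary")
  pairedSurvivalTask(X, tm, st, ta, sa, ids, name)
}

# Full-precision numeric formatting (%.17g round-trips IEEE doubles).
.fmtNum <- function(x) sprintf("%.17g", x)

#' Write a survival task to CSV
#'
#' Writes the layout read by [readSurvivalCsv()]: `sample_id`, feature
#' columns, `time`, `event`, and for paired tasks `time_aux`, `event_aux`.
#' Numbers are written with 17 significant digits so a write/read round trip
#' reproduces the task exactly.
#'
#' @param task a [SurvivalTask-class] or [PairedSurvivalTask-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSurvivalCsv <- function(task, path) {
  X <- features(task)
  featNames <- colnames(X)
  if (is.null(featNames)) featNames <- paste0("f", seq_len(ncol(X)))
  df <- data.frame(sample_id = sampleIds(task), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) df[[featNames[j]]] <- .fmtNum(X[, j])
  df$time <- .fmtNum(eventTime(task))
  df$event <- format(eventStatus(task))
  if (is(task, "PairedSurvivalTask")) {
    df$time_aux <- .fmtNum(auxTime(task))
    df$event_aux <- format(auxStatus(task))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
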
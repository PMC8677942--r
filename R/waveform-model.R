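#' Construct an ERGRecordingSet
#'
#' @param potentials Numeric matrix of potentials in microvolts, timepoints in
#'   rows and recordings in columns (`n_samples x n_records`).
#' @param recordInfo `data.frame` (or `DataFrame`) with one row per recording.
#'   `subject_id` and `eye` are required; `visit_index` (0), `recording_index`
#'   (0), `n_flashes` (100), `duration_ms` (220), `stimulus_time_ms` (100),
#'   `label` and `eye_class` are filled with defaults when missing. If only
#'   one of `label`/`eye_class` is given the other is inferred (`ON_POS`
#'   defaults to class `on_chronic`, `ON_NEG` to `control_healthy`).
#'   Covariate columns (`age_years`, `gender`, `logmar`, `hvf_md_db`,
#'   `rnfl_um`, `gclipl_um`) are kept and padded with `NA` when absent.
#' @return A validated [ERGRecordingSet-class].
#' @examples
#' uv <- matrix(rnorm(430 * 2), 430, 2)
#' es <- ERGRecordingSet(uv, data.frame(subject_id = c("S1", "S1"),
#'                                      eye = c("OD", "OS")))
#' es
#' @export
ERGRecordingSet <- function(potentials, recordInfo) {
  potentials <- as.matrix(potentials)
  storage.mode(potentials) <- "double"
  recordInfo <- as.data.frame(recordInfo)
  if (nrow(recordInfo) != ncol(potentials))
    stop("recordInfo must have one row per column of 'potentials'")
  for (col in c("subject_id", "eye"))
    if (is.null(recordInfo[[col]]))
      stop(sprintf("recordInfo column '%s' is required", col))
  n <- nrow(recordInfo)
  recordInfo$subject_id <- as.character(recordInfo$subject_id)
  recordInfo$eye <- as.character(recordInfo$eye)
  recordInfo$visit_index <- as.integer(recordInfo$visit_index %||% rep(0L, n))
  recordInfo$recording_index <- as.integer(recordInfo$recording_index %||% rep(0L, n))
  recordInfo$n_flashes <- as.integer(recordInfo$n_flashes %||% rep(100L, n))
  recordInfo$duration_ms <- as.numeric(recordInfo$duration_ms %||% rep(220, n))
  recordInfo$stimulus_time_ms <- as.numeric(recordInfo$stimulus_time_ms %||% rep(100, n))
  if (is.null(recordInfo$eye_class) && is.null(recordInfo$label)) {
    recordInfo$label <- rep("UNKNOWN", n)
    recordInfo$eye_class <- rep("unknown", n)
  } else if (is.null(recordInfo$eye_class)) {
    recordInfo$label <- as.character(recordInfo$label)
    recordInfo$eye_class <- c(ON_POS = "on_chronic", ON_NEG = "control_healthy",
                              UNKNOWN = "unknown")[recordInfo$label]
  } else {
    recordInfo$eye_class <- as.character(recordInfo$eye_class)
    if (is.null(recordInfo$label))
      recordInfo$label <- .labelForEyeClass(recordInfo$eye_class)
    recordInfo$label <- as.character(recordInfo$label)
  }
  for (col in .covariateCols)
    if (is.null(recordInfo[[col]]))
      recordInfo[[col]] <- rep(if (col == "gender") NA_character_ else NA_real_, n)
  recordInfo$gender <- as.character(recordInfo$gender)
  for (col in setdiff(.covariateCols, "gender"))
    recordInfo[[col]] <- as.numeric(recordInfo[[col]])
  recordInfo <- recordInfo[, c(.requiredColData, .covariateCols), drop = FALSE]
  ids <- .recordId(recordInfo$subject_id, recordInfo$eye,
                   recordInfo$visit_index, recordInfo$recording_index)
  if (anyDuplicated(ids))
    stop("duplicate record identity (subject_id, eye, visit_index, recording_index): ",
         ids[duplicated(ids)][1])
  colnames(potentials) <- ids
  rownames(recordInfo) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(uv = potentials),
    colData = S4Vectors::DataFrame(recordInfo))
  new("ERGRecordingSet", se)
}

#' Time of a sample index on the uniform recording grid
#'
#' Sample `i` (0-based) occurs at `i * duration_ms / n_samples`. With the
#' default geometry (220 ms, 430 samples) the step is 220/430 = 0.5116 ms,
#' so 11 consecutive samples span 5.63 ms.
#'
#' @param index 0-based sample index (vectorised).
#' @param duration_ms Record duration in ms.
#' @param n_samples Number of samples in the record.
#' @return Time(s) in ms.
#' @examples
#' timeOfSample(0:3, 220, 430)
#' @export
timeOfSample <- function(index, duration_ms = 220, n_samples = 430) {
  duration_ms <- .assertNumber(duration_ms, "duration_ms", lower = 1e-12)
  n_samples <- .assertCount(n_samples, "n_samples", lower = 1L)
  if (any(index < 0 | index >= n_samples) || any(index != round(index)))
    stop("index out of range [0, n_samples)")
  index * (duration_ms / n_samples)
}

#' Nearest sample index for a time
#'
#' Returns the index minimising `|timeOfSample(i) - t_ms|`, with ties broken
#' toward the smaller index and the result clamped to the last sample.
#'
#' @param t_ms Time in ms, within `[0, duration_ms]` (vectorised).
#' @inheritParams timeOfSample
#' @return 0-based sample index (integer).
#' @examples
#' sampleAtTime(172, 220, 430)  # 72 ms after a 100 ms stimulus -> index 336
#' @export
sampleAtTime <- function(t_ms, duration_ms = 220, n_samples = 430) {
  duration_ms <- .assertNumber(duration_ms, "duration_ms", lower = 1e-12)
  n_samples <- .assertCount(n_samples, "n_samples", lower = 1L)
  if (any(t_ms < 0 | t_ms > duration_ms))
    stop("t_ms outside the record [0, duration_ms]")
  dt <- duration_ms / n_samples
  u <- t_ms / dt
  i <- floor(u)
  up <- (u - i) > (i + 1 - u)  # strict: ties go to the smaller index
  as.integer(pmin(i + as.numeric(up), n_samples - 1L))
}

#' @describeIn ERGRecordingSet Potentials matrix (timepoints x recordings), µV.
#' @param x An `ERGRecordingSet`.
#' @export
potentials <- function(x) {
  stopifnot(is(x, "ERGRecordingSet"))
  SummarizedExperiment::assay(x, "uv")
}

#' @describeIn ERGRecordingSet Per-recording metadata as a `DataFrame`.
#' @export
recordInfo <- function(x) {
  stopifnot(is(x, "ERGRecordingSet"))
  SummarizedExperiment::colData(x)
}

#' @describeIn ERGRecordingSet Sample times (ms) for one recording's grid.
#' @param record Column index or name of the recording (default 1).
#' @export
sampleTimes <- function(x, record = 1L) {
  stopifnot(is(x, "ERGRecordingSet"), ncol(x) >= 1)
  d <- recordInfo(x)$duration_ms[record]
  timeOfSample(seq_len(nrow(x)) - 1L, d, nrow(x))
}

#' @describeIn ERGRecordingSet Diagnosis labels (`ON_POS`/`ON_NEG`/`UNKNOWN`).
#' @export
recordLabels <- function(x) recordInfo(x)$label

#' @describeIn ERGRecordingSet Subject identifiers.
#' @export
subjectIDs <- function(x) recordInfo(x)$subject_id

setMethod("show", "ERGRecordingSet", function(object) {
  cd <- recordInfo(object)
  cat(sprintf("ERGRecordingSet: %d recordings x %d samples\n",
              ncol(object), nrow(object)))
  if (ncol(object) > 0) {
    cat(sprintf("  subjects: %d | eyes: %d | labels: %s\n",
                length(unique(cd$subject_id)),
                length(unique(paste(cd$subject_id, cd$eye))),
                paste(sprintf("%s=%d", names(table(cd$label)),
                              as.integer(table(cd$label))), collapse = " ")))
    cat(sprintf("  duration %g ms, stimulus at %g ms, dt = %.4f ms\n",
                cd$duration_ms[1], cd$stimulus_time_ms[1],
                cd$duration_ms[1] / nrow(object)))
  }
  invisible(NULL)
})

setMethod("show", "GEEFit", function(object) {
  cat(sprintf("Linear GEE (%s working correlation): %s\n",
              object@corstr, object@model_label))
  cat(sprintf("  %d observations in %d clusters", object@n_obs, object@n_clusters))
  if (!is.na(object@alpha)) cat(sprintf("; alpha = %.3f", object@alpha))
  cat("\n")
  tab <- data.frame(estimate = object@coefficients, robust_se = object@robust_se,
                    z = object@wald_z, p = object@p_values)
  print(format(tab, digits = 4))
  invisible(NULL)
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve (%s): %d operating points, %d positive / %d negative\n",
              object@orientation, length(object@thresholds),
              object@n_positive, object@n_negative))
  cat(sprintf("  AUC (trapezoid) = %.4f\n", aucTrapezoid(object)))
  invisible(NULL)
})
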
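#' ERGRecordingSet: a cohort of averaged photopic ERG waveforms
#'
#' An S4 container extending [SummarizedExperiment::SummarizedExperiment] for
#' averaged full-field ERG recordings. Rows are timepoints of the sampling
#' grid, columns are recordings, and the single assay `"uv"` holds potentials
#' in microvolts. Per-recording metadata (subject, eye, visit, label, eye
#' class, stimulus timing, and optional clinical covariates) live in
#' `colData`.
#'
#' The time convention is that sample `i` (0-based) occurs at
#' `i * duration_ms / n_samples`; with the defaults of the recording protocol
#' (220 ms, 430 samples) the sampling step is about 0.512 ms, so 11
#' consecutive samples span about 5.63 ms. The flash is delivered at
#' `stimulus_time_ms` (default 100 ms), a per-recording field so other
#' protocols can be represented.
#'
#' Required `colData` columns: `subject_id`, `eye` (`"OD"`/`"OS"`),
#' `visit_index`, `recording_index`, `n_flashes`, `duration_ms`,
#' `stimulus_time_ms`, `label` (`"ON_POS"`, `"ON_NEG"`, `"UNKNOWN"`),
#' `eye_class` (`"on_acute"`, `"on_chronic"`, `"control_fellow"`,
#' `"control_patient"`, `"control_healthy"`, `"unknown"`). Optional covariate
#' columns (`age_years`, `gender`, `logmar`, `hvf_md_db`, `rnfl_um`,
#' `gclipl_um`) use `NA` for absent values; sentinel numbers are never used.
#'
#' Validity enforces that the label and eye class agree: optic-neuropathy
#' (`ON_POS`) eyes have class `on_acute`/`on_chronic`, control (`ON_NEG`)
#' eyes one of the `control_*` classes, and `UNKNOWN` eyes class `unknown`.
#'
#' @seealso [ERGRecordingSet()] for the constructor,
#'   [readWaveformCSV()]/[writeWaveformCSV()] for on-disk formats,
#'   [extractFeatures()] for the feature pipeline.
#' @export
setClass("ERGRecordingSet", contains = "SummarizedExperiment")

.requiredColData <- c("subject_id", "eye", "visit_index", "recording_index",
                      "n_flashes", "duration_ms", "stimulus_time_ms",
                      "label", "eye_class")
.covariateCols <- c("age_years", "gender", "logmar", "hvf_md_db",
                    "rnfl_um", "gclipl_um")

setValidity("ERGRecordingSet", function(object) {
  msgs <- character()
  if (!"uv" %in% SummarizedExperiment::assayNames(object))
    return("assay 'uv' (potentials in microvolts) is required")
  a <- SummarizedExperiment::assay(object, "uv")
  if (!is.numeric(a)) msgs <- c(msgs, "assay 'uv' must be numeric")
  if (anyNA(a)) msgs <- c(msgs, "assay 'uv' must not contain NA")
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.requiredColData, colnames(cd))
  if (length(miss))
    return(sprintf("missing colData column(s): %s", paste(miss, collapse = ", ")))
  if (ncol(object) > 0) {
    if (!all(cd$eye %in% .eyeLevels))
      msgs <- c(msgs, "eye must be 'OD' or 'OS'")
    if (!all(cd$label %in% .labelLevels))
      msgs <- c(msgs, "label must be ON_POS, ON_NEG or UNKNOWN")
    if (!all(cd$eye_class %in% .eyeClassLevels))
      msgs <- c(msgs, "invalid eye_class value")
    bad <- cd$label != .labelForEyeClass(cd$eye_class)
    if (any(bad))
      msgs <- c(msgs, sprintf("label/eye_class mismatch for record(s): %s",
                              paste(head(colnames(object)[bad], 5), collapse = ", ")))
    if (any(cd$visit_index < 0) || any(cd$recording_index < 0))
      msgs <- c(msgs, "visit_index and recording_index must be non-negative")
    if (any(cd$n_flashes < 1))
      msgs <- c(msgs, "n_flashes must be positive")
    if (any(cd$duration_ms <= 0))
      msgs <- c(msgs, "duration_ms must be positive")
    if (any(cd$stimulus_time_ms < 0 | cd$stimulus_time_ms >= cd$duration_ms))
      msgs <- c(msgs, "stimulus_time_ms must lie in [0, duration_ms)")
  }
  if (length(msgs)) msgs else TRUE
})

#' GEEFit: a fitted linear generalized estimating equation
#'
#' Result of [fitLinearGEE()]: a linear mean model for clustered eye-level
#' data (clusters are subjects, observations are eyes/recordings) with a
#' working correlation of either `"independence"` or `"exchangeable"` and a
#' robust (sandwich) covariance. Wald z statistics are coefficient divided by
#' robust SE and p-values are two-sided normal tail probabilities.
#'
#' @slot coefficients Named numeric vector of estimates.
#' @slot robust_se Robust (sandwich) standard errors.
#' @slot wald_z Wald z statistics (`coefficients / robust_se`).
#' @slot p_values Two-sided normal p-values.
#' @slot vcov_robust Robust covariance matrix.
#' @slot corstr Working correlation structure used.
#' @slot alpha Estimated exchangeable correlation (`NA` under independence).
#' @slot scale Estimated residual variance (scale parameter).
#' @slot n_clusters,n_obs Cluster and observation counts.
#' @slot converged Whether the estimating equations converged.
#' @slot model_label Free-text description of the model.
#' @export
setClass("GEEFit", representation(
  coefficients = "numeric", robust_se = "numeric", wald_z = "numeric",
  p_values = "numeric", vcov_robust = "matrix", corstr = "character",
  alpha = "numeric", scale = "numeric", n_clusters = "integer",
  n_obs = "integer", converged = "logical", model_label = "character"))

setValidity("GEEFit", function(object) {
  p <- length(object@coefficients)
  if (length(object@robust_se) != p || length(object@wald_z) != p ||
      length(object@p_values) != p)
    return("coefficient, SE, z and p vectors must have equal length")
  if (any(object@robust_se <= 0)) return("robust_se must be positive")
  if (any(object@p_values < 0 | object@p_values > 1))
    return("p_values must lie in [0, 1]")
  if (object@n_obs < object@n_clusters)
    return("n_obs must be at least n_clusters")
  TRUE
})

#' ROCCurve: an empirical receiver operating characteristic curve
#'
#' Operating points of an empirical ROC over all distinct-score midpoint
#' thresholds plus the two infinite endpoints, so the curve always contains
#' the (sensitivity 1, specificity 0) and (sensitivity 0, specificity 1)
#' corners. `orientation` records whether scores above (`higher_is_positive`)
#' or below (`lower_is_positive`) the threshold are called positive.
#'
#' @slot thresholds Sorted decision thresholds (including -Inf, Inf).
#' @slot sensitivity,specificity Operating characteristics per threshold.
#' @slot orientation `"higher_is_positive"` or `"lower_is_positive"`.
#' @slot n_positive,n_negative Class counts.
#' @export
setClass("ROCCurve", representation(
  thresholds = "numeric", sensitivity = "numeric", specificity = "numeric",
  orientation = "character", n_positive = "integer", n_negative = "integer"))

setValidity("ROCCurve", function(object) {
  k <- length(object@thresholds)
  if (length(object@sensitivity) != k || length(object@specificity) != k)
    return("thresholds, sensitivity and specificity must align")
  if (!object@orientation %in% c("higher_is_positive", "lower_is_positive"))
    return("invalid orientation")
  if (any(object@sensitivity < 0 | object@sensitivity > 1) ||
      any(object@specificity < 0 | object@specificity > 1))
    return("sensitivity and specificity must lie in [0, 1]")
  if (!any(object@sensitivity == 1 & object@specificity == 0) ||
      !any(object@sensitivity == 0 & object@specificity == 1))
    return("curve must include both trivial endpoints")
  TRUE
})
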
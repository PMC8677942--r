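.asBinaryLabels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (all(labels %in% c(0, 1))) return(labels == 1)
    if (all(labels %in% c(-1, 1))) return(labels == 1)
    stop("numeric labels must be 0/1 or -1/1")
  }
  labels <- as.character(labels)
  if (all(labels %in% c("ON_POS", "ON_NEG"))) return(labels == "ON_POS")
  stop("labels must be logical, 0/1, -1/1 or ON_POS/ON_NEG")
}

#' Keep one eye per subject
#'
#' For analyses that require independent observations, retains the right eye
#' (OD) of each subject, or the left eye (OS) when the subject contributed no
#' right eye. All rows of the retained eye (e.g. repeated recordings) are
#' kept.
#'
#' @param records `data.frame` with `subject_id` and `eye` columns (e.g. a
#'   feature table).
#' @return The filtered `data.frame`.
#' @export
selectOneEyePerSubject <- function(records) {
  stopifnot(all(c("subject_id", "eye") %in% colnames(records)))
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$subject_id),
                        function(idx) {
    eyes <- records$eye[idx]
    idx[eyes == if ("OD" %in% eyes) "OD" else "OS"]
  }), use.names = FALSE)
  records[sort(keep), , drop = FALSE]
}

#' Average features per eye
#'
#' Collapses a recording-level feature table to one row per (subject, eye),
#' averaging the numeric feature columns over recordings that passed QC (all
#' recordings when none passed). Metadata and covariates are taken from the
#' first row of each eye.
#'
#' @param features Feature table from [extractFeatures()].
#' @return Eye-level `data.frame`.
#' @export
summarizeFeaturesByEye <- function(features) {
  num_cols <- intersect(c("baseline_uv", "a_trough_time_ms", "a_trough_uv",
                          "b_peak_time_ms", "b_peak_uv", "a_amp_uv", "b_amp_uv",
                          "phnr72_uv", "phnr_trough_time_ms", "phnr_min_uv",
                          "p_ratio", "w_ratio"), colnames(features))
  eye_key <- paste(features$subject_id, features$eye, sep = ":")
  out <- lapply(split(seq_len(nrow(features)), factor(eye_key, unique(eye_key))),
                function(idx) {
    use <- if (!is.null(features$qc_pass) && any(features$qc_pass[idx]))
      idx[features$qc_pass[idx]] else idx
    row <- features[idx[1], , drop = FALSE]
    for (col in num_cols) row[[col]] <- mean(features[[col]][use], na.rm = TRUE)
    if (!is.null(row$qc_pass)) row$qc_pass <- any(features$qc_pass[idx])
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Empirical ROC curve
#'
#' Operating points over all midpoints between consecutive distinct scores,
#' plus the -Inf and +Inf endpoints, so the (1,0) and (0,1) corners are
#' always present. With `orientation = "higher_is_positive"` a case is called
#' positive when its score exceeds the threshold; `"lower_is_positive"`
#' reverses the comparison.
#'
#' @param scores Numeric classifier scores or feature values.
#' @param labels Case labels (logical, 0/1, -1/1 or `ON_POS`/`ON_NEG`).
#' @param orientation Score direction that indicates a positive case.
#' @return A [ROCCurve-class].
#' @export
rocCurve <- function(scores, labels,
                     orientation = c("higher_is_positive", "lower_is_positive")) {
  orientation <- match.arg(orientation)
  pos <- .asBinaryLabels(labels)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  if (!any(pos) || all(pos)) stop("both classes must be present")
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    call_pos <- if (orientation == "higher_is_positive") scores > thr[i]
                else scores < thr[i]
    sens[i] <- sum(call_pos & pos) / sum(pos)
    spec[i] <- sum(!call_pos & !pos) / sum(!pos)
  }
  if (orientation == "lower_is_positive") {
    # order so the threshold "tightens" along the vector
    ord <- order(thr, decreasing = TRUE)
    thr <- thr[ord]; sens <- sens[ord]; spec <- spec[ord]
  }
  new("ROCCurve", thresholds = thr, sensitivity = sens, specificity = spec,
      orientation = orientation, n_positive = sum(pos),
      n_negative = sum(!pos))
}

#' Trapezoidal area under an ROC curve
#'
#' @param curve A [ROCCurve-class].
#' @return AUC in `[0, 1]`.
#' @export
aucTrapezoid <- function(curve) {
  stopifnot(is(curve, "ROCCurve"))
  fpr <- 1 - curve@specificity
  tpr <- curve@sensitivity
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Youden-index optimal operating point
#'
#' Maximizes J = sensitivity + specificity - 1 over the curve's thresholds;
#' ties are broken by the smallest cutoff.
#'
#' @param curve A [ROCCurve-class].
#' @return List with `cutoff`, `j_statistic`, `sensitivity`, `specificity`.
#' @export
youdenOptimal <- function(curve) {
  stopifnot(is(curve, "ROCCurve"))
  j <- curve@sensitivity + curve@specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.min(curve@thresholds[best])]
  list(cutoff = curve@thresholds[best], j_statistic = j[best],
       sensitivity = curve@sensitivity[best],
       specificity = curve@specificity[best])
}

#' Confusion counts and metrics at a threshold
#'
#' Dichotomises scores at `cutoff` (positive call when the score is above the
#' cutoff for `higher_is_positive`, below it otherwise — the same convention
#' as [rocCurve()]) and returns the confusion counts with the derived
#' metrics in both the standard and the literal-definition variants (see
#' [metricsPaperVariant()]).
#'
#' @inheritParams rocCurve
#' @param cutoff Decision threshold.
#' @return List with `tp`, `tn`, `fp`, `fn`, `sensitivity`, `specificity`,
#'   `accuracy`, `precision_std`, `f1_std`, `precision_paper`,
#'   `recall_paper`, `f1_paper`.
#' @export
confusionFromThreshold <- function(scores, labels, cutoff,
                                   orientation = c("higher_is_positive",
                                                   "lower_is_positive")) {
  orientation <- match.arg(orientation)
  pos <- .asBinaryLabels(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  call_pos <- if (orientation == "higher_is_positive") scores > cutoff
              else scores < cutoff
  confusionFromCalls(call_pos, pos)
}

#' Confusion counts and metrics from predicted calls
#'
#' @param predicted Logical vector (or coercible via the same encodings as
#'   `labels`) of positive calls.
#' @param labels True labels.
#' @return As [confusionFromThreshold()].
#' @export
confusionFromCalls <- function(predicted, labels) {
  pos <- .asBinaryLabels(labels)
  call_pos <- .asBinaryLabels(predicted)
  tp <- sum(call_pos & pos); fn <- sum(!call_pos & pos)
  tn <- sum(!call_pos & !pos); fp <- sum(call_pos & !pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  pv <- metricsPaperVariant(tp, tn, fp, fn)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       precision_std = prec, f1_std = f1,
       precision_paper = pv$precision_paper, recall_paper = pv$recall_paper,
       f1_paper = pv$f1_paper)
}

#' Literal-definition classification metrics
#'
#' The study report that this package reproduces defines its metrics
#' literally as precision = TN/(TN+FP) (numerically the specificity),
#' recall = TP/(TP+FN) (numerically the sensitivity) and
#' F1 = precision x recall / (precision + recall) — without the conventional
#' factor of 2. These literal definitions are the only reading that
#' reproduces that report's printed F1 values, so they are provided as an
#' explicit "paper-variant" mode for reproduction; standard definitions are
#' always computed alongside (see [confusionFromCalls()]) and are the
#' default for new analyses. Note a perfect classifier scores `f1_paper =
#' 0.5`, which exposes the missing factor of 2.
#'
#' @param tp,tn,fp,fn Confusion counts.
#' @return List with `precision_paper`, `recall_paper`, `accuracy`,
#'   `f1_paper` (`NA` when a denominator is zero).
#' @examples
#' # sensitivity 0.61, specificity 0.63 -> literal F1 of 0.31
#' metricsPaperVariant(tp = 61, tn = 63, fp = 37, fn = 39)
#' @export
metricsPaperVariant <- function(tp, tn, fp, fn) {
  prec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    prec * rec / (prec + rec) else NA_real_
  list(precision_paper = prec, recall_paper = rec,
       accuracy = (tp + tn) / (tp + tn + fp + fn), f1_paper = f1)
}

#' Literal-definition F1 from sensitivity and specificity
#'
#' Convenience for the paper-variant F1 (see [metricsPaperVariant()]):
#' `specificity * sensitivity / (specificity + sensitivity)`.
#'
#' @param sensitivity,specificity Operating characteristics.
#' @return The literal-definition F1 score.
#' @export
paperF1 <- function(sensitivity, specificity) {
  specificity * sensitivity / (specificity + sensitivity)
}

#' Per-feature ROC evaluation of a feature table
#'
#' Runs the one-eye-per-subject ROC pipeline on each user-defined ERG
#' feature: eye-level averaging, optional severity restriction, orientation
#' chosen on the data so AUC >= 0.5 (recorded in the output), AUC, the
#' Youden-optimal cutoff and its sensitivity/specificity, and F1 in both
#' metric modes.
#'
#' @param features Recording-level feature table from [extractFeatures()].
#' @param one_eye_per_subject Apply [selectOneEyePerSubject()] (default
#'   TRUE).
#' @param severity_hvf_md_db If non-`NULL`, restrict positive (ON) eyes to
#'   those with Humphrey mean deviation below this bound (dB), e.g. -5 for
#'   severe disease; controls are kept.
#' @param qc_only Use QC-passing recordings only.
#' @return `data.frame` with one row per feature: `feature`, `orientation`,
#'   `auc`, `cutoff`, `youden_j`, `sensitivity`, `specificity`, `f1_paper`,
#'   `f1_std`, `n_positive`, `n_negative`.
#' @export
evaluateFeatureROC <- function(features, one_eye_per_subject = TRUE,
                               severity_hvf_md_db = NULL, qc_only = TRUE) {
  features <- .dropUnknown(features)
  if (qc_only && !is.null(features$qc_pass))
    features <- features[features$qc_pass, , drop = FALSE]
  eyes <- summarizeFeaturesByEye(features)
  if (one_eye_per_subject) eyes <- selectOneEyePerSubject(eyes)
  if (!is.null(severity_hvf_md_db))
    eyes <- eyes[eyes$label == "ON_NEG" |
                   (!is.na(eyes$hvf_md_db) & eyes$hvf_md_db < severity_hvf_md_db),
                 , drop = FALSE]
  out <- lapply(.ergFeatureNames, function(f) {
    col <- .featureColumn[[f]]
    if (!col %in% colnames(eyes)) return(NULL)
    ok <- !is.na(eyes[[col]])
    scores <- eyes[[col]][ok]; labels <- eyes$label[ok]
    curve <- rocCurve(scores, labels, "higher_is_positive")
    orientation <- "higher_is_positive"
    if (aucTrapezoid(curve) < 0.5) {
      curve <- rocCurve(scores, labels, "lower_is_positive")
      orientation <- "lower_is_positive"
    }
    yo <- youdenOptimal(curve)
    cm <- confusionFromThreshold(scores, labels, yo$cutoff, orientation)
    data.frame(feature = f, orientation = orientation,
               auc = aucTrapezoid(curve), cutoff = yo$cutoff,
               youden_j = yo$j_statistic, sensitivity = yo$sensitivity,
               specificity = yo$specificity, f1_paper = cm$f1_paper,
               f1_std = cm$f1_std, n_positive = curve@n_positive,
               n_negative = curve@n_negative, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
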
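.ergFeatureNames <- c("phnr_min", "phnr72", "p_ratio", "w_ratio")
.featureColumn <- c(phnr_min = "phnr_min_uv", phnr72 = "phnr72_uv",
                    p_ratio = "p_ratio", w_ratio = "w_ratio")

# keep labelled rows only; UNKNOWN labels never enter the statistics
.dropUnknown <- function(features) {
  if (is.null(features$label)) stop("features table must carry a 'label' column")
  unk <- features$label == "UNKNOWN"
  if (all(unk)) stop("all records are unlabeled (label UNKNOWN)")
  if (any(unk))
    warning(sprintf("excluding %d UNKNOWN-label record(s) from statistics",
                    sum(unk)))
  features[!unk, , drop = FALSE]
}

# Fit one feature ~ design GEE after listwise deletion, returning tidy rows.
.fitFeatureGEE <- function(features, feature, rhs_cols, corstr, label) {
  col <- .featureColumn[[feature]]
  keep <- complete.cases(features[, c(col, rhs_cols), drop = FALSE])
  dat <- features[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(dat[, rhs_cols, drop = FALSE]))
  fit <- fitLinearGEE(dat[[col]], X, dat$subject_id, corstr = corstr,
                      model_label = sprintf("%s ~ %s", feature,
                                            paste(rhs_cols, collapse = " + ")))
  .tidyGEE(fit, model = label, feature = feature)
}

#' Compare ERG features between optic-neuropathy and control eyes
#'
#' Fits, per feature (trough-averaged PhNR, fixed-latency PhNR, P-ratio,
#' W-ratio), a linear GEE of the feature on an optic-neuropathy indicator
#' (`on = 1` for `ON_POS` eyes), clustered by subject, optionally adjusted
#' for age. The `on` coefficient is the ON-minus-control difference; a
#' positive sign for the PhNR variants means the (negative) response is
#' attenuated in optic neuropathy.
#'
#' @param features Feature table from [extractFeatures()] (or any table with
#'   `subject_id`, `label`, the feature columns, and `age_years` when
#'   adjusting).
#' @param adjust_age Include age (years) as a covariate.
#' @param corstr Working correlation for the GEE.
#' @param qc_only Drop rows failing QC first (default TRUE when a `qc_pass`
#'   column is present).
#' @return Tidy `data.frame` with one row per model term: `model`, `feature`,
#'   `term`, `estimate`, `robust_se`, `z`, `p`, `n_obs`, `n_clusters`.
#' @export
compareOnVsControl <- function(features, adjust_age = FALSE,
                               corstr = c("exchangeable", "independence"),
                               qc_only = TRUE) {
  corstr <- match.arg(corstr)
  features <- .dropUnknown(features)
  if (qc_only && !is.null(features$qc_pass))
    features <- features[features$qc_pass, , drop = FALSE]
  features$on <- as.numeric(features$label == "ON_POS")
  rhs <- c("on", if (.assertFlag(adjust_age, "adjust_age")) "age_years")
  out <- lapply(.ergFeatureNames, function(f) {
    if (!.featureColumn[[f]] %in% colnames(features) ||
        all(is.na(features[[.featureColumn[[f]]]]))) {
      warning(sprintf("feature '%s' missing; skipped", f))
      return(NULL)
    }
    .fitFeatureGEE(features, f, rhs, corstr,
                   if (adjust_age) "on_vs_control_age_adjusted" else "on_vs_control")
  })
  do.call(rbind, out)
}

#' Compare ERG features between sources of control eyes
#'
#' Among control (`ON_NEG`) eyes, fits per feature two GEE contrasts
#' mirroring the study's control-source checks: fellow eyes of unilateral
#' optic-neuropathy subjects versus all other controls, and healthy controls
#' versus all other controls.
#'
#' @inheritParams compareOnVsControl
#' @return Tidy `data.frame` as in [compareOnVsControl()], with `model`
#'   identifying the contrast.
#' @export
compareControlSources <- function(features,
                                  corstr = c("exchangeable", "independence"),
                                  qc_only = TRUE) {
  corstr <- match.arg(corstr)
  features <- .dropUnknown(features)
  if (qc_only && !is.null(features$qc_pass))
    features <- features[features$qc_pass, , drop = FALSE]
  ctrl <- features[features$label == "ON_NEG", , drop = FALSE]
  if (length(unique(ctrl$eye_class)) < 2)
    stop("control-source comparison needs at least 2 control eye classes")
  ctrl$fellow <- as.numeric(ctrl$eye_class == "control_fellow")
  ctrl$healthy <- as.numeric(ctrl$eye_class == "control_healthy")
  out <- lapply(.ergFeatureNames, function(f) {
    if (!.featureColumn[[f]] %in% colnames(ctrl)) return(NULL)
    rbind(.fitFeatureGEE(ctrl, f, "fellow", corstr, "fellow_vs_other_controls"),
          .fitFeatureGEE(ctrl, f, "healthy", corstr, "healthy_vs_other_controls"))
  })
  do.call(rbind, out)
}

#' Structure-function models of ERG features
#'
#' Linear GEE of each feature on a structural or functional measure of the
#' optic nerve: Humphrey visual field mean deviation (`hvf_md`), retinal
#' nerve fibre layer thickness (`rnfl`) or ganglion cell + inner plexiform
#' layer thickness (`gclipl`), with listwise deletion of missing predictor
#' values. For the OCT predictors the fit is restricted to control and
#' chronic optic-neuropathy eyes, because acute disc swelling inflates the
#' structural measures.
#'
#' @inheritParams compareOnVsControl
#' @param predictor One of `"hvf_md"`, `"rnfl"`, `"gclipl"`.
#' @param exclude_acute Drop `on_acute` eyes (default TRUE for the OCT
#'   predictors, FALSE for `hvf_md`).
#' @param min_eyes Minimum number of eyes with a non-missing predictor.
#' @return Tidy `data.frame` as in [compareOnVsControl()].
#' @export
structureFunctionModels <- function(features,
                                    predictor = c("hvf_md", "rnfl", "gclipl"),
                                    exclude_acute = NULL,
                                    corstr = c("exchangeable", "independence"),
                                    qc_only = TRUE, min_eyes = 10L) {
  predictor <- match.arg(predictor)
  corstr <- match.arg(corstr)
  pcol <- c(hvf_md = "hvf_md_db", rnfl = "rnfl_um", gclipl = "gclipl_um")[[predictor]]
  exclude_acute <- exclude_acute %||% (predictor %in% c("rnfl", "gclipl"))
  features <- .dropUnknown(features)
  if (qc_only && !is.null(features$qc_pass))
    features <- features[features$qc_pass, , drop = FALSE]
  if (exclude_acute)
    features <- features[features$eye_class != "on_acute", , drop = FALSE]
  if (nrow(features) == 0) stop("empty subset after filtering")
  n_pred <- length(unique(paste(features$subject_id, features$eye)[
    !is.na(features[[pcol]])]))
  if (n_pred < min_eyes)
    stop(sprintf("predictor '%s' available for only %d eyes (< %d)",
                 predictor, n_pred, min_eyes))
  features$predictor <- features[[pcol]]
  out <- lapply(.ergFeatureNames, function(f) {
    if (!.featureColumn[[f]] %in% colnames(features)) return(NULL)
    .fitFeatureGEE(features, f, "predictor", corstr,
                   sprintf("structure_function_%s", predictor))
  })
  do.call(rbind, out)
}
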
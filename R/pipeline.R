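.pipelineDefaults <- function() {
  list(stages = c("simulate", "extract", "stats", "roc", "tsc"),
       seed = 1L, output_dir = "ergdx-run",
       cohort = list(), extraction = list(),
       stats = list(adjust_age = FALSE, corstr = "exchangeable"),
       roc = list(one_eye_per_subject = TRUE, severity_hvf_md_db = NULL),
       tsc = list(kinds = c("nn_dtw", "svm_linear", "svm_rbf", "rf", "gb", "tsf"),
                  fractions = c(train = 0.44, validation = 0.27, test = 0.29),
                  tolerance = 0.05, lstm_epochs = 100L),
       waveforms_csv = NULL)
}

#' Parse a pipeline configuration
#'
#' Reads a YAML file (or takes a list) of pipeline settings, fills defaults
#' and rejects unknown keys by name. An empty file yields the full default
#' configuration. The resolved configuration is serializable and is written
#' alongside a run's outputs, so a run can be reproduced from its artifacts.
#'
#' @param path YAML file path, or a named list of settings.
#' @return A list of class `"PipelineConfig"`.
#' @export
parsePipelineConfig <- function(path = NULL) {
  user <- if (is.null(path)) list()
          else if (is.list(path)) path
          else yaml::read_yaml(path) %||% list()
  def <- .pipelineDefaults()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (grp in c("cohort", "extraction", "stats", "roc", "tsc")) {
    if (!is.null(user[[grp]])) {
      known <- switch(grp,
        cohort = names(formals(cohortSpec)),
        extraction = names(formals(extractionConfig)),
        names(def[[grp]]))
      bad <- setdiff(names(user[[grp]]), known)
      if (length(bad))
        stop(sprintf("unknown key(s) under '%s': %s", grp,
                     paste(bad, collapse = ", ")))
      if (grp %in% c("stats", "roc", "tsc"))
        user[[grp]] <- utils::modifyList(def[[grp]], user[[grp]],
                                         keep.null = TRUE)
    }
  }
  cfg <- utils::modifyList(def, user, keep.null = TRUE)
  cfg$stages <- as.character(unlist(cfg$stages))
  cfg$tsc$kinds <- as.character(unlist(cfg$tsc$kinds))
  cfg$tsc$fractions <- unlist(cfg$tsc$fractions)
  if (length(cfg$tsc$fractions) != 3)
    stop("tsc fractions must have 3 entries (train, validation, test)")
  names(cfg$tsc$fractions) <- c("train", "validation", "test")
  bad_stage <- setdiff(cfg$stages, c("simulate", "extract", "stats", "roc", "tsc"))
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  cfg$seed <- .assertCount(cfg$seed, "seed")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in order — simulate (synthetic cohort),
#' extract (user-defined features), stats (GEE group comparisons), roc
#' (per-feature diagnostic evaluation), tsc (time-series classification
#' benchmark) — writing one CSV per stage into `output_dir`, together with
#' the resolved configuration (`config.yaml`) and a run log recording
#' package version, seeds, row counts and the QC exclusion list. When
#' `simulate` is disabled, waveforms are read from `waveforms_csv`; a stage
#' whose upstream artifact is missing raises an error. The global seed fans
#' out to per-stage seeds by fixed offsets so stages are independently
#' reproducible.
#'
#' @param config A `"PipelineConfig"` from [parsePipelineConfig()] (or a
#'   list/path accepted by it).
#' @param force Overwrite an existing output directory.
#' @return The output directory, invisibly.
#' @export
runPipeline <- function(config = parsePipelineConfig(), force = FALSE) {
  if (!inherits(config, "PipelineConfig")) config <- parsePipelineConfig(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$output_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logfile,
                               append = TRUE)
  if (file.exists(logfile) && !force)
    stop("output directory already holds a run; use force = TRUE to overwrite")
  cat("", file = logfile)
  yaml::write_yaml(unclass(config), file.path(config$output_dir, "config.yaml"))
  logline("ERGdx %s | seed %d | %s", as.character(packageVersion("ERGdx")),
          config$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  stage_seed <- function(offset) config$seed + offset

  paths <- list(waveforms = file.path(config$output_dir, "waveforms.csv"),
                truth = file.path(config$output_dir, "truth.csv"),
                features = file.path(config$output_dir, "features.csv"),
                stats = file.path(config$output_dir, "stats.csv"),
                roc = file.path(config$output_dir, "roc.csv"),
                tsc = file.path(config$output_dir, "tsc_report.csv"))
  writeCsv <- function(d, p) {
    utils::write.csv(d, p, row.names = FALSE)
    logline("wrote %s (%d rows)", basename(p), nrow(d))
  }

  if ("simulate" %in% config$stages) {
    spec <- do.call(cohortSpec, utils::modifyList(config$cohort,
                                                  list(seed = stage_seed(101L))))
    sim <- simulateCohort(spec)
    writeWaveformCSV(sim$records, paths$waveforms)
    logline("wrote %s (%d recordings)", basename(paths$waveforms),
            ncol(sim$records))
    writeCsv(sim$truth, paths$truth)
  }
  needWaveforms <- function() {
    src <- if (file.exists(paths$waveforms)) paths$waveforms
           else config$waveforms_csv
    if (is.null(src) || !file.exists(src))
      stop("no waveforms available: enable the simulate stage or set waveforms_csv")
    readWaveformCSV(src)
  }
  if ("extract" %in% config$stages) {
    records <- needWaveforms()
    ecfg <- do.call(extractionConfig, config$extraction)
    feats <- extractFeatures(records, ecfg)
    writeCsv(feats, paths$features)
    excl <- feats[!feats$qc_pass, ]
    logline("QC excluded %d recording(s)%s", nrow(excl),
            if (nrow(excl)) paste0(": ", paste(
              .recordId(excl$subject_id, excl$eye, excl$visit_index,
                        excl$recording_index), collapse = ", ")) else "")
  }
  needFeatures <- function() {
    if (!file.exists(paths$features))
      stop("missing upstream artifact features.csv: enable the extract stage")
    read.csv(paths$features, stringsAsFactors = FALSE)
  }
  if ("stats" %in% config$stages) {
    feats <- needFeatures()
    res <- rbind(compareOnVsControl(feats, adjust_age = config$stats$adjust_age,
                                    corstr = config$stats$corstr),
                 tryCatch(compareControlSources(feats,
                                                corstr = config$stats$corstr),
                          error = function(e) {
                            logline("control-source comparison skipped: %s",
                                    conditionMessage(e)); NULL
                          }))
    writeCsv(res, paths$stats)
  }
  if ("roc" %in% config$stages) {
    feats <- needFeatures()
    writeCsv(evaluateFeatureROC(
      feats, one_eye_per_subject = config$roc$one_eye_per_subject,
      severity_hvf_md_db = config$roc$severity_hvf_md_db), paths$roc)
  }
  if ("tsc" %in% config$stages) {
    records <- needWaveforms()
    keep <- recordLabels(records) != "UNKNOWN"
    records <- records[, keep]
    configs <- lapply(config$tsc$kinds, function(k)
      if (k == "lstm")
        classifierConfig(k, seed = stage_seed(404L),
                         lstm = list(n_epochs = config$tsc$lstm_epochs))
      else classifierConfig(k, seed = stage_seed(404L)))
    rep <- runBenchmark(records, configs, split_seed = stage_seed(303L),
                        fractions = unlist(config$tsc$fractions),
                        tolerance = config$tsc$tolerance)
    writeCsv(rep$results, paths$tsc)
  }
  logline("pipeline complete")
  invisible(config$output_dir)
}
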
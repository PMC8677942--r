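#' Configuration for user-defined ERG feature extraction
#'
#' @param phnr_fixed_latency_ms Fixed PhNR latency after the stimulus (ms).
#' @param trough_window_halfwidth_ms Half-width of the PhNR trough search
#'   window around the fixed latency (ms).
#' @param trough_average_points Odd number of consecutive samples averaged at
#'   the trough (11 samples span ~5.63 ms at the default grid).
#' @param b_peak_search_window_ms Post-stimulus window (relative to the
#'   stimulus, ms) searched for the b-wave peak. The search is restricted so
#'   that pre-stimulus artifacts cannot be selected as the "maximum
#'   potential".
#' @param ratio_phnr_variant Which PhNR variant enters the P- and W-ratios:
#'   `"phnr_min"` (trough-averaged, the primary variant) or `"phnr72"`.
#' @param detrend `"full_record"` fits the least-squares line over the whole
#'   record (default); `"prestimulus"` fits it over pre-stimulus samples only.
#' @param qc_prominence_sd b-wave amplitude must exceed this multiple of the
#'   pre-stimulus standard deviation, otherwise the record fails QC with
#'   "no defined b-wave peak".
#' @param qc_min_b_amp_uv Absolute floor (µV) on the b-wave amplitude for the
#'   same rule, so drift-only records with negligible pre-stimulus variance
#'   are still rejected.
#' @param qc_amplitude_bound_uv Any detrended |sample| above this bound (µV)
#'   fails QC.
#' @param qc_exclude_ids Record identifiers (`"subject:eye:vX:rY"`) excluded
#'   by manual review, honoured as QC failures.
#' @return A list of class `"ExtractionConfig"`.
#' @export
extractionConfig <- function(phnr_fixed_latency_ms = 72,
                             trough_window_halfwidth_ms = 10,
                             trough_average_points = 11L,
                             b_peak_search_window_ms = c(0, 150),
                             ratio_phnr_variant = c("phnr_min", "phnr72"),
                             detrend = c("full_record", "prestimulus"),
                             qc_prominence_sd = 2,
                             qc_min_b_amp_uv = 0.5,
                             qc_amplitude_bound_uv = 200,
                             qc_exclude_ids = character()) {
  trough_average_points <- .assertCount(trough_average_points,
                                        "trough_average_points", lower = 1L)
  if (trough_average_points %% 2L == 0L)
    stop("trough_average_points must be odd")
  .assertNumber(trough_window_halfwidth_ms, "trough_window_halfwidth_ms",
                lower = 1e-9)
  stopifnot(length(b_peak_search_window_ms) == 2,
            b_peak_search_window_ms[1] < b_peak_search_window_ms[2])
  cfg <- list(phnr_fixed_latency_ms = .assertNumber(phnr_fixed_latency_ms,
                                                    "phnr_fixed_latency_ms", 0),
              trough_window_halfwidth_ms = trough_window_halfwidth_ms,
              trough_average_points = trough_average_points,
              b_peak_search_window_ms = as.numeric(b_peak_search_window_ms),
              ratio_phnr_variant = match.arg(ratio_phnr_variant),
              detrend = match.arg(detrend),
              qc_prominence_sd = .assertNumber(qc_prominence_sd,
                                               "qc_prominence_sd", 0),
              qc_min_b_amp_uv = .assertNumber(qc_min_b_amp_uv,
                                              "qc_min_b_amp_uv", 0),
              qc_amplitude_bound_uv = .assertNumber(qc_amplitude_bound_uv,
                                                    "qc_amplitude_bound_uv", 0),
              qc_exclude_ids = as.character(qc_exclude_ids))
  class(cfg) <- "ExtractionConfig"
  cfg
}

#' Remove the least-squares linear trend from a waveform
#'
#' Subtracts the ordinary-least-squares line (intercept and slope in sample
#' index) fitted over the entire record, so steady upward or downward drifts
#' are removed. The residual has zero mean and zero OLS slope.
#'
#' @param samples Numeric vector of potentials (µV), at least 2 values.
#' @return Detrended samples.
#' @export
detrendLinear <- function(samples) {
  n <- length(samples)
  if (n < 2) stop("detrendLinear needs at least 2 samples")
  i <- seq_len(n)
  ic <- i - mean(i)
  slope <- sum(ic * samples) / sum(ic * ic)
  samples - mean(samples) - slope * ic
}

# Detrend using only pre-stimulus samples for the line fit (config option).
.detrendPrestim <- function(samples, pre_idx) {
  if (length(pre_idx) < 2) stop("prestimulus detrend needs >= 2 pre-stimulus samples")
  i <- seq_along(samples)
  fit <- lm.fit(cbind(1, i[pre_idx]), samples[pre_idx])
  samples - (fit$coefficients[1] + fit$coefficients[2] * i)
}

#' Pre-stimulus baseline potential
#'
#' Arithmetic mean of all samples strictly before the stimulus time (for the
#' default protocol, the first 100 ms of the record).
#'
#' @param samples Detrended potentials (µV).
#' @param stimulus_time_ms Flash time (ms).
#' @param duration_ms Record duration (ms).
#' @return Baseline potential (µV).
#' @export
computeBaseline <- function(samples, stimulus_time_ms = 100, duration_ms = 220) {
  t <- timeOfSample(seq_along(samples) - 1L, duration_ms, length(samples))
  pre <- t < stimulus_time_ms - 1e-9
  if (!any(pre)) stop("no pre-stimulus samples: cannot compute baseline")
  mean(samples[pre])
}

#' Locate the b-wave peak
#'
#' Maximum potential within the configured post-stimulus search window
#' (default stimulus to stimulus + 150 ms); ties are broken by the earliest
#' time.
#'
#' @inheritParams computeBaseline
#' @param config An [extractionConfig()].
#' @return List with `time_ms` and `potential_uv`.
#' @export
findBPeak <- function(samples, stimulus_time_ms = 100, duration_ms = 220,
                      config = extractionConfig()) {
  t <- timeOfSample(seq_along(samples) - 1L, duration_ms, length(samples))
  win <- stimulus_time_ms + config$b_peak_search_window_ms
  idx <- which(t >= win[1] - 1e-9 & t <= win[2] + 1e-9)
  if (!length(idx)) stop("empty b-peak search window")
  j <- idx[which.max(samples[idx])]
  list(time_ms = t[j], potential_uv = samples[j])
}

#' Locate the a-wave trough
#'
#' Minimum potential between the stimulus and the b-wave peak (both ends
#' inclusive); ties are broken by the earliest time.
#'
#' @inheritParams computeBaseline
#' @param b_peak_time_ms Time of the b-wave peak (ms).
#' @return List with `time_ms` and `potential_uv`.
#' @export
findATrough <- function(samples, b_peak_time_ms, stimulus_time_ms = 100,
                        duration_ms = 220) {
  if (b_peak_time_ms <= stimulus_time_ms)
    stop("b-peak time must be after the stimulus")
  t <- timeOfSample(seq_along(samples) - 1L, duration_ms, length(samples))
  idx <- which(t >= stimulus_time_ms - 1e-9 & t <= b_peak_time_ms + 1e-9)
  j <- idx[which.min(samples[idx])]
  list(time_ms = t[j], potential_uv = samples[j])
}

#' Fixed-latency PhNR amplitude
#'
#' Signed amplitude at a fixed latency after the stimulus (default 72 ms):
#' the potential at the nearest sample minus the baseline. Negative when the
#' waveform lies below baseline, matching the sign convention in which group
#' means of the PhNR are negative. A single sample is read; no interpolation.
#'
#' @inheritParams computeBaseline
#' @param baseline_uv Baseline potential (µV).
#' @param latency_ms Latency after the stimulus (ms).
#' @return Signed amplitude (µV).
#' @export
phnrFixedLatency <- function(samples, baseline_uv, stimulus_time_ms = 100,
                             duration_ms = 220, latency_ms = 72) {
  t_target <- stimulus_time_ms + latency_ms
  if (t_target > duration_ms)
    stop("fixed PhNR latency beyond the end of the record")
  i <- sampleAtTime(t_target, duration_ms, length(samples))
  samples[i + 1L] - baseline_uv
}

#' Trough-averaged PhNR amplitude
#'
#' Finds the minimum potential within ±`trough_window_halfwidth_ms` of the
#' fixed latency (default 72 ± 10 ms after the stimulus, bounds inclusive,
#' ties to the earliest sample), then averages `trough_average_points`
#' consecutive samples (default 11, ~5.63 ms) centred on that trough and
#' subtracts the baseline. If the averaging span would run past the record
#' it is clipped and flagged.
#'
#' @inheritParams phnrFixedLatency
#' @param config An [extractionConfig()].
#' @return List with `trough_time_ms`, `phnr_min_uv` (signed) and
#'   `clipped` (logical; averaging window truncated at a record boundary).
#' @export
phnrTrough <- function(samples, baseline_uv, stimulus_time_ms = 100,
                       duration_ms = 220, config = extractionConfig()) {
  t <- timeOfSample(seq_along(samples) - 1L, duration_ms, length(samples))
  lo <- stimulus_time_ms + config$phnr_fixed_latency_ms -
    config$trough_window_halfwidth_ms
  hi <- stimulus_time_ms + config$phnr_fixed_latency_ms +
    config$trough_window_halfwidth_ms
  if (lo < 0 || hi > duration_ms)
    stop("PhNR trough window falls outside the record")
  idx <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
  if (!length(idx)) stop("PhNR trough window contains no samples")
  j <- idx[which.min(samples[idx])]
  half <- (config$trough_average_points - 1L) %/% 2L
  span <- (j - half):(j + half)
  clipped <- any(span < 1L | span > length(samples))
  span <- span[span >= 1L & span <= length(samples)]
  list(trough_time_ms = t[j],
       phnr_min_uv = mean(samples[span]) - baseline_uv,
       clipped = clipped)
}

#' PhNR normalisation ratios
#'
#' `p_ratio = -phnr / b_amp` and `w_ratio = (b_amp - phnr) / (b_amp - a_amp)`
#' with signed inputs (a-wave amplitude and PhNR are negative for waveforms
#' below baseline). Undefined ratios (non-positive b-wave amplitude, or
#' `b_amp == a_amp` for the W-ratio) are returned as `NA` and flagged.
#'
#' @param a_amp_uv Signed a-wave amplitude (trough minus baseline), µV.
#' @param b_amp_uv b-wave amplitude (peak minus a-trough), µV.
#' @param phnr_uv Signed PhNR amplitude, µV.
#' @return List with `p_ratio`, `w_ratio`, `defined` (logical).
#' @examples
#' computeRatios(a_amp_uv = -3, b_amp_uv = 10, phnr_uv = -2)
#' @export
computeRatios <- function(a_amp_uv, b_amp_uv, phnr_uv) {
  if (is.na(b_amp_uv) || b_amp_uv <= 0)
    return(list(p_ratio = NA_real_, w_ratio = NA_real_, defined = FALSE))
  p <- -phnr_uv / b_amp_uv
  if (b_amp_uv == a_amp_uv)
    return(list(p_ratio = p, w_ratio = NA_real_, defined = FALSE))
  list(p_ratio = p, w_ratio = (b_amp_uv - phnr_uv) / (b_amp_uv - a_amp_uv),
       defined = TRUE)
}

#' Automated waveform quality control
#'
#' Automates the manual exclusion of outlier tracings and tracings without a
#' defined b-wave: a record fails when (a) the b-wave amplitude does not
#' exceed `qc_prominence_sd` times the pre-stimulus standard deviation
#' ("no defined b-wave peak"), (b) any detrended sample magnitude exceeds
#' `qc_amplitude_bound_uv` ("amplitude bound exceeded"), (c) the PhNR
#' averaging window was clipped at a record boundary, or (d) the record is on
#' the manual exclusion list. All violated rules are reported.
#'
#' @param detrended Detrended samples (µV).
#' @param b_amp_uv b-wave amplitude (µV).
#' @param clipped Whether the trough-averaging window was clipped.
#' @param ratios_defined Whether the P-/W-ratios were defined.
#' @inheritParams computeBaseline
#' @param config An [extractionConfig()].
#' @param record_id Record identifier checked against the exclusion list.
#' @return List with `qc_pass` and `qc_reasons` (character vector).
#' @export
qcWaveform <- function(detrended, b_amp_uv, clipped, ratios_defined,
                       stimulus_time_ms = 100, duration_ms = 220,
                       config = extractionConfig(), record_id = NA_character_) {
  reasons <- character()
  t <- timeOfSample(seq_along(detrended) - 1L, duration_ms, length(detrended))
  pre <- detrended[t < stimulus_time_ms - 1e-9]
  pre_sd <- if (length(pre) > 1) sd(pre) else 0
  if (is.na(b_amp_uv) ||
      b_amp_uv <= max(config$qc_prominence_sd * pre_sd, config$qc_min_b_amp_uv))
    reasons <- c(reasons, "no defined b-wave peak")
  if (any(abs(detrended) > config$qc_amplitude_bound_uv))
    reasons <- c(reasons, "amplitude bound exceeded")
  if (isTRUE(clipped))
    reasons <- c(reasons, "phnr averaging window clipped")
  if (!isTRUE(ratios_defined))
    reasons <- c(reasons, "ratios undefined")
  if (!is.na(record_id) && record_id %in% config$qc_exclude_ids)
    reasons <- c(reasons, "manual exclusion")
  list(qc_pass = length(reasons) == 0L, qc_reasons = reasons)
}

#' Snellen visual acuity to logMAR
#'
#' Snellen fractions `"20/X"` convert as `log10(X/20)` (metric `"6/X"` as
#' `log10(X/6)`); the non-numeric acuities count fingers, hand motions and no
#' light perception are assigned logMAR 2, 3 and 6.
#'
#' @param acuity Character vector of acuities (`"20/40"`, `"6/12"`, `"CF"`,
#'   `"HM"`, `"NLP"`).
#' @return Numeric logMAR values.
#' @examples
#' logmarFromAcuity(c("20/20", "20/200", "CF"))
#' @export
logmarFromAcuity <- function(acuity) {
  vapply(as.character(acuity), function(a) {
    a0 <- toupper(trimws(a))
    if (a0 %in% c("CF", "HM", "NLP"))
      return(c(CF = 2, HM = 3, NLP = 6)[[a0]])
    m <- regmatches(a0, regexec("^(20|6)\\s*/\\s*([0-9.]+)$", a0))[[1]]
    if (length(m) != 3) stop("unparseable acuity: '", a, "'")
    log10(as.numeric(m[3]) / as.numeric(m[2]))
  }, numeric(1), USE.NAMES = FALSE)
}

# Feature extraction for a single numeric waveform; internal workhorse.
.extractOne <- function(samples, stimulus_time_ms, duration_ms, config,
                        record_id = NA_character_) {
  t_all <- timeOfSample(seq_along(samples) - 1L, duration_ms, length(samples))
  detr <- if (config$detrend == "full_record") detrendLinear(samples)
          else .detrendPrestim(samples, which(t_all < stimulus_time_ms - 1e-9))
  baseline <- computeBaseline(detr, stimulus_time_ms, duration_ms)
  bp <- findBPeak(detr, stimulus_time_ms, duration_ms, config)
  at <- findATrough(detr, bp$time_ms, stimulus_time_ms, duration_ms)
  a_amp <- at$potential_uv - baseline
  b_amp <- bp$potential_uv - at$potential_uv
  phnr72 <- phnrFixedLatency(detr, baseline, stimulus_time_ms, duration_ms,
                             config$phnr_fixed_latency_ms)
  tr <- phnrTrough(detr, baseline, stimulus_time_ms, duration_ms, config)
  phnr_used <- if (config$ratio_phnr_variant == "phnr_min") tr$phnr_min_uv
               else phnr72
  ratios <- computeRatios(a_amp, b_amp, phnr_used)
  qc <- qcWaveform(detr, b_amp, tr$clipped, ratios$defined,
                   stimulus_time_ms, duration_ms, config, record_id)
  data.frame(baseline_uv = baseline,
             a_trough_time_ms = at$time_ms, a_trough_uv = at$potential_uv,
             b_peak_time_ms = bp$time_ms, b_peak_uv = bp$potential_uv,
             a_amp_uv = a_amp, b_amp_uv = b_amp,
             phnr72_uv = phnr72,
             phnr_trough_time_ms = tr$trough_time_ms,
             phnr_min_uv = tr$phnr_min_uv,
             p_ratio = ratios$p_ratio, w_ratio = ratios$w_ratio,
             qc_pass = qc$qc_pass,
             qc_reasons = paste(qc$qc_reasons, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Extract user-defined ERG features from a cohort
#'
#' Applies, per recording and in order: linear detrend, pre-stimulus
#' baseline, b-wave peak, a-wave trough, fixed-latency PhNR, trough-averaged
#' PhNR, P-/W-ratios, and automated QC — all on the detrended trace.
#' Amplitudes are signed: `a_amp_uv` and the PhNR variants are value minus
#' baseline (negative below baseline), `b_amp_uv` is b-peak minus a-trough.
#'
#' @param x An [ERGRecordingSet-class].
#' @param config An [extractionConfig()].
#' @return `data.frame`, one row per recording (order preserved), with the
#'   record identity, label, covariates, all feature fields, `qc_pass` and
#'   semicolon-joined `qc_reasons`.
#' @export
extractFeatures <- function(x, config = extractionConfig()) {
  stopifnot(is(x, "ERGRecordingSet"))
  cd <- as.data.frame(recordInfo(x))
  uv <- potentials(x)
  feats <- lapply(seq_len(ncol(uv)), function(j) {
    id <- colnames(uv)[j]
    f <- tryCatch(
      .extractOne(uv[, j], cd$stimulus_time_ms[j], cd$duration_ms[j], config, id),
      error = function(e) stop(sprintf("record %s: %s", id, conditionMessage(e)),
                               call. = FALSE))
    f
  })
  out <- cbind(cd[, c("subject_id", "eye", "visit_index", "recording_index",
                      "label", "eye_class", .covariateCols)],
               do.call(rbind, feats))
  rownames(out) <- NULL
  out
}
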
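#' Waveform component parameters for the synthetic ERG model
#'
#' The synthetic photopic ERG is a sum of three bell-shaped (Gaussian)
#' post-stimulus components — a negative a-wave, a positive b-wave, and a
#' slow negative late response (the PhNR) — plus a baseline offset, a linear
#' drift and white noise. Latencies are relative to the stimulus and must be
#' ordered a < b < PhNR. Real ERG components are asymmetric, but the feature
#' extractor only uses extrema, means and latencies, so symmetric pulses
#' suffice for validation; `skew` (per component, in (-1, 1)) exposes a
#' skewed-pulse option.
#'
#' @param a_amp_uv Non-positive a-wave component amplitude (µV).
#' @param a_latency_ms,a_width_ms a-wave centre (post-stimulus) and width.
#' @param b_amp_uv Positive b-wave component amplitude (µV).
#' @param b_latency_ms,b_width_ms b-wave centre and width.
#' @param phnr_uv Non-positive PhNR component amplitude (µV).
#' @param phnr_latency_ms,phnr_width_ms PhNR centre and width (slow
#'   component).
#' @param drift_slope_uv_per_ms Linear baseline drift.
#' @param baseline_offset_uv Constant offset.
#' @param noise_sd_uv White-noise standard deviation.
#' @param skew Common skewness parameter for the pulses (0 = symmetric).
#' @return A list of class `"WaveformParams"`.
#' @export
waveformParams <- function(a_amp_uv = -2, a_latency_ms = 15, a_width_ms = 4,
                           b_amp_uv = 10, b_latency_ms = 32, b_width_ms = 9,
                           phnr_uv = -3.7, phnr_latency_ms = 72,
                           phnr_width_ms = 25, drift_slope_uv_per_ms = 0,
                           baseline_offset_uv = 0, noise_sd_uv = 0,
                           skew = 0) {
  if (a_amp_uv > 0 || phnr_uv > 0) stop("a-wave and PhNR amplitudes are non-positive")
  if (b_amp_uv <= 0) stop("b-wave amplitude must be positive")
  if (!(a_latency_ms < b_latency_ms && b_latency_ms < phnr_latency_ms))
    stop("latencies must be ordered a < b < phnr")
  stopifnot(a_width_ms > 0, b_width_ms > 0, phnr_width_ms > 0,
            noise_sd_uv >= 0, abs(skew) < 1)
  structure(list(a_amp_uv = a_amp_uv, a_latency_ms = a_latency_ms,
                 a_width_ms = a_width_ms, b_amp_uv = b_amp_uv,
                 b_latency_ms = b_latency_ms, b_width_ms = b_width_ms,
                 phnr_uv = phnr_uv, phnr_latency_ms = phnr_latency_ms,
                 phnr_width_ms = phnr_width_ms,
                 drift_slope_uv_per_ms = drift_slope_uv_per_ms,
                 baseline_offset_uv = baseline_offset_uv,
                 noise_sd_uv = noise_sd_uv, skew = skew),
            class = "WaveformParams")
}

#' Bell-shaped component pulse
#'
#' `amplitude * exp(-(t - center)^2 / (2 width^2))`, optionally skewed by
#' making the width `width * (1 + skew)` right of the centre and
#' `width * (1 - skew)` left of it.
#'
#' @param t_ms Time(s), ms.
#' @param amplitude Peak amplitude (µV), reached exactly at the centre.
#' @param center_ms Pulse centre (ms).
#' @param width_ms Pulse width (ms, > 0).
#' @param skew Skewness in (-1, 1); 0 is symmetric.
#' @return Pulse value(s), µV.
#' @export
componentPulse <- function(t_ms, amplitude, center_ms, width_ms, skew = 0) {
  stopifnot(width_ms > 0, abs(skew) < 1)
  w <- width_ms * (1 + skew * sign(t_ms - center_ms))
  amplitude * exp(-(t_ms - center_ms)^2 / (2 * w^2))
}

# clean component waveform (no offset/drift/noise) at arbitrary times;
# components are gated to zero before the stimulus
.cleanWaveform <- function(params, t_ms, stimulus_time_ms) {
  post <- t_ms >= stimulus_time_ms
  v <- numeric(length(t_ms))
  v[post] <-
    componentPulse(t_ms[post], params$a_amp_uv,
                   stimulus_time_ms + params$a_latency_ms, params$a_width_ms,
                   params$skew) +
    componentPulse(t_ms[post], params$b_amp_uv,
                   stimulus_time_ms + params$b_latency_ms, params$b_width_ms,
                   params$skew) +
    componentPulse(t_ms[post], params$phnr_uv,
                   stimulus_time_ms + params$phnr_latency_ms,
                   params$phnr_width_ms, params$skew)
  v
}

#' Simulate one averaged ERG waveform
#'
#' Sum of the three post-stimulus components (zero before the stimulus),
#' plus baseline offset, linear drift and white noise, sampled on the
#' uniform recording grid. Uses the current R random-number state for the
#' noise.
#'
#' @param params A [waveformParams()].
#' @param n_samples,duration_ms,stimulus_time_ms Recording geometry.
#' @return List with `samples` (µV) and `params` (the ground truth echoed).
#' @export
simulateWaveform <- function(params, n_samples = 430L, duration_ms = 220,
                             stimulus_time_ms = 100) {
  stopifnot(inherits(params, "WaveformParams"))
  t <- timeOfSample(seq_len(n_samples) - 1L, duration_ms, n_samples)
  v <- .cleanWaveform(params, t, stimulus_time_ms) +
    params$baseline_offset_uv + params$drift_slope_uv_per_ms * t +
    rnorm(n_samples, 0, params$noise_sd_uv)
  list(samples = v, params = params)
}

#' Planted (ground-truth) features of a clean waveform
#'
#' Features of the continuous noiseless drift-free waveform, evaluated on a
#' fine grid (default 0.02 ms) through the same mathematical definitions as
#' the extractor — full-record linear detrend, pre-stimulus baseline, b-wave
#' peak, a-wave trough, fixed-latency PhNR, and the trough-average over the
#' same ~5.6 ms span that 11 samples cover on the recording grid. Extraction
#' from the sampled waveform then differs from these planted values only
#' through discretization, noise and drift, which is what recovery reports
#' quantify. Note these planted features are not the raw component
#' amplitudes: detrending and pulse overlap shrink them (e.g. the planted
#' PhNR trough amplitude is smaller in magnitude than `phnr_uv`).
#'
#' @param params A [waveformParams()].
#' @param n_samples,duration_ms,stimulus_time_ms Recording geometry (used
#'   for the trough-average span and window definitions).
#' @param config An [extractionConfig()].
#' @param fine_dt_ms Fine grid step (ms).
#' @return One-row `data.frame` of planted feature values (column names as
#'   in [extractFeatures()], prefixed `planted_`).
#' @export
plantedFeatures <- function(params, n_samples = 430L, duration_ms = 220,
                            stimulus_time_ms = 100,
                            config = extractionConfig(), fine_dt_ms = 0.02) {
  t <- seq(0, duration_ms, by = fine_dt_ms)
  v <- .cleanWaveform(params, t, stimulus_time_ms)
  # full-record OLS detrend on the fine grid
  tc <- t - mean(t)
  v <- v - mean(v) - (sum(tc * v) / sum(tc * tc)) * tc
  baseline <- mean(v[t < stimulus_time_ms])
  win_b <- stimulus_time_ms + config$b_peak_search_window_ms
  idx_b <- which(t >= win_b[1] & t <= win_b[2])
  jb <- idx_b[which.max(v[idx_b])]
  idx_a <- which(t >= stimulus_time_ms & t <= t[jb])
  ja <- idx_a[which.min(v[idx_a])]
  phnr72 <- v[which.min(abs(t - (stimulus_time_ms + config$phnr_fixed_latency_ms)))] -
    baseline
  lo <- stimulus_time_ms + config$phnr_fixed_latency_ms -
    config$trough_window_halfwidth_ms
  hi <- stimulus_time_ms + config$phnr_fixed_latency_ms +
    config$trough_window_halfwidth_ms
  idx_w <- which(t >= lo & t <= hi)
  jw <- idx_w[which.min(v[idx_w])]
  half_span <- ((config$trough_average_points - 1) / 2) * (duration_ms / n_samples)
  idx_avg <- which(t >= t[jw] - half_span & t <= t[jw] + half_span)
  phnr_min <- mean(v[idx_avg]) - baseline
  a_amp <- v[ja] - baseline
  b_amp <- v[jb] - v[ja]
  phnr_used <- if (config$ratio_phnr_variant == "phnr_min") phnr_min else phnr72
  ratios <- computeRatios(a_amp, b_amp, phnr_used)
  data.frame(planted_baseline_uv = baseline,
             planted_a_trough_time_ms = t[ja], planted_a_amp_uv = a_amp,
             planted_b_peak_time_ms = t[jb], planted_b_amp_uv = b_amp,
             planted_phnr72_uv = phnr72,
             planted_phnr_trough_time_ms = t[jw],
             planted_phnr_min_uv = phnr_min,
             planted_p_ratio = ratios$p_ratio,
             planted_w_ratio = ratios$w_ratio)
}

#' Cohort design for the synthetic ERG study
#'
#' Defaults emulate the clinical cohort the generator stands in for: optic
#' neuropathy (ON) prevalence 0.57 at the subject level, two eyes per
#' subject, three recordings per eye, planted trough-component (PhNR)
#' amplitude distributions of -2.8 ± 1.5 µV for ON eyes and -3.7 ± 1.8 µV
#' for control eyes, and an intra-subject (inter-eye) correlation of 0.5 on
#' the latent PhNR amplitude. A fraction of ON subjects are unilateral,
#' contributing a fellow-eye control; control subjects are split into
#' healthy and patient controls; ON eyes are split acute/chronic (fractions
#' follow the clinical sample's composition: 24/63 unilateral, 64/84 healthy
#' controls, 33/109 acute).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param prevalence Subject-level ON probability.
#' @param eyes_per_subject 1 or 2.
#' @param recordings_per_eye Recordings per eye per visit.
#' @param phnr_mean_control,phnr_sd_control,phnr_mean_on,phnr_sd_on Planted
#'   PhNR component moments (µV).
#' @param intrasubject_correlation Latent inter-eye correlation in `[0, 1)`.
#' @param noise_sd_uv White-noise SD per recording (µV).
#' @param drift_sd Per-recording drift-slope SD (µV/ms).
#' @param baseline_sd Per-recording baseline-offset SD (µV).
#' @param fellow_eye_fraction Fraction of ON subjects with unilateral
#'   disease (fellow eye is a control).
#' @param healthy_control_fraction Fraction of control subjects recruited as
#'   healthy controls (vs patient controls).
#' @param acute_fraction Fraction of ON eyes with acute disease.
#' @param b_amp_mean,b_amp_sd,a_amp_mean,a_amp_sd Per-eye a-/b-wave
#'   component moments (µV).
#' @param seed Integer seed.
#' @return A list of class `"CohortSpec"`.
#' @export
cohortSpec <- function(n_subjects = 109L, prevalence = 0.57,
                       eyes_per_subject = 2L, recordings_per_eye = 3L,
                       phnr_mean_control = -3.7, phnr_sd_control = 1.8,
                       phnr_mean_on = -2.8, phnr_sd_on = 1.5,
                       intrasubject_correlation = 0.5,
                       noise_sd_uv = 0.5, drift_sd = 0.01, baseline_sd = 0.5,
                       fellow_eye_fraction = 24 / 63,
                       healthy_control_fraction = 64 / 84,
                       acute_fraction = 33 / 109,
                       b_amp_mean = 10, b_amp_sd = 1.5,
                       a_amp_mean = -2, a_amp_sd = 0.5, seed = 1L) {
  n_subjects <- .assertCount(n_subjects, "n_subjects", lower = 2L)
  .assertNumber(prevalence, "prevalence", 1e-12, 1)
  stopifnot(eyes_per_subject %in% c(1L, 2L))
  .assertNumber(intrasubject_correlation, "intrasubject_correlation", 0,
                1 - 1e-9)
  structure(list(n_subjects = n_subjects, prevalence = prevalence,
                 eyes_per_subject = as.integer(eyes_per_subject),
                 recordings_per_eye = .assertCount(recordings_per_eye,
                                                   "recordings_per_eye", 1L),
                 phnr_mean_control = phnr_mean_control,
                 phnr_sd_control = phnr_sd_control,
                 phnr_mean_on = phnr_mean_on, phnr_sd_on = phnr_sd_on,
                 intrasubject_correlation = intrasubject_correlation,
                 noise_sd_uv = noise_sd_uv, drift_sd = drift_sd,
                 baseline_sd = baseline_sd,
                 fellow_eye_fraction = fellow_eye_fraction,
                 healthy_control_fraction = healthy_control_fraction,
                 acute_fraction = acute_fraction,
                 b_amp_mean = b_amp_mean, b_amp_sd = b_amp_sd,
                 a_amp_mean = a_amp_mean, a_amp_sd = a_amp_sd,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

# draw subject/eye structure and latent per-eye component amplitudes; the
# truth table without waveforms. Used by simulateCohort and directly by
# statistical calibration studies that do not need sampled waveforms.
.simulateTruth <- function(spec) {
  rho <- spec$intrasubject_correlation
  rows <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%04d", s)
    on_subject <- runif(1) < spec$prevalence
    eyes <- .eyeLevels[seq_len(spec$eyes_per_subject)]
    if (on_subject) {
      unilateral <- spec$eyes_per_subject == 2L &&
        runif(1) < spec$fellow_eye_fraction
      classes <- if (unilateral) {
        on_eye <- sample(eyes, 1)
        ifelse(eyes == on_eye,
               ifelse(runif(1) < spec$acute_fraction, "on_acute", "on_chronic"),
               "control_fellow")
      } else {
        vapply(eyes, function(e)
          ifelse(runif(1) < spec$acute_fraction, "on_acute", "on_chronic"),
          character(1))
      }
      age <- max(18, rnorm(1, 48.9, 17.2))
    } else {
      classes <- rep(ifelse(runif(1) < spec$healthy_control_fraction,
                            "control_healthy", "control_patient"),
                     length(eyes))
      age <- max(18, rnorm(1, 40.0, 15.3))
    }
    z_subj <- rnorm(1)
    for (k in seq_along(eyes)) {
      cls <- classes[k]
      on_eye <- cls %in% c("on_acute", "on_chronic")
      z <- sqrt(rho) * z_subj + sqrt(1 - rho) * rnorm(1)
      phnr <- if (on_eye) spec$phnr_mean_on + spec$phnr_sd_on * z
              else spec$phnr_mean_control + spec$phnr_sd_control * z
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, eye = eyes[k], eye_class = cls,
        label = .labelForEyeClass(cls), age_years = age,
        phnr_component_uv = min(phnr, -0.01),
        b_amp_component_uv = max(spec$b_amp_mean + spec$b_amp_sd * rnorm(1), 3),
        a_amp_component_uv = min(spec$a_amp_mean + spec$a_amp_sd * rnorm(1), 0),
        hvf_md_db = if (on_eye) rnorm(1, -10.6, 10.1) else rnorm(1, -1.1, 2.19),
        rnfl_um = switch(cls, on_acute = rnorm(1, 182, 104),
                         on_chronic = rnorm(1, 69, 14), rnorm(1, 97, 9)),
        gclipl_um = switch(cls, on_acute = rnorm(1, 64, 17),
                           on_chronic = rnorm(1, 60, 10), rnorm(1, 81, 11)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$rnfl_um <- pmax(out$rnfl_um, 20)
  out$gclipl_um <- pmax(out$gclipl_um, 20)
  out
}

#' Simulate a synthetic photopic-ERG cohort with known ground truth
#'
#' Draws subjects (ON with probability `prevalence`; a fraction of ON
#' subjects unilateral, with the fellow eye a control), per-eye latent PhNR
#' component amplitudes sharing the specified intra-subject correlation
#' (bivariate-normal construction on the standardized scale, so the GEE
#' exchangeable working-correlation assumption is met by construction), and
#' per-eye a-/b-wave amplitudes; then synthesises `recordings_per_eye`
#' waveforms per eye with independent per-recording drift, offset and noise.
#' Group-wise clinical covariates (age, visual-field mean deviation, OCT
#' thicknesses) are drawn so downstream models have realistic inputs.
#'
#' @param spec A [cohortSpec()].
#' @return List with `records` (an [ERGRecordingSet-class]) and `truth`
#'   (`data.frame` with every planted parameter, the planted effective
#'   features from [plantedFeatures()], and per-recording nuisance values).
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  .withSeed(spec$seed, {
    eyes <- .simulateTruth(spec)
    n_samples <- 430L; duration <- 220; stim <- 100
    uv <- matrix(NA_real_, n_samples,
                 nrow(eyes) * spec$recordings_per_eye)
    info <- vector("list", ncol(uv))
    truth <- vector("list", ncol(uv))
    col <- 0L
    for (i in seq_len(nrow(eyes))) {
      base_params <- waveformParams(
        a_amp_uv = eyes$a_amp_component_uv[i],
        b_amp_uv = eyes$b_amp_component_uv[i],
        phnr_uv = eyes$phnr_component_uv[i])
      planted <- plantedFeatures(base_params, n_samples, duration, stim)
      for (r in seq_len(spec$recordings_per_eye) - 1L) {
        col <- col + 1L
        params <- base_params
        params$drift_slope_uv_per_ms <- rnorm(1, 0, spec$drift_sd)
        params$baseline_offset_uv <- rnorm(1, 0, spec$baseline_sd)
        params$noise_sd_uv <- spec$noise_sd_uv
        uv[, col] <- simulateWaveform(params, n_samples, duration, stim)$samples
        info[[col]] <- data.frame(
          subject_id = eyes$subject_id[i], eye = eyes$eye[i],
          visit_index = 0L, recording_index = r, n_flashes = 100L,
          duration_ms = duration, stimulus_time_ms = stim,
          label = eyes$label[i], eye_class = eyes$eye_class[i],
          age_years = eyes$age_years[i], hvf_md_db = eyes$hvf_md_db[i],
          rnfl_um = eyes$rnfl_um[i], gclipl_um = eyes$gclipl_um[i],
          stringsAsFactors = FALSE)
        truth[[col]] <- cbind(
          data.frame(subject_id = eyes$subject_id[i], eye = eyes$eye[i],
                     visit_index = 0L, recording_index = r,
                     label = eyes$label[i], eye_class = eyes$eye_class[i],
                     phnr_component_uv = eyes$phnr_component_uv[i],
                     b_amp_component_uv = eyes$b_amp_component_uv[i],
                     a_amp_component_uv = eyes$a_amp_component_uv[i],
                     drift_slope_uv_per_ms = params$drift_slope_uv_per_ms,
                     baseline_offset_uv = params$baseline_offset_uv,
                     noise_sd_uv = params$noise_sd_uv,
                     stringsAsFactors = FALSE),
          planted)
      }
    }
    list(records = ERGRecordingSet(uv, do.call(rbind, info)),
         truth = do.call(rbind, truth))
  })
}

#' Recovery of planted parameters by the feature extractor
#'
#' Joins an extracted feature table with a cohort truth table on the record
#' identity and summarises, per feature and noise level, the bias and RMSE
#' of the extracted values against the planted (ground-truth) features.
#'
#' @param features Table from [extractFeatures()].
#' @param truth Truth table from [simulateCohort()].
#' @return `data.frame` with `noise_sd_uv`, `feature`, `bias`, `rmse`, `n`.
#' @export
truthRecoveryReport <- function(features, truth) {
  key <- function(d) .recordId(d$subject_id, d$eye, d$visit_index,
                               d$recording_index)
  m <- match(key(features), key(truth))
  if (all(is.na(m))) stop("no record identifiers shared between features and truth")
  features <- features[!is.na(m), , drop = FALSE]
  truth <- truth[m[!is.na(m)], , drop = FALSE]
  pairs <- c(b_amp_uv = "planted_b_amp_uv", a_amp_uv = "planted_a_amp_uv",
             phnr_min_uv = "planted_phnr_min_uv",
             phnr72_uv = "planted_phnr72_uv",
             phnr_trough_time_ms = "planted_phnr_trough_time_ms")
  out <- lapply(names(pairs), function(f) {
    err <- features[[f]] - truth[[pairs[[f]]]]
    agg <- lapply(split(err, truth$noise_sd_uv), function(e)
      c(bias = mean(e), rmse = sqrt(mean(e^2)), n = length(e)))
    data.frame(noise_sd_uv = as.numeric(names(agg)), feature = f,
               bias = vapply(agg, `[[`, numeric(1), "bias"),
               rmse = vapply(agg, `[[`, numeric(1), "rmse"),
               n = vapply(agg, `[[`, numeric(1), "n"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
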
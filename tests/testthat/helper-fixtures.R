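# Fixture builders shared across test files. Everything is generated in code;
# no data files are read.

DT <- 220 / 430  # default sampling step, ms

# grid of default sample times
gridTimes <- function(n_samples = 430L, duration_ms = 220) {
  timeOfSample(seq_len(n_samples) - 1L, duration_ms, n_samples)
}

# a single-recording ERGRecordingSet around a raw sample vector
recordingFromSamples <- function(samples, subject_id = "S1", eye = "OD",
                                 label = "UNKNOWN", stimulus_time_ms = 100,
                                 duration_ms = 220, ...) {
  ERGRecordingSet(matrix(samples, ncol = 1),
                  data.frame(subject_id = subject_id, eye = eye,
                             label = label, stimulus_time_ms = stimulus_time_ms,
                             duration_ms = duration_ms, ...))
}

# triangular bump of given height centred at peak_ms with half-width w_ms
triangularBump <- function(t, peak_ms, height, w_ms = 8) {
  pmax(0, height * (1 - abs(t - peak_ms) / w_ms))
}

# a clean synthetic wave through the package generator, no nuisance terms
cleanWaveParams <- function(...) {
  args <- utils::modifyList(list(noise_sd_uv = 0, drift_slope_uv_per_ms = 0,
                                 baseline_offset_uv = 0), list(...))
  do.call(waveformParams, args)
}

# small labeled cohort for classifier tests, with a wide planted PhNR gap
separatedCohort <- function(n_subjects = 40, seed = 1, gap = 3,
                            noise_sd = 0.5, recordings_per_eye = 1) {
  simulateCohort(cohortSpec(
    n_subjects = n_subjects, recordings_per_eye = recordings_per_eye,
    phnr_mean_on = -1, phnr_mean_control = -1 - gap,
    phnr_sd_on = 0.3, phnr_sd_control = 0.3,
    noise_sd_uv = noise_sd, seed = seed))
}

# features table built directly from planted truth values (one row per eye),
# for statistical calibration studies that do not need sampled waveforms
featuresFromTruth <- function(truth) {
  eyes <- truth[!duplicated(paste(truth$subject_id, truth$eye)), ]
  ph <- eyes$phnr_component_uv
  b <- eyes$b_amp_component_uv
  a <- eyes$a_amp_component_uv
  data.frame(subject_id = eyes$subject_id, eye = eyes$eye,
             visit_index = 0L, recording_index = 0L,
             label = eyes$label, eye_class = eyes$eye_class,
             phnr_min_uv = ph, phnr72_uv = 0.8 * ph,
             p_ratio = -ph / b, w_ratio = (b - ph) / (b - a),
             stringsAsFactors = FALSE)
}

# rank-based AUC oracle: pairwise comparison with half credit for ties
aucRankOracle <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
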
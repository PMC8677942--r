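test_that("linear detrend annihilates lines and is idempotent", {
  expect_equal(detrendLinear(c(5, 5, 5, 5)), rep(0, 4))
  expect_equal(detrendLinear(c(0, 1, 2, 3)), rep(0, 4))
  t <- gridTimes()
  x <- sin(t / 9) + 0.03 * t + 2
  d <- detrendLinear(x)
  refit <- lm(d ~ seq_along(d))
  expect_lt(abs(coef(refit)[2]), 1e-10)
  expect_lt(abs(mean(d)), 1e-10)
  expect_equal(detrendLinear(d), d, tolerance = 1e-9)
  expect_error(detrendLinear(5), "at least 2")
})

test_that("baseline is the mean of strictly pre-stimulus samples", {
  x <- rep(5, 430)
  expect_equal(computeBaseline(x), 5)
  set.seed(1)
  x <- rnorm(430)
  t <- gridTimes()
  expect_equal(computeBaseline(x), mean(x[t < 100]))
  # a step at exactly the stimulus time does not leak into the baseline
  x2 <- ifelse(t >= 100, 50, 1)
  expect_equal(computeBaseline(x2), 1)
  expect_error(computeBaseline(x, stimulus_time_ms = 0), "pre-stimulus")
})

test_that("b-peak search finds the windowed maximum, earliest on ties", {
  t <- gridTimes()
  x <- triangularBump(t, 135, 7)
  bp <- findBPeak(x)
  expect_equal(bp$time_ms, t[which.max(x)])
  expect_equal(bp$potential_uv, max(x), tolerance = 1e-12)
  expect_lt(abs(bp$time_ms - 135), DT)
  # flat record: earliest sample of the window by the tie rule
  flat <- rep(1, 430)
  expect_equal(findBPeak(flat)$time_ms, t[min(which(t >= 100 - 1e-9))])
  # a large pre-stimulus artifact is outside the window and ignored
  x3 <- x + triangularBump(t, 50, 100)
  expect_equal(findBPeak(x3)$time_ms, bp$time_ms)
})

test_that("a-trough is the windowed minimum between stimulus and b-peak", {
  t <- gridTimes()
  x <- triangularBump(t, 135, 7) - triangularBump(t, 117, 4)
  at <- findATrough(x, b_peak_time_ms = 135)
  expect_lt(abs(at$time_ms - 117), DT)
  # monotone rise: boundary minimum at the stimulus sample
  rise <- pmax(0, t - 100)
  expect_equal(findATrough(rise, 200)$time_ms, t[min(which(t >= 100 - 1e-9))])
  # equal minima: earlier wins
  x2 <- rep(0, 430); x2[c(220, 240)] <- -3
  expect_equal(findATrough(x2, 150)$time_ms, t[220])
  expect_error(findATrough(x, 99), "after the stimulus")
})

test_that("fixed-latency PhNR reads the 72 ms sample minus baseline", {
  x <- rep(2, 430)
  expect_equal(phnrFixedLatency(x, baseline_uv = 2), 0)
  x[337] <- -2  # 0-based index 336 is the sample nearest 172 ms
  expect_equal(phnrFixedLatency(x, baseline_uv = 2), -4)
  expect_equal(phnrFixedLatency(x, 2), x[sampleAtTime(172) + 1] - 2)
  expect_error(phnrFixedLatency(x, 2, latency_ms = 130), "beyond")
})

test_that("trough-averaged PhNR averages 11 samples at the windowed minimum", {
  t <- gridTimes()
  # flat at baseline - 4 across the window and averaging span: exact
  x <- rep(1, 430)
  x[t >= 150 & t <= 195] <- -3
  tr <- phnrTrough(x, baseline_uv = 1)
  expect_equal(tr$phnr_min_uv, -4)
  expect_true(tr$trough_time_ms >= 162 && tr$trough_time_ms <= 182)
  expect_false(tr$clipped)
  # V-shaped trough: the point minimum is at least as low as V(172) - baseline
  v <- -pmax(0, 6 - abs(t - 174) / 2)
  trv <- phnrTrough(v, baseline_uv = 0)
  expect_lte(min(v[t >= 162 & t <= 182]) - 0, v[sampleAtTime(172) + 1])
  # averaging check against a direct 11-point mean around the trough sample
  j <- which.min(v[t >= 162 & t <= 182]) + min(which(t >= 162)) - 1L
  expect_equal(trv$phnr_min_uv, mean(v[(j - 5):(j + 5)]))
})

test_that("ratio formulas evaluate exactly and propagate signs", {
  r <- computeRatios(a_amp_uv = -3, b_amp_uv = 10, phnr_uv = -2)
  expect_equal(r$p_ratio, 0.2)
  expect_equal(r$w_ratio, 12 / 13)
  r0 <- computeRatios(0, 10, 0)
  expect_equal(r0$p_ratio, 0)
  expect_equal(r0$w_ratio, 1)
  set.seed(3)
  for (k in 1:50) {
    a <- -runif(1, 0, 5); b <- runif(1, 0.5, 15); ph <- -runif(1, 0, 6)
    expect_gt(computeRatios(a, b, ph)$p_ratio, 0)
  }
  expect_false(computeRatios(-3, 0, -2)$defined)
  expect_false(computeRatios(5, 5, -2)$defined)
})

test_that("QC fails flat, spiky and drifty records and passes clean ones", {
  set.seed(4)
  flat <- rep(0.4, 430)
  f <- extractFeatures(recordingFromSamples(flat))
  expect_false(f$qc_pass)
  expect_match(f$qc_reasons, "no defined b-wave peak")
  # a noise-only trace needs a stricter prominence threshold to be caught:
  # its spurious peak-to-trough span is several noise SDs by construction
  noise <- rnorm(430, 0, 0.3)
  cfg8 <- extractionConfig(qc_prominence_sd = 8)
  f8 <- extractFeatures(recordingFromSamples(noise), cfg8)
  expect_false(f8$qc_pass)
  # clean generator output passes with no reasons
  clean <- simulateWaveform(cleanWaveParams(noise_sd_uv = 0.2))$samples
  fc <- extractFeatures(recordingFromSamples(clean))
  expect_true(fc$qc_pass)
  expect_identical(fc$qc_reasons, "")
  spike <- clean; spike[250] <- 500
  fs <- extractFeatures(recordingFromSamples(spike))
  expect_match(fs$qc_reasons, "amplitude bound")
  # pure linear drift: no b-wave
  drift <- 0.05 * gridTimes()
  fd <- extractFeatures(recordingFromSamples(drift))
  expect_false(fd$qc_pass)
  # manual exclusion list is honoured
  cfg <- extractionConfig(qc_exclude_ids = "S1:OD:v0:r0")
  fm <- extractFeatures(recordingFromSamples(clean), cfg)
  expect_match(fm$qc_reasons, "manual exclusion")
})

test_that("Snellen and non-numeric acuities convert to logMAR", {
  expect_equal(logmarFromAcuity(c("CF", "HM", "NLP")), c(2, 3, 6))
  expect_equal(logmarFromAcuity("20/20"), 0)
  expect_equal(logmarFromAcuity("20/200"), 1)
  expect_equal(logmarFromAcuity("6/60"), 1)
  expect_equal(logmarFromAcuity("20/40"), log10(2))
  expect_error(logmarFromAcuity("20-40"), "unparseable")
})

test_that("extraction recovers planted features on clean waveforms", {
  p <- cleanWaveParams(phnr_uv = -4.2, b_amp_uv = 11, a_amp_uv = -2.5)
  planted <- plantedFeatures(p)
  f <- extractFeatures(recordingFromSamples(simulateWaveform(p)$samples))
  # discretization-only differences: well within the sampling step
  expect_equal(f$b_amp_uv, planted$planted_b_amp_uv, tolerance = 0.01)
  expect_equal(f$phnr_min_uv, planted$planted_phnr_min_uv, tolerance = 0.01)
  expect_equal(f$a_amp_uv, planted$planted_a_amp_uv, tolerance = 0.01)
  expect_lt(abs(f$phnr_trough_time_ms - planted$planted_phnr_trough_time_ms),
            2 * DT)
  expect_true(f$qc_pass)
})

test_that("features are shift-invariant and scale-equivariant", {
  set.seed(8)
  x <- simulateWaveform(cleanWaveParams(noise_sd_uv = 0.3))$samples
  f0 <- extractFeatures(recordingFromSamples(x))
  fshift <- extractFeatures(recordingFromSamples(x + 17.3))
  amp_cols <- c("baseline_uv", "a_amp_uv", "b_amp_uv", "phnr72_uv",
                "phnr_min_uv")
  for (col in c(amp_cols, "p_ratio", "w_ratio", "a_trough_time_ms",
                "b_peak_time_ms", "phnr_trough_time_ms"))
    expect_equal(fshift[[col]], f0[[col]], tolerance = 1e-9, label = col)
  fscale <- extractFeatures(recordingFromSamples(3 * x))
  for (col in amp_cols)
    expect_equal(fscale[[col]], 3 * f0[[col]], tolerance = 1e-9, label = col)
  for (col in c("p_ratio", "w_ratio"))
    expect_equal(fscale[[col]], f0[[col]], tolerance = 1e-9, label = col)
})

test_that("batch extraction preserves record order and attaches identity", {
  sim <- simulateCohort(cohortSpec(n_subjects = 4, recordings_per_eye = 2,
                                   seed = 5))
  f <- extractFeatures(sim$records)
  expect_identical(nrow(f), ncol(sim$records))
  expect_identical(paste(f$subject_id, f$eye, f$recording_index),
                   paste(recordInfo(sim$records)$subject_id,
                         recordInfo(sim$records)$eye,
                         recordInfo(sim$records)$recording_index))
})
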
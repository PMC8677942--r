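test_that("one eye per subject keeps OD when present, else OS", {
  d <- data.frame(subject_id = c("A", "A", "B", "C", "C"),
                  eye = c("OD", "OS", "OS", "OD", "OS"),
                  v = 1:5)
  out <- selectOneEyePerSubject(d)
  expect_identical(nrow(out), 3L)                     # one eye per subject
  expect_identical(out$eye[out$subject_id == "A"], "OD")
  expect_identical(out$eye[out$subject_id == "B"], "OS")
  expect_identical(sort(unique(out$subject_id)), c("A", "B", "C"))
})

test_that("ROC curves have the required endpoints and match enumeration", {
  # perfect separation passes through (sens 1, spec 1)
  cv <- rocCurve(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_true(any(cv@sensitivity == 1 & cv@specificity == 1))
  expect_equal(aucTrapezoid(cv), 1)
  # all scores identical: only the two trivial operating points
  cv2 <- rocCurve(rep(4, 6), c(0, 0, 0, 1, 1, 1))
  expect_length(cv2@thresholds, 2L)
  expect_equal(sort(cv2@sensitivity), c(0, 1))
  # identical class distributions give AUC 1/2
  cv3 <- rocCurve(c(1:5, 1:5), rep(c(0, 1), each = 5))
  expect_equal(aucTrapezoid(cv3), 0.5)
  # random instance: every operating point matches exhaustive thresholding
  set.seed(61)
  s <- sample(1:6, 20, replace = TRUE) + runif(20, -0.01, 0.01)
  l <- rbinom(20, 1, 0.5); l[1:2] <- c(0, 1)
  cv4 <- rocCurve(s, l)
  for (i in seq_along(cv4@thresholds)) {
    thr <- cv4@thresholds[i]
    expect_equal(cv4@sensitivity[i], mean(s[l == 1] > thr))
    expect_equal(cv4@specificity[i], mean(s[l == 0] <= thr))
  }
  expect_error(rocCurve(1:5, rep(1, 5)), "both classes")
})

test_that("trapezoidal AUC equals the rank statistic and is monotone-invariant", {
  set.seed(62)
  for (r in 1:50) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    s <- c(rnorm(n1, 0.5), rnorm(n0))
    s <- round(s, 1)                      # force ties
    l <- rep(c(TRUE, FALSE), c(n1, n0))
    auc <- aucTrapezoid(rocCurve(s, l))
    expect_equal(auc, aucRankOracle(s, l), tolerance = 1e-10)
    # strictly monotone transform leaves the AUC unchanged
    expect_equal(aucTrapezoid(rocCurve(exp(s), l)), auc, tolerance = 1e-10)
  }
})

test_that("the Youden optimum beats every other threshold", {
  set.seed(63)
  for (r in 1:50) {
    s <- rnorm(30); l <- rbinom(30, 1, 0.5); l[1:2] <- c(0, 1)
    cv <- rocCurve(s, l)
    yo <- youdenOptimal(cv)
    expect_equal(yo$j_statistic, yo$sensitivity + yo$specificity - 1)
    # brute-force scan over all midpoint thresholds
    ss <- sort(unique(s))
    grid <- c(-Inf, (ss[-1] + ss[-length(ss)]) / 2, Inf)
    j_all <- vapply(grid, function(thr)
      mean(s[l == 1] > thr) + mean(s[l == 0] <= thr) - 1, numeric(1))
    expect_equal(yo$j_statistic, max(j_all), tolerance = 1e-12)
  }
})

test_that("confusion metrics are exact and orientation-symmetric", {
  # cutoff below all scores: everything called positive
  cm <- confusionFromThreshold(1:10, rep(c(0, 1), 5), 0)
  expect_identical(cm$tn + cm$fn, 0L)
  expect_equal(cm$sensitivity, 1)
  # direct arithmetic on planted counts (38, 35, 21, 25)
  scores <- c(rep(1, 38), rep(-1, 25), rep(-1, 35), rep(1, 21))
  labels <- rep(c(TRUE, FALSE), c(63, 56))
  cm2 <- confusionFromThreshold(scores, labels, 0)
  expect_identical(c(cm2$tp, cm2$tn, cm2$fp, cm2$fn), c(38L, 35L, 21L, 25L))
  expect_equal(cm2$accuracy, (38 + 35) / 119)
  # flipping orientation and scores swaps the confusion quadrants
  cm3 <- confusionFromThreshold(-scores, labels, 0, "lower_is_positive")
  expect_identical(c(cm3$tp, cm3$tn, cm3$fp, cm3$fn),
                   c(cm2$tp, cm2$tn, cm2$fp, cm2$fn))
})

test_that("literal-definition metrics expose the missing factor of two", {
  pv <- metricsPaperVariant(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(pv$precision_paper, 1)
  expect_equal(pv$recall_paper, 1)
  expect_equal(pv$f1_paper, 0.5)          # a perfect classifier scores 0.5
  expect_equal(paperF1(0.61, 0.63), 0.63 * 0.61 / (0.63 + 0.61))
  # zero denominator flagged as NA
  expect_true(is.na(metricsPaperVariant(0, 0, 0, 5)$precision_paper))
})

test_that("feature-level ROC pipeline picks an orientation with AUC >= 0.5", {
  sim <- simulateCohort(cohortSpec(n_subjects = 25, recordings_per_eye = 1,
                                   seed = 64))
  f <- extractFeatures(sim$records)
  res <- evaluateFeatureROC(f)
  expect_true(all(res$auc >= 0.5))
  expect_true(all(c("phnr_min", "phnr72", "p_ratio", "w_ratio") %in% res$feature))
  expect_equal(res$youden_j, res$sensitivity + res$specificity - 1,
               tolerance = 1e-12)
  # severity restriction drops mild ON eyes
  res_sev <- evaluateFeatureROC(f, severity_hvf_md_db = -5)
  expect_lte(res_sev$n_positive[1], res$n_positive[1])
  expect_identical(res_sev$n_negative[1], res$n_negative[1])
})
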
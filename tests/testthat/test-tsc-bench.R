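test_that("grouped split keeps subjects whole and balances labels", {
  # a subject's six waveforms (2 eyes x 3 visits) land in a single set
  sim <- simulateCohort(cohortSpec(n_subjects = 115, recordings_per_eye = 3,
                                   seed = 71))
  info <- as.data.frame(recordInfo(sim$records))
  sp <- groupedStratifiedSplit(info$subject_id, recordLabels(sim$records),
                               seed = 5)
  per_subject <- tapply(sp$set, info$subject_id,
                        function(s) length(unique(s)))
  expect_true(all(per_subject == 1))
  # per-set positive proportions within tolerance of the overall proportion
  pos <- recordLabels(sim$records) == "ON_POS"
  overall <- mean(pos)
  for (s in c("train", "validation", "test"))
    expect_lte(abs(mean(pos[sp$set == s]) - overall), 0.05 + 1e-12)
  # determinism: same seed identical, different seed different
  sp2 <- groupedStratifiedSplit(info$subject_id, pos, seed = 5)
  expect_identical(sp$subject_to_set, sp2$subject_to_set)
  sp3 <- groupedStratifiedSplit(info$subject_id, pos, seed = 6)
  expect_false(identical(sp$subject_to_set, sp3$subject_to_set))
  # infeasible tolerance errors with advice
  expect_error(groupedStratifiedSplit(info$subject_id, pos, seed = 5,
                                      tolerance = 1e-6, max_tries = 3),
               "relax")
})

test_that("DTW distance has the identity, band and symmetry properties", {
  set.seed(72)
  x <- rnorm(50)
  expect_identical(dtwDistance(x, x), 0)
  expect_equal(dtwDistance(c(0, 0), c(1, 1)), 2)  # diagonal path, 1 + 1
  y <- rnorm(50)
  expect_equal(dtwDistance(x, y), dtwDistance(y, x))
  expect_gte(dtwDistance(x, y), 0)
  # band 0 on equal lengths forces the diagonal: L1 distance
  expect_equal(dtwDistance(x, y, band = 0), sum(abs(x - y)))
  expect_error(dtwDistance(1:5, 1:9, band = 2), "band")
})

test_that("DTW equals exhaustive path enumeration on random small series", {
  set.seed(73)
  for (r in 1:100) {
    nx <- sample(1:5, 1); ny <- sample(1:5, 1)
    x <- sample(0:2, nx, replace = TRUE)
    y <- sample(0:2, ny, replace = TRUE)
    expect_equal(dtwDistance(x, y), ERGdx:::.dtw_brute_cpp(x, y, FALSE))
  }
})

test_that("1-NN DTW respects exact matches and index tie-breaks", {
  train <- list(c(0, 1, 2), c(5, 5, 5), c(2, 1, 0))
  labels <- c("ON_POS", "ON_NEG", "ON_POS")
  expect_identical(knnDtwPredict(train, labels, c(5, 5, 5)), "ON_NEG")
  # two equidistant neighbours with different labels: earlier index wins
  train2 <- list(c(0, 0), c(2, 2))
  expect_identical(knnDtwPredict(train2, c("A", "B"), c(1, 1)), "A")
  expect_error(knnDtwPredict(train, labels, c(1, 1, 1), k = 5), "exceeds")
})

test_that("TSF interval features match direct recomputation", {
  set.seed(74)
  X <- matrix(rnorm(100 * 60), 100, 60)
  for (r in 1:20) {
    a <- sample(1:50, 1); b <- a + sample(2:9, 1)
    Fi <- intervalFeatures(X, a, b)
    for (i in sample(1:100, 5)) {
      seg <- X[i, a:b]
      expect_equal(unname(Fi[i, "mean"]), mean(seg))
      expect_equal(unname(Fi[i, "sd"]), sd(seg))
      expect_equal(unname(Fi[i, "slope"]),
                   unname(coef(lm(seg ~ seq_along(seg)))[2]),
                   tolerance = 1e-10)
    }
  }
  # interval slope of an exact ramp equals the ramp coefficient
  ramp <- matrix(0.37 * (1:60), 1, 60)
  expect_equal(unname(intervalFeatures(ramp, 10, 30)[, "slope"]), 0.37)
})

test_that("TSF is deterministic and invariant to training-row order", {
  set.seed(75)
  X <- rbind(matrix(rnorm(20 * 30, 0), 20, 30),
             matrix(rnorm(20 * 30, 2), 20, 30))
  y <- rep(c(FALSE, TRUE), each = 20)
  Q <- matrix(rnorm(10 * 30, 1), 10, 30)
  m1 <- tsfFit(X, y, n_estimators = 15, seed = 9)
  m2 <- tsfFit(X, y, n_estimators = 15, seed = 9)
  expect_identical(tsfPredict(m1, Q), tsfPredict(m2, Q))
  perm <- sample(40)
  m3 <- tsfFit(X[perm, ], y[perm], n_estimators = 15, seed = 9)
  expect_identical(tsfPredict(m1, Q), tsfPredict(m3, Q))
  # separable means give a perfect training fit
  expect_identical(tsfPredict(m1, X)$label,
                   ifelse(y, "ON_POS", "ON_NEG"))
  expect_error(tsfFit(X[, 1:2], y), "at least 3")
  expect_error(tsfPredict(m1, Q[, 1:10]), "does not match")
})

test_that("TSF vote ties resolve to the negative class", {
  X <- rbind(matrix(0, 3, 10), matrix(5, 3, 10))
  y <- rep(c(FALSE, TRUE), each = 3)
  m <- tsfFit(X, y, n_estimators = 2, seed = 1)
  # hand-build a two-tree forest that disagrees on everything
  leafA <- list(list(id = 1L, feature = NA_integer_, threshold = NA_real_,
                     left = NA_integer_, right = NA_integer_, prob = 1))
  leafB <- list(list(id = 1L, feature = NA_integer_, threshold = NA_real_,
                     left = NA_integer_, right = NA_integer_, prob = 0))
  m$trees[[1]]$nodes <- leafA
  m$trees[[2]]$nodes <- leafB
  pred <- tsfPredict(m, matrix(1, 1, 10))
  expect_equal(pred$probability, 0.5)
  expect_identical(pred$label, "ON_NEG")
})

test_that("classifier configurations echo the benchmark hyperparameters", {
  expect_equal(classifierConfig("svm_rbf")$C, 1.5)
  expect_identical(classifierConfig("svm_rbf")$gamma_mode, "scale")
  expect_identical(classifierConfig("rf")$n_estimators, 200L)
  expect_identical(classifierConfig("gb")$n_estimators, 100L)
  expect_identical(classifierConfig("tsf")$n_estimators, 100L)
  l <- classifierConfig("lstm")$lstm
  expect_identical(l[c("n_layers", "batch_size", "hidden_dims", "n_epochs")],
                   list(n_layers = 3L, batch_size = 6L, hidden_dims = 16L,
                        n_epochs = 100L))
  expect_equal(l$dropout, 0.6)
  expect_equal(l$learning_rate, 0.001)
  expect_identical(l$optimizer, "adam")
  expect_error(classifierConfig("svm_rbf", Cc = 3), "unknown")
  expect_error(classifierConfig("boost"))
})

test_that("every classifier kind trains and predicts on a small cohort", {
  sim <- separatedCohort(n_subjects = 20, seed = 76)
  X <- t(potentials(sim$records))
  y <- recordLabels(sim$records)
  for (kind in c("nn_dtw", "svm_linear", "svm_rbf", "rf", "gb", "tsf")) {
    fit <- fitStandardClassifier(kind, X, y, classifierConfig(kind, seed = 3))
    pred <- predictClassifier(fit, X[1:4, ])
    expect_true(all(pred %in% c("ON_POS", "ON_NEG")), label = kind)
  }
  cfg <- classifierConfig("lstm", seed = 3, lstm = list(n_epochs = 2))
  fit <- fitStandardClassifier("lstm", X[1:12, ], y[1:12], cfg)
  pred <- predictClassifier(fit, X[1:4, ])
  expect_true(all(pred %in% c("ON_POS", "ON_NEG")))
  # LSTM training is deterministic given the seed
  fit2 <- fitStandardClassifier("lstm", X[1:12, ], y[1:12], cfg)
  expect_identical(lstmPredict(fit$fit, X[1:6, ]),
                   lstmPredict(fit2$fit, X[1:6, ]))
  expect_error(fitStandardClassifier("lda", X, y), "arg")
})

test_that("the benchmark harness touches test labels only at evaluation", {
  sim <- separatedCohort(n_subjects = 24, seed = 77)
  log <- list()
  hook <- function(phase, set) log[[length(log) + 1]] <<- c(phase, set)
  rep <- runBenchmark(sim$records,
                      configs = list(classifierConfig("rf", seed = 1),
                                     classifierConfig("tsf", seed = 1,
                                                      n_estimators = 20)),
                      split_seed = 2, tolerance = 0.15,
                      label_access_hook = hook)
  phases <- vapply(log, `[`, character(1), 1)
  sets <- vapply(log, `[`, character(1), 2)
  # test labels only under the final-evaluation phase
  expect_true(all(phases[sets == "test"] == "final_evaluation"))
  # and only after training/tuning labels were served
  expect_gt(min(which(sets == "test")),
            max(which(sets %in% c("train", "validation"))))
  # subjects never straddle sets
  info <- as.data.frame(recordInfo(sim$records))
  test_subj <- names(rep$split$subject_to_set)[rep$split$subject_to_set == "test"]
  other_subj <- names(rep$split$subject_to_set)[rep$split$subject_to_set != "test"]
  expect_length(intersect(test_subj, other_subj), 0L)
  expect_identical(sort(rep$results$classifier), c("rf", "tsf"))
  expect_true(all(rep$results$accuracy >= 0 & rep$results$accuracy <= 1))
})
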
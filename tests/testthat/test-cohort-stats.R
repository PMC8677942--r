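test_that("independence GEE with singleton clusters reproduces OLS", {
  set.seed(11)
  n <- 80
  x <- rnorm(n); y <- 2 - 0.7 * x + rnorm(n)
  fit <- fitLinearGEE(y, cbind(`(Intercept)` = 1, x = x),
                      cluster = paste0("c", 1:n), corstr = "independence")
  ols <- lm(y ~ x)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
})

test_that("independence sandwich matches the cluster-robust covariance", {
  skip_if_not_installed("sandwich")
  set.seed(12)
  id <- rep(1:30, each = 3)
  x <- rnorm(90)
  u <- rnorm(30)[id]               # cluster random effect
  y <- 1 + 0.5 * x + u + rnorm(90)
  fit <- fitLinearGEE(y, cbind(`(Intercept)` = 1, x = x), id, "independence")
  lmfit <- lm(y ~ x)
  vc <- sandwich::vcovCL(lmfit, cluster = id, type = "HC0", cadjust = FALSE)
  expect_equal(unname(robustSE(fit)), unname(sqrt(diag(vc))),
               tolerance = 1e-10)
})

test_that("a null group contrast gives a zero coefficient and p near 1", {
  set.seed(13)
  v <- rnorm(25)
  y <- c(v, v)                      # identical response in both groups
  g <- rep(c(0, 1), each = 25)
  fit <- fitLinearGEE(y, cbind(1, on = g), cluster = paste0("c", 1:50),
                      corstr = "independence")
  expect_lt(abs(coef(fit)["on"]), 1e-12)
  expect_equal(unname(pValues(fit)["on"]), 1, tolerance = 1e-9)
})

test_that("exchangeable GEE recovers a planted effect and the correlation", {
  # Monte-Carlo recovery: planted beta = 0.9 on two-eye clusters, rho = 0.5
  hits <- 0L
  reps <- 60L
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    K <- 60
    g <- rbinom(K, 1, 0.5)
    z_subj <- rnorm(K)
    y <- x <- id <- numeric(0)
    for (k in seq_len(K)) {
      eff <- sqrt(0.5) * z_subj[k] + sqrt(0.5) * rnorm(2)
      y <- c(y, 0.9 * g[k] + eff)
      x <- c(x, rep(g[k], 2)); id <- c(id, rep(k, 2))
    }
    fit <- fitLinearGEE(y, cbind(1, on = x), id, "exchangeable")
    hits <- hits + (abs(coef(fit)["on"] - 0.9) <= 3 * robustSE(fit)["on"])
  }
  expect_gte(hits / reps, 0.95)
  # correlation recovery at 500 clusters
  set.seed(99)
  K <- 500
  z <- rnorm(K)
  y <- unlist(lapply(seq_len(K), function(k)
    sqrt(0.5) * z[k] + sqrt(0.5) * rnorm(2)))
  fit <- fitLinearGEE(y, matrix(1, 2 * K, 1), rep(seq_len(K), each = 2),
                      "exchangeable")
  expect_lt(abs(workingAlpha(fit) - 0.5), 0.1)
})

test_that("degenerate GEE inputs are rejected", {
  expect_error(fitLinearGEE(rnorm(10), cbind(1, rep(1, 10)), rep("a", 10)),
               "singular")
  expect_error(fitLinearGEE(rnorm(10), matrix(1, 10, 1), rep("a", 10)),
               "2 clusters")
})

test_that("ON-vs-control models find the planted deficit with the right sign", {
  sim <- ERGdx:::.withSeed(21, ERGdx:::.simulateTruth(cohortSpec(n_subjects = 109)))
  res <- compareOnVsControl(featuresFromTruth(sim))
  on_row <- res[res$feature == "phnr_min" & res$term == "on", ]
  expect_gt(on_row$estimate, 0)  # ON eyes have less-negative PhNR
  expect_lt(on_row$p, 0.05)
  # age adjustment keeps the effect
  ft <- featuresFromTruth(sim)
  ft$age_years <- sim$age_years[!duplicated(paste(sim$subject_id, sim$eye))]
  res_adj <- compareOnVsControl(ft, adjust_age = TRUE)
  expect_lt(res_adj[res_adj$feature == "phnr_min" & res_adj$term == "on", "p"],
            0.05)
  expect_true("age_years" %in% res_adj$term)
})

test_that("label permutation yields null p-values at the nominal rate", {
  reject <- 0L
  reps <- 100L
  spec <- cohortSpec(n_subjects = 80)
  for (r in seq_len(reps)) {
    sim <- ERGdx:::.withSeed(3000 + r, ERGdx:::.simulateTruth(spec))
    ft <- featuresFromTruth(sim)
    # permute ON status at the subject level: the null holds by construction
    subs <- unique(ft$subject_id)
    sub_label <- vapply(split(ft$label, ft$subject_id)[subs],
                        `[[`, character(1), 1)
    perm <- setNames(sample(sub_label), subs)
    ft$label <- unname(perm[ft$subject_id])
    ft$eye_class <- ifelse(ft$label == "ON_POS", "on_chronic", "control_healthy")
    res <- compareOnVsControl(ft)
    p <- res[res$feature == "phnr_min" & res$term == "on", "p"]
    reject <- reject + (p < 0.05)
  }
  expect_lte(reject / reps, 0.10)
})

test_that("age adjustment moves a confounded coefficient as constructed", {
  set.seed(31)
  n <- 200
  sid <- paste0("S", 1:n)
  on <- rbinom(n, 1, 0.5)
  age <- 40 + 15 * on + rnorm(n, 0, 5)     # ON subjects older by design
  y <- 0.1 * age + rnorm(n, 0, 0.5)        # feature depends on age only
  ft <- data.frame(subject_id = sid, eye = "OD", label =
                     ifelse(on == 1, "ON_POS", "ON_NEG"),
                   eye_class = ifelse(on == 1, "on_chronic", "control_healthy"),
                   phnr_min_uv = y, age_years = age)
  raw <- suppressWarnings(compareOnVsControl(ft))       # only phnr_min present
  adj <- suppressWarnings(compareOnVsControl(ft, adjust_age = TRUE))
  b_raw <- raw[raw$feature == "phnr_min" & raw$term == "on", "estimate"]
  b_adj <- adj[adj$feature == "phnr_min" & adj$term == "on", "estimate"]
  expect_gt(b_raw, 1)            # inherits the 0.1 * 15 age gap
  expect_lt(abs(b_adj), abs(b_raw) / 2)
})

test_that("control-source contrasts detect planted deficits and stay calibrated", {
  # planted fellow-eye deficit is detected
  sim <- ERGdx:::.withSeed(41, ERGdx:::.simulateTruth(cohortSpec(n_subjects = 150)))
  ft <- featuresFromTruth(sim)
  fellow <- ft$eye_class == "control_fellow"
  ft$phnr_min_uv[fellow] <- ft$phnr_min_uv[fellow] - 2.5
  res <- compareControlSources(ft)
  expect_lt(res[res$model == "fellow_vs_other_controls" &
                  res$feature == "phnr_min" & res$term == "fellow", "p"], 0.05)
  # under identical generating distributions the contrasts are calibrated
  ps <- c()
  for (r in 1:25) {
    sim <- ERGdx:::.withSeed(5000 + r,
                             ERGdx:::.simulateTruth(cohortSpec(n_subjects = 100)))
    res <- compareControlSources(featuresFromTruth(sim))
    ps <- c(ps, res[res$term %in% c("fellow", "healthy"), "p"])
  }
  expect_lte(mean(ps < 0.05), 0.10)
  # single subtype input errors
  one <- featuresFromTruth(sim)
  one <- one[one$eye_class == "control_healthy", ]
  expect_error(compareControlSources(one), "at least 2")
})

test_that("structure-function slopes are recovered and subsets respected", {
  sim <- ERGdx:::.withSeed(51, ERGdx:::.simulateTruth(cohortSpec(n_subjects = 120)))
  ft <- featuresFromTruth(sim)
  eyes <- sim[!duplicated(paste(sim$subject_id, sim$eye)), ]
  ft$rnfl_um <- eyes$rnfl_um
  ft$hvf_md_db <- eyes$hvf_md_db
  # plant a linear RNFL relationship
  set.seed(52)
  ft$phnr_min_uv <- -1 - 0.03 * ft$rnfl_um + rnorm(nrow(ft), 0, 0.5)
  res <- structureFunctionModels(ft, "rnfl")
  row <- res[res$feature == "phnr_min" & res$term == "predictor", ]
  expect_lt(abs(row$estimate - (-0.03)), 3 * row$robust_se)
  # acute eyes are excluded from OCT fits
  expect_identical(row$n_obs,
                   as.integer(sum(ft$eye_class != "on_acute" &
                                    !is.na(ft$rnfl_um))))
  # an independent predictor has a null slope
  ft$phnr_min_uv <- rnorm(nrow(ft))
  res0 <- structureFunctionModels(ft, "hvf_md")
  row0 <- res0[res0$feature == "phnr_min" & res0$term == "predictor", ]
  expect_lt(abs(row0$z), 3.5)
  expect_error(structureFunctionModels(ft[0, ], "rnfl"))
})
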
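test_that("analysis table joins RTACC values and conserves participants", {
  cfg <- cohort_config(n_participants = 6, seed = 15)
  cohort <- generate_cohort(cfg, dir = NULL)
  vals <- rtacc_windows(cohort$training_log, windows = c(2, 4))
  tab <- build_analysis_table(cohort$participants, vals, window = 4)
  expect_equal(nrow(tab) + attr(tab, "n_dropped"), nrow(cohort$participants))
  expect_equal(nrow(tab), sum(vals$defined[vals$window_weeks == 4]))
  expect_true("rtacc" %in% names(tab))
  expect_error(build_analysis_table(cohort$participants, vals, window = 13),
               "window 13")
})

test_that("the adjusted linear fit matches the normal-equations closed form", {
  set.seed(22)
  for (i in 1:20) {
    tab <- random_table(n = sample(40:120, 1))
    fit <- fit_linear_rbans(tab)
    expect_equal(unname(fit$coefficients), unname(ols_oracle(tab)),
                 tolerance = 1e-8)
    expect_equal(fit$n_obs, nrow(tab))
    expect_true(all(fit$p_values >= 0 & fit$p_values <= 1))
  }
})

test_that("noiseless planted tables are recovered to numerical precision", {
  cfg <- cohort_config(
    n_participants = 40, seed = 23,
    outcome_params = list(resid_sd = 0),
    biomarker_params = list(
      bdnf = list(resid_sd = 0), ptau = list(resid_sd = 0),
      nfl = list(resid_sd = 0), gfap = list(resid_sd = 0)))
  tab <- planted_table(cfg)
  fit <- suppressWarnings(fit_linear_rbans(tab))  # perfect-fit summary warning
  op <- cfg$outcome_params
  # regressing week-24 on baseline turns the planted change-score baseline
  # effect beta_baseline into a coefficient of 1 + beta_baseline
  truth <- c(op$beta0, op$beta_age, op$beta_sex, op$beta_edu, op$beta_apoe,
             1 + op$beta_baseline, op$beta_rtacc)
  expect_equal(unname(fit$coefficients), truth, tolerance = 1e-8)
})

test_that("rank-deficient designs fail with the collinear term named", {
  tab <- random_table(50)
  tab$rtacc <- 0.25
  expect_error(fit_linear_rbans(tab), "rtacc")
  expect_error(fit_robust_rbans(tab), "rtacc")
})

test_that("the Huber fit reduces to OLS in the no-outlier limits", {
  set.seed(31)
  tab <- random_table(80)
  ols <- fit_linear_rbans(tab)

  # tuning -> infinity: psi is the identity, IRLS stays at least squares
  rlm_wide <- fit_robust_rbans(tab, tuning = 1e8)
  expect_equal(unname(rlm_wide$coefficients), unname(ols$coefficients),
               tolerance = 1e-6)

  # bounded two-point errors: every |residual| < tuning * MAD-scale,
  # so all Huber weights are 1 and the M-estimate is the LS estimate
  tab2 <- random_table(80)
  beta <- c(5, -0.1, 1, 0.2, -2, 0.9, -11.9)
  X <- cbind(1, tab2$age, tab2$sex, tab2$education_years, tab2$apoe_e4,
             tab2$rbans_baseline, tab2$rtacc)
  tab2$rbans_week24 <- drop(X %*% beta) + sample(c(-2, 2), 80, replace = TRUE)
  rlm_fit <- fit_robust_rbans(tab2)
  expect_true(all(rlm_fit$weights > 1 - 1e-10))
  expect_equal(unname(rlm_fit$coefficients),
               unname(fit_linear_rbans(tab2)$coefficients), tolerance = 1e-6)
  expect_true(rlm_fit$converged)
})

test_that("the Huber fit resists gross outcome contamination", {
  cfg <- cohort_config(seed = 33)
  set.seed(33)
  wins <- vapply(1:40, function(i) {
    tab <- planted_table(cfg)
    bad <- sample(nrow(tab), round(0.1 * nrow(tab)))
    tab$rbans_week24[bad] <- tab$rbans_week24[bad] + 50
    b_ols <- fit_linear_rbans(tab)$coefficients["rtacc"]
    b_rlm <- fit_robust_rbans(tab)$coefficients["rtacc"]
    abs(b_rlm + 11.90) < abs(b_ols + 11.90)
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})

test_that("a noiseless outcome equation recovers the planted path system exactly", {
  # markers keep their own residual variation (otherwise they would be
  # collinear with the coupling); the outcome equation itself is noiseless,
  # so its coefficients are recovered to numerical precision
  cfg <- cohort_config(
    n_participants = 50, seed = 35,
    outcome_params = list(resid_sd = 0, beta_rtacc = -11.98),
    biomarker_params = list(
      bdnf = list(slope = -3.132, resid_sd = 0.5, outcome_beta = -0.5),
      ptau = list(slope = 2.832, resid_sd = 0.5, outcome_beta = 0.25),
      nfl = list(slope = 0.5, resid_sd = 0.5, outcome_beta = 0),
      gfap = list(slope = -1.5, resid_sd = 0.5, outcome_beta = 0)))
  tab <- planted_table(cfg)
  res <- suppressWarnings(fit_path_model(tab, adjust_covariates = TRUE))
  oc <- res$equations$outcome$coefficients
  expect_equal(unname(oc["rtacc"]), -11.98, tolerance = 1e-8)
  expect_equal(unname(oc["bdnf_change"]), -0.5, tolerance = 1e-8)
  expect_equal(unname(oc["ptau_change"]), 0.25, tolerance = 1e-8)
  expect_equal(unname(oc["nfl_change"]), 0, tolerance = 1e-8)
  expect_equal(unname(oc["rbans_baseline"]),
               1 + cfg$outcome_params$beta_baseline, tolerance = 1e-8)
  # marker equations carry sampling noise; slopes are near the planted values
  expect_equal(unname(res$equations$bdnf$coefficients["rtacc"]), -3.132,
               tolerance = 0.3)
})

test_that("indirect effects equal the product of their path estimates exactly", {
  cfg <- cohort_config(n_participants = 60, seed = 36)
  tab <- planted_table(cfg)
  res <- fit_path_model(tab)
  for (m in res$markers) {
    expect_identical(
      res$indirect_effects[[m]],
      unname(res$equations[[m]]$coefficients["rtacc"]) *
        unname(res$equations$outcome$coefficients[paste0(m, "_change")]))
  }
  expect_equal(res$direct_effect,
               unname(res$equations$outcome$coefficients["rtacc"]))
})

test_that("pruning at alpha = 1 is a no-op and the trace conserves paths", {
  cfg <- cohort_config(n_participants = 60, seed = 37)
  tab <- planted_table(cfg)
  full <- fit_path_model(tab)
  expect_error(fit_path_model(tab, markers = c("bdnf", "nope")), "nope")

  same <- prune_path_model(full, alpha = 1.0000001)
  expect_equal(same$retained, full$retained)
  expect_equal(nrow(same$pruning_trace), 0L)
  expect_equal(same$direct_effect, full$direct_effect)

  pruned <- prune_path_model(full, alpha = 0.05)
  n_in <- 2 * length(full$markers)
  n_out <- sum(unlist(pruned$retained$marker_eq)) +
    sum(unlist(pruned$retained$outcome))
  expect_equal(nrow(pruned$pruning_trace), n_in - n_out)
  # the direct path survives pruning by construction
  expect_true(is.finite(pruned$direct_effect))
})

test_that("rank AUC matches hand counts and edge cases", {
  # good scores 0.9, 0.4 vs poor 0.8, 0.3, 0.2: 5 of 6 pairs concordant
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.3, 0.2),
                       c(TRUE, TRUE, FALSE, FALSE, FALSE)), 5 / 6)
  expect_equal(roc_auc(c(10, 9, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "each class")
})

test_that("rank AUC equals trapezoidal ROC integration and the pROC reference", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(10:80, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
    expect_lt(abs(roc_auc(scores, labels) - auc_trapezoid(scores, labels)),
              1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(42)
  labels <- runif(60) > 0.4
  labels[1:2] <- c(TRUE, FALSE)
  scores <- rnorm(60)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(
                 labels, scores, quiet = TRUE, direction = "<",
                 levels = c(FALSE, TRUE)))),
               tolerance = 1e-12)
})

test_that("responder models are nested, scored and bootstrap-bounded", {
  cfg <- cohort_config(seed = 43)
  tab <- planted_table(cfg)
  mods <- fit_responder_models(tab, bootstrap_reps = 300, seed = 43)
  expect_length(mods, 3)
  m1 <- mods[[1]]; m2 <- mods[[2]]; m3 <- mods[[3]]
  expect_setequal(m3$fit$terms, union(m1$fit$terms, "rtacc"))
  expect_setequal(m2$fit$terms, c("(Intercept)", "rtacc"))
  expect_lte(m3$deviance, m1$deviance)  # nested models
  for (m in mods) {
    expect_true(m$auc >= 0 && m$auc <= 1)
    expect_lte(m$auc_ci[1], m$auc)
    expect_gte(m$auc_ci[2], m$auc)
    expect_equal(m$n_good + m$n_poor, nrow(tab))
  }
})

test_that("degenerate responder inputs are caught", {
  cfg <- cohort_config(n_participants = 40, seed = 44)
  tab <- planted_table(cfg)
  lab <- label_responders(tab)
  lab$label[] <- "good"
  expect_error(fit_responder_models(tab, lab), "each class")

  # a perfectly separating predictor triggers the separation warning
  tab2 <- tab
  lab2 <- label_responders(tab2)
  tab2$rtacc <- ifelse(lab2$label == "good", 1, -1) + rnorm(40, 0, 1e-4)
  expect_warning(
    mods <- fit_responder_models(tab2, lab2, bootstrap_reps = 50, seed = 1),
    "separation")
  expect_true(mods[[2]]$fit$separated)
})

test_that("an informative coupling lifts AUC above the clinical-only model", {
  cfg <- cohort_config(
    seed = 45,
    outcome_params = list(beta_age = 0, beta_sex = 0, beta_edu = 0,
                          beta_apoe = 0, beta_baseline = 0, beta0 = 0,
                          beta_rtacc = -30, resid_sd = 5))
  set.seed(45)
  diffs <- vapply(1:30, function(i) {
    tab <- planted_table(cfg)
    mods <- fit_responder_models(tab, bootstrap_reps = 20, seed = i)
    mods[[2]]$auc - mods[[1]]$auc
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
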
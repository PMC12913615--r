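test_that("participant generation is seed-deterministic and respects bounds", {
  cfg <- cohort_config(n_participants = 50, seed = 7)
  a <- generate_participants(cfg)
  b <- generate_participants(cfg)
  expect_identical(a, b)

  expect_true(all(a$age >= 60 & a$age <= 85))
  expect_true(all(a$education_years >= 0))
  expect_true(all(a$sex %in% c(0, 1)))
  expect_true(all(a$apoe_e4 %in% c(0, 1)))
  expect_true(all(abs(a$rho_true) < 1))
  expect_true(all(is.na(a$rbans_week24)))

  expect_equal(nrow(generate_participants(cohort_config(n_participants = 0))), 0L)
})

test_that("generated covariate means match the configured truth over seeds", {
  cfg <- cohort_config()
  ages <- numeric(0)
  edus <- numeric(0)
  for (s in 1:40) {
    p <- generate_participants(cohort_config(seed = s))
    ages <- c(ages, p$age)
    edus <- c(edus, p$education_years)
  }
  # truncation to [60, 85] shifts the configured 73.02 by < 0.1
  expect_lt(abs(mean(ages) - cfg$covariate_params$age_mean), 0.5)
  expect_lt(abs(mean(edus) - cfg$covariate_params$edu_mean), 0.5)
})

test_that("training streams follow the schedule and record invariants", {
  cfg <- cohort_config(seed = 3)
  p <- generate_participants(cfg)[1, ]
  s <- simulate_training_stream(p, cfg, seed = 11)

  expect_lt(abs(nrow(s) - 390), 0.1 * 390)
  expect_true(all(s$accuracy >= 0 & s$accuracy <= 1))
  expect_true(all(s$mean_rt_s > 0))
  expect_true(all(s$week >= 1 & s$week <= cfg$n_weeks))
  expect_setequal(unique(s$week), seq_len(cfg$n_weeks))
  expect_true(all(s$difficulty >= cfg$difficulty_params$level_min &
                  s$difficulty <= cfg$difficulty_params$level_max))
  expect_true(all(s$game_id %in% default_catalog()$game_id))
  # within a week, tasks come in sessions of tasks_per_session
  per_week <- table(s$week)
  expect_true(all(per_week %% cfg$schedule$tasks_per_session == 0))

  expect_identical(simulate_training_stream(p, cfg, seed = 11), s)
})

test_that("staircase saturates at the maximum level under perfect accuracy", {
  cfg <- cohort_config(acc_params = list(mean = 5, sd = 1e-6), seed = 2)
  p <- generate_participants(cfg)[1, ]
  s <- simulate_training_stream(p, cfg, seed = 5)
  expect_true(all(s$accuracy == 1))
  lmax <- cfg$difficulty_params$level_max
  first_max <- match(lmax, s$difficulty)
  expect_false(is.na(first_max))
  expect_true(all(s$difficulty[first_max:nrow(s)] == lmax))
})

test_that("streams realise the planted RT-accuracy coupling", {
  cfg <- cohort_config(seed = 1)
  p <- generate_participants(cfg)[1, ]
  p$rho_true <- -0.5
  r <- vapply(1:30, function(i) {
    s <- simulate_training_stream(p, cfg, seed = 1000 + i)
    cor(s$mean_rt_s, s$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(r) + 0.5), 0.05)
})

test_that("sample correlation stays within 0.07 of the planted coupling in ≥95% of long streams", {
  cfg <- cohort_config(n_weeks = 96, seed = 1)  # ~1560 pairs per stream
  p <- generate_participants(cohort_config(seed = 1))[1, ]
  for (rho in c(-0.6, 0.3)) {
    p$rho_true <- rho
    dev <- vapply(1:100, function(i) {
      s <- simulate_training_stream(p, cfg, seed = 5000 + i)
      abs(cor(s$mean_rt_s, s$accuracy) - rho)
    }, numeric(1))
    expect_gte(mean(dev < 0.07), 0.95)
  }
})

test_that("noiseless outcomes reproduce the planted linear map exactly", {
  cfg <- cohort_config(
    n_participants = 5, seed = 4,
    outcome_params = list(resid_sd = 0),
    biomarker_params = list(
      bdnf = list(resid_sd = 0), ptau = list(resid_sd = 0),
      nfl = list(resid_sd = 0), gfap = list(resid_sd = 0))
  )
  p <- generate_participants(cfg)
  p <- simulate_outcomes(p, cfg)
  op <- cfg$outcome_params
  by_hand <- op$beta0 + op$beta_age * p$age + op$beta_sex * p$sex +
    op$beta_edu * p$education_years + op$beta_apoe * p$apoe_e4 +
    op$beta_baseline * p$rbans_baseline + op$beta_rtacc * p$rho_true
  expect_equal(p$rbans_change, by_hand, tolerance = 1e-12)
  expect_equal(p$rbans_week24, p$rbans_baseline + by_hand, tolerance = 1e-12)
  expect_equal(p$bdnf_change,
               cfg$biomarker_params$bdnf$slope * p$rho_true,
               tolerance = 1e-12)
})

test_that("a zero planted effect yields no coupling-outcome association", {
  cfg <- cohort_config(n_participants = 80,
                       outcome_params = list(beta_rtacc = 0))
  set.seed(42)
  r <- vapply(1:100, function(i) {
    p <- simulate_outcomes(generate_participants(cfg, seed = NULL), cfg)
    cor(p$rho_true, p$rbans_change)
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.05)
})

test_that("outcome simulation validates input lengths", {
  cfg <- cohort_config(n_participants = 4)
  p <- generate_participants(cfg)
  expect_error(simulate_outcomes(p, cfg, rtacc_true = c(0.1, 0.2)),
               "one value per profile")
})

test_that("cohort generation conserves records, round-trips, and is byte-stable", {
  cfg <- cohort_config(n_participants = 3, n_weeks = 2, seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- generate_cohort(cfg, dir = d1)
  c2 <- generate_cohort(cfg, dir = d2)

  lens <- vapply(split(c1$training_log, c1$training_log$participant_id),
                 nrow, integer(1))
  expect_equal(nrow(c1$training_log), sum(lens))

  for (f in c("participants.csv", "training_log.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }

  # round-trip through the readers with zero validation rejects
  log_back <- read_training_log(file.path(d1, "training_log.csv"))
  part_back <- read_participants(file.path(d1, "participants.csv"))
  expect_equal(nrow(attr(log_back, "rejected")), 0L)
  expect_equal(nrow(attr(part_back, "rejected")), 0L)
  expect_equal(nrow(log_back), nrow(c1$training_log))
  expect_equal(part_back$rbans_change, c1$participants$rbans_change,
               tolerance = 1e-12)
})
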
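# shared fixture builders; everything is generated in code at test time

tiny_config <- function(n = 8, weeks = 4, seed = 101, ...) {
  cohort_config(n_participants = n, n_weeks = weeks, seed = seed, ...)
}

# participant table with outcomes filled and the planted coupling exposed
# as the rtacc column (bypasses the training stream; used by model tests)
planted_table <- function(config, seed = NULL) {
  p <- generate_participants(config, seed = seed)
  p <- simulate_outcomes(p, config)
  p$rtacc <- p$rho_true
  p
}

# random well-conditioned regression table for algebra oracles
random_table <- function(n = 60) {
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = stats::rnorm(n, 73, 5),
    sex = stats::rbinom(n, 1, 0.6),
    education_years = stats::rnorm(n, 11, 4),
    apoe_e4 = stats::rbinom(n, 1, 0.3),
    rbans_baseline = stats::rnorm(n, 90, 15),
    rtacc = stats::rnorm(n, -0.2, 0.3),
    rbans_week24 = stats::rnorm(n, 98, 16),
    stringsAsFactors = FALSE
  )
}

# independent product-moment correlation oracle (explicit sum formula)
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x * x) - sx * sx) * (n * sum(y * y) - sy * sy))
}

# independent OLS oracle: normal equations solved directly
ols_oracle <- function(table) {
  X <- cbind(1, table$age, table$sex, table$education_years, table$apoe_e4,
             table$rbans_baseline, table$rtacc)
  solve(crossprod(X), crossprod(X, table$rbans_week24))[, 1]
}

# independent AUC oracle: trapezoidal integration of the empirical ROC
auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels] >= t), numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(scores[!labels] >= t), numeric(1)))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# brute-force MAD flags: sort-based median, explicit absolute deviations
mad_flags_oracle <- function(v, k = 3, scale = 1.4826) {
  med_of <- function(x) {
    s <- sort(x)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  med <- med_of(v)
  dev <- abs(v - med)
  m <- med_of(dev)
  if (m == 0) rep(FALSE, length(v)) else dev > k * scale * m
}

# hand-built training-log records for one participant
make_records <- function(rt, acc, pid = "P1", week = NULL, game = NULL) {
  n <- length(rt)
  cat18 <- default_catalog()
  data.frame(
    participant_id = rep(pid, n),
    week = week %||% rep(1L, n),
    session_index = rep(1L, n),
    task_index = seq_len(n),
    game_id = game %||% rep_len(cat18$game_id, n),
    domain = rep("attention", n),
    difficulty = rep(3L, n),
    mean_rt_s = rt,
    accuracy = acc,
    n_trials = rep(20L, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
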
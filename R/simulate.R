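#' Generate baseline participant profiles
#'
#' Draws covariates independently from the configured distributions:
#' truncated normals for age (eligibility bounds) and education (floored at
#' 0), a normal for baseline RBANS, Bernoulli indicators for sex
#' (1 = female) and APOE e4 carriage, and the latent per-participant
#' RT-accuracy coupling `rho_true` from a normal truncated to (-1, 1).
#' Outcome and biomarker columns are left unfilled (see
#' [simulate_outcomes()]).
#'
#' @param config A [cohort_config()].
#' @param seed Seed to set before drawing; defaults to `config$seed`. Pass
#'   `NULL` to continue from the current RNG state (used by
#'   [generate_cohort()], which seeds once for the whole cohort).
#' @return A `data.frame` with one row per participant: `participant_id`,
#'   `age`, `sex`, `education_years`, `apoe_e4`, `rbans_baseline`,
#'   `rho_true`, and `NA` columns for `rbans_week24`, `rbans_change` and
#'   the four biomarker changes.
#' @export
generate_participants <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_participants
  cv <- config$covariate_params
  cp <- config$coupling_params

  if (n == 0L) {
    return(empty_participants())
  }

  df <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = rtrunc_norm(n, cv$age_mean, cv$age_sd, cv$age_min, cv$age_max),
    sex = stats::rbinom(n, 1L, cv$p_female),
    education_years = rtrunc_norm(n, cv$edu_mean, cv$edu_sd, 0, Inf),
    apoe_e4 = stats::rbinom(n, 1L, cv$p_apoe4),
    rbans_baseline = stats::rnorm(n, cv$rbans_mean, cv$rbans_sd),
    rbans_week24 = NA_real_,
    rbans_change = NA_real_,
    bdnf_change = NA_real_,
    ptau_change = NA_real_,
    nfl_change = NA_real_,
    gfap_change = NA_real_,
    rho_true = rtrunc_norm(n, cp$mean, cp$sd, -1, 1),
    stringsAsFactors = FALSE
  )
  df
}

empty_participants <- function() {
  data.frame(
    participant_id = character(0), age = numeric(0), sex = integer(0),
    education_years = numeric(0), apoe_e4 = integer(0),
    rbans_baseline = numeric(0), rbans_week24 = numeric(0),
    rbans_change = numeric(0), bdnf_change = numeric(0),
    ptau_change = numeric(0), nfl_change = numeric(0),
    gfap_change = numeric(0), rho_true = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Simulate one participant's adaptive training stream
#'
#' Schedules `sessions_min + Binomial(sessions_extra, p_extra)` sessions per
#' week, each of `tasks_per_session` 3-minute tasks cycling through the game
#' catalogue. Each task draws a bivariate standard-normal latent with
#' correlation `rho_true`; one component drives log RT (log-normal, floored
#' at `rt_params$floor` seconds) and the other drives accuracy through a
#' clamped linear link into \[0, 1\]. Difficulty follows a staircase: it
#' increments after a task with accuracy at or above `difficulty_params$up`,
#' decrements below `difficulty_params$down`, and is clamped to the level
#' bounds. With the default zero per-level performance gradients the
#' population RT-accuracy correlation across tasks equals the planted
#' `rho_true` (up to the mild attenuation of the positive/bounded links).
#'
#' @param profile One row of [generate_participants()] output (needs
#'   `participant_id` and `rho_true`).
#' @param config A [cohort_config()].
#' @param seed Optional seed; default `NULL` continues the current RNG
#'   stream.
#' @return A `data.frame` of task records: `participant_id`, `week`,
#'   `session_index`, `task_index`, `game_id`, `domain`, `difficulty`,
#'   `mean_rt_s`, `accuracy`, `n_trials`.
#' @export
simulate_training_stream <- function(profile, config, seed = NULL) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  rho <- profile$rho_true
  if (is.null(rho) || is.na(rho)) stop("profile must carry rho_true")
  if (abs(rho) >= 1) stop("rho_true must lie in (-1, 1)")

  sc <- config$schedule
  dp <- config$difficulty_params
  rp <- config$rt_params
  ap <- config$acc_params
  catal <- default_catalog()

  sessions <- sc$sessions_min + stats::rbinom(config$n_weeks, sc$sessions_extra, sc$p_extra)
  tasks_per_week <- sessions * sc$tasks_per_session
  n_tasks <- sum(tasks_per_week)
  if (n_tasks == 0L) return(empty_training_log())

  week <- rep(seq_len(config$n_weeks), times = tasks_per_week)
  session_index <- unlist(lapply(sessions, function(s) rep(seq_len(s), each = sc$tasks_per_session)),
                          use.names = FALSE)
  task_index <- rep_len(seq_len(sc$tasks_per_session), n_tasks)

  # performance on short standardized game tasks has a bounded dynamic
  # range (response windows and task design cap how extreme a 3-minute
  # mean can be), so the latent variation is truncated; this reproduces
  # the absence of MAD-rule outliers in real training streams
  z_rt <- stats::rnorm(n_tasks)
  z_acc <- rho * z_rt + sqrt(1 - rho^2) * stats::rnorm(n_tasks)
  z_rt <- clamp(z_rt, -rp$latent_trunc, rp$latent_trunc)
  z_acc <- clamp(z_acc, -ap$latent_trunc, ap$latent_trunc)
  n_trials <- sample(seq(config$trials_per_task[1], config$trials_per_task[2]),
                     n_tasks, replace = TRUE)

  # staircase is inherently sequential: level_i depends on accuracy_{i-1}
  level <- integer(n_tasks)
  accuracy <- numeric(n_tasks)
  mean_rt <- numeric(n_tasks)
  lvl <- dp$start_level
  for (i in seq_len(n_tasks)) {
    acc <- clamp(ap$mean + ap$per_level * (lvl - dp$start_level) + ap$sd * z_acc[i], 0, 1)
    rt <- max(rp$floor,
              exp(rp$log_mean + rp$per_level * (lvl - dp$start_level) + rp$log_sd * z_rt[i]))
    level[i] <- lvl
    accuracy[i] <- acc
    mean_rt[i] <- rt
    if (acc >= dp$up) {
      lvl <- min(lvl + 1L, dp$level_max)
    } else if (acc < dp$down) {
      lvl <- max(lvl - 1L, dp$level_min)
    }
  }

  g <- ((seq_len(n_tasks) - 1L) %% nrow(catal)) + 1L
  data.frame(
    participant_id = rep(profile$participant_id, n_tasks),
    week = week,
    session_index = session_index,
    task_index = task_index,
    game_id = catal$game_id[g],
    domain = catal$domain[g],
    difficulty = level,
    mean_rt_s = mean_rt,
    accuracy = accuracy,
    n_trials = n_trials,
    stringsAsFactors = FALSE
  )
}

empty_training_log <- function() {
  data.frame(
    participant_id = character(0), week = integer(0),
    session_index = integer(0), task_index = integer(0),
    game_id = character(0), domain = character(0), difficulty = integer(0),
    mean_rt_s = numeric(0), accuracy = numeric(0), n_trials = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Fill in outcome and biomarker changes from planted linear effects
#'
#' Biomarker changes are generated first, one per marker:
#' `change_m = a_m + b_m * rho + eps_m`. The RBANS change score is then
#' `beta0 + beta_age*age + beta_sex*sex + beta_edu*education +
#' beta_apoe*APOEe4 + beta_baseline*rbans_baseline + beta_rtacc*rho +
#' sum_m c_m * change_m + eps`, and week-24 RBANS is baseline plus change.
#' The planted effect `rho` is the latent coupling (`rho_true`), not an
#' estimate; the marker-to-outcome terms `c_m` default to 0.
#'
#' @param profiles Output of [generate_participants()].
#' @param config A [cohort_config()].
#' @param rtacc_true Per-participant planted coupling values; defaults to
#'   `profiles$rho_true`. Must match `nrow(profiles)`.
#' @param seed Optional seed; default `NULL` continues the RNG stream.
#' @return `profiles` with `rbans_week24`, `rbans_change` and the four
#'   `*_change` biomarker columns filled.
#' @export
simulate_outcomes <- function(profiles, config, rtacc_true = profiles$rho_true,
                              seed = NULL) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(profiles)
  if (length(rtacc_true) != n)
    stop("rtacc_true must have one value per profile (got ",
         length(rtacc_true), " for ", n, " profiles)")
  if (n == 0L) return(profiles)

  bp <- config$biomarker_params
  marker_cols <- paste0(names(bp), "_change")
  marker_contrib <- numeric(n)
  for (m in names(bp)) {
    pm <- bp[[m]]
    change <- pm$intercept + pm$slope * rtacc_true + stats::rnorm(n, 0, pm$resid_sd)
    profiles[[paste0(m, "_change")]] <- change
    marker_contrib <- marker_contrib + pm$outcome_beta * change
  }

  op <- config$outcome_params
  change <- op$beta0 +
    op$beta_age * profiles$age +
    op$beta_sex * profiles$sex +
    op$beta_edu * profiles$education_years +
    op$beta_apoe * profiles$apoe_e4 +
    op$beta_baseline * profiles$rbans_baseline +
    op$beta_rtacc * rtacc_true +
    marker_contrib +
    stats::rnorm(n, 0, op$resid_sd)

  profiles$rbans_week24 <- profiles$rbans_baseline + change
  profiles$rbans_change <- change
  profiles
}

#' Generate a full synthetic cohort and write it to disk
#'
#' Seeds the RNG once from `config$seed`, then draws participants, one
#' adaptive training stream per participant, and outcomes, in a fixed
#' order, so a given config is bit-for-bit reproducible. Writes
#' `participants.csv`, `training_log.csv` and a `cohort_config.json`
#' sidecar recording the exact configuration and seed.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return Invisibly, a list with `participants`, `training_log`, and
#'   `paths` (named character vector of written files, empty if
#'   `dir = NULL`).
#' @examples
#' cfg <- cohort_config(n_participants = 3, n_weeks = 2, seed = 42)
#' cohort <- generate_cohort(cfg, dir = NULL)
#' nrow(cohort$training_log)
#' @export
generate_cohort <- function(config, dir = NULL) {
  validate_cohort_config(config)
  profiles <- generate_participants(config, seed = config$seed)
  streams <- lapply(seq_len(nrow(profiles)), function(i) {
    simulate_training_stream(profiles[i, , drop = FALSE], config, seed = NULL)
  })
  training_log <- if (length(streams)) do.call(rbind, streams) else empty_training_log()
  rownames(training_log) <- NULL
  profiles <- simulate_outcomes(profiles, config, seed = NULL)

  paths <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
      participants = file.path(dir, "participants.csv"),
      training_log = file.path(dir, "training_log.csv"),
      config = file.path(dir, "cohort_config.json")
    )
    utils::write.csv(profiles, paths[["participants"]], row.names = FALSE, na = "")
    utils::write.csv(training_log, paths[["training_log"]], row.names = FALSE, na = "")
    sidecar <- c(unclass(config), list(config_hash = config_hash(unclass(config))))
    jsonlite::write_json(sidecar, paths[["config"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(list(participants = profiles, training_log = training_log, paths = paths))
}
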
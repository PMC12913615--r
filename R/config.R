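#' Synthetic cohort configuration
#'
#' Builds the full set of generator knobs for a synthetic multi-domain
#' intervention cohort. The defaults are calibrated to the published
#' summaries of the trial the generator emulates: 130 participants aged
#' 60-85 (mean 73.02, SD 5.53), 10.73 (4.54) years of education, 63.85%
#' female, 31.54% APOE e4 carriers, baseline RBANS 90.10 (15.26); a 24-week
#' schedule of 3-5 sessions/week of four 3-minute tasks, giving an expected
#' 390 RT-accuracy pairs per participant; a planted RTACC effect on the
#' cognitive outcome of -11.90 RBANS points per correlation unit; and
#' planted biomarker paths (RTACC to change in BDNF, pTau181, NfL, GFAP)
#' matching the reported path coefficients, with zero biomarker-to-outcome
#' effects by default.
#'
#' Partial lists are merged into the documented defaults, so
#' `cohort_config(coupling_params = list(mean = -0.4))` changes only the
#' coupling mean.
#'
#' @param n_participants Number of participants to simulate.
#' @param n_weeks Length of the training period in weeks.
#' @param schedule Weekly schedule parameters: `sessions_min` (guaranteed
#'   sessions/week), `sessions_extra` and `p_extra` (the extra sessions are
#'   binomial, so sessions/week ranges over
#'   `sessions_min .. sessions_min + sessions_extra`), and
#'   `tasks_per_session` (game-based tasks per session). The defaults give
#'   an expected `24 * 4 * (3 + 2 * 0.53) = 389.76` tasks per participant.
#' @param trials_per_task Integer range `c(min, max)` of trials within one
#'   3-minute task (uniform).
#' @param covariate_params Means/SDs/proportions for the baseline table:
#'   `age_mean`, `age_sd`, `age_min`, `age_max` (eligibility truncation),
#'   `edu_mean`, `edu_sd` (truncated at 0), `p_female`, `p_apoe4`,
#'   `rbans_mean`, `rbans_sd` (untruncated).
#' @param coupling_params `mean` and `sd` of the latent per-participant
#'   RT-accuracy coupling `rho_p`, truncated to (-1, 1).
#' @param outcome_params Planted linear model for the RBANS change score:
#'   `beta0` (intercept), `beta_age`, `beta_sex`, `beta_edu`, `beta_apoe`,
#'   `beta_baseline`, `beta_rtacc` and the residual SD `resid_sd`. Week-24
#'   RBANS is baseline plus this change plus Gaussian noise.
#' @param biomarker_params One list per marker (`bdnf`, `ptau`, `nfl`,
#'   `gfap`), each with `intercept`, `slope` (coupling-to-marker path),
#'   `resid_sd`, and `outcome_beta` (marker-to-outcome path, default 0 for
#'   all markers, mirroring the non-significant reported paths).
#' @param difficulty_params Adaptive staircase: `level_min`, `level_max`,
#'   `start_level`, `up` (accuracy at or above which difficulty increments)
#'   and `down` (accuracy below which it decrements).
#' @param rt_params Log-scale RT model: `log_mean` (log seconds at the
#'   starting level), `per_level` (additive log-RT shift per difficulty
#'   level, 0 by default so the planted coupling is exact), `log_sd`,
#'   `floor` (positivity floor in seconds), and `latent_trunc` (the latent
#'   normal is truncated at this many SDs: short standardized tasks have a
#'   bounded dynamic range, which is what makes real training streams free
#'   of MAD-rule outliers).
#' @param acc_params Accuracy model: `mean`, `per_level` (0 by default),
#'   `sd`, `latent_trunc` (as for `rt_params`); values are clamped into
#'   \[0, 1\].
#' @param seed Integer master seed; every stochastic stage derives from it.
#' @return A validated object of class `cohort_config`.
#' @seealso [generate_cohort()], [expected_pairs_per_participant()]
#' @examples
#' cfg <- cohort_config(n_participants = 10, seed = 7)
#' expected_pairs_per_participant(cfg)
#' @export
cohort_config <- function(n_participants = 130L,
                          n_weeks = 24L,
                          schedule = list(),
                          trials_per_task = c(10L, 30L),
                          covariate_params = list(),
                          coupling_params = list(),
                          outcome_params = list(),
                          biomarker_params = list(),
                          difficulty_params = list(),
                          rt_params = list(),
                          acc_params = list(),
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_weeks = as.integer(n_weeks),
    schedule = utils::modifyList(
      list(sessions_min = 3L, sessions_extra = 2L, p_extra = 0.53,
           tasks_per_session = 4L),
      schedule
    ),
    trials_per_task = as.integer(trials_per_task),
    covariate_params = utils::modifyList(
      list(age_mean = 73.02, age_sd = 5.53, age_min = 60, age_max = 85,
           edu_mean = 10.73, edu_sd = 4.54,
           p_female = 0.6385, p_apoe4 = 0.3154,
           rbans_mean = 90.10, rbans_sd = 15.26),
      covariate_params
    ),
    coupling_params = utils::modifyList(
      list(mean = -0.2, sd = 0.25),
      coupling_params
    ),
    outcome_params = utils::modifyList(
      list(beta0 = 20.038, beta_age = -0.10, beta_sex = 1.0,
           beta_edu = 0.20, beta_apoe = -2.0, beta_baseline = -0.10,
           beta_rtacc = -11.90, resid_sd = 7.94),
      outcome_params
    ),
    biomarker_params = utils::modifyList(
      list(
        bdnf = list(intercept = 0, slope = -3.132, resid_sd = 4.6,
                    outcome_beta = 0),
        ptau = list(intercept = 0, slope = 2.832, resid_sd = 11.9,
                    outcome_beta = 0),
        nfl  = list(intercept = 0, slope = 3.879, resid_sd = 20.7,
                    outcome_beta = 0),
        gfap = list(intercept = 0, slope = -31.69, resid_sd = 72.9,
                    outcome_beta = 0)
      ),
      biomarker_params
    ),
    difficulty_params = utils::modifyList(
      list(level_min = 1L, level_max = 10L, start_level = 3L,
           up = 0.85, down = 0.65),
      difficulty_params
    ),
    rt_params = utils::modifyList(
      list(log_mean = log(1.8), per_level = 0, log_sd = 0.15, floor = 0.2,
           latent_trunc = 1.8),
      rt_params
    ),
    acc_params = utils::modifyList(
      list(mean = 0.78, per_level = 0, sd = 0.10, latent_trunc = 1.8),
      acc_params
    ),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' @param config A `cohort_config` (or a plain list with the same fields,
#'   e.g. read back from JSON/YAML).
#' @return The validated config, invisibly classed as `cohort_config`.
#' @export
validate_cohort_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or cohort_config")
  fail <- function(msg) stop("invalid cohort_config: ", msg, call. = FALSE)

  if (!is_count(config$n_participants)) fail("n_participants must be a non-negative integer")
  if (!is_count(config$n_weeks, min = 1)) fail("n_weeks must be >= 1")

  sc <- config$schedule
  if (!is_count(sc$sessions_min, 1) || !is_count(sc$sessions_extra) ||
      !is_count(sc$tasks_per_session, 1))
    fail("schedule counts must be positive integers")
  if (!is_number(sc$p_extra) || sc$p_extra < 0 || sc$p_extra > 1)
    fail("schedule$p_extra must be in [0, 1]")

  tr <- config$trials_per_task
  if (length(tr) != 2L || !is_count(tr[1], 1) || !is_count(tr[2], 1) || tr[1] > tr[2])
    fail("trials_per_task must be an increasing integer pair")

  cv <- config$covariate_params
  for (f in c("age_sd", "edu_sd", "rbans_sd"))
    if (!is_number(cv[[f]]) || cv[[f]] <= 0) fail(paste(f, "must be > 0"))
  for (f in c("p_female", "p_apoe4"))
    if (!is_number(cv[[f]]) || cv[[f]] < 0 || cv[[f]] > 1) fail(paste(f, "must be in [0, 1]"))
  if (cv$age_min >= cv$age_max) fail("age_min must be < age_max")

  cp <- config$coupling_params
  if (!is_number(cp$sd) || cp$sd <= 0) fail("coupling sd must be > 0")
  if (!is_number(cp$mean) || cp$mean <= -1 || cp$mean >= 1)
    fail("coupling mean must lie in (-1, 1)")

  if (!is_number(config$outcome_params$resid_sd) || config$outcome_params$resid_sd < 0)
    fail("outcome resid_sd must be >= 0")

  for (m in names(config$biomarker_params)) {
    bm <- config$biomarker_params[[m]]
    if (!is_number(bm$resid_sd) || bm$resid_sd < 0)
      fail(paste0("biomarker ", m, " resid_sd must be >= 0"))
  }

  dp <- config$difficulty_params
  if (!is_count(dp$level_min, 1) || !is_count(dp$level_max, 1) ||
      dp$level_min > dp$level_max)
    fail("difficulty level bounds must satisfy level_min <= level_max")
  if (dp$start_level < dp$level_min || dp$start_level > dp$level_max)
    fail("start_level must lie inside the level bounds")
  if (!is_number(dp$up) || !is_number(dp$down) || dp$down > dp$up)
    fail("staircase thresholds must satisfy down <= up")

  if (!is_number(config$rt_params$log_sd) || config$rt_params$log_sd <= 0)
    fail("rt_params$log_sd must be > 0")
  if (!is_number(config$rt_params$floor) || config$rt_params$floor <= 0)
    fail("rt_params$floor must be > 0")
  if (!is_number(config$acc_params$sd) || config$acc_params$sd <= 0)
    fail("acc_params$sd must be > 0")
  if (!is_count(abs(config$seed))) fail("seed must be an integer")

  class(config) <- "cohort_config"
  invisible(config)
}

#' Expected number of RT-accuracy pairs per participant
#'
#' Closed form from the schedule parameters:
#' `n_weeks * tasks_per_session * (sessions_min + sessions_extra * p_extra)`.
#'
#' @param config A `cohort_config`.
#' @return Expected task count (a double).
#' @export
expected_pairs_per_participant <- function(config) {
  sc <- config$schedule
  config$n_weeks * sc$tasks_per_session * (sc$sessions_min + sc$sessions_extra * sc$p_extra)
}

#' Write a cohort configuration to JSON or YAML
#'
#' @param config A `cohort_config`.
#' @param path Output path; the extension (`.json`, `.yaml`/`.yml`)
#'   selects the format.
#' @return `path`, invisibly.
#' @export
save_cohort_config <- function(config, path) {
  validate_cohort_config(config)
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    stop("unsupported config format: .", ext)
  }
  invisible(path)
}

#' Read a cohort configuration from JSON or YAML
#'
#' The loaded fields are merged into the package defaults and re-validated,
#' so a hand-written partial config file is acceptable.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext)
  }
  top <- c("n_participants", "n_weeks", "trials_per_task", "seed")
  args <- x[intersect(names(x), top)]
  nested <- setdiff(names(x), top)
  args <- c(args, x[nested])
  do.call(cohort_config, args)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  participants: %d, weeks: %d, seed: %d\n",
              x$n_participants, x$n_weeks, x$seed))
  cat(sprintf("  expected pairs/participant: %.1f\n",
              expected_pairs_per_participant(x)))
  cat(sprintf("  coupling rho_p ~ TN(%.2f, %.2f; -1, 1)\n",
              x$coupling_params$mean, x$coupling_params$sd))
  cat(sprintf("  planted RTACC effect on outcome: %.2f\n",
              x$outcome_params$beta_rtacc))
  invisible(x)
}
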
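#' Pipeline run configuration
#'
#' Bundles every stage's settings into one serializable object. `cohort`
#' is either a [cohort_config()] (synthetic run) or a list
#' `list(participants = <csv>, training_log = <csv>)` pointing at real-format
#' inputs.
#'
#' @param cohort Cohort source, see above.
#' @param preprocess `k`, `scale`, `pooled` for the MAD outlier rule.
#' @param metrics `windows` (ascending), `min_pairs`, `method`.
#' @param models `adjust_covariates`, `alpha` (path pruning),
#'   `bootstrap_reps` (AUC CI).
#' @param seed Master seed; propagated to every stochastic stage.
#' @return A validated `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       preprocess = list(),
                       metrics = list(),
                       models = list(),
                       seed = 1L) {
  cfg <- list(
    cohort = cohort,
    preprocess = utils::modifyList(
      list(k = 3, scale = 1.4826, pooled = FALSE), preprocess),
    metrics = utils::modifyList(
      list(windows = c(1, 2, 3, 6, 12, 24), min_pairs = 10L,
           method = "pearson"), metrics),
    models = utils::modifyList(
      list(adjust_covariates = TRUE, alpha = 0.05, bootstrap_reps = 2000L),
      models),
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' @noRd
validate_run_config <- function(cfg) {
  if (is.unsorted(cfg$metrics$windows, strictly = TRUE))
    stop("metrics$windows must be sorted ascending without duplicates")
  if (!is_number(cfg$preprocess$k) || cfg$preprocess$k <= 0)
    stop("preprocess$k must be > 0")
  if (!is_count(cfg$models$bootstrap_reps, 1))
    stop("models$bootstrap_reps must be a positive integer")
  if (inherits(cfg$cohort, "cohort_config") ||
      (is.list(cfg$cohort) && !is.null(cfg$cohort$n_participants))) {
    validate_cohort_config(cfg$cohort)
  } else if (!(is.list(cfg$cohort) &&
               all(c("participants", "training_log") %in% names(cfg$cohort)))) {
    stop("cohort must be a cohort_config or a list of CSV paths ",
         "(participants, training_log)")
  }
  invisible(cfg)
}

#' Demographics summary table
#'
#' Mean (SD) for continuous baseline fields, n (%) for binary ones, plus
#' the mean 24-week RBANS change — the usual baseline-characteristics
#' layout of an intervention cohort.
#'
#' @param profiles Non-empty participant table with filled outcomes.
#' @return A `data.frame` with columns `statistic`, `value`, `spread`,
#'   `spread_type` (`"sd"` or `"pct"`).
#' @export
summarize_cohort <- function(profiles) {
  if (nrow(profiles) == 0L) stop("summarize_cohort: empty participant table")
  n <- nrow(profiles)
  msd <- function(x) c(mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))
  npct <- function(x) c(sum(x, na.rm = TRUE), 100 * mean(x, na.rm = TRUE))
  rows <- rbind(
    c(msd(profiles$age), 0),
    c(msd(profiles$education_years), 0),
    c(npct(profiles$sex), 1),
    c(npct(profiles$apoe_e4), 1),
    c(msd(profiles$rbans_baseline), 0),
    c(msd(profiles$rbans_week24), 0),
    c(msd(profiles$rbans_change), 0)
  )
  data.frame(
    statistic = c("age_years", "education_years", "female_n", "apoe_e4_n",
                  "rbans_baseline", "rbans_week24", "rbans_change"),
    value = rows[, 1],
    spread = rows[, 2],
    spread_type = ifelse(rows[, 3] == 1, "pct", "sd"),
    stringsAsFactors = FALSE
  )
}

fit_row <- function(mf, label_name, label_value) {
  df <- data.frame(
    label_value,
    beta_rtacc = unname(mf$coefficients["rtacc"]),
    se = unname(mf$standard_errors["rtacc"]),
    statistic = unname(mf$t_or_z["rtacc"]),
    p_value = unname(mf$p_values["rtacc"]),
    n = mf$n_obs,
    stringsAsFactors = FALSE
  )
  names(df)[1] <- label_name
  df
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or ingest), preprocess, RTACC metrics and all
#' model fits into one reproducible run directory:
#'
#' * `participants.csv`, `training_log.csv`, `cohort_config.json` (synthetic
#'   runs only)
#' * `rejected_rows.csv`, `preprocess_report.json`
#' * `rtacc_values.csv` (all windows and leave-one-game-out values)
#' * `window_fits.csv` (adjusted fit per time window, plus the Huber robust
#'   fit of the full window), `exclusion_fits.csv` (one fit per excluded
#'   game), `path_model.csv` (full and pruned path coefficients),
#'   `responders_auc.json` (three models, AUCs, bootstrap CIs)
#' * `summary.csv` (demographics), `report.md`, and optional figures
#'   (RTACC-vs-change scatter, ROC curves).
#'
#' Every artifact carries the configuration hash, and a fixed seed makes
#' the whole run bit-for-bit reproducible.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @param make_plots Write PNG figures (default `TRUE`).
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `preprocess`, `rtacc_values`, `window_fits`, `exclusion_fits`,
#'   `path_full`, `path_pruned`, `responders`, `summary`, `paths`).
#' @export
run_pipeline <- function(config = run_config(), out_dir, make_plots = TRUE) {
  validate_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(unclass(config))
  stage <- "simulate/ingest"
  res <- tryCatch(
    run_pipeline_stages(config, out_dir, make_plots, hash),
    error = function(e) {
      stop("pipeline failed in stage [", attr(e, "stage") %||% stage, "]: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  invisible(res)
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    attr(e, "stage") <- name
    stop(e)
  })
}

run_pipeline_stages <- function(config, out_dir, make_plots, hash) {
  paths <- character(0)
  meta <- list(config_hash = hash, seed = config$seed)

  # -- simulate or ingest ---------------------------------------------------
  synth <- inherits(config$cohort, "cohort_config") ||
    !is.null(config$cohort$n_participants)
  if (synth) {
    cohort_cfg <- validate_cohort_config(config$cohort)
    cohort <- with_stage("simulate",
      generate_cohort(cohort_cfg, dir = file.path(out_dir, "cohort")))
    profiles <- cohort$participants
    raw_log <- cohort$training_log
    rejected <- empty_training_log()
    rejected$line <- integer(0); rejected$reason <- character(0)
    paths <- c(paths, cohort$paths)
  } else {
    profiles <- with_stage("ingest", read_participants(config$cohort$participants))
    raw_log <- with_stage("ingest", read_training_log(config$cohort$training_log))
    rejected <- rbind_fill(attr(raw_log, "rejected"), attr(profiles, "rejected"))
  }
  p_rej <- file.path(out_dir, "rejected_rows.csv")
  utils::write.csv(rejected, p_rej, row.names = FALSE, na = "")
  paths <- c(paths, rejected_rows = p_rej)

  # -- preprocess -----------------------------------------------------------
  pp <- with_stage("preprocess", apply_outlier_filter(
    raw_log, k = config$preprocess$k, scale = config$preprocess$scale,
    pooled = config$preprocess$pooled))
  p_rep <- file.path(out_dir, "preprocess_report.json")
  jsonlite::write_json(c(meta, unclass(pp$report)), p_rep,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, preprocess_report = p_rep)
  records <- pp$records

  # -- metrics --------------------------------------------------------------
  vals_w <- with_stage("rtacc", rtacc_windows(
    records, windows = config$metrics$windows,
    min_pairs = config$metrics$min_pairs, method = config$metrics$method))
  vals_g <- with_stage("rtacc", rtacc_leave_one_game_out(
    records, window_weeks = max(config$metrics$windows),
    min_pairs = config$metrics$min_pairs, method = config$metrics$method))
  rtacc_values <- rbind(vals_w, vals_g)
  p_vals <- file.path(out_dir, "rtacc_values.csv")
  utils::write.csv(rtacc_values, p_vals, row.names = FALSE, na = "")
  paths <- c(paths, rtacc_values = p_vals)

  # -- models ---------------------------------------------------------------
  full_w <- max(config$metrics$windows)
  window_fits <- with_stage("fit", do.call(rbind, lapply(
    config$metrics$windows, function(w) {
      tab <- build_analysis_table(profiles, rtacc_values, window = w)
      fit_row(fit_linear_rbans(tab), "window_weeks", w)
    })))
  tab_full <- build_analysis_table(profiles, rtacc_values, window = full_w)
  rlm_fit <- with_stage("fit", fit_robust_rbans(tab_full))
  window_fits$model <- "ols"
  window_fits <- rbind(window_fits,
                       cbind(fit_row(rlm_fit, "window_weeks", full_w),
                             model = "rlm"))
  p_w <- file.path(out_dir, "window_fits.csv")
  utils::write.csv(cbind(window_fits, config_hash = hash), p_w,
                   row.names = FALSE, na = "")
  paths <- c(paths, window_fits = p_w)

  catal <- default_catalog()
  exclusion_fits <- with_stage("fit", do.call(rbind, lapply(
    catal$game_id, function(g) {
      tab <- build_analysis_table(profiles, rtacc_values, window = full_w,
                                  excluded_game = g)
      fit_row(fit_linear_rbans(tab), "excluded_game", g)
    })))
  exclusion_fits <- cbind(
    domain = catal$domain, game_name = catal$name, exclusion_fits)
  p_e <- file.path(out_dir, "exclusion_fits.csv")
  utils::write.csv(cbind(exclusion_fits, config_hash = hash), p_e,
                   row.names = FALSE, na = "")
  paths <- c(paths, exclusion_fits = p_e)

  markers <- c("bdnf", "ptau", "nfl", "gfap")
  have_markers <- all(paste0(markers, "_change") %in% names(tab_full)) &&
    sum(stats::complete.cases(tab_full[, paste0(markers, "_change")])) >
      length(markers) + 6
  path_full <- path_pruned <- NULL
  if (have_markers) {
    path_full <- with_stage("fit", fit_path_model(
      tab_full, markers, adjust_covariates = config$models$adjust_covariates))
    path_pruned <- with_stage("fit", prune_path_model(
      path_full, alpha = config$models$alpha))
    p_p <- file.path(out_dir, "path_model.csv")
    utils::write.csv(cbind(path_table(path_full, path_pruned),
                           config_hash = hash),
                     p_p, row.names = FALSE, na = "")
    paths <- c(paths, path_model = p_p)
  }

  labels <- with_stage("fit", label_responders(tab_full))
  responders <- with_stage("fit", fit_responder_models(
    tab_full, labels, bootstrap_reps = config$models$bootstrap_reps,
    seed = config$seed))
  p_auc <- file.path(out_dir, "responders_auc.json")
  jsonlite::write_json(c(meta, list(models = lapply(responders, function(r) {
    list(model_id = r$model_id, auc = r$auc,
         auc_ci_lower = r$auc_ci[1], auc_ci_upper = r$auc_ci[2],
         n_good = r$n_good, n_poor = r$n_poor, deviance = r$deviance,
         terms = r$fit$terms, coefficients = unname(r$fit$coefficients))
  }))), p_auc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, responders_auc = p_auc)

  # -- report ---------------------------------------------------------------
  summary_tab <- summarize_cohort(profiles)
  p_s <- file.path(out_dir, "summary.csv")
  utils::write.csv(cbind(summary_tab, config_hash = hash), p_s,
                   row.names = FALSE, na = "")
  paths <- c(paths, summary = p_s)

  if (make_plots) {
    paths <- c(paths, with_stage("report", pipeline_plots(
      out_dir, tab_full, responders)))
  }
  p_md <- file.path(out_dir, "report.md")
  with_stage("report", write_report_md(
    p_md, hash, config, summary_tab, window_fits, exclusion_fits,
    path_full, path_pruned, responders, pp$report))
  paths <- c(paths, report = p_md)

  invisible(list(
    cohort = list(participants = profiles, training_log = records),
    preprocess = pp$report, rtacc_values = rtacc_values,
    window_fits = window_fits, exclusion_fits = exclusion_fits,
    path_full = path_full, path_pruned = path_pruned,
    responders = responders, summary = summary_tab, paths = paths,
    config_hash = hash
  ))
}

rbind_fill <- function(a, b) {
  cols <- union(names(a), names(b))
  for (col in setdiff(cols, names(a))) a[[col]] <- rep(NA, nrow(a))
  for (col in setdiff(cols, names(b))) b[[col]] <- rep(NA, nrow(b))
  rbind(a[cols], b[cols])
}

path_table <- function(full, pruned) {
  one <- function(res, stage) {
    rows <- list()
    oc <- res$equations$outcome
    rows[[1]] <- data.frame(stage = stage, path = "rtacc->outcome",
                            estimate = unname(oc$coefficients["rtacc"]),
                            se = unname(oc$standard_errors["rtacc"]),
                            p_value = unname(oc$p_values["rtacc"]),
                            retained = TRUE, stringsAsFactors = FALSE)
    for (m in res$markers) {
      if (res$retained$marker_eq[[m]]) {
        eq <- res$equations[[m]]
        rows[[length(rows) + 1]] <- data.frame(
          stage = stage, path = paste0("rtacc->", m),
          estimate = unname(eq$coefficients["rtacc"]),
          se = unname(eq$standard_errors["rtacc"]),
          p_value = unname(eq$p_values["rtacc"]),
          retained = TRUE, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          stage = stage, path = paste0("rtacc->", m), estimate = NA_real_,
          se = NA_real_, p_value = NA_real_, retained = FALSE,
          stringsAsFactors = FALSE)
      }
      if (res$retained$outcome[[m]]) {
        rows[[length(rows) + 1]] <- data.frame(
          stage = stage, path = paste0(m, "->outcome"),
          estimate = unname(oc$coefficients[paste0(m, "_change")]),
          se = unname(oc$standard_errors[paste0(m, "_change")]),
          p_value = unname(oc$p_values[paste0(m, "_change")]),
          retained = TRUE, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          stage = stage, path = paste0(m, "->outcome"), estimate = NA_real_,
          se = NA_real_, p_value = NA_real_, retained = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  rbind(one(full, "full"), one(pruned, "pruned"))
}

pipeline_plots <- function(out_dir, tab, responders) {
  fig_dir <- file.path(out_dir, "figures")
  if (!dir.exists(fig_dir)) dir.create(fig_dir)
  p1 <- file.path(fig_dir, "rtacc_vs_change.png")
  grDevices::png(p1, width = 800, height = 600)
  graphics::plot(tab$rtacc, tab$rbans_change,
                 xlab = "RTACC", ylab = "RBANS change (24 wk)",
                 pch = 19, col = "#00000088",
                 main = "RTACC vs cognitive outcome change")
  graphics::abline(stats::lm(rbans_change ~ rtacc, data = tab), col = "red")
  grDevices::dev.off()

  p2 <- file.path(fig_dir, "roc_curves.png")
  grDevices::png(p2, width = 700, height = 700)
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "Responder classification")
  cols <- c("black", "blue", "red")
  for (r in responders) {
    roc <- roc_points(r$scores, r$labels)
    graphics::lines(roc$fpr, roc$tpr, col = cols[r$model_id], lwd = 2)
  }
  graphics::legend("bottomright", lwd = 2, col = cols, legend = sprintf(
    "Model %d (AUC %.2f)", vapply(responders, `[[`, 1, "model_id"),
    vapply(responders, `[[`, 1, "auc")))
  grDevices::dev.off()
  c(fig_scatter = p1, fig_roc = p2)
}

# empirical ROC curve points from scores by threshold sweep
roc_points <- function(scores, labels) {
  th <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!labels] >= t), numeric(1))
  list(fpr = fpr, tpr = tpr)
}

write_report_md <- function(path, hash, config, summary_tab, window_fits,
                            exclusion_fits, path_full, path_pruned,
                            responders, pp_report) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("# RTACC pipeline report")
  add("")
  add("config hash: `%s`; seed: %d", hash, config$seed)
  add("")
  add("## Cohort")
  add("")
  add("| statistic | value | spread |")
  add("|---|---|---|")
  for (i in seq_len(nrow(summary_tab))) {
    add("| %s | %.2f | %s%.2f |", summary_tab$statistic[i],
        summary_tab$value[i],
        if (summary_tab$spread_type[i] == "pct") "%: " else "SD: ",
        summary_tab$spread[i])
  }
  add("")
  add("## Preprocessing")
  add("")
  add("%d records in, %d out; %d missing RT, %d missing accuracy; %d / %d MAD-flagged (RT / accuracy).",
      pp_report$n_records_in, pp_report$n_records_out,
      pp_report$n_missing_rt, pp_report$n_missing_accuracy,
      pp_report$n_flagged_rt, pp_report$n_flagged_accuracy)
  add("")
  add("## RTACC association with RBANS change, by time window")
  add("")
  add("| window (wk) | model | beta (RTACC) | SE | stat | p | n |")
  add("|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(window_fits))) {
    add("| %s | %s | %.3f | %.3f | %.2f | %.4g | %d |",
        window_fits$window_weeks[i], window_fits$model[i],
        window_fits$beta_rtacc[i], window_fits$se[i],
        window_fits$statistic[i], window_fits$p_value[i], window_fits$n[i])
  }
  add("")
  add("## Leave-one-game-out fits")
  add("")
  add("| excluded game | domain | beta (RTACC) | SE | p |")
  add("|---|---|---|---|---|")
  for (i in seq_len(nrow(exclusion_fits))) {
    add("| %s | %s | %.3f | %.3f | %.4g |", exclusion_fits$game_name[i],
        exclusion_fits$domain[i], exclusion_fits$beta_rtacc[i],
        exclusion_fits$se[i], exclusion_fits$p_value[i])
  }
  if (!is.null(path_full)) {
    add("")
    add("## Path model")
    add("")
    add("Direct RTACC->outcome (full): %.3f; after pruning: %.3f.",
        path_full$direct_effect, path_pruned$direct_effect)
    if (nrow(path_pruned$pruning_trace)) {
      add("Pruned paths: %s.",
          paste(sprintf("%s (p = %.3f)", path_pruned$pruning_trace$path,
                        path_pruned$pruning_trace$p_value), collapse = ", "))
    } else {
      add("No paths pruned.")
    }
  }
  add("")
  add("## Responder classification")
  add("")
  add("| model | AUC | 95%% CI | good | poor |")
  add("|---|---|---|---|---|")
  for (r in responders) {
    add("| %d | %.3f | %.3f-%.3f | %d | %d |", r$model_id, r$auc,
        r$auc_ci[1], r$auc_ci[2], r$n_good, r$n_poor)
  }
  warns <- character(0)
  for (r in responders) if (isTRUE(r$fit$separated))
    warns <- c(warns, sprintf("model %d: possible separation", r$model_id))
  if (length(pp_report$skipped_participants))
    warns <- c(warns, sprintf("%d participant(s) skipped from outlier flagging",
                              length(pp_report$skipped_participants)))
  if (length(warns)) {
    add("")
    add("## Warnings")
    add("")
    for (w in warns) add("- %s", w)
  }
  writeLines(ln, path)
  invisible(path)
}
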
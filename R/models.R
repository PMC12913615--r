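# model-fit container shared by the OLS, robust, logistic and path fits

new_model_fit <- function(model_kind, terms, coefficients, standard_errors,
                          t_or_z, p_values, n_obs, converged = TRUE,
                          iterations = NA_integer_, extra = list()) {
  stopifnot(length(terms) == length(coefficients),
            length(terms) == length(standard_errors),
            length(terms) == length(t_or_z),
            length(terms) == length(p_values))
  structure(c(list(
    model_kind = model_kind,
    terms = terms,
    coefficients = stats::setNames(as.numeric(coefficients), terms),
    standard_errors = stats::setNames(as.numeric(standard_errors), terms),
    t_or_z = stats::setNames(as.numeric(t_or_z), terms),
    p_values = stats::setNames(as.numeric(p_values), terms),
    n_obs = n_obs,
    converged = converged,
    iterations = iterations
  ), extra), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit: %s, n = %d%s>\n", x$model_kind, x$n_obs,
              if (isTRUE(x$converged)) "" else ", NOT converged"))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.model_fit <- function(x, ...) {
  data.frame(
    term = x$terms,
    estimate = unname(x$coefficients),
    std_error = unname(x$standard_errors),
    statistic = unname(x$t_or_z),
    p_value = unname(x$p_values),
    stringsAsFactors = FALSE
  )
}

#' Coefficients of a model fit
#' @param object A `model_fit`.
#' @param ... Unused.
#' @export
coef.model_fit <- function(object, ...) object$coefficients

model_fit_from_lm <- function(fit, kind = "ols") {
  sm <- summary(fit)$coefficients
  n <- length(stats::residuals(fit))
  new_model_fit(kind, rownames(sm), sm[, 1], sm[, 2], sm[, 3], sm[, 4], n)
}

covariate_terms <- function() c("age", "sex", "education_years", "apoe_e4")

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Join RTACC values onto the participant table
#'
#' Selects one defined RTACC value per participant for the requested time
#' window and game exclusion, merges it with the covariates and outcomes,
#' and keeps complete cases on the regression columns (biomarker columns
#' may remain `NA`; the path model handles its own complete-case subset).
#'
#' @param profiles Participant table ([read_participants()] or
#'   [generate_cohort()] output).
#' @param rtacc_values Output of [rtacc_windows()] and/or
#'   [rtacc_leave_one_game_out()].
#' @param window Time window (upper week bound) to select.
#' @param excluded_game Game exclusion to select, or `NA`/`NULL` for the
#'   all-games value.
#' @return A `data.frame` with the regression terms, outcomes, biomarker
#'   change columns and `rtacc`; attribute `n_dropped` counts participants
#'   lost to an undefined RTACC or incomplete covariates/outcomes.
#' @export
build_analysis_table <- function(profiles, rtacc_values, window = 24,
                                 excluded_game = NULL) {
  if (is.null(excluded_game)) excluded_game <- NA_character_
  sel <- rtacc_values$window_weeks == window &
    (if (is.na(excluded_game)) is.na(rtacc_values$excluded_game)
     else !is.na(rtacc_values$excluded_game) &
       rtacc_values$excluded_game == excluded_game)
  vals <- rtacc_values[sel, , drop = FALSE]
  if (nrow(vals) == 0L)
    stop("no RTACC values computed for window ", window,
         if (!is.na(excluded_game)) paste0(" with game '", excluded_game,
                                           "' excluded"))
  vals <- vals[vals$defined, c("participant_id", "value")]
  names(vals)[2] <- "rtacc"

  tab <- merge(profiles, vals, by = "participant_id")
  core <- c(covariate_terms(), "rbans_baseline", "rbans_week24", "rtacc")
  complete <- stats::complete.cases(tab[, core])
  tab <- tab[complete, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no usable rows after joining RTACC values")
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- nrow(profiles) - nrow(tab)
  tab
}

#' Covariate-adjusted linear model of the week-24 cognitive outcome
#'
#' Fits `rbans_week24 ~ age + sex + education_years + apoe_e4 +
#' rbans_baseline + rtacc` by least squares. Because baseline RBANS is a
#' covariate, the RTACC coefficient is interpretable as the adjusted effect
#' on the 24-week change in RBANS; a negative coefficient means a more
#' negative RTACC (faster-and-more-accurate training performance) predicts
#' greater cognitive improvement.
#'
#' @param table Output of [build_analysis_table()].
#' @return A `model_fit` (kind `"ols"`).
#' @export
fit_linear_rbans <- function(table) {
  fm <- stats::as.formula(
    "rbans_week24 ~ age + sex + education_years + apoe_e4 + rbans_baseline + rtacc")
  X <- stats::model.matrix(fm, data = table)
  if (nrow(X) <= ncol(X))
    stop("too few observations (", nrow(X), ") for ", ncol(X), " terms")
  check_full_rank(X)
  model_fit_from_lm(stats::lm(fm, data = table), "ols")
}

#' Huber robust linear model of the week-24 cognitive outcome
#'
#' Same design as [fit_linear_rbans()], estimated by Huber M-estimation via
#' iteratively reweighted least squares with the residual scale
#' re-estimated by MAD at each iteration. With the conventional tuning
#' constant 1.345 the estimator has 95% efficiency at the Gaussian model
#' while bounding the influence of gross outcome outliers; as the tuning
#' constant grows the fit converges to ordinary least squares.
#'
#' @param table Output of [build_analysis_table()].
#' @param tuning Huber tuning constant (in residual-scale units).
#' @param tol Convergence tolerance on the coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @return A `model_fit` (kind `"rlm"`); non-convergence is reported with a
#'   warning and `converged = FALSE`, not an error.
#' @export
fit_robust_rbans <- function(table, tuning = 1.345, tol = 1e-8,
                             max_iter = 50L) {
  fm <- stats::as.formula(
    "rbans_week24 ~ age + sex + education_years + apoe_e4 + rbans_baseline + rtacc")
  X <- stats::model.matrix(fm, data = table)
  if (nrow(X) <= ncol(X))
    stop("too few observations (", nrow(X), ") for ", ncol(X), " terms")
  check_full_rank(X)
  fit <- MASS::rlm(fm, data = table, psi = MASS::psi.huber, k = tuning,
                   scale.est = "MAD", maxit = max_iter, acc = tol)
  if (!fit$converged)
    warning("Huber IRLS did not converge in ", max_iter, " iterations")
  sm <- summary(fit)$coefficients
  n <- length(stats::residuals(fit))
  df <- n - nrow(sm)
  p <- 2 * stats::pt(-abs(sm[, 3]), df)
  new_model_fit("rlm", rownames(sm), sm[, 1], sm[, 2], sm[, 3], p, n,
                converged = fit$converged,
                iterations = length(fit$conv),
                extra = list(weights = fit$w, tuning = tuning))
}

# ---- recursive path model -------------------------------------------------

path_equations <- function(table, markers, adjust_covariates, retained) {
  cov_part <- if (adjust_covariates)
    paste("+", paste(covariate_terms(), collapse = " + ")) else ""
  eqs <- list()
  for (m in markers) {
    rhs <- if (retained$marker_eq[[m]]) paste("rtacc", cov_part) else
      if (adjust_covariates) paste(covariate_terms(), collapse = " + ") else "1"
    fm <- stats::as.formula(paste0(m, "_change ~ ", rhs))
    eqs[[m]] <- model_fit_from_lm(stats::lm(fm, data = table), "path_equation")
  }
  in_outcome <- markers[vapply(markers, function(m) retained$outcome[[m]], TRUE)]
  rhs <- paste(c("rtacc", paste0(in_outcome, "_change", recycle0 = TRUE),
                 if (adjust_covariates) c(covariate_terms(), "rbans_baseline")),
               collapse = " + ")
  lhs <- if (adjust_covariates) "rbans_week24" else "rbans_change"
  eqs$outcome <- model_fit_from_lm(
    stats::lm(stats::as.formula(paste(lhs, "~", rhs)), data = table),
    "path_equation")
  eqs
}

build_path_result <- function(table, markers, adjust_covariates, retained,
                              trace, alpha = NA_real_) {
  eqs <- path_equations(table, markers, adjust_covariates, retained)
  direct <- unname(eqs$outcome$coefficients["rtacc"])
  indirect <- vapply(markers, function(m) {
    if (retained$marker_eq[[m]] && retained$outcome[[m]]) {
      unname(eqs[[m]]$coefficients["rtacc"]) *
        unname(eqs$outcome$coefficients[paste0(m, "_change")])
    } else 0
  }, numeric(1))
  structure(list(
    equations = eqs,
    direct_effect = direct,
    indirect_effects = indirect,
    pruning_trace = trace,
    markers = markers,
    adjust_covariates = adjust_covariates,
    retained = retained,
    alpha = alpha,
    n_obs = nrow(table),
    table = table
  ), class = "path_model")
}

#' Recursive path model linking RTACC, blood biomarkers and the outcome
#'
#' Estimates a recursive (acyclic) system of observed-variable linear
#' equations by equation-wise least squares, which coincides with full
#' maximum likelihood for recursive systems with uncorrelated errors:
#' each biomarker change is regressed on RTACC, and the cognitive outcome
#' is regressed on RTACC plus all biomarker changes. With
#' `adjust_covariates = TRUE` (default) every equation also adjusts for
#' age, sex, education and APOE e4, and the outcome equation additionally
#' for baseline RBANS (modelling week-24 RBANS); with `FALSE` the raw
#' change score is the outcome. The RTACC-to-outcome coefficient is the
#' direct effect; each marker's indirect effect is the product of its two
#' path coefficients.
#'
#' @param table Output of [build_analysis_table()]; must contain
#'   `<marker>_change` columns. Complete cases across all markers are used.
#' @param markers Marker stems, default `c("bdnf", "ptau", "nfl", "gfap")`.
#' @param adjust_covariates Adjust every equation for the clinical
#'   covariates (and the outcome equation for baseline RBANS)?
#' @return A `path_model`: `equations` (one `model_fit` per endogenous
#'   variable), `direct_effect`, `indirect_effects`, `pruning_trace`.
#' @seealso [prune_path_model()]
#' @export
fit_path_model <- function(table, markers = c("bdnf", "ptau", "nfl", "gfap"),
                           adjust_covariates = TRUE) {
  cols <- paste0(markers, "_change")
  absent <- setdiff(cols, names(table))
  if (length(absent))
    stop("missing biomarker column(s): ", paste(absent, collapse = ", "))
  keep <- stats::complete.cases(table[, cols, drop = FALSE])
  table <- table[keep, , drop = FALSE]
  if (nrow(table) == 0L) stop("no complete-case rows across biomarkers")

  retained <- list(
    marker_eq = stats::setNames(as.list(rep(TRUE, length(markers))), markers),
    outcome = stats::setNames(as.list(rep(TRUE, length(markers))), markers)
  )
  trace <- data.frame(step = integer(0), path = character(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  build_path_result(table, markers, adjust_covariates, retained, trace)
}

# p-values of the currently retained marker paths, named "rtacc->m" /
# "m->outcome"
marker_path_pvalues <- function(result) {
  out <- numeric(0)
  for (m in result$markers) {
    if (result$retained$marker_eq[[m]])
      out[paste0("rtacc->", m)] <-
        unname(result$equations[[m]]$p_values["rtacc"])
    if (result$retained$outcome[[m]])
      out[paste0(m, "->outcome")] <-
        unname(result$equations$outcome$p_values[paste0(m, "_change")])
  }
  out
}

#' Prune a path model by backward elimination
#'
#' Repeatedly removes the single marker path with the largest p-value at or
#' above `alpha`, refitting the system after each removal, until every
#' remaining marker path is significant at `alpha` or no marker path is
#' left. The direct RTACC-to-outcome path is never dropped. The full
#' removal trace (path name and the p-value at removal) is recorded for
#' auditability.
#'
#' @param result A fitted `path_model`.
#' @param alpha Retention threshold.
#' @return A pruned `path_model` with `pruning_trace` filled.
#' @export
prune_path_model <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "path_model"))
  retained <- result$retained
  trace <- result$pruning_trace
  repeat {
    cur <- build_path_result(result$table, result$markers,
                             result$adjust_covariates, retained, trace, alpha)
    ps <- marker_path_pvalues(cur)
    if (length(ps) == 0L || max(ps) < alpha) return(cur)
    worst <- names(ps)[which.max(ps)]
    trace <- rbind(trace, data.frame(step = nrow(trace) + 1L, path = worst,
                                     p_value = unname(max(ps)),
                                     stringsAsFactors = FALSE))
    if (startsWith(worst, "rtacc->")) {
      retained$marker_eq[[sub("^rtacc->", "", worst)]] <- FALSE
    } else {
      retained$outcome[[sub("->outcome$", "", worst)]] <- FALSE
    }
  }
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("<path_model: %d markers, n = %d%s>\n", length(x$markers),
              x$n_obs,
              if (is.na(x$alpha)) "" else sprintf(", pruned at alpha = %g", x$alpha)))
  cat(sprintf("  direct RTACC -> outcome: %.3f (p = %.3g)\n",
              x$direct_effect, x$equations$outcome$p_values["rtacc"]))
  for (m in x$markers) {
    a <- if (x$retained$marker_eq[[m]])
      sprintf("%.3f", unname(x$equations[[m]]$coefficients["rtacc"])) else "--"
    b <- if (x$retained$outcome[[m]])
      sprintf("%.3f", unname(x$equations$outcome$coefficients[paste0(m, "_change")])) else "--"
    cat(sprintf("  %s: rtacc->marker %s, marker->outcome %s, indirect %.4f\n",
                m, a, b, x$indirect_effects[[m]]))
  }
  if (nrow(x$pruning_trace))
    cat("  pruned:", paste(x$pruning_trace$path, collapse = ", "), "\n")
  invisible(x)
}

# ---- responder classification --------------------------------------------

#' Area under the ROC curve (rank formulation)
#'
#' The probability that a randomly chosen positive score exceeds a randomly
#' chosen negative score, with ties counted one half — the Mann-Whitney
#' statistic, identical to trapezoidal integration of the ROC curve.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical (or coercible) class labels, `TRUE` = positive.
#' @return The AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.4, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("roc_auc needs at least one score in each class")
  r <- rank(scores)  # midranks handle ties at 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified percentile bootstrap CI for an AUC
#'
#' Resamples scores with replacement within each class, recomputes the AUC,
#' and returns percentile limits.
#'
#' @inheritParams roc_auc
#' @param reps Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Seed for the resampling.
#' @return Numeric `c(lower, upper)`.
#' @export
auc_ci_boot <- function(scores, labels, reps = 2000L, conf = 0.95,
                        seed = 1L) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!is.null(seed)) set.seed(seed)
  stat <- vapply(seq_len(reps), function(i) {
    p <- sample(pos, length(pos), replace = TRUE)
    n <- sample(neg, length(neg), replace = TRUE)
    roc_auc(c(p, n), c(rep(TRUE, length(p)), rep(FALSE, length(n))))
  }, numeric(1))
  a <- (1 - conf) / 2
  unname(stats::quantile(stat, c(a, 1 - a)))
}

fit_one_logistic <- function(table, y, rhs, model_id, bootstrap_reps, conf,
                             seed) {
  fm <- stats::as.formula(paste("y ~", rhs))
  dat <- cbind(table, y = y)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fm, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  # quasi-separation can pass glm's own numeric check while still driving
  # fitted probabilities to the boundary; flag it from the fit itself
  separated <- separated || any(stats::fitted(fit) < 1e-7) ||
    any(stats::fitted(fit) > 1 - 1e-7)
  if (separated)
    warning("model ", model_id, ": possible complete separation; ",
            "coefficients reported but unstable")
  sm <- summary(fit)$coefficients
  mf <- new_model_fit("logistic", rownames(sm), sm[, 1], sm[, 2], sm[, 3],
                      sm[, 4], length(y), converged = fit$converged,
                      iterations = fit$iter,
                      extra = list(separated = separated))
  scores <- stats::fitted(fit)
  auc <- roc_auc(scores, y)
  ci <- auc_ci_boot(scores, y, reps = bootstrap_reps, conf = conf,
                    seed = seed)
  structure(list(
    model_id = model_id,
    fit = mf,
    auc = auc,
    auc_ci = ci,
    n_good = sum(y),
    n_poor = sum(!y),
    deviance = fit$deviance,
    scores = scores,
    labels = y
  ), class = "responder_model")
}

#' Responder classification models scored by ROC/AUC
#'
#' Fits three in-sample logistic models for good-responder status (RBANS
#' increased after 24 weeks): Model 1 uses clinical information only (age,
#' sex, education, APOE e4); Model 2 uses RTACC alone; Model 3 combines
#' both. Participants labelled `tie` (exactly zero change) are excluded.
#' Each model's fitted probabilities are scored by [roc_auc()] with a
#' stratified percentile bootstrap 95% CI. No cross-validation is applied,
#' so the AUCs are apparent (in-sample) performance.
#'
#' @param table Output of [build_analysis_table()].
#' @param labels Output of [label_responders()]; defaults to labels derived
#'   from `table` itself.
#' @param bootstrap_reps,conf,seed Passed to [auc_ci_boot()].
#' @return A list of three `responder_model` objects (`model_id` 1-3),
#'   each with `fit`, `auc`, `auc_ci`, `n_good`, `n_poor`, `deviance`.
#' @export
fit_responder_models <- function(table, labels = label_responders(table),
                                 bootstrap_reps = 2000L, conf = 0.95,
                                 seed = 1L) {
  tab <- merge(table, labels, by = "participant_id")
  tab <- tab[tab$label != "tie", , drop = FALSE]
  y <- tab$label == "good"
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("need at least 2 responders in each class (got ", sum(y), " good, ",
         sum(!y), " poor)")
  clinical <- paste(covariate_terms(), collapse = " + ")
  rhs <- c(clinical, "rtacc", paste(clinical, "+ rtacc"))
  lapply(1:3, function(k) {
    fit_one_logistic(tab, y, rhs[k], k, bootstrap_reps, conf,
                     seed = derive_seed(seed, k))
  })
}

#' @export
print.responder_model <- function(x, ...) {
  cat(sprintf("<responder_model %d: AUC %.3f (95%% CI %.3f-%.3f), %d good / %d poor>\n",
              x$model_id, x$auc, x$auc_ci[1], x$auc_ci[2], x$n_good, x$n_poor))
  invisible(x)
}
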
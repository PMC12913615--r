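#' Product-moment correlation with an undefined-result convention
#'
#' The correlation at the heart of the RTACC metric. Returns `NA_real_`
#' (rather than throwing) when fewer than 3 complete pairs are available or
#' when either series has zero variance, so a batch of per-participant
#' computations can record the value as undefined and continue.
#'
#' @param xs,ys Equal-length numeric vectors.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The correlation, or `NA_real_` when undefined.
#' @export
pearson_corr <- function(xs, ys, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  ok <- !(is.na(xs) | is.na(ys))
  xs <- xs[ok]
  ys <- ys[ok]
  if (length(xs) < 3L) return(NA_real_)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys, method = method)
}

#' Compute RTACC for one participant
#'
#' RTACC is the correlation, across 3-minute training tasks, between each
#' task's mean reaction time and its accuracy (proportion of correct
#' trials). Pairs are pooled across all games and sessions with
#' `week <= window_weeks`, optionally excluding one game; a negative value
#' means tasks done faster were also done more accurately.
#'
#' @param records Preprocessed training-log rows for a single participant.
#' @param window_weeks Upper week bound (inclusive); default 24 uses the
#'   full period.
#' @param excluded_game A `game_id` to leave out, or `NULL`.
#' @param min_pairs Minimum number of pairs for a defined value.
#' @param method Correlation type, see [pearson_corr()].
#' @return A one-row `data.frame`: `participant_id`, `window_weeks`,
#'   `excluded_game` (`NA` when none), `n_pairs`, `value`, `defined`.
#' @export
compute_rtacc <- function(records, window_weeks = 24, excluded_game = NULL,
                          min_pairs = 10L, method = "pearson") {
  if (window_weeks < 1) stop("window_weeks must be >= 1")
  pid <- unique(records$participant_id)
  if (length(pid) > 1L)
    stop("compute_rtacc expects records from a single participant; got ",
         length(pid))
  if (length(pid) == 0L) pid <- NA_character_

  sel <- records$week <= window_weeks
  if (!is.null(excluded_game) && !is.na(excluded_game))
    sel <- sel & records$game_id != excluded_game
  sub <- records[sel, , drop = FALSE]

  value <- NA_real_
  defined <- FALSE
  if (nrow(sub) >= min_pairs) {
    value <- pearson_corr(sub$mean_rt_s, sub$accuracy, method = method)
    defined <- !is.na(value)
  }
  data.frame(
    participant_id = pid,
    window_weeks = window_weeks,
    excluded_game = if (is.null(excluded_game)) NA_character_ else excluded_game,
    n_pairs = nrow(sub),
    value = value,
    defined = defined,
    stringsAsFactors = FALSE
  )
}

#' RTACC over nested time windows
#'
#' Computes one RTACC per participant per window, where window `w` uses all
#' tasks from the first `w` weeks. Because the windows nest, `n_pairs` is
#' non-decreasing in the window.
#'
#' @param records Preprocessed training log (any number of participants).
#' @param windows Ascending integer vector of upper week bounds.
#' @inheritParams compute_rtacc
#' @return A `data.frame` with one row per participant x window, same
#'   columns as [compute_rtacc()].
#' @export
rtacc_windows <- function(records, windows = c(1, 2, 3, 6, 12, 24),
                          min_pairs = 10L, method = "pearson") {
  if (is.unsorted(windows, strictly = TRUE))
    stop("windows must be sorted ascending without duplicates")
  by_part <- split(records, records$participant_id)
  out <- lapply(by_part, function(rec) {
    do.call(rbind, lapply(windows, function(w) {
      compute_rtacc(rec, window_weeks = w, min_pairs = min_pairs,
                    method = method)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Leave-one-game-out RTACC
#'
#' Recomputes each participant's full-period RTACC 18 times, excluding one
#' catalogue game at a time; the content-sensitivity analysis asks whether
#' the metric is driven by any single game.
#'
#' @param records Preprocessed training log.
#' @param catalog Game catalogue; defaults to [default_catalog()].
#' @param window_weeks Upper week bound for the underlying metric.
#' @inheritParams compute_rtacc
#' @return A `data.frame` with one row per participant x excluded game.
#' @export
rtacc_leave_one_game_out <- function(records, catalog = default_catalog(),
                                     window_weeks = 24, min_pairs = 10L,
                                     method = "pearson") {
  by_part <- split(records, records$participant_id)
  out <- lapply(by_part, function(rec) {
    do.call(rbind, lapply(catalog$game_id, function(g) {
      compute_rtacc(rec, window_weeks = window_weeks, excluded_game = g,
                    min_pairs = min_pairs, method = method)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Label responders by the sign of the RBANS change
#'
#' A good responder has an increased RBANS score after 24 weeks, a poor
#' responder a decreased one. Exact zero changes get a third label, `tie`,
#' and are excluded from classification fits by default.
#'
#' @param profiles Participant table with `rbans_change` (or both
#'   `rbans_baseline` and `rbans_week24`).
#' @return A `data.frame`: `participant_id`, `label` (factor with levels
#'   `poor`, `tie`, `good`).
#' @export
label_responders <- function(profiles) {
  change <- profiles$rbans_change
  if (is.null(change))
    change <- profiles$rbans_week24 - profiles$rbans_baseline
  if (anyNA(change)) {
    bad <- profiles$participant_id[is.na(change)]
    stop("missing rbans_change for participant(s): ",
         paste(bad, collapse = ", "))
  }
  lab <- ifelse(change > 0, "good", ifelse(change < 0, "poor", "tie"))
  data.frame(
    participant_id = profiles$participant_id,
    label = factor(lab, levels = c("poor", "tie", "good")),
    stringsAsFactors = FALSE
  )
}
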
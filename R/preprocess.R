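#' Read and validate a training log CSV
#'
#' Expects the long-format schema written by [generate_cohort()]: one row
#' per 3-minute task with columns `participant_id`, `week`,
#' `session_index`, `task_index`, `game_id`, `domain`, `difficulty`,
#' `mean_rt_s`, `accuracy`, `n_trials`. Rows violating the task-record
#' invariants (`mean_rt_s > 0`, `accuracy` in \[0, 1\], `week >= 1`,
#' `n_trials >= 1`, unparseable numerics) are quarantined in a `rejected`
#' attribute (with file line numbers and reasons) rather than aborting the
#' read; empty cells are kept as `NA` and counted later by
#' [check_missing()].
#'
#' @param path CSV path.
#' @return A `data.frame` of valid records with attribute `rejected`, a
#'   `data.frame` with columns `line`, `reason` and the offending fields.
#' @export
read_training_log <- function(path) {
  required <- c("participant_id", "week", "session_index", "task_index",
                "game_id", "domain", "difficulty", "mean_rt_s", "accuracy",
                "n_trials")
  df <- read_checked_csv(path, required)
  num_cols <- c("week", "session_index", "task_index", "difficulty",
                "mean_rt_s", "accuracy", "n_trials")
  df <- coerce_numeric(df, num_cols)

  bad_parse <- attr(df, "bad_parse")
  reason <- character(nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    ifelse(cond & reason == "", why, reason)
  }
  reason <- flag(bad_parse, "unparseable numeric")
  reason <- flag(df$mean_rt_s <= 0, "mean_rt_s must be > 0")
  reason <- flag(df$accuracy < 0 | df$accuracy > 1, "accuracy outside [0, 1]")
  reason <- flag(df$week < 1, "week must be >= 1")
  reason <- flag(df$n_trials < 1, "n_trials must be >= 1")

  keep <- reason == ""
  rejected <- df[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$line <- which(!keep) + 1L  # +1 for the header line
    rejected$reason <- reason[!keep]
  } else {
    rejected$line <- integer(0)
    rejected$reason <- character(0)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bad_parse") <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Read and validate a participants CSV
#'
#' Required columns: `participant_id`, `age`, `sex`, `education_years`,
#' `apoe_e4`, `rbans_baseline`, `rbans_week24`. Biomarker change columns
#' and `rho_true` are optional; empty cells are missing. `rbans_change` is
#' (re)computed as `rbans_week24 - rbans_baseline`. Rows with `sex` or
#' `apoe_e4` outside {0, 1} are quarantined like in [read_training_log()].
#'
#' @param path CSV path.
#' @return A `data.frame` with attribute `rejected`.
#' @export
read_participants <- function(path) {
  required <- c("participant_id", "age", "sex", "education_years",
                "apoe_e4", "rbans_baseline", "rbans_week24")
  df <- read_checked_csv(path, required)
  optional <- c("bdnf_change", "ptau_change", "nfl_change", "gfap_change",
                "rho_true")
  for (col in optional) if (is.null(df[[col]])) df[[col]] <- NA_real_
  num_cols <- c("age", "sex", "education_years", "apoe_e4",
                "rbans_baseline", "rbans_week24", optional)
  df <- coerce_numeric(df, num_cols)

  bad_parse <- attr(df, "bad_parse")
  reason <- character(nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    ifelse(cond & reason == "", why, reason)
  }
  reason <- flag(bad_parse, "unparseable numeric")
  reason <- flag(!(df$sex %in% c(0, 1)) & !is.na(df$sex), "sex must be 0 or 1")
  reason <- flag(!(df$apoe_e4 %in% c(0, 1)) & !is.na(df$apoe_e4),
                 "apoe_e4 must be 0 or 1")

  keep <- reason == ""
  rejected <- df[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$line <- which(!keep) + 1L
    rejected$reason <- reason[!keep]
  } else {
    rejected$line <- integer(0)
    rejected$reason <- character(0)
  }
  out <- df[keep, , drop = FALSE]
  out$rbans_change <- out$rbans_week24 - out$rbans_baseline
  rownames(out) <- NULL
  attr(out, "bad_parse") <- NULL
  attr(out, "rejected") <- rejected
  out
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df
}

# convert character columns to numeric, remembering rows where a non-empty
# cell failed to parse (those become quarantine candidates, not silent NA)
coerce_numeric <- function(df, cols) {
  bad <- rep(FALSE, nrow(df))
  for (col in cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- bad | (!is.na(raw) & is.na(val))
    df[[col]] <- val
  }
  attr(df, "bad_parse") <- bad
  df
}

#' Count missing RT and accuracy values
#'
#' @param records A training-log `data.frame`.
#' @return A list: `n_records`, `n_missing_rt`, `n_missing_accuracy`.
#' @export
check_missing <- function(records) {
  list(
    n_records = nrow(records),
    n_missing_rt = if (nrow(records)) sum(is.na(records$mean_rt_s)) else 0L,
    n_missing_accuracy = if (nrow(records)) sum(is.na(records$accuracy)) else 0L
  )
}

#' MAD-based outlier flags
#'
#' Flags value `v` when `|v - median| > k * scale * MAD`, where `MAD` is the
#' raw median absolute deviation `median(|v - median|)`. With the defaults
#' `k = 3` and `scale = 1.4826` (the consistency constant for the normal
#' distribution) this is the conventional robust three-sigma rule. When the
#' MAD is zero the scale is degenerate; the rule then flags nothing and a
#' warning is emitted, since flagging every deviant under a zero scale
#' would discard valid near-constant series. `NA` values are never flagged.
#'
#' @param values Numeric vector (non-empty).
#' @param k Threshold multiplier, > 0.
#' @param scale Consistency constant.
#' @return Logical vector of flags, same length as `values`.
#' @examples
#' mad_flags(c(10, 12, 11, 10, 11, 50))
#' @export
mad_flags <- function(values, k = 3, scale = 1.4826) {
  if (length(values) == 0L) stop("mad_flags: empty input")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
    stop("mad_flags: k must be > 0")  # k = Inf is allowed (flag nothing)
  med <- stats::median(values, na.rm = TRUE)
  if (is.na(med)) return(rep(FALSE, length(values)))
  dev <- abs(values - med)
  mad <- stats::median(dev, na.rm = TRUE)
  if (mad == 0) {
    warning("degenerate MAD (= 0): no values flagged")
    return(rep(FALSE, length(values)))
  }
  flags <- dev > k * scale * mad
  flags[is.na(flags)] <- FALSE
  flags
}

#' Apply the MAD outlier rule to a training log
#'
#' Flags are computed per participant (default) on the `mean_rt_s` series
#' and the `accuracy` series separately; a record is removed when flagged
#' on either. Participants with fewer than `min_records` tasks are skipped
#' from flagging and noted in the report. Records with a missing RT or
#' accuracy are removed as missing (and counted), since no metric can be
#' computed from them.
#'
#' @param records Training-log `data.frame`.
#' @param k,scale Passed to [mad_flags()].
#' @param pooled If `TRUE`, flags are computed over the whole cohort pooled
#'   rather than per participant.
#' @param min_records Minimum records a participant needs to enter
#'   flagging.
#' @return A list with `records` (the filtered log) and `report`, an object
#'   of class `preprocess_report` holding `n_records_in`, `n_missing_rt`,
#'   `n_missing_accuracy`, `n_flagged_rt`, `n_flagged_accuracy`,
#'   `n_removed_missing`, `n_records_out`, `skipped_participants`, and
#'   `per_participant` (a `data.frame` of per-participant flag counts).
#' @export
apply_outlier_filter <- function(records, k = 3, scale = 1.4826,
                                 pooled = FALSE, min_records = 3L) {
  n_in <- nrow(records)
  miss <- check_missing(records)
  incomplete <- if (n_in) is.na(records$mean_rt_s) | is.na(records$accuracy) else logical(0)

  flag_rt <- rep(FALSE, n_in)
  flag_acc <- rep(FALSE, n_in)
  skipped <- character(0)

  if (n_in) {
    groups <- if (pooled) list(all = seq_len(n_in)) else
      split(seq_len(n_in), records$participant_id)
    for (idx in groups) {
      usable <- idx[!incomplete[idx]]
      if (length(usable) < min_records) {
        skipped <- c(skipped, unique(records$participant_id[idx]))
        next
      }
      flag_rt[usable] <- mad_flags(records$mean_rt_s[usable], k, scale)
      flag_acc[usable] <- mad_flags(records$accuracy[usable], k, scale)
    }
  }

  drop <- incomplete | flag_rt | flag_acc
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL

  per_part <- if (n_in) {
    agg <- stats::aggregate(
      cbind(n_flagged_rt = flag_rt, n_flagged_accuracy = flag_acc),
      by = list(participant_id = records$participant_id), FUN = sum
    )
    agg[order(agg$participant_id), , drop = FALSE]
  } else {
    data.frame(participant_id = character(0), n_flagged_rt = integer(0),
               n_flagged_accuracy = integer(0))
  }

  report <- structure(list(
    n_records_in = n_in,
    n_missing_rt = miss$n_missing_rt,
    n_missing_accuracy = miss$n_missing_accuracy,
    n_flagged_rt = sum(flag_rt),
    n_flagged_accuracy = sum(flag_acc),
    n_removed_missing = sum(incomplete),
    n_records_out = nrow(out),
    skipped_participants = sort(unique(skipped)),
    per_participant = per_part,
    k = k, scale = scale, pooled = pooled
  ), class = "preprocess_report")

  list(records = out, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  cat(sprintf("  records in/out: %d / %d\n", x$n_records_in, x$n_records_out))
  cat(sprintf("  missing RT: %d, missing accuracy: %d\n",
              x$n_missing_rt, x$n_missing_accuracy))
  cat(sprintf("  MAD-flagged RT: %d, accuracy: %d (k = %g, scale = %g, %s)\n",
              x$n_flagged_rt, x$n_flagged_accuracy, x$k, x$scale,
              if (x$pooled) "pooled" else "per participant"))
  if (length(x$skipped_participants))
    cat("  skipped (too few records):",
        paste(x$skipped_participants, collapse = ", "), "\n")
  invisible(x)
}
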
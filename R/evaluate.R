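#' Mean absolute error for one task
#'
#' @param predictions data.frame with `task`, `y_true`, `y_pred` (raw scale).
#' @param task which task to evaluate.
#' @return mean of `|y_true - y_pred|`.
#' @export
mae <- function(predictions, task) {
  p <- predictions[predictions$task == task, ]
  if (!nrow(p)) stop("no predictions for task ", task)
  mean(abs(p$y_true - p$y_pred))
}

#' Coefficient of determination for one task
#'
#' `1 - SS_res / SS_tot`; negative for predictors worse than the mean.
#'
#' @param predictions data.frame with `task`, `y_true`, `y_pred`.
#' @param task which task to evaluate.
#' @return R-squared.
#' @export
r_squared <- function(predictions, task) {
  p <- predictions[predictions$task == task, ]
  if (!nrow(p)) stop("no predictions for task ", task)
  ss_tot <- sum((p$y_true - mean(p$y_true))^2)
  if (ss_tot == 0) stop("degenerate input: y_true has zero variance")
  1 - sum((p$y_true - p$y_pred)^2) / ss_tot
}

#' Inter-test variability of a sub-score
#'
#' For every visit record ("entry") i, gathers the same participant's visits
#' dated within +/- `window_days` of entry i (inclusive) and returns the range
#' `max(q) - min(q)` of the sub-score over that window. The per-sub-score mean
#' ITV averages over entries; by default entries whose window contains only
#' themselves are excluded from the mean (their ITV is trivially 0 and would
#' deflate the benchmark); `include_singletons = TRUE` restores the inclusive
#' behaviour.
#'
#' The +/- 3-month window is interpreted as +/- 91 days (calendar-month
#' arithmetic is ambiguous across month lengths).
#'
#' @param visits data.frame with `subject_id`, `visit_date` (ISO-8601) and
#'   sub-score columns.
#' @param score sub-score column name (e.g. `"q1"`).
#' @param window_days window half-width in days.
#' @param include_singletons include single-visit entries (ITV 0) in the mean.
#' @return list with `per_entry` (data.frame `subject_id`, `visit_date`,
#'   `itv`, `n_in_window`) and `mean_itv`.
#' @export
compute_itv <- function(visits, score, window_days = 91,
                        include_singletons = FALSE) {
  if (!score %in% names(visits)) stop("no column ", score)
  dates <- as.Date(visits$visit_date, format = "%Y-%m-%d")
  if (anyNA(dates)) stop("unparseable visit dates (expected ISO-8601)")
  q <- visits[[score]]
  itv <- numeric(nrow(visits))
  n_in <- integer(nrow(visits))
  for (sid in unique(visits$subject_id)) {
    idx <- which(visits$subject_id == sid)
    d <- as.numeric(dates[idx])
    for (k in seq_along(idx)) {
      inw <- abs(d - d[k]) <= window_days
      itv[idx[k]] <- max(q[idx][inw]) - min(q[idx][inw])
      n_in[idx[k]] <- sum(inw)
    }
  }
  per_entry <- data.frame(subject_id = visits$subject_id,
                          visit_date = visits$visit_date,
                          itv = itv, n_in_window = n_in,
                          stringsAsFactors = FALSE)
  keep <- if (include_singletons) rep(TRUE, nrow(per_entry))
          else per_entry$n_in_window >= 2L
  mean_itv <- if (any(keep)) mean(per_entry$itv[keep]) else NA_real_
  list(per_entry = per_entry, mean_itv = mean_itv, score = score,
       window_days = window_days)
}

#' One-tailed comparison of model error against inter-test variability
#'
#' Welch two-sample t-test of H1: mean absolute prediction error exceeds mean
#' ITV. A non-significant result means the model's errors are statistically
#' comparable to the natural visit-to-visit fluctuation of the score.
#'
#' @param abs_errors per-entry absolute prediction errors.
#' @param itvs per-entry ITV values.
#' @param alpha significance level for the `n.s.` flag.
#' @return list with `t`, `p` (one-sided, H1: errors > ITV), `ns`
#'   (TRUE when not significant at `alpha`), and the sample means.
#' @export
compare_mae_itv <- function(abs_errors, itvs, alpha = 0.05) {
  if (!length(abs_errors) || !length(itvs)) stop("both samples must be non-empty")
  if (var(abs_errors) == 0 && var(itvs) == 0)
    stop("degenerate input: zero variance in both samples")
  tt <- t.test(abs_errors, itvs, alternative = "greater", var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value, ns = tt$p.value >= alpha,
       mean_abs_error = mean(abs_errors), mean_itv = mean(itvs))
}

#' Per-task evaluation report
#'
#' MAE and R-squared per task from a prediction table, plus (when a visit
#' table is supplied) the mean ITV and the one-tailed MAE-vs-ITV test.
#'
#' @param predictions data.frame with `subject_id`, `task`, `y_true`,
#'   `y_pred`.
#' @param visits optional visit table for the ITV benchmark.
#' @param window_days ITV window half-width in days.
#' @param alpha significance level.
#' @return data.frame, one row per task.
#' @export
evaluate_predictions <- function(predictions, visits = NULL, window_days = 91,
                                 alpha = 0.05) {
  tasks <- unique(predictions$task)
  rows <- lapply(tasks, function(tk) {
    out <- data.frame(task = tk, mae = mae(predictions, tk),
                      r2 = r_squared(predictions, tk),
                      stringsAsFactors = FALSE)
    if (!is.null(visits)) {
      itv <- compute_itv(visits, tk, window_days)
      keep <- itv$per_entry$n_in_window >= 2L
      p <- predictions[predictions$task == tk, ]
      cmp <- compare_mae_itv(abs(p$y_true - p$y_pred),
                             itv$per_entry$itv[keep], alpha)
      out$mean_itv <- itv$mean_itv
      out$t <- cmp$t
      out$p <- cmp$p
      out$ns <- cmp$ns
    }
    out
  })
  do.call(rbind, rows)
}
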
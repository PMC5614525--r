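#' Binary prediction error (percent incorrect)
#'
#' @param predicted,actual equal-length vectors of class labels.
#' @return Percent of observations incorrectly predicted, in \[0, 100\].
#' @export
prediction_error <- function(predicted, actual) {
  if (length(predicted) != length(actual) || !length(actual)) {
    ul_abort("predicted and actual must have equal, positive length",
             "userlift_contract_error")
  }
  100 * mean(predicted != actual)
}

#' Root mean squared error
#'
#' @param predicted,actual equal-length numeric vectors (Likert units).
#' @return `sqrt(mean((predicted - actual)^2))`.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual) || !length(actual)) {
    ul_abort("predicted and actual must have equal, positive length",
             "userlift_contract_error")
  }
  sqrt(mean((predicted - actual)^2))
}

# Mode of binary labels; ties go to the negative class (deterministic, and
# either choice incurs the same error).
mode_binary <- function(x) sum(x) > length(x) / 2

#' Personal constant baselines
#'
#' For each user, the constant guess that they are always at their most
#' frequently reported state (binary task: the mode of their daily binary
#' labels; ties to the negative class) or always at their average level
#' (regression task: the mean of their daily levels), evaluated on all of the
#' user's qualifying days. With `loocv = TRUE` each day is instead scored
#' against the mode/mean of the user's other days (strict out-of-sample
#' variant; off by default, matching the framing of a fixed constant guess).
#'
#' @param day_records filtered day records ([filter_participants()]).
#' @param task `"binary"` or `"regression"`.
#' @param loocv logical; see above.
#' @return Tibble `user_id`, `task`, `constant`, `error` (percent for
#'   binary, RMSE for regression), `n_days`.
#' @export
personal_baseline <- function(day_records, task = c("binary", "regression"),
                              loocv = FALSE) {
  task <- match.arg(task)
  per_user <- split(day_records, day_records$user_id)
  rows <- lapply(per_user, function(du) {
    if (task == "binary") {
      yb <- du$label_binary
      if (loocv) {
        pred <- vapply(seq_along(yb), function(i) mode_binary(yb[-i]), logical(1))
        err <- prediction_error(pred, yb)
        const <- mode_binary(yb)
      } else {
        const <- mode_binary(yb)
        err <- prediction_error(rep(const, length(yb)), yb)
      }
      tibble(user_id = du$user_id[1L], task = task,
             constant = as.numeric(const), error = err, n_days = length(yb))
    } else {
      yl <- du$label_level
      if (loocv) {
        pred <- vapply(seq_along(yl), function(i) mean(yl[-i]), numeric(1))
        err <- rmse(pred, yl)
        const <- mean(yl)
      } else {
        const <- mean(yl)
        err <- rmse(rep(const, length(yl)), yl)
      }
      tibble(user_id = du$user_id[1L], task = task, constant = const,
             error = err, n_days = length(yl))
    }
  })
  dplyr::bind_rows(rows)
}

#' Population constant baseline
#'
#' One constant guess for everybody: the pooled mode (binary) or pooled mean
#' (regression) over all users' qualifying days. Returns that constant's
#' error on each user alongside the pooled error (row with
#' `user_id = ".population"`).
#'
#' @inheritParams personal_baseline
#' @return Tibble `user_id`, `task`, `constant`, `error`, `n_days`; the
#'   pooled row has `user_id = ".population"`.
#' @export
population_baseline <- function(day_records, task = c("binary", "regression")) {
  task <- match.arg(task)
  if (task == "binary") {
    const <- mode_binary(day_records$label_binary)
    per_user_err <- function(du) prediction_error(rep(const, nrow(du)), du$label_binary)
  } else {
    const <- mean(day_records$label_level)
    per_user_err <- function(du) rmse(rep(const, nrow(du)), du$label_level)
  }
  per_user <- split(day_records, day_records$user_id)
  rows <- lapply(per_user, function(du) {
    tibble(user_id = du$user_id[1L], task = task, constant = as.numeric(const),
           error = per_user_err(du), n_days = nrow(du))
  })
  pooled_err <- if (task == "binary") {
    prediction_error(rep(const, nrow(day_records)), day_records$label_binary)
  } else {
    rmse(rep(const, nrow(day_records)), day_records$label_level)
  }
  dplyr::bind_rows(c(rows, list(tibble(
    user_id = ".population", task = task, constant = as.numeric(const),
    error = pooled_err, n_days = nrow(day_records)))))
}
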
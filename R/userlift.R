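#' User lift
#'
#' The improvement of a model over the trivial per-user constant guess:
#' personal baseline error minus model error, in the error's own units
#' (percentage points for binary prediction error, Likert units for RMSE).
#' Positive lift means the model beats the personal baseline.
#'
#' @param personal_baseline_error,model_error numeric vectors of per-user
#'   errors in the same metric.
#' @param baseline_metric,model_metric optional metric tags (e.g. `"percent"`
#'   / `"rmse"`); if both are given they must be identical.
#' @return `personal_baseline_error - model_error`.
#' @export
user_lift <- function(personal_baseline_error, model_error,
                      baseline_metric = NULL, model_metric = NULL) {
  if (!is.null(baseline_metric) && !is.null(model_metric) &&
      !identical(baseline_metric, model_metric)) {
    ul_abort(sprintf("metric mismatch: baseline is '%s' but model is '%s'",
                     baseline_metric, model_metric), "userlift_contract_error")
  }
  personal_baseline_error - model_error
}

#' Descriptive statistics of a user-lift distribution
#'
#' Mean, quartiles and the 5th/95th percentiles of per-user lifts, the
#' summary used to display how a model's benefit varies across people.
#' Percentiles use linear interpolation between order statistics
#' (`quantile()` type 7).
#'
#' @param lifts numeric vector of per-user lifts (length >= 1).
#' @return Tibble with columns `n`, `mean`, `p05`, `q1`, `median`, `q3`,
#'   `p95`.
#' @export
lift_descriptives <- function(lifts) {
  if (!length(lifts)) ul_abort("need >= 1 lift", "userlift_contract_error")
  q <- stats::quantile(lifts, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                       names = FALSE)
  tibble(n = length(lifts), mean = mean(lifts),
         p05 = q[1], q1 = q[2], median = q[3], q3 = q[4], p95 = q[5])
}

#' One-sample sign-flip permutation test of mean lift > 0
#'
#' Tests whether the average user lift is greater than zero without
#' distributional assumptions. Under the null the sign of each user's lift is
#' exchangeable; the test statistic is the mean. For `n <= exact_cap` users
#' all `2^n` sign patterns are enumerated (via meet-in-the-middle subset-sum
#' counting, so n = 20 is instant) and
#' `p = #\{patterns with mean >= observed\} / 2^n`; patterns tying the
#' observed mean count, so all-zero lifts give p = 1. Beyond the cap a seeded
#' Monte Carlo with `B = n_permutations` sign draws is used with the add-one
#' correction `p = (1 + #\{resampled mean >= observed\}) / (1 + B)`.
#'
#' @param lifts numeric vector of per-user lifts (length >= 2).
#' @param n_permutations Monte Carlo draws when enumeration is infeasible.
#' @param seed integer seed (Monte Carlo mode; recorded either way).
#' @param exact_cap largest n for exact enumeration (default 20).
#' @param method `"auto"` (exact iff `n <= exact_cap`), `"exact"` or
#'   `"monte_carlo"`.
#' @return List of class `ul_perm_test`: `mean_lift`, `p_value`, `method`,
#'   `n_permutations` (`2^n` when exact), `seed`, `lifts`.
#' @export
permutation_test_lift <- function(lifts, n_permutations = 10000, seed = 1,
                                  exact_cap = 20,
                                  method = c("auto", "exact", "monte_carlo")) {
  method <- match.arg(method)
  n <- length(lifts)
  if (n < 2L) ul_abort("need >= 2 lifts", "userlift_contract_error")
  if (any(!is.finite(lifts))) ul_abort("lifts must be finite", "userlift_validation_error")
  if (method == "auto") method <- if (n <= exact_cap) "exact" else "monte_carlo"
  if (method == "exact" && n > 30L) {
    ul_abort("exact enumeration is limited to n <= 30", "userlift_contract_error")
  }
  # Mean over a sign pattern s is >= observed mean  iff  the sum of the lifts
  # whose sign was flipped is <= 0, so exact mode counts subsets with
  # non-positive sum.
  eps <- 1e-9 * max(1, sum(abs(lifts)))
  if (method == "exact") {
    a <- lifts[seq_len(ceiling(n / 2))]
    b <- lifts[setdiff(seq_len(n), seq_len(ceiling(n / 2)))]
    sums_a <- subset_sums(a)
    sums_b <- sort(subset_sums(b))
    count <- sum(findInterval(eps - sums_a, sums_b))
    p <- count / 2^n
    n_perm <- 2^n
  } else {
    obs <- mean(lifts)
    perm_means <- withr::with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                      nrow = n_permutations)
      as.numeric(signs %*% lifts) / n
    })
    p <- (1 + sum(perm_means >= obs - eps / n)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(mean_lift = mean(lifts), p_value = p, method = method,
                 n_permutations = n_perm, seed = seed, lifts = lifts),
            class = "ul_perm_test")
}

# All 2^k subset sums of x (k <= 15 in practice).
subset_sums <- function(x) {
  k <- length(x)
  if (!k) return(0)
  sums <- 0
  for (v in x) sums <- c(sums, sums + v)
  sums
}

#' @export
print.ul_perm_test <- function(x, ...) {
  cat(sprintf("<ul_perm_test> mean lift = %.4g, p = %.4g (%s, %s sign patterns)\n",
              x$mean_lift, x$p_value, x$method,
              format(x$n_permutations, big.mark = ",")))
  invisible(x)
}

#' Join baselines and model errors into the user-lift evaluation
#'
#' Combines per-user personal baseline errors and per-user model errors into
#' the per-user lift table, runs the sign-flip permutation test of mean
#' lift > 0 for each model family, and emits a summary shaped like the usual
#' reporting table (average personal baseline error, average model error,
#' average user lift, p-value).
#'
#' @param personal_baselines tibble from [personal_baseline()].
#' @param model_results tibble from [loocv_personal()] /
#'   [loocv_population()]; rows with `scope == "personal"` drive the lift.
#' @param population_baselines optional tibble from [population_baseline()];
#'   carried through into the per-user table when given.
#' @param n_permutations,seed,exact_cap passed to
#'   [permutation_test_lift()].
#' @return List of class `ul_eval`: `per_user` (one row per user and family
#'   with the errors and `user_lift`), `summary` (one row per task/family),
#'   `tests` (named list of `ul_perm_test`).
#' @export
evaluate_cohort <- function(personal_baselines, model_results,
                            population_baselines = NULL,
                            n_permutations = 10000, seed = 1, exact_cap = 20) {
  personal_models <- model_results[model_results$scope == "personal", , drop = FALSE]
  if (!nrow(personal_models)) {
    ul_abort("model_results contains no personal-scope rows", "userlift_contract_error")
  }
  b_users <- sort(unique(personal_baselines$user_id))
  m_users <- sort(unique(personal_models$user_id))
  extra <- c(setdiff(b_users, m_users), setdiff(m_users, b_users))
  if (length(extra)) {
    ul_abort(paste("user(s) present in only one input:",
                   paste(extra, collapse = ", ")), "userlift_contract_error")
  }
  base <- dplyr::select(personal_baselines, "user_id", "task",
                        personal_baseline_error = "error")
  per_user <- dplyr::inner_join(
    base,
    dplyr::select(personal_models, "user_id", "task", "family",
                  personal_model_error = "error"),
    by = c("user_id", "task"))
  per_user$user_lift <- user_lift(per_user$personal_baseline_error,
                                  per_user$personal_model_error)
  if (!is.null(population_baselines)) {
    per_user <- dplyr::left_join(
      per_user,
      dplyr::select(
        population_baselines[population_baselines$user_id != ".population", ,
                             drop = FALSE],
        "user_id", "task", population_baseline_error = "error"),
      by = c("user_id", "task"))
  }
  pop_models <- model_results[model_results$scope == "population" &
                                model_results$user_id != ".population", ,
                              drop = FALSE]
  if (nrow(pop_models)) {
    per_user <- dplyr::left_join(
      per_user,
      dplyr::select(pop_models, "user_id", "task", "family",
                    population_model_error = "error"),
      by = c("user_id", "task", "family"))
  }

  groups <- split(per_user, interaction(per_user$task, per_user$family, drop = TRUE))
  tests <- list()
  summary_rows <- lapply(groups, function(g) {
    key <- paste(g$task[1L], g$family[1L], sep = "/")
    test <- permutation_test_lift(g$user_lift, n_permutations = n_permutations,
                                  seed = seed, exact_cap = exact_cap)
    tests[[key]] <<- test
    tibble(task = g$task[1L], family = g$family[1L], n_users = nrow(g),
           avg_personal_baseline_error = mean(g$personal_baseline_error),
           avg_model_error = mean(g$personal_model_error),
           avg_user_lift = mean(g$user_lift),
           p_value = test$p_value)
  })
  structure(list(per_user = per_user,
                 summary = dplyr::bind_rows(summary_rows),
                 tests = tests),
            class = "ul_eval")
}

#' @export
print.ul_eval <- function(x, ...) {
  cat("<ul_eval> user-lift evaluation\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
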
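# Families per task, ordered simplest-first (the tie-break order for
# select_best_family).
UL_FAMILIES <- list(
  binary = c("logistic_l2", "svm_rbf", "random_forest", "constant"),
  regression = c("lasso", "elastic_net", "constant")
)

default_grid <- function(family, n_features) {
  lambda <- 10^seq(1, -3, length.out = 5)
  switch(family,
    logistic_l2 = expand.grid(lambda = lambda),
    lasso = expand.grid(lambda = lambda),
    elastic_net = expand.grid(lambda = lambda, alpha = c(0.2, 0.5, 0.8)),
    svm_rbf = expand.grid(cost = c(0.1, 1, 10),
                          gamma = c(0.5, 1, 2) / max(n_features, 1)),
    random_forest = expand.grid(mtry = unique(pmin(c(2L, 4L, 7L), n_features))),
    constant = expand.grid(dummy = 0),
    ul_abort(paste("unknown model family:", family), "userlift_config_error")
  )
}

#' Specify a predictive model
#'
#' @param task `"binary"` or `"regression"`.
#' @param family one of `"logistic_l2"`, `"svm_rbf"`, `"random_forest"`,
#'   `"constant"` (binary) or `"elastic_net"`, `"lasso"`, `"constant"`
#'   (regression). `"constant"` is the trivial mode/mean learner, useful as a
#'   reference and as the fallback for single-class training sets.
#' @param grid data frame of hyperparameter combinations; `NULL` uses a
#'   small documented default (penalized models: 5 penalty values, elastic
#'   net also 3 mixing values; SVM: 3 costs x 3 kernel widths; forest:
#'   3 `mtry` values).
#' @param inner_folds folds for inner hyperparameter cross-validation
#'   (default 10).
#' @param hyper_mode `"nested"` re-selects hyperparameters inside every outer
#'   training set (the default, leak-free); `"once"` selects once on the full
#'   data before the outer loop (faster, slightly optimistic; intended for
#'   large simulation sweeps).
#' @param standardize center/scale features using training-fold statistics
#'   (default TRUE; penalized models need it).
#' @param clip_to_scale optional `c(min, max)`; regression predictions are
#'   clipped into it (off by default).
#' @param seed integer seed for fold assignment and stochastic learners.
#' @return List of class `ul_model_spec`.
#' @export
model_spec <- function(task = c("binary", "regression"), family = NULL,
                       grid = NULL, inner_folds = 10,
                       hyper_mode = c("nested", "once"),
                       standardize = TRUE, clip_to_scale = NULL, seed = 1) {
  task <- match.arg(task)
  family <- family %||% UL_FAMILIES[[task]][1L]
  if (!family %in% UL_FAMILIES[[task]]) {
    ul_abort(sprintf("family '%s' is not valid for task '%s' (choose from: %s)",
                     family, task, paste(UL_FAMILIES[[task]], collapse = ", ")),
             "userlift_config_error")
  }
  if (!is.null(grid) && (!is.data.frame(grid) || !nrow(grid))) {
    ul_abort("grid must be NULL or a non-empty data frame", "userlift_config_error")
  }
  structure(list(task = task, family = family, grid = grid,
                 inner_folds = check_count(inner_folds, "inner_folds", 2L),
                 hyper_mode = match.arg(hyper_mode),
                 standardize = isTRUE(standardize),
                 clip_to_scale = clip_to_scale,
                 seed = check_count(seed, "seed", 0L)),
            class = "ul_model_spec")
}

# ---- learners ---------------------------------------------------------------

fit_learner <- function(family, X, y, task, hyper, seed) {
  if (task == "binary" && min(table(factor(y, levels = c(FALSE, TRUE)))) < 2L) {
    # (near-)single-class training set: constant-predictor fallback (the
    # penalized/kernel fitters need at least two observations per class)
    return(structure(list(value = mode_binary(y), fallback = TRUE),
                     class = "ul_const_fit"))
  }
  switch(family,
    constant = structure(
      list(value = if (task == "binary") mode_binary(y) else mean(y),
           fallback = FALSE),
      class = "ul_const_fit"),
    logistic_l2 = structure(
      list(fit = suppressWarnings(glmnet::glmnet(X, factor(y, levels = c(FALSE, TRUE)),
                                family = "binomial", alpha = 0,
                                lambda = sort(unique(c(hyper$lambda, 10^seq(1, -3, length.out = 5))), decreasing = TRUE))),
           s = hyper$lambda),
      class = "ul_glmnet_binary_fit"),
    lasso = structure(
      list(fit = glmnet::glmnet(X, y, alpha = 1,
                                lambda = sort(unique(c(hyper$lambda, 10^seq(1, -3, length.out = 5))), decreasing = TRUE)),
           s = hyper$lambda),
      class = "ul_glmnet_gaussian_fit"),
    elastic_net = structure(
      list(fit = glmnet::glmnet(X, y, alpha = hyper$alpha,
                                lambda = sort(unique(c(hyper$lambda, 10^seq(1, -3, length.out = 5))), decreasing = TRUE)),
           s = hyper$lambda),
      class = "ul_glmnet_gaussian_fit"),
    svm_rbf = structure(
      list(fit = e1071::svm(X, factor(y, levels = c(FALSE, TRUE)),
                            kernel = "radial", cost = hyper$cost,
                            gamma = hyper$gamma, scale = FALSE)),
      class = "ul_svm_fit"),
    random_forest = structure(
      list(fit = withr::with_seed(seed,
             randomForest::randomForest(X, factor(y, levels = c(FALSE, TRUE)),
                                        ntree = 200,
                                        mtry = min(hyper$mtry, ncol(X))))),
      class = "ul_rf_fit"),
    ul_abort(paste("unknown model family:", family), "userlift_config_error")
  )
}

predict_learner <- function(object, X) UseMethod("predict_learner")

#' @export
predict_learner.ul_const_fit <- function(object, X) {
  rep(object$value, nrow(X))
}
# linear predictor straight from the path coefficients when the requested
# lambda sits on the fitted path (it always does here); falls back to
# glmnet's interpolating predict otherwise
glmnet_linpred <- function(fit, X, s) {
  j <- which.min(abs(fit$lambda - s))
  if (abs(fit$lambda[j] - s) > 1e-10 * max(s, 1e-10)) {
    return(as.numeric(predict(fit, X, s = s)))
  }
  as.numeric(fit$a0[j] + X %*% fit$beta[, j])
}

#' @export
predict_learner.ul_glmnet_binary_fit <- function(object, X) {
  glmnet_linpred(object$fit, X, object$s) >= 0   # logit 0 <=> probability 0.5
}
#' @export
predict_learner.ul_glmnet_gaussian_fit <- function(object, X) {
  glmnet_linpred(object$fit, X, object$s)
}
#' @export
predict_learner.ul_svm_fit <- function(object, X) {
  as.logical(predict(object$fit, X))
}
#' @export
predict_learner.ul_rf_fit <- function(object, X) {
  as.logical(predict(object$fit, X))
}

# training-fold standardization; constant columns get scale 1
standardize_params <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardize <- function(X, pars) {
  sweep(sweep(X, 2L, pars$center), 2L, pars$scale, "/")
}

fold_error <- function(pred, y, task) {
  if (task == "binary") prediction_error(pred, y) else rmse(pred, y)
}

# inner k-fold CV over the hyperparameter grid; returns the winning row
# (ties: first row, i.e. the simplest setting in the documented grid order)
select_hyper <- function(X, y, task, family, grid, folds, seed) {
  n <- nrow(X)
  folds <- min(folds, n)
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  if (family %in% c("logistic_l2", "lasso", "elastic_net")) {
    return(select_hyper_glmnet(X, y, task, family, grid, folds, fold_id))
  }
  errs <- vapply(seq_len(nrow(grid)), function(g) {
    hy <- grid[g, , drop = FALSE]
    fe <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (task == "binary" && length(unique(y[tr])) < 2L) {
        pred <- rep(y[tr][1L], sum(!tr))
      } else {
        fit <- fit_learner(family, X[tr, , drop = FALSE], y[tr], task, hy, seed)
        pred <- predict_learner(fit, X[!tr, , drop = FALSE])
      }
      fold_error(pred, y[!tr], task)
    }, numeric(1))
    mean(fe)
  }, numeric(1))
  grid[which.min(errs), , drop = FALSE]
}

# glmnet families: one path fit per fold (and per alpha) scores every lambda
# in the grid at once; same folds and same selection rule as the generic path
select_hyper_glmnet <- function(X, y, task, family, grid, folds, fold_id) {
  alpha_of <- function(g) if (family == "elastic_net") g$alpha else
    if (family == "lasso") 1 else 0
  alphas <- if (family == "elastic_net") unique(grid$alpha) else alpha_of(grid)[1]
  errs <- rep(NA_real_, nrow(grid))
  for (a in alphas) {
    rows <- if (family == "elastic_net") which(grid$alpha == a) else
      seq_len(nrow(grid))
    lam <- grid$lambda[rows]
    path <- sort(unique(c(lam, 10^seq(1, -3, length.out = 5))), decreasing = TRUE)
    fold_err <- matrix(NA_real_, folds, length(rows))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      ytr <- y[tr]
      if (task == "binary") {
        if (min(table(factor(ytr, levels = c(FALSE, TRUE)))) < 2L) {
          pred <- matrix(mode_binary(ytr), sum(!tr), length(rows))
        } else {
          fit <- suppressWarnings(glmnet::glmnet(
            X[tr, , drop = FALSE], factor(ytr, levels = c(FALSE, TRUE)),
            family = "binomial", alpha = a, lambda = path))
          pred <- predict(fit, X[!tr, , drop = FALSE], s = lam,
                          type = "response") >= 0.5
        }
        fold_err[f, ] <- 100 * colMeans(pred != y[!tr])
      } else {
        fit <- glmnet::glmnet(X[tr, , drop = FALSE], ytr, alpha = a,
                              lambda = path)
        pred <- predict(fit, X[!tr, , drop = FALSE], s = lam)
        fold_err[f, ] <- sqrt(colMeans((pred - y[!tr])^2))
      }
    }
    errs[rows] <- colMeans(fold_err)
  }
  grid[which.min(errs), , drop = FALSE]
}

# ---- LOOCV ------------------------------------------------------------------

loocv_core <- function(X, y, spec, audit_hook = NULL, user_ids = NULL) {
  n <- nrow(X)
  grid <- spec$grid %||% default_grid(spec$family, ncol(X))
  hyper_global <- NULL
  if (spec$hyper_mode == "once" || nrow(grid) == 1L) {
    hyper_global <- if (nrow(grid) == 1L) grid[1L, , drop = FALSE] else
      select_hyper(X, y, spec$task, spec$family, grid, spec$inner_folds, spec$seed)
  }
  pred <- vector(if (spec$task == "binary") "logical" else "numeric", n)
  n_fallback <- 0L
  for (i in seq_len(n)) {
    tr <- seq_len(n) != i
    if (!is.null(audit_hook)) audit_hook(user_ids[tr])
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (spec$standardize) {
      pars <- standardize_params(Xtr)
      Xtr <- apply_standardize(Xtr, pars)
      Xte <- apply_standardize(X[i, , drop = FALSE], pars)
    } else {
      Xte <- X[i, , drop = FALSE]
    }
    hyper <- hyper_global %||%
      select_hyper(Xtr, ytr, spec$task, spec$family, grid, spec$inner_folds,
                   spec$seed)
    fit <- fit_learner(spec$family, Xtr, ytr, spec$task, hyper, spec$seed)
    if (inherits(fit, "ul_const_fit") && isTRUE(fit$fallback)) {
      n_fallback <- n_fallback + 1L
    }
    p <- predict_learner(fit, Xte)
    if (spec$task == "regression" && !is.null(spec$clip_to_scale)) {
      p <- pmin(pmax(p, spec$clip_to_scale[1L]), spec$clip_to_scale[2L])
    }
    pred[i] <- p
  }
  if (n_fallback > 0L) {
    inform(sprintf("%d LOOCV fold(s) had a single-class training set; constant fallback used",
                   n_fallback))
  }
  pred
}

# build X / y from a model frame (user_id, label, feature columns)
model_matrix_from_frame <- function(data, feature_cols, label_col) {
  missing <- setdiff(c(feature_cols, label_col), names(data))
  if (length(missing)) {
    ul_abort(paste("model frame missing column(s):", paste(missing, collapse = ", ")),
             "userlift_contract_error")
  }
  X <- as.matrix(data[feature_cols])
  storage.mode(X) <- "double"
  X[!is.finite(X)] <- 0                    # defensive: degenerate features
  if (ncol(X) == 1L) {                     # glmnet needs >= 2 columns
    X <- cbind(X, .pad = 0)
  }
  list(X = X, y = data[[label_col]])
}

#' Personal models under leave-one-out cross-validation
#'
#' For each user separately: hold out one day, train on the user's remaining
#' days only (hyperparameters by inner k-fold cross-validation on that
#' training set), predict the held-out day, and repeat until every day was
#' held out once. The user's model error aggregates all held-out predictions
#' (percent incorrect or RMSE).
#'
#' @param data model frame: one row per qualifying user-day with `user_id`,
#'   the label column and the feature columns.
#' @param spec an `ul_model_spec`.
#' @param feature_cols character vector of feature column names (default: the
#'   15 mobility features).
#' @param label_col label column; default `"label_binary"` for binary task,
#'   `"label_level"` for regression.
#' @param audit_hook optional function called with the training-set user ids
#'   of every outer fold (used to audit against cross-user leakage).
#' @return Tibble `user_id`, `scope = "personal"`, `task`, `family`, `error`,
#'   `n_evaluations`; attribute `predictions` holds the held-out predictions
#'   per user.
#' @export
loocv_personal <- function(data, spec, feature_cols = UL_FEATURES,
                           label_col = NULL, audit_hook = NULL) {
  stopifnot(inherits(spec, "ul_model_spec"))
  label_col <- label_col %||%
    if (spec$task == "binary") "label_binary" else "label_level"
  min_days <- max(spec$inner_folds + 1L, 10L)
  preds <- list()
  rows <- lapply(split(data, data$user_id), function(du) {
    if (nrow(du) < min_days) {
      ul_abort(sprintf("user %s has %d qualifying days; personal LOOCV needs >= %d",
                       du$user_id[1L], nrow(du), min_days),
               "userlift_contract_error")
    }
    mm <- model_matrix_from_frame(du, feature_cols, label_col)
    pred <- loocv_core(mm$X, mm$y, spec, audit_hook = audit_hook,
                       user_ids = du$user_id)
    preds[[du$user_id[1L]]] <<- pred
    tibble(user_id = du$user_id[1L], scope = "personal", task = spec$task,
           family = spec$family, error = fold_error(pred, mm$y, spec$task),
           n_evaluations = nrow(du))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "predictions") <- preds
  out
}

#' Population model under leave-one-out cross-validation
#'
#' Pools all users' days into one set, then holds out one observation at a
#' time and trains on all of the others (so some of each user's data is seen
#' during training). Per-user errors are computed from each user's held-out
#' predictions; the pooled error (row `user_id = ".population"`) is the
#' average over all predictions.
#'
#' @inheritParams loocv_personal
#' @return Tibble as in [loocv_personal()] with `scope = "population"` and an
#'   extra pooled row.
#' @export
loocv_population <- function(data, spec, feature_cols = UL_FEATURES,
                             label_col = NULL, audit_hook = NULL) {
  stopifnot(inherits(spec, "ul_model_spec"))
  label_col <- label_col %||%
    if (spec$task == "binary") "label_binary" else "label_level"
  mm <- model_matrix_from_frame(data, feature_cols, label_col)
  pred <- loocv_core(mm$X, mm$y, spec, audit_hook = audit_hook,
                     user_ids = data$user_id)
  per_user <- lapply(split(seq_len(nrow(data)), data$user_id), function(ix) {
    tibble(user_id = data$user_id[ix[1L]], scope = "population",
           task = spec$task, family = spec$family,
           error = fold_error(pred[ix], mm$y[ix], spec$task),
           n_evaluations = length(ix))
  })
  out <- dplyr::bind_rows(c(per_user, list(tibble(
    user_id = ".population", scope = "population", task = spec$task,
    family = spec$family, error = fold_error(pred, mm$y, spec$task),
    n_evaluations = nrow(data)))))
  attr(out, "predictions") <- pred
  out
}

#' Pick the best model family
#'
#' Returns the family with the lowest average per-user error; exact ties go
#' to the simpler family in the documented order (binary: logistic_l2,
#' svm_rbf, random_forest, constant; regression: lasso, elastic_net,
#' constant).
#'
#' @param results tibble of model results (rows from [loocv_personal()] or
#'   [loocv_population()], possibly several families; pooled rows are
#'   ignored).
#' @return The winning family name (character).
#' @export
select_best_family <- function(results) {
  res <- results[results$user_id != ".population", , drop = FALSE]
  if (!nrow(res)) ul_abort("no model results", "userlift_contract_error")
  avg <- tapply(res$error, res$family, mean)
  order_ref <- unlist(UL_FAMILIES, use.names = FALSE)
  fams <- names(avg)[order(match(names(avg), order_ref))]
  avg <- avg[fams]
  fams[which.min(avg)]
}
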
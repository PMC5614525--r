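noise_days <- function(binary, user = "u1", n_features = 4, seed = 1) {
  n <- length(binary)
  feats <- withr::with_seed(seed, matrix(rnorm(n * n_features), n))
  colnames(feats) <- paste0("noise", seq_len(n_features))
  dplyr::bind_cols(
    tibble::tibble(user_id = user, date = as.Date("2024-01-01") + seq_len(n),
                   label_level = as.numeric(binary) + 2,
                   label_binary = as.logical(binary)),
    tibble::as_tibble(feats))
}

test_that("model specs validate families and grids", {
  expect_error(model_spec("binary", "lasso"), class = "userlift_config_error")
  expect_error(model_spec("regression", "svm_rbf"), class = "userlift_config_error")
  expect_error(model_spec("binary", grid = data.frame()),
               class = "userlift_config_error")
  expect_equal(model_spec("regression")$family, "lasso")
})

test_that("personal LOOCV with the constant learner reproduces hand-enumerated errors", {
  # 9 positive, 3 negative days: every leave-one-out mode is positive, so the
  # constant learner errs exactly on the negatives
  du <- noise_days(c(rep(1, 9), rep(0, 3)))
  res <- loocv_personal(du, model_spec("binary", "constant"),
                        feature_cols = paste0("noise", 1:4))
  expect_equal(res$error, 25)
  expect_equal(res$n_evaluations, 12)

  # all labels identical: zero error for a learner with fallback
  du0 <- noise_days(rep(1, 12))
  res0 <- suppressMessages(loocv_personal(du0, model_spec("binary", "logistic_l2"),
                                          feature_cols = paste0("noise", 1:4)))
  expect_equal(res0$error, 0)

  # regression constant learner: hand-computed leave-one-out mean RMSE
  lv <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3)
  dur <- noise_days(rep(1, 12)); dur$label_level <- lv
  resr <- loocv_personal(dur, model_spec("regression", "constant"),
                         feature_cols = paste0("noise", 1:4))
  oracle <- sqrt(mean(vapply(seq_along(lv),
                             function(i) (mean(lv[-i]) - lv[i])^2, numeric(1))))
  expect_equal(resr$error, oracle)

  # too few days is a contract error
  expect_error(loocv_personal(noise_days(c(1, 1, 1, 0)),
                              model_spec("binary", "constant"),
                              feature_cols = paste0("noise", 1:4)),
               class = "userlift_contract_error")
})

test_that("personal training sets never contain other users' rows", {
  du <- dplyr::bind_rows(noise_days(rep(c(1, 0), 6), user = "a"),
                         noise_days(rep(c(1, 1, 0), 4), user = "b", seed = 2))
  seen <- list()
  hook <- function(uids) seen[[length(seen) + 1]] <<- unique(uids)
  res <- suppressMessages(loocv_personal(du, model_spec("binary", "logistic_l2",
                                                        hyper_mode = "once"),
                                         feature_cols = paste0("noise", 1:4),
                                         audit_hook = hook))
  expect_length(seen, 24)                       # one audit per held-out day
  expect_true(all(lengths(seen) == 1))          # never another user's rows
  # population scope does see several users
  seen <- list()
  resp <- suppressMessages(loocv_population(du, model_spec("binary", "logistic_l2",
                                                           hyper_mode = "once"),
                                            feature_cols = paste0("noise", 1:4),
                                            audit_hook = hook))
  expect_true(all(lengths(seen) == 2))
})

test_that("LOOCV accounting: every observation held out once; pooled error is weighted", {
  du <- dplyr::bind_rows(noise_days(rep(c(1, 0, 0), 4), user = "a"),
                         noise_days(rep(c(1, 1, 0), 5), user = "b", seed = 2))
  spec <- model_spec("binary", "constant")
  res <- loocv_population(du, spec, feature_cols = paste0("noise", 1:4))
  pred <- attr(res, "predictions")
  expect_length(pred, nrow(du))
  per_user <- res[res$user_id != ".population", ]
  pooled <- res[res$user_id == ".population", ]
  expect_equal(pooled$error,
               sum(per_user$error * per_user$n_evaluations) /
                 sum(per_user$n_evaluations))
  expect_equal(pooled$n_evaluations, nrow(du))

  # a cohort of one user: population LOOCV equals personal LOOCV
  solo <- noise_days(rep(c(1, 0, 0), 4), user = "a")
  rp <- loocv_personal(solo, spec, feature_cols = paste0("noise", 1:4))
  rpop <- loocv_population(solo, spec, feature_cols = paste0("noise", 1:4))
  expect_equal(rpop$error[rpop$user_id == "a"], rp$error)
})

test_that("standardization parameters come from the training rows only", {
  X <- matrix(c(1, 2, 3, 100, 0, 0, 0, 0), ncol = 2)
  pars <- userlift:::standardize_params(X[1:3, , drop = FALSE])
  expect_equal(pars$center, c(2, 0))
  expect_equal(pars$scale, c(1, 1))            # constant column -> scale 1
  Z <- userlift:::apply_standardize(X[4, , drop = FALSE], pars)
  expect_equal(as.numeric(Z), c(98, 0))        # outlier scaled by train stats
})

test_that("the best family has the lowest average error, ties to the simpler", {
  res <- tibble::tibble(user_id = rep(c("a", "b"), 2), scope = "personal",
                        task = "binary",
                        family = rep(c("random_forest", "logistic_l2"), each = 2),
                        error = c(30, 20, 30, 20), n_evaluations = 30)
  expect_equal(select_best_family(res), "logistic_l2")  # tie -> simpler
  res$error[res$family == "random_forest"] <- c(24, 24)
  expect_equal(select_best_family(res), "random_forest")
  expect_equal(select_best_family(res[res$family == "logistic_l2", ]),
               "logistic_l2")
})

test_that("an informative mobility feature beats the personal baseline under strong signal", {
  # the planted driver itself (plus small noise) as the single feature: the
  # model should out-predict the constant personal guess for most users
  wins <- 0L; total <- 0L
  for (s in 1:3) {
    co <- generate_cohort(tiny_config(seed = s, beta = 2, n_users = 5))
    days <- filter_participants(build_day_records(co$responses, co$locations,
                                                  co$scale))
    truth <- co$truth$days
    du <- dplyr::inner_join(days,
                            tibble::tibble(user_id = truth$user_id,
                                           date = truth$date,
                                           driver = truth$s_z),
                            by = c("user_id", "date"))
    du$driver <- du$driver + withr::with_seed(s, rnorm(nrow(du), sd = 0.05))
    mr <- suppressMessages(loocv_personal(du, model_spec("binary", "logistic_l2",
                                                         hyper_mode = "once"),
                                          feature_cols = "driver"))
    pb <- personal_baseline(days, "binary")
    wins <- wins + sum(mr$error < pb$error)
    total <- total + nrow(mr)
  }
  expect_gt(wins / total, 0.8)
})

test_that("pooled null-regime model error approaches the population baseline error", {
  diffs <- vapply(1:20, function(s) {
    du <- noise_frame(seed = s + 200, beta = 0, n_users = 4)
    mr <- suppressMessages(loocv_population(
      du, model_spec("binary", "logistic_l2", hyper_mode = "once", seed = s),
      feature_cols = paste0("noise", 1:5)))
    popb <- population_baseline(du, "binary")
    mr$error[mr$user_id == ".population"] -
      popb$error[popb$user_id == ".population"]
  }, numeric(1))
  # pure-noise features cannot beat pooled guessing; on average the model
  # should sit near (within a few points of) the population baseline
  expect_lt(abs(mean(diffs)), 5)
})
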
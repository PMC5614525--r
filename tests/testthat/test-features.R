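# hand-built models so feature arithmetic is isolated from fitting
toy_gmm <- function(means, vars = NULL) {
  K <- nrow(means)
  structure(list(K = K, weights = rep(1 / K, K), means = means,
                 vars = vars %||% matrix(100, K, 2), bic = NULL, n = 100L),
            class = "ul_gmm")
}
toy_kmeans <- function(centers) {
  structure(list(K = nrow(centers), centers = centers, bic = NULL, n = 100L),
            class = "ul_kmeans")
}

test_that("degenerate single-point days produce the expected feature values", {
  n <- 40
  full <- toy_gmm(matrix(c(0, 0), 1))
  stat <- toy_kmeans(matrix(c(0, 0), 1))
  sem <- list(home_id = 1L, work_id = 1L, night_id = 1L)
  f <- compute_daily_features(rep(0, n), rep(0, n), seq_len(n) * 60,
                              rep(TRUE, n), full, stat, sem,
                              user_mean_fracs = 1)
  expect_equal(f$frac_not_stationary, 0)
  expect_equal(f$mean_displacement, 0)
  expect_equal(f$sd_displacement, 0)
  expect_equal(f$location_entropy, 0)
  expect_equal(f$mec_radius, 0)
  expect_equal(f$n_full_clusters, 1)
  expect_equal(f$n_stat_clusters, 1)
  expect_equal(f$circadian_movement, 0)   # day fractions equal the user mean
  expect_equal(f$frac_home, 1)
  expect_error(compute_daily_features(0, 0, 0, TRUE, full, stat, sem),
               class = "userlift_contract_error")
})

test_that("entropy, fractions and circadian movement follow their definitions", {
  # day split equally across two stationary clusters: entropy ln 2
  full <- toy_gmm(matrix(c(0, 0, 1000, 0), 2, byrow = TRUE))
  stat <- toy_kmeans(matrix(c(0, 0, 1000, 0), 2, byrow = TRUE))
  sem <- list(home_id = 1L, work_id = 2L, night_id = 1L)
  x <- rep(c(0, 1000), each = 20); ts <- seq_len(40) * 60
  f <- compute_daily_features(x, rep(0, 40), ts, rep(TRUE, 40), full, stat,
                              sem, user_mean_fracs = c(0.5, 0.5))
  expect_equal(f$location_entropy, log(2))
  expect_equal(f$circadian_movement, 0)
  expect_equal(f$frac_home, 0.5)
  expect_equal(f$frac_work, 0.5)
  expect_equal(f$frac_night, 0.5)
  expect_equal(f$n_full_clusters, 2)

  # circadian movement is the Euclidean distance between fraction vectors
  f2 <- compute_daily_features(x, rep(0, 40), ts, rep(TRUE, 40), full, stat,
                               sem, user_mean_fracs = c(0.9, 0.1))
  expect_equal(f2$circadian_movement, sqrt(2 * 0.4^2))

  # undefined semantic ids zero the corresponding fractions
  sem_na <- list(home_id = NA_integer_, work_id = 2L, night_id = NA_integer_)
  f3 <- compute_daily_features(x, rep(0, 40), ts, rep(TRUE, 40), full, stat,
                               sem_na, user_mean_fracs = c(0.5, 0.5))
  expect_equal(f3$frac_home, 0)
  expect_equal(f3$frac_night, 0)
})

test_that("displacement and variance features scale correctly", {
  withr::with_seed(7, {
    x <- cumsum(rnorm(50, sd = 40)); y <- cumsum(rnorm(50, sd = 40))
  })
  ts <- seq_len(50) * 120
  full <- toy_gmm(matrix(c(0, 0), 1)); stat <- toy_kmeans(matrix(c(0, 0), 1))
  sem <- list(home_id = 1L, work_id = 1L, night_id = 1L)
  f1 <- compute_daily_features(x, y, ts, rep(TRUE, 50), full, stat, sem,
                               user_mean_fracs = 1, var_eps = 0)
  f2 <- compute_daily_features(2 * x, 2 * y, ts, rep(TRUE, 50), full, stat,
                               sem, user_mean_fracs = 1, var_eps = 0)
  expect_equal(f2$mean_displacement, 2 * f1$mean_displacement)
  expect_equal(f2$sd_displacement, 2 * f1$sd_displacement)
  expect_equal(f2$mec_radius, 2 * f1$mec_radius)
  expect_equal(f2$log_location_variance, f1$log_location_variance + log(4))

  # displacement pairs across gaps larger than 10 minutes are skipped
  ts_gap <- ts; ts_gap[26:50] <- ts_gap[26:50] + 7200
  f3 <- compute_daily_features(x, y, ts_gap, rep(TRUE, 50), full, stat, sem,
                               user_mean_fracs = 1)
  d <- sqrt(diff(x)^2 + diff(y)^2)
  expect_equal(f3$mean_displacement, mean(d[-25]))

  # determinism: identical inputs give identical features
  expect_identical(f1, compute_daily_features(x, y, ts, rep(TRUE, 50), full,
                                              stat, sem, user_mean_fracs = 1,
                                              var_eps = 0))
})

test_that("extracted feature tables satisfy the bound invariants", {
  frame <- tiny_model_frame(seed = 42)
  expect_true(all(frame$frac_not_stationary >= 0 & frame$frac_not_stationary <= 1))
  expect_true(all(frame$frac_home >= 0 & frame$frac_home <= 1))
  expect_true(all(frame$frac_work >= 0 & frame$frac_work <= 1))
  expect_true(all(frame$frac_night >= 0 & frame$frac_night <= 1))
  expect_true(all(frame$location_entropy >= 0))
  expect_true(all(frame$mec_radius >= 0))
  expect_true(all(frame$sd_displacement >= 0))
  expect_true(all(frame$circadian_movement >= 0))
  expect_true(all(frame$n_full_clusters >= 1))
  expect_true(all(frame$n_stat_clusters >= 1))
  expect_true(all(is.finite(as.matrix(frame[UL_FEATURES]))))

  co <- tiny_cohort(seed = 42)
  fe <- suppressMessages(extract_mobility_features(co$locations,
                                                   tiny_days(seed = 42),
                                                   max_K = 6, seed = 42))
  for (u in names(fe$models)) {
    m <- fe$models[[u]]
    rows <- frame[frame$user_id == u, ]
    expect_true(all(rows$location_entropy <= log(m$stationary$K) + 1e-9))
    expect_true(all(rows$n_full_clusters <= m$full$K))
    expect_true(all(rows$n_stat_clusters <= m$stationary$K))
    expect_true(m$full$K >= 1 && m$full$K <= 6)
  }

  # every featurized day satisfies the inclusion predicate
  expect_true(all(frame$n_gps_obs.x >= 35))
})
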
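test_that("invalid configurations are rejected naming the violated bound", {
  expect_error(cohort_config(n_users = 1), "n_users",
               class = "userlift_config_error")
  expect_error(cohort_config(n_days = 29), "n_days",
               class = "userlift_config_error")
  expect_error(cohort_config(gps_obs_per_day = 34), "gps_obs_per_day",
               class = "userlift_config_error")
  expect_error(cohort_config(scale_min = 5, scale_max = 5),
               class = "userlift_config_error")
  expect_error(cohort_config(within_user_sd = -0.1), "within_user_sd",
               class = "userlift_config_error")
  expect_error(generate_cohort(list(n_users = 3)),
               class = "userlift_config_error")
})

test_that("generation is deterministic and has the configured shape", {
  cfg <- tiny_config(seed = 5, n_users = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$locations, b$locations)
  expect_identical(a$responses, b$responses)
  expect_identical(a$truth$days, b$truth$days)

  # counts follow the configuration
  expect_equal(nrow(a$responses), 3 * 30 * cfg$responses_per_day)
  expect_equal(nrow(a$locations), 3 * 30 * cfg$gps_obs_per_day)

  # a different seed changes the data
  expect_false(identical(generate_cohort(tiny_config(seed = 6, n_users = 3))$responses,
                         a$responses))
})

test_that("no-variance regime yields constant reports and zero personal baseline error", {
  co <- generate_cohort(tiny_config(seed = 3, n_users = 3, beta = 0,
                                    within_user_sd = 0, report_noise_sd = 0))
  per_user_vals <- tapply(co$responses$value, co$responses$user_id,
                          function(v) length(unique(v)))
  expect_true(all(per_user_vals == 1))
  days <- filter_participants(build_day_records(co$responses, co$locations,
                                                co$scale))
  expect_true(all(personal_baseline(days, "binary")$error == 0))
  expect_true(all(personal_baseline(days, "regression")$error == 0))
})

test_that("generated cohorts pass the inclusion filters they were configured for", {
  co <- tiny_cohort(seed = 42)
  days <- build_day_records(co$responses, co$locations, co$scale)
  kept <- filter_participants(days)
  expect_setequal(attr(kept, "retained_users"), unique(co$responses$user_id))
  expect_true(all(kept$n_gps_obs >= 35))
  expect_equal(nrow(kept), co$config$n_users * co$config$n_days)
})

test_that("cohorts round-trip through the fixture files and ingest readers", {
  co <- generate_cohort(tiny_config(seed = 8, n_users = 2))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))

  loc <- read_locations(paths[["locations"]])
  expect_equal(nrow(loc), nrow(co$locations))
  expect_equal(loc$latitude, co$locations$latitude)
  expect_equal(loc$timestamp, co$locations$timestamp)
  expect_equal(loc$is_moving, as.logical(co$locations$is_moving))

  scales <- read_scales(paths[["scales"]])
  expect_equal(scales[["sim"]], co$scale)
  resp <- read_responses(paths[["responses"]], scales[["sim"]])
  expect_equal(resp$value, co$responses$value)
  expect_equal(resp$timestamp, co$responses$timestamp)

  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$users$mu, co$truth$users$mu)
})

test_that("label variance components match a direct simulation oracle", {
  # Wide scale so rounding/clamping distortion is small; no report noise so
  # the daily label equals the latent level. The oracle simulates the scalar
  # label model directly, without the cohort machinery.
  between_sd <- 2; within_sd <- 1
  oracle_within <- withr::with_seed(1, {
    mu1 <- pmin(pmax(rnorm(1e3, 10, between_sd), 0), 20)
    mean(vapply(mu1, function(m)
      var(pmin(pmax(round(m + rnorm(200, 0, within_sd)), 0), 20)),
      numeric(1)))
  })

  withins <- c(); user_means <- c()
  for (s in 1:6) {
    co <- generate_cohort(cohort_config(
      n_users = 20, n_days = 40, scale_min = 0, scale_max = 20,
      between_user_sd = between_sd, within_user_sd = within_sd,
      report_noise_sd = 0, effect_size = 0, gps_obs_per_day = 35, seed = s))
    lev <- co$truth$days$level
    uid <- co$truth$days$user_id
    withins <- c(withins, tapply(lev, uid, var))
    user_means <- c(user_means, tapply(lev, uid, mean))
  }
  # 120 user-level replicates of the within-user variance
  expect_equal(mean(withins), oracle_within, tolerance = 0.1)
  # between-user variance of user means (clamped normal + small within term)
  mu_var_oracle <- withr::with_seed(2,
    var(pmin(pmax(rnorm(2e5, 10, between_sd), 0), 20)))
  expect_equal(var(user_means), mu_var_oracle + mean(withins) / 40,
               tolerance = 0.25)
  # and the configured regime is low-within, high-between
  expect_lt(mean(withins), var(user_means))
})

test_that("labels are independent of mobility in the null regime", {
  cors <- vapply(1:6, function(s) {
    co <- generate_cohort(cohort_config(n_users = 10, n_days = 40,
                                        gps_obs_per_day = 35,
                                        effect_size = 0, seed = s + 100))
    stats::cor(co$truth$days$s_z, co$truth$days$level)
  }, numeric(1))
  expect_true(all(abs(cors) < 0.1))
  expect_lt(abs(mean(cors)), 0.05)

  # and strongly dependent in the signal regime
  co <- generate_cohort(cohort_config(n_users = 10, n_days = 40,
                                      gps_obs_per_day = 35,
                                      effect_size = 2, seed = 101))
  expect_gt(stats::cor(co$truth$days$s_z, co$truth$days$level), 0.5)
})
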
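#' Configure a synthetic smartphone-sensing cohort
#'
#' Defines the study conditions for [generate_cohort()]: cohort size, Likert
#' scale, sampling rates, the user's set of recurrent dwelling locations, and
#' the variance structure of the self-reports. Defaults emulate a
#' single-campus sensing study: 20 users followed for 40 days, a 5-point
#' stress scale reported twice a day, 40 GPS observations per day around 3
#' recurrent locations (home, work, one other), and much larger between-user
#' than within-user variance in reported state.
#'
#' The latent daily state of user u on day d is
#' `clamp(round(mu_u + beta * s_ud + eps_ud))`, with `mu_u ~ N(midpoint,
#' between_user_sd)` clamped to the scale, `eps_ud ~ N(0, within_user_sd)`,
#' and `s_ud` the within-user z-score of the fraction of the day spent away
#' from home. `beta = 0` is the null regime (state independent of mobility);
#' `beta > 0` plants a mobility-driven signal. Each report adds
#' integer-rounded `N(0, report_noise_sd)` noise, clamped to the scale.
#'
#' @param n_users number of users (>= 2).
#' @param n_days labeled days per user (>= 30, so cohorts pass the standard
#'   inclusion filter).
#' @param scale_min,scale_max integer Likert bounds.
#' @param responses_per_day reports per user-day (>= 1).
#' @param gps_obs_per_day GPS observations per user-day (>= 35).
#' @param n_locations_per_user recurrent locations (home, work, extras; >= 2).
#' @param effect_size beta, in Likert units per SD of the mobility driver.
#' @param within_user_sd,between_user_sd,report_noise_sd Likert-unit SDs.
#' @param gps_noise_sd isotropic GPS noise, meters.
#' @param origin `c(lat, lon)` about which synthetic planar coordinates are
#'   mapped to latitude/longitude.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return List of class `ul_cohort_config`.
#' @export
cohort_config <- function(n_users = 20, n_days = 40,
                          scale_min = 1, scale_max = 5,
                          responses_per_day = 2, gps_obs_per_day = 40,
                          n_locations_per_user = 3,
                          effect_size = 0,
                          within_user_sd = 0.7, between_user_sd = 1.0,
                          report_noise_sd = 0.5, gps_noise_sd = 20,
                          origin = c(44.0, -71.0), seed = 1) {
  cfg <- list(
    n_users = check_count(n_users, "n_users", 2L),
    n_days = check_count(n_days, "n_days", 30L),
    scale_min = check_count(scale_min, "scale_min", -1000L),
    scale_max = check_count(scale_max, "scale_max", -1000L),
    responses_per_day = check_count(responses_per_day, "responses_per_day", 1L),
    gps_obs_per_day = check_count(gps_obs_per_day, "gps_obs_per_day", 35L),
    n_locations_per_user = check_count(n_locations_per_user,
                                       "n_locations_per_user", 2L),
    effect_size = check_number(effect_size, "effect_size"),
    within_user_sd = check_number(within_user_sd, "within_user_sd", 0),
    between_user_sd = check_number(between_user_sd, "between_user_sd", 0),
    report_noise_sd = check_number(report_noise_sd, "report_noise_sd", 0),
    gps_noise_sd = check_number(gps_noise_sd, "gps_noise_sd", 0),
    origin = as.numeric(origin),
    seed = check_count(seed, "seed", 0L)
  )
  if (cfg$scale_min >= cfg$scale_max) {
    ul_abort("scale_min must be < scale_max", "userlift_config_error")
  }
  structure(cfg, class = "ul_cohort_config")
}

# epoch seconds of the first simulated day (2024-01-01 UTC)
SIM_EPOCH0 <- 1704067200

#' Generate a synthetic cohort
#'
#' Simulates GPS traces and Likert self-reports for every user-day under the
#' configured regime. Each day is a piecewise-constant hourly dwell schedule
#' over the user's locations — evening hours (11pm-6am) predominantly at
#' home, working hours (11am-4pm) predominantly at work — with brief
#' transition segments between dwells sampled at the same rate and flagged
#' moving, plus isotropic GPS noise. Ground truth (per-user mean state,
#' per-day mobility driver and latent level) is retained for recovery tests.
#'
#' @param config an `ul_cohort_config` from [cohort_config()].
#' @return List of class `ul_cohort`: `locations` (tibble matching the
#'   locations.csv schema, with `is_moving`), `responses` (responses.csv
#'   schema), `scale` (the `ul_scale` used, threshold at the scale
#'   midpoint), `truth` (list: `users`, `days` tibbles, `effect_size`,
#'   `seed`), `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "ul_cohort_config")) {
    ul_abort("config must come from cohort_config()", "userlift_config_error")
  }
  cfg <- config
  mid <- (cfg$scale_min + cfg$scale_max) / 2
  clamp <- function(v) pmin(pmax(v, cfg$scale_min), cfg$scale_max)
  n_loc <- cfg$n_locations_per_user
  loc_w <- c(2, 1, rep(1, n_loc - 2L)); loc_w <- loc_w / sum(loc_w)

  withr::with_seed(cfg$seed, {
    loc_rows <- vector("list", cfg$n_users)
    resp_rows <- vector("list", cfg$n_users)
    truth_users <- vector("list", cfg$n_users)
    truth_days <- vector("list", cfg$n_users)

    for (u in seq_len(cfg$n_users)) {
      uid <- sprintf("u%03d", u)
      # recurrent locations: home, work, extras (planar meters)
      th <- runif(n_loc, 0, 2 * pi)
      r <- c(sqrt(runif(1)) * 2000,
             runif(1, 800, 3000),
             if (n_loc > 2L) sqrt(runif(n_loc - 2L)) * 4000)
      centers <- cbind(r * cos(th), r * sin(th))
      centers[2L, ] <- centers[1L, ] + centers[2L, ]   # work offset from home
      mu_u <- clamp(rnorm(1, mid, cfg$between_user_sd))

      # hourly dwell schedule for every day: n_days x 24 location indices
      sched <- matrix(0L, cfg$n_days, 24L)
      for (h in 0:23) {
        col <- h + 1L
        if (h >= 23 || h < 6) {
          at_home <- runif(cfg$n_days) < 0.95
          other <- sample.int(n_loc, cfg$n_days, replace = TRUE, prob = loc_w)
          sched[, col] <- ifelse(at_home, 1L, other)
        } else if (h >= 11 && h < 16) {
          at_work <- runif(cfg$n_days) < 0.9
          other <- sample.int(n_loc, cfg$n_days, replace = TRUE, prob = loc_w)
          sched[, col] <- ifelse(at_work, 2L, other)
        } else {
          sched[, col] <- sample.int(n_loc, cfg$n_days, replace = TRUE,
                                     prob = loc_w)
        }
      }

      # GPS observations: distinct random seconds within each day
      k <- cfg$gps_obs_per_day
      secs <- unlist(lapply(seq_len(cfg$n_days),
                            function(d) sort(sample.int(86400L, k) - 1L)))
      day_idx <- rep(seq_len(cfg$n_days), each = k)
      hour <- secs %/% 3600L
      idx <- sched[cbind(day_idx, hour + 1L)]
      prev_col <- ifelse(hour == 0L, 24L, hour)        # hour 0 follows hour 23
      prev_idx <- sched[cbind(day_idx, prev_col)]
      sec_in_hour <- secs %% 3600L
      moving <- idx != prev_idx & sec_in_hour < 360L   # 6-min transit window
      frac <- sec_in_hour / 360
      px <- centers[idx, 1L]; py <- centers[idx, 2L]
      px[moving] <- centers[prev_idx[moving], 1L] +
        frac[moving] * (centers[idx[moving], 1L] - centers[prev_idx[moving], 1L])
      py[moving] <- centers[prev_idx[moving], 2L] +
        frac[moving] * (centers[idx[moving], 2L] - centers[prev_idx[moving], 2L])
      px <- px + rnorm(length(px), 0, cfg$gps_noise_sd)
      py <- py + rnorm(length(py), 0, cfg$gps_noise_sd)
      ll <- plane_to_latlon(px, py, cfg$origin)
      ts <- SIM_EPOCH0 + (day_idx - 1L) * 86400 + secs
      loc_rows[[u]] <- tibble(user_id = uid, timestamp = ts,
                              latitude = ll$latitude, longitude = ll$longitude,
                              is_moving = as.integer(moving))

      # latent daily state driven by the away-from-home fraction
      s_raw <- tapply(idx != 1L, day_idx, mean)
      s_sd <- stats::sd(s_raw)
      s_z <- if (is.na(s_sd) || s_sd == 0) rep(0, cfg$n_days) else
        as.numeric((s_raw - mean(s_raw)) / s_sd)
      eps <- rnorm(cfg$n_days, 0, cfg$within_user_sd)
      level <- clamp(round(mu_u + cfg$effect_size * s_z + eps))

      # reports: level plus integer-rounded noise, at daytime moments
      rpd <- cfg$responses_per_day
      rep_day <- rep(seq_len(cfg$n_days), each = rpd)
      rep_sec <- 8L * 3600L +
        unlist(lapply(seq_len(cfg$n_days),
                      function(d) sort(sample.int(14L * 3600L, rpd))))
      value <- clamp(round(level[rep_day] +
                             rnorm(length(rep_day), 0, cfg$report_noise_sd)))
      resp_rows[[u]] <- tibble(user_id = uid,
                               timestamp = SIM_EPOCH0 + (rep_day - 1L) * 86400 + rep_sec,
                               scale_id = "sim", value = as.integer(value))

      truth_users[[u]] <- tibble(user_id = uid, mu = mu_u,
                                 home_x = centers[1L, 1L], home_y = centers[1L, 2L],
                                 work_x = centers[2L, 1L], work_y = centers[2L, 2L])
      truth_days[[u]] <- tibble(user_id = uid, day = seq_len(cfg$n_days),
                                date = as.Date("2024-01-01") + seq_len(cfg$n_days) - 1L,
                                s_raw = as.numeric(s_raw), s_z = s_z,
                                level = level)
    }
  })

  structure(list(
    locations = dplyr::bind_rows(loc_rows),
    responses = dplyr::bind_rows(resp_rows),
    scale = scale_definition("sim", cfg$scale_min, cfg$scale_max,
                             binarize_threshold = mid, positive_is_high = TRUE),
    truth = list(users = dplyr::bind_rows(truth_users),
                 days = dplyr::bind_rows(truth_days),
                 effect_size = cfg$effect_size, seed = cfg$seed),
    config = cfg
  ), class = "ul_cohort")
}

#' @export
print.ul_cohort <- function(x, ...) {
  cat(sprintf("<ul_cohort> %d users x %d days (beta = %g, seed = %d)\n",
              x$config$n_users, x$config$n_days, x$config$effect_size,
              x$config$seed))
  cat(sprintf("  %d GPS samples, %d responses on a %d..%d scale\n",
              nrow(x$locations), nrow(x$responses),
              x$config$scale_min, x$config$scale_max))
  invisible(x)
}

#' Write a cohort to the ingest file formats
#'
#' Emits `locations.csv`, `responses.csv` and `scales.yaml` exactly as the
#' ingest readers expect, plus a `truth.json` sidecar with the simulation
#' ground truth. The CSVs round-trip losslessly through [read_locations()]
#' and [read_responses()].
#'
#' @param cohort an `ul_cohort`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ul_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) ul_abort(paste("cannot create directory:", dir), "userlift_io_error")
  paths <- c(locations = file.path(dir, "locations.csv"),
             responses = file.path(dir, "responses.csv"),
             scales = file.path(dir, "scales.yaml"),
             truth = file.path(dir, "truth.json"))
  readr::write_csv(cohort$locations, paths[["locations"]], progress = FALSE)
  readr::write_csv(cohort$responses, paths[["responses"]], progress = FALSE)
  sc <- cohort$scale
  yaml::write_yaml(list(list(scale_id = sc$scale_id, min = sc$min, max = sc$max,
                             binarize_threshold = sc$binarize_threshold,
                             positive_is_high = sc$positive_is_high)),
                   paths[["scales"]])
  jsonlite::write_json(
    list(users = cohort$truth$users, days = cohort$truth$days,
         effect_size = cohort$truth$effect_size, seed = cohort$truth$seed),
    paths[["truth"]], dataframe = "columns", auto_unbox = TRUE, digits = NA)
  paths
}
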
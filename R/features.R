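#' Canonical daily feature column names
#'
#' The daily location/mobility features, in documentation order. The "AIC and
#' BIC of the mixture on the day's coordinates" item contributes two columns,
#' so the 14 documented features occupy 15 numeric columns.
#'
#' @format Character vector of column names used by
#'   [extract_mobility_features()] and, by default, the modeling functions.
#' @export
UL_FEATURES <- c(
  "frac_not_stationary",   # f1
  "mean_displacement",     # f2, meters per consecutive pair
  "sd_displacement",       # f3
  "log_location_variance", # f4, ln(var_x + var_y + eps)
  "circadian_movement",    # f5, distance of day's cluster fractions to user mean
  "location_entropy",      # f6, nats
  "mec_radius",            # f7, minimum enclosing circle radius, meters
  "frac_home",             # f8
  "frac_work",             # f9
  "frac_night",            # f10
  "gmm_loglik",            # f11
  "gmm_aic",               # f12a
  "gmm_bic",               # f12b
  "n_full_clusters",       # f13
  "n_stat_clusters"        # f14
)

#' Daily location/mobility feature vector
#'
#' Computes the per-day feature vector from one day's planar GPS samples and
#' the user's fitted cluster model. Features (15 columns covering the 14
#' documented quantities; AIC and BIC are reported separately):
#' fraction of the day not stationary; mean and SD of consecutive-pair
#' displacements (pairs more than `pair_gap_max_s` apart are skipped so
#' overnight gaps do not dominate); log location variance
#' `ln(var_x + var_y + eps)`; circadian movement (Euclidean distance between
#' the day's stationary-cluster time-fraction vector and the user's
#' study-long mean fraction vector); location entropy of the day's
#' stationary-cluster fractions (nats); minimum enclosing circle radius;
#' fraction of samples at the home / work (mixture responsibility) and night
#' (nearest stationary centroid) clusters; day log-likelihood, AIC and BIC
#' under the user's full mixture; number of distinct full and stationary
#' clusters visited.
#'
#' @param x,y,timestamp the day's planar samples (meters) and epoch seconds,
#'   time-ordered.
#' @param stationary logical per sample (`TRUE` = stationary).
#' @param full `ul_gmm` for the user; `stationary_model` `ul_kmeans`.
#' @param stationary_model `ul_kmeans` for the user.
#' @param semantic list from [identify_semantic_clusters()].
#' @param user_mean_fracs the user's study-long mean stationary-cluster
#'   fraction vector (length `K_stat`); used by circadian movement. If
#'   `NULL`, circadian movement is `NA` (single-day usage).
#' @param pair_gap_max_s displacement pairs with a larger time gap are
#'   skipped (default 600 s).
#' @param var_eps floor inside the log of the location variance (default
#'   1e-12 m^2).
#' @return Named list of the 15 feature values plus `day_stat_fracs` (the
#'   day's stationary-cluster fraction vector, used to build user means).
#' @export
compute_daily_features <- function(x, y, timestamp, stationary, full,
                                   stationary_model, semantic,
                                   user_mean_fracs = NULL,
                                   pair_gap_max_s = 600, var_eps = 1e-12) {
  n <- length(x)
  if (n < 2L) ul_abort("day has < 2 usable samples", "userlift_contract_error")

  d <- sqrt(diff(x)^2 + diff(y)^2)
  dt <- diff(timestamp)
  use <- dt > 0 & dt <= pair_gap_max_s
  f2 <- if (any(use)) mean(d[use]) else 0
  f3 <- if (sum(use) > 1L) stats::sd(d[use]) else 0

  f4 <- log(stats::var(x) + stats::var(y) + var_eps)

  stat_assign <- assign_stationary(stationary_model, x, y)
  p_stat <- tabulate(stat_assign, nbins = stationary_model$K) / n
  nz <- p_stat > 0
  f6 <- -sum(p_stat[nz] * log(p_stat[nz]))
  f5 <- if (is.null(user_mean_fracs)) NA_real_ else
    sqrt(sum((p_stat - user_mean_fracs)^2))

  gs <- gmm_day_stats(full, x, y)
  p_full <- tabulate(gs$assignment, nbins = full$K) / n

  frac_of <- function(p, id) if (is.na(id)) 0 else p[id]

  out <- list(
    frac_not_stationary   = mean(!stationary),
    mean_displacement     = f2,
    sd_displacement       = f3,
    log_location_variance = f4,
    circadian_movement    = f5,
    location_entropy      = f6,
    mec_radius            = min_enclosing_circle(x, y)$radius,
    frac_home             = frac_of(p_full, semantic$home_id),
    frac_work             = frac_of(p_full, semantic$work_id),
    frac_night            = frac_of(p_stat, semantic$night_id),
    gmm_loglik            = gs$loglik,
    gmm_aic               = gs$aic,
    gmm_bic               = gs$bic,
    n_full_clusters       = sum(p_full > 0),
    n_stat_clusters       = sum(p_stat > 0)
  )
  out$day_stat_fracs <- p_stat
  out
}

#' Per-user cluster models and daily feature table
#'
#' Runs the full mobility-feature stage for a filtered cohort: for each user,
#' projects their trace to a local planar frame about their median
#' coordinate, splits samples into stationary/moving (passing a provided
#' `is_moving` flag through, else thresholding the speed derivative at
#' 1 km/h), fits the full mixture clustering and the stationary K-means
#' clustering, identifies home/work/night clusters, and computes the daily
#' feature vector for every qualifying day.
#'
#' Circadian movement compares each day with the user's study-long mean
#' stationary-cluster fraction vector over qualifying days; by default the
#' featurized day is included in that mean (the literal reading of the
#' definition); set `exclude_current_day = TRUE` for the leakage-free
#' variant.
#'
#' @param locations tibble from [read_locations()] (columns `user_id`,
#'   `timestamp`, `latitude`, `longitude`, optionally `is_moving`).
#' @param day_records tibble from [build_day_records()] /
#'   [filter_participants()]; features are computed for these user-days only.
#' @param max_K cluster cap for both clusterings (default 20).
#' @param tz study timezone for hours and day boundaries (default "UTC").
#' @param seed integer seed for clustering initialisation/restarts.
#' @param exclude_current_day logical; see above.
#' @param speed_threshold_kmh stationary speed threshold (default 1).
#' @param pair_gap_max_s,var_eps passed to [compute_daily_features()].
#' @return List: `features` (tibble `user_id`, `date`, 15 feature columns,
#'   `n_gps_obs`), `models` (per-user list with the fitted `full` and
#'   `stationary` models, semantic cluster ids and projection origin).
#' @export
extract_mobility_features <- function(locations, day_records, max_K = 20,
                                      tz = "UTC", seed = 1,
                                      exclude_current_day = FALSE,
                                      speed_threshold_kmh = 1,
                                      pair_gap_max_s = 600, var_eps = 1e-12) {
  users <- unique(day_records$user_id)
  models <- list()
  rows <- list()
  for (u in users) {
    loc_u <- locations[locations$user_id == u, , drop = FALSE]
    loc_u <- loc_u[order(loc_u$timestamp), , drop = FALSE]
    if (nrow(loc_u) < 2L) next
    pl <- project_to_plane(loc_u$latitude, loc_u$longitude)
    origin <- attr(pl, "origin")
    xs <- pl$x; ys <- pl$y; ts <- loc_u$timestamp
    im <- if ("is_moving" %in% names(loc_u)) loc_u$is_moving else NULL
    stat_flag <- detect_stationary(xs, ys, ts, is_moving = im,
                                   speed_threshold_kmh = speed_threshold_kmh)
    full <- fit_full_clustering(xs, ys, max_K = max_K, seed = seed)
    xs_stat <- xs[stat_flag]; ys_stat <- ys[stat_flag]
    if (length(xs_stat) < 2L) { xs_stat <- xs; ys_stat <- ys }  # all-moving user
    stat_model <- fit_stationary_clustering(xs_stat, ys_stat, max_K = max_K,
                                            seed = seed)
    hour <- as.POSIXlt(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
                       tz = tz)$hour
    semantic <- identify_semantic_clusters(full, stat_model, xs, ys, hour)

    dates_u <- sort(day_records$date[day_records$user_id == u])
    loc_date <- as.Date(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
                        tz = tz)
    day_feats <- list()
    for (d in as.character(dates_u)) {
      sel <- loc_date == as.Date(d)
      if (sum(sel) < 2L) next                    # dropped and logged below
      day_feats[[d]] <- compute_daily_features(
        xs[sel], ys[sel], ts[sel], stat_flag[sel], full, stat_model, semantic,
        user_mean_fracs = NULL, pair_gap_max_s = pair_gap_max_s,
        var_eps = var_eps)
      day_feats[[d]]$n_gps_obs <- sum(sel)
    }
    if (!length(day_feats)) next
    frac_mat <- do.call(rbind, lapply(day_feats, `[[`, "day_stat_fracs"))
    mean_fracs <- colMeans(frac_mat)
    for (d in names(day_feats)) {
      mf <- if (exclude_current_day && nrow(frac_mat) > 1L) {
        colMeans(frac_mat[rownames(frac_mat) != d, , drop = FALSE])
      } else mean_fracs
      day_feats[[d]]$circadian_movement <-
        sqrt(sum((day_feats[[d]]$day_stat_fracs - mf)^2))
    }
    n_dropped <- length(dates_u) - length(day_feats)
    if (n_dropped > 0L) {
      inform(sprintf("user %s: %d qualifying day(s) had < 2 usable GPS samples and were dropped",
                     u, n_dropped))
    }
    feat_mat <- t(vapply(day_feats, function(f)
      c(unlist(f[UL_FEATURES], use.names = FALSE), f$n_gps_obs),
      numeric(length(UL_FEATURES) + 1L)))
    colnames(feat_mat) <- c(UL_FEATURES, "n_gps_obs")
    rows[[u]] <- dplyr::bind_cols(
      tibble(user_id = u, date = as.Date(names(day_feats))),
      as_tibble(feat_mat))
    models[[u]] <- list(user_id = u, full = full, stationary = stat_model,
                        semantic = semantic, origin = origin)
  }
  if (!length(rows)) ul_abort("no users had usable GPS data", "userlift_empty_cohort_error")
  list(features = dplyr::bind_rows(rows), models = models)
}
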
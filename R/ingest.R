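#' Define a Likert scale and its binarization
#'
#' @param scale_id string identifying the scale (matches `scale_id` in the
#'   responses table).
#' @param min,max integer scale bounds (`min < max`).
#' @param binarize_threshold daily-average threshold separating the two
#'   states. A daily mean exactly at the threshold counts as the positive
#'   (stressed/happy) class.
#' @param positive_is_high `TRUE` if values at or above the threshold are the
#'   positive class (the usual orientation), `FALSE` for reversed scales.
#' @return List of class `ul_scale`.
#' @export
scale_definition <- function(scale_id, min, max, binarize_threshold,
                             positive_is_high = TRUE) {
  min <- check_count(min, "min", min = -1000L)
  max <- check_count(max, "max", min = -1000L)
  if (min >= max) ul_abort("scale min must be < max", "userlift_config_error")
  thr <- check_number(binarize_threshold, "binarize_threshold")
  if (thr <= min || thr > max) {
    ul_abort("binarize_threshold must satisfy min < threshold <= max",
             "userlift_config_error")
  }
  structure(list(scale_id = as.character(scale_id), min = min, max = max,
                 binarize_threshold = thr,
                 positive_is_high = isTRUE(positive_is_high)),
            class = "ul_scale")
}

#' Read scale definitions from YAML
#'
#' The file holds a list of entries with fields `scale_id`, `min`, `max`,
#' `binarize_threshold`, `positive_is_high`.
#'
#' @param path path to `scales.yaml`.
#' @return Named list of `ul_scale` objects, keyed by `scale_id`.
#' @export
read_scales <- function(path) {
  if (!file.exists(path)) ul_abort(paste("no such file:", path), "userlift_io_error")
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || !length(raw)) {
    ul_abort("scales.yaml must contain a non-empty list of scale entries",
             "userlift_schema_error")
  }
  scales <- lapply(raw, function(e) {
    need <- c("scale_id", "min", "max", "binarize_threshold")
    missing <- setdiff(need, names(e))
    if (length(missing)) {
      ul_abort(paste("scale entry missing field(s):",
                     paste(missing, collapse = ", ")), "userlift_schema_error")
    }
    scale_definition(e$scale_id, e$min, e$max, e$binarize_threshold,
                     e$positive_is_high %||% TRUE)
  })
  stats::setNames(scales, vapply(scales, `[[`, "", "scale_id"))
}

ul_read_csv <- function(path, required, col_types) {
  if (!file.exists(path)) ul_abort(paste("no such file:", path), "userlift_io_error")
  # readr's own parse warnings are replaced by this module's schema errors
  # and malformed-row accounting
  tab <- suppressWarnings(readr::read_csv(path, col_types = col_types,
                                          progress = FALSE))
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    ul_abort(sprintf("%s: missing required column(s): %s", path,
                     paste(missing, collapse = ", ")), "userlift_schema_error")
  }
  tab
}

#' Read a GPS location table
#'
#' Schema: `user_id,timestamp,latitude,longitude[,is_moving]` with timestamps
#' as integer UTC epoch seconds and `is_moving` an optional 0/1 column. Rows
#' that fail to parse are dropped with a warning naming the count; rows with
#' out-of-range coordinates raise a validation error naming the first bad
#' row. Output is sorted by (user, timestamp).
#'
#' @param path path to `locations.csv`.
#' @return Tibble `user_id`, `timestamp`, `latitude`, `longitude` and, when
#'   present in the file, `is_moving` (logical). Attribute `n_malformed`
#'   counts dropped rows.
#' @export
read_locations <- function(path) {
  tab <- ul_read_csv(path, c("user_id", "timestamp", "latitude", "longitude"),
                     readr::cols(user_id = readr::col_character(),
                                 timestamp = readr::col_double(),
                                 latitude = readr::col_double(),
                                 longitude = readr::col_double(),
                                 .default = readr::col_double()))
  core <- c("user_id", "timestamp", "latitude", "longitude")
  ok <- stats::complete.cases(tab[core])
  n_malformed <- sum(!ok)
  if (n_malformed) {
    warn(sprintf("%s: dropped %d malformed row(s)", path, n_malformed))
    tab <- tab[ok, , drop = FALSE]
  }
  bad <- which(abs(tab$latitude) > 90 | abs(tab$longitude) > 180)
  if (length(bad)) {
    ul_abort(sprintf("%s: coordinate out of range at data row %d", path, bad[1L]),
             "userlift_validation_error")
  }
  if ("is_moving" %in% names(tab)) tab$is_moving <- as.logical(tab$is_moving)
  tab <- dplyr::arrange(tab, .data$user_id, .data$timestamp)
  attr(tab, "n_malformed") <- n_malformed
  tab
}

#' Read a self-report response table
#'
#' Schema: `user_id,timestamp,scale_id,value`. Values must lie within the
#' declared scale bounds; a violation raises a validation error naming the
#' first offending row. Output is sorted by (user, timestamp).
#'
#' @param path path to `responses.csv`.
#' @param scale an `ul_scale` from [scale_definition()]; only rows with this
#'   `scale_id` are returned.
#' @return Tibble `user_id`, `timestamp`, `scale_id`, `value` (integer).
#'   Attribute `n_malformed` counts dropped unparseable rows.
#' @export
read_responses <- function(path, scale) {
  stopifnot(inherits(scale, "ul_scale"))
  tab <- ul_read_csv(path, c("user_id", "timestamp", "scale_id", "value"),
                     readr::cols(user_id = readr::col_character(),
                                 timestamp = readr::col_double(),
                                 scale_id = readr::col_character(),
                                 value = readr::col_double()))
  ok <- stats::complete.cases(tab[c("user_id", "timestamp", "value")])
  n_malformed <- sum(!ok)
  if (n_malformed) {
    warn(sprintf("%s: dropped %d malformed row(s)", path, n_malformed))
    tab <- tab[ok, , drop = FALSE]
  }
  tab <- tab[tab$scale_id == scale$scale_id, , drop = FALSE]
  bad <- which(tab$value < scale$min | tab$value > scale$max)
  if (length(bad)) {
    ul_abort(sprintf("%s: value outside scale [%d, %d] at data row %d",
                     path, scale$min, scale$max, bad[1L]),
             "userlift_validation_error")
  }
  tab$value <- as.integer(tab$value)
  tab <- dplyr::arrange(tab, .data$user_id, .data$timestamp)
  attr(tab, "n_malformed") <- n_malformed
  tab
}

#' Build per-user per-day labeled records
#'
#' Averages all of a user's same-day responses into a daily level, binarizes
#' it against the scale's threshold (a mean exactly at the threshold is the
#' positive class), and counts the day's GPS observations. Days with no
#' response produce no row. Day boundaries are local civil midnight in the
#' study timezone.
#'
#' @param responses tibble from [read_responses()].
#' @param locations tibble from [read_locations()] (may be `NULL`: then
#'   `n_gps_obs` is 0).
#' @param scale an `ul_scale`.
#' @param tz study timezone (default "UTC").
#' @return Tibble `user_id`, `date`, `label_level`, `label_binary`,
#'   `n_responses`, `n_gps_obs`.
#' @export
build_day_records <- function(responses, locations, scale, tz = "UTC") {
  stopifnot(inherits(scale, "ul_scale"))
  to_date <- function(ts) as.Date(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"), tz = tz)
  resp <- dplyr::mutate(responses, date = to_date(.data$timestamp))
  days <- dplyr::summarise(
    dplyr::group_by(resp, .data$user_id, .data$date),
    label_level = mean(.data$value),
    n_responses = dplyr::n(),
    .groups = "drop"
  )
  days$label_binary <- if (scale$positive_is_high) {
    days$label_level >= scale$binarize_threshold
  } else {
    days$label_level <= scale$binarize_threshold
  }
  if (!is.null(locations) && nrow(locations)) {
    loc <- dplyr::mutate(locations, date = to_date(.data$timestamp))
    gps <- dplyr::count(loc, .data$user_id, .data$date, name = "n_gps_obs")
    days <- dplyr::left_join(days, gps, by = c("user_id", "date"))
    days$n_gps_obs[is.na(days$n_gps_obs)] <- 0L
  } else {
    days$n_gps_obs <- 0L
  }
  dplyr::arrange(
    days[, c("user_id", "date", "label_level", "label_binary", "n_responses",
             "n_gps_obs")],
    .data$user_id, .data$date)
}

#' Apply the participant-inclusion filters
#'
#' A day qualifies when it has a label and at least `min_gps_obs` GPS
#' observations; a user is retained when they have at least `min_days`
#' qualifying days. Only qualifying days of retained users are passed
#' downstream.
#'
#' @param day_records tibble from [build_day_records()].
#' @param min_days minimum qualifying days per retained user (default 30).
#' @param min_gps_obs minimum GPS observations per qualifying day
#'   (default 35).
#' @return The filtered day-record tibble. Attribute `retained_users` lists
#'   the retained user ids.
#' @export
filter_participants <- function(day_records, min_days = 30, min_gps_obs = 35) {
  qual <- day_records[!is.na(day_records$label_level) &
                        day_records$n_gps_obs >= min_gps_obs, , drop = FALSE]
  counts <- table(qual$user_id)
  keep <- names(counts)[counts >= min_days]
  if (!length(keep)) {
    ul_abort(sprintf("no users meet the inclusion filter (>= %d days with a label and >= %d GPS observations)",
                     min_days, min_gps_obs), "userlift_empty_cohort_error")
  }
  out <- qual[qual$user_id %in% keep, , drop = FALSE]
  attr(out, "retained_users") <- keep
  out
}
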
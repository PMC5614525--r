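#' Classify GPS samples as stationary or moving
#'
#' Approximates movement speed at each observation by the time derivative of
#' position between consecutive samples and thresholds it at about 1 km/h,
#' the convention used for splitting traces into stationary dwells and
#' movement. When the source dataset already provides a moving/stationary
#' flag (as some sensing platforms do), that flag is passed through untouched.
#'
#' @param x,y planar coordinates in meters, ordered by time within one user.
#' @param timestamp epoch seconds, non-decreasing.
#' @param is_moving optional logical/0-1 vector; if supplied (any non-NA) it
#'   is returned as the stationary complement without recomputation.
#' @param speed_threshold_kmh speed below which a sample is stationary
#'   (default 1 km/h).
#' @return Logical vector, `TRUE` = stationary. Attribute `n_anomalies`
#'   counts samples with zero time difference but distinct coordinates
#'   (undefined speed); these are flagged moving.
#' @export
detect_stationary <- function(x, y, timestamp, is_moving = NULL,
                              speed_threshold_kmh = 1) {
  n <- length(x)
  if (!is.null(is_moving) && any(!is.na(is_moving))) {
    out <- !as.logical(is_moving)
    attr(out, "n_anomalies") <- 0L
    return(out)
  }
  if (n < 2L) {
    ul_abort("need >= 2 samples to estimate speed", "userlift_contract_error")
  }
  d <- sqrt(diff(x)^2 + diff(y)^2)           # meters
  dt <- diff(timestamp)                      # seconds
  speed_kmh <- rep(NA_real_, n - 1L)
  ok <- dt > 0
  speed_kmh[ok] <- (d[ok] / 1000) / (dt[ok] / 3600)
  anomaly <- !ok & d > 0                     # dt == 0 but moved: undefined
  speed_kmh[!ok & d == 0] <- 0               # duplicate sample: stationary
  stationary_at <- speed_kmh < speed_threshold_kmh
  stationary_at[anomaly] <- FALSE
  out <- c(stationary_at[1L], stationary_at)  # first sample inherits second's state
  attr(out, "n_anomalies") <- sum(anomaly)
  out
}
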
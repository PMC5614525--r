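# Shared fixtures, built in code. Small cohorts are cached per option set so
# several test files can reuse them without regenerating.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, force(expr), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

tiny_config <- function(seed = 42, beta = 0, n_users = 6, n_days = 30, ...) {
  cohort_config(n_users = n_users, n_days = n_days, gps_obs_per_day = 35,
                effect_size = beta, seed = seed, ...)
}

tiny_cohort <- function(seed = 42, beta = 0, ...) {
  cached(paste0("cohort_", seed, "_", beta),
         generate_cohort(tiny_config(seed = seed, beta = beta, ...)))
}

# filtered day records for a tiny cohort
tiny_days <- function(seed = 42, beta = 0) {
  co <- tiny_cohort(seed, beta)
  cached(paste0("days_", seed, "_", beta),
         filter_participants(build_day_records(co$responses, co$locations,
                                               co$scale)))
}

# features joined onto day records (the model frame)
tiny_model_frame <- function(seed = 42, beta = 0, max_K = 6) {
  co <- tiny_cohort(seed, beta)
  days <- tiny_days(seed, beta)
  cached(paste0("frame_", seed, "_", beta, "_", max_K), {
    fe <- suppressMessages(extract_mobility_features(co$locations, days,
                                                     max_K = max_K,
                                                     seed = seed))
    dplyr::inner_join(days, fe$features, by = c("user_id", "date"))
  })
}

# labels-only model frame with pure-noise features: day records from a real
# cohort, features that carry no signal (for modeling-behaviour tests that do
# not need the GPS stage)
noise_frame <- function(seed = 42, beta = 0, n_users = 4, n_features = 5) {
  co <- generate_cohort(tiny_config(seed = seed, beta = beta,
                                    n_users = n_users))
  days <- filter_participants(build_day_records(co$responses, co$locations,
                                                co$scale))
  feats <- withr::with_seed(seed, matrix(rnorm(nrow(days) * n_features),
                                         nrow(days)))
  colnames(feats) <- paste0("noise", seq_len(n_features))
  dplyr::bind_cols(days, tibble::as_tibble(feats))
}

# Independent brute-force oracle for the minimum enclosing circle: test every
# pair-diameter circle and every triple circumcircle against all points (no
# hull reduction), plus the single-point case.
mec_brute_oracle <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(0)
  best <- Inf
  covers <- function(cx, cy, r) all(sqrt((x - cx)^2 + (y - cy)^2) <= r * (1 + 1e-9) + 1e-12)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    cx <- (x[i] + x[j]) / 2; cy <- (y[i] + y[j]) / 2
    r <- sqrt((x[i] - cx)^2 + (y[i] - cy)^2)
    if (r < best && covers(cx, cy, r)) best <- r
  }
  if (n >= 3L) {
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (i >= j || j >= k) next
      ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx0 <- x[k]; cy0 <- y[k]
      d <- 2 * (ax * (by - cy0) + bx * (cy0 - ay) + cx0 * (ay - by))
      if (abs(d) < 1e-12) next
      a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx0^2 + cy0^2
      ux <- (a2 * (by - cy0) + b2 * (cy0 - ay) + c2 * (ay - by)) / d
      uy <- (a2 * (cx0 - bx) + b2 * (ax - cx0) + c2 * (bx - ax)) / d
      r <- sqrt((ax - ux)^2 + (ay - uy)^2)
      if (r < best && covers(ux, uy, r)) best <- r
    }
  }
  best
}

# Independent exact sign-flip p-value by full enumeration (n small).
perm_p_naive <- function(lifts) {
  n <- length(lifts)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  means <- as.numeric(signs %*% lifts) / n
  mean(means >= mean(lifts) - 1e-12)
}
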
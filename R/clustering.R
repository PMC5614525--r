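#' Fit the full location clustering (Gaussian mixture, BIC-selected order)
#'
#' Fits diagonal-covariance Gaussian mixtures with 1 to `max_K` components to
#' all of one user's planar location samples and keeps the order that
#' minimizes BIC (ties broken toward fewer components). A user is assumed to
#' frequent at most twenty locations over a study, hence the default cap.
#'
#' Fitting is delegated to \pkg{mclust} (model "VVI": diagonal, per-component
#' variances) with its deterministic model-based hierarchical initialisation;
#' for large traces the initialisation runs on a seeded subsample. Degenerate
#' input (all samples at one point) yields a single component with a floored
#' covariance.
#'
#' @param x,y planar coordinates (meters) of all of one user's samples.
#' @param max_K maximum number of mixture components (default 20). With fewer
#'   than 20 samples the search is capped at `floor(n/2)`.
#' @param seed integer; seeds the initialisation subsample.
#' @param init_subset_size initialisation subsample size for large traces.
#' @return List of class `ul_gmm`: `K`, `weights`, `means` (K x 2), `vars`
#'   (K x 2 diagonal variances), `bic` (named vector of standard BIC, lower
#'   better, over the orders tried), `n`.
#' @export
fit_full_clustering <- function(x, y, max_K = 20, seed = 1,
                                init_subset_size = 300) {
  X <- cbind(x = x, y = y)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 2L) ul_abort("need >= 2 location samples to cluster", "userlift_contract_error")
  k_cap <- if (n >= 20L) max_K else max(1L, n %/% 2L)
  k_cap <- max(1L, min(max_K, k_cap))
  spread <- max(stats::sd(X[, 1L]), stats::sd(X[, 2L]), na.rm = TRUE)
  if (!is.finite(spread) || spread < 1e-6) {
    return(degenerate_gmm(X, n))
  }
  init <- NULL
  if (n > init_subset_size) {
    sub <- withr::with_seed(seed, sample.int(n, init_subset_size))
    init <- list(subset = sub)
  }
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(X, G = seq_len(k_cap), modelNames = "VVI",
                                    verbose = FALSE, initialization = init)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(degenerate_gmm(X, n))
  # mclust maximizes 2*loglik - m*log(n); convert to standard (minimized) BIC
  # and re-select so exact ties go to the smallest order.
  bic_tab <- -as.numeric(fit$BIC[, "VVI"])
  names(bic_tab) <- rownames(fit$BIC)
  ok <- which(is.finite(bic_tab))
  if (!length(ok)) return(degenerate_gmm(X, n))
  k_best <- as.integer(names(bic_tab)[ok[which.min(bic_tab[ok])]])
  if (k_best != fit$G) {
    fit <- suppressWarnings(mclust::Mclust(X, G = k_best, modelNames = "VVI",
                                           verbose = FALSE, initialization = init))
  }
  p <- fit$parameters
  K <- fit$G
  vars <- t(vapply(seq_len(K), function(k) diag(p$variance$sigma[, , k]),
                   numeric(2L)))
  structure(list(
    K = K,
    weights = as.numeric(p$pro),
    means = t(p$mean),                       # K x 2
    vars = pmax(matrix(vars, nrow = K), 1e-8),
    bic = bic_tab,
    n = n
  ), class = "ul_gmm")
}

degenerate_gmm <- function(X, n) {
  structure(list(
    K = 1L,
    weights = 1,
    means = matrix(colMeans(X), nrow = 1L),
    vars = matrix(pmax(c(stats::var(X[, 1L]), stats::var(X[, 2L])), 1e-4),
                  nrow = 1L),
    bic = c(`1` = NA_real_),
    n = n
  ), class = "ul_gmm")
}

#' @export
print.ul_gmm <- function(x, ...) {
  cat(sprintf("<ul_gmm> %d component(s) fitted to %d samples (diagonal covariances)\n",
              x$K, x$n))
  invisible(x)
}

# Per-sample log density matrix (n x K) under a diagonal GMM.
gmm_log_component_density <- function(model, x, y) {
  K <- model$K
  out <- matrix(NA_real_, length(x), K)
  for (k in seq_len(K)) {
    out[, k] <- log(model$weights[k]) +
      stats::dnorm(x, model$means[k, 1L], sqrt(model$vars[k, 1L]), log = TRUE) +
      stats::dnorm(y, model$means[k, 2L], sqrt(model$vars[k, 2L]), log = TRUE)
  }
  out
}

#' Evaluate a day's samples under a user's full mixture model
#'
#' Computes the total log-likelihood of the day's coordinates under the
#' study-long mixture, the corresponding AIC/BIC (free-parameter count
#' m = (K-1) weights + 2K means + 2K diagonal variances = 5K - 1), and the
#' maximum-responsibility component assignment of each sample.
#'
#' @param model an `ul_gmm` from [fit_full_clustering()].
#' @param x,y the day's planar coordinates.
#' @return List: `loglik`, `aic`, `bic`, `assignment` (component index per
#'   sample), `m` (parameter count).
#' @export
gmm_day_stats <- function(model, x, y) {
  lc <- gmm_log_component_density(model, x, y)
  rowmax <- apply(lc, 1L, max)
  ll_rows <- rowmax + log(rowSums(exp(lc - rowmax)))   # log-sum-exp
  ll <- sum(ll_rows)
  m <- 5L * model$K - 1L
  n <- length(x)
  list(
    loglik = ll,
    aic = 2 * m - 2 * ll,
    bic = m * log(n) - 2 * ll,
    assignment = max.col(lc, ties.method = "first"),
    m = m
  )
}

#' Fit the stationary clustering (K-means, BIC-selected K)
#'
#' K-means over a user's stationary samples only, with the number of clusters
#' selected by BIC under a spherical-Gaussian reading of the K-means solution
#' (shared variance `WSS / (d * (n - K))`, free parameters
#' `(K - 1) + K * d + 1`), mirroring the BIC selection of the full
#' clustering. Ties break toward fewer clusters.
#'
#' @param x,y planar coordinates of the user's stationary samples.
#' @param max_K maximum K (default 20; also capped by the number of distinct
#'   points).
#' @param seed integer seed for the K-means restarts.
#' @param nstart random restarts per K.
#' @return List of class `ul_kmeans`: `K`, `centers` (K x 2), `bic` (named,
#'   lower better), `n`.
#' @export
fit_stationary_clustering <- function(x, y, max_K = 20, seed = 1, nstart = 5) {
  X <- cbind(x = x, y = y)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 1L) ul_abort("need >= 1 stationary sample", "userlift_contract_error")
  n_distinct <- nrow(unique(X))
  k_cap <- max(1L, min(max_K, n_distinct))
  d <- 2
  fits <- vector("list", k_cap)
  bic <- rep(NA_real_, k_cap)
  withr::with_seed(seed, {
    for (K in seq_len(k_cap)) {
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = K, nstart = nstart,
                                       iter.max = 50)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      wss <- sum(fit$withinss)
      sigma2 <- if (n > K) max(wss / (d * (n - K)), 1e-8) else 1e-8
      nk <- fit$size
      ll <- sum(nk * log(nk / n)) - n * d / 2 * log(2 * pi * sigma2) -
        d * (n - K) / 2
      m <- (K - 1) + K * d + 1
      bic[K] <- m * log(n) - 2 * ll
      fits[[K]] <- fit
    }
  })
  ok <- which(is.finite(bic))
  if (!length(ok)) {                      # all K-means failed: single center
    return(structure(list(K = 1L, centers = matrix(colMeans(X), nrow = 1L),
                          bic = c(`1` = NA_real_), n = n),
                     class = "ul_kmeans"))
  }
  k_best <- ok[which.min(bic[ok])]
  structure(list(
    K = as.integer(k_best),
    centers = matrix(fits[[k_best]]$centers, ncol = 2L,
                     dimnames = list(NULL, c("x", "y"))),
    bic = stats::setNames(bic[seq_len(k_cap)], seq_len(k_cap)),
    n = n
  ), class = "ul_kmeans")
}

#' @export
print.ul_kmeans <- function(x, ...) {
  cat(sprintf("<ul_kmeans> %d stationary cluster(s) from %d samples\n", x$K, x$n))
  invisible(x)
}

# Nearest stationary centroid per sample.
assign_stationary <- function(model, x, y) {
  d2 <- outer(x, model$centers[, 1L], "-")^2 + outer(y, model$centers[, 2L], "-")^2
  max.col(-d2, ties.method = "first")
}

#' Identify home, work and night clusters
#'
#' Home is the full-mixture component where the user spends the most time in
#' the evening hours (11pm-6am), work the component with the most time in
#' working hours (11am-4pm), and the night cluster is the stationary cluster
#' with the most time between midnight and 6am. Dwell time is measured in
#' sample counts (the pipeline does not interpolate traces to regular
#' sampling, so counts are the natural dwell weight).
#'
#' @param full an `ul_gmm`; `stationary` an `ul_kmeans`.
#' @param stationary an `ul_kmeans` model.
#' @param x,y all of the user's planar samples (same order as `hour`).
#' @param hour local hour-of-day (0-23) of each sample.
#' @return List: `home_id`, `work_id` (full-mixture component indices),
#'   `night_id` (stationary cluster index); `NA` where a window has no
#'   samples.
#' @export
identify_semantic_clusters <- function(full, stationary, x, y, hour) {
  full_assign <- gmm_day_stats(full, x, y)$assignment
  stat_assign <- assign_stationary(stationary, x, y)
  window_mode <- function(assign, in_window, K) {
    if (!any(in_window)) return(NA_integer_)
    counts <- tabulate(assign[in_window], nbins = K)
    which.max(counts)          # first max: deterministic tie-break
  }
  list(
    home_id  = window_mode(full_assign, hour >= 23 | hour < 6, full$K),
    work_id  = window_mode(full_assign, hour >= 11 & hour < 16, full$K),
    night_id = window_mode(stat_assign, hour < 6, stationary$K)
  )
}
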
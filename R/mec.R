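#' Exact minimum enclosing circle
#'
#' Radius (and center) of the smallest circle containing a set of planar
#' points. The minimum enclosing circle is determined by at most three points
#' of the convex hull: the implementation reduces to the hull, enumerates all
#' circles through two hull points (as a diameter) and all circumcircles of
#' hull triples, and returns the smallest candidate that contains every hull
#' point. This is exact and, after the hull reduction, fast enough for daily
#' GPS traces.
#'
#' @param x,y numeric coordinates (meters).
#' @return List with `radius`, `center` (length-2). Zero or one point gives
#'   radius 0.
#' @export
min_enclosing_circle <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n == 0L) return(list(radius = 0, center = c(NA_real_, NA_real_)))
  if (n == 1L) return(list(radius = 0, center = c(x, y)))
  pts <- unique(cbind(x, y))
  if (nrow(pts) == 1L) return(list(radius = 0, center = as.numeric(pts[1L, ])))
  hull <- if (nrow(pts) > 2L) {
    h <- tryCatch(grDevices::chull(pts[, 1L], pts[, 2L]), error = function(e) NULL)
    if (is.null(h) || length(h) < 2L) pts else pts[h, , drop = FALSE]
  } else pts
  mec_candidates(hull[, 1L], hull[, 2L])
}

# Enumerate candidate circles over points (assumed already hull-reduced) and
# return the smallest that contains all of them. Containment is checked with
# a relative tolerance so circumcircles through the defining points pass.
mec_candidates <- function(x, y) {
  n <- length(x)
  scale <- max(abs(x), abs(y), 1)
  tol <- 1e-9 * scale
  best_r <- Inf; best_c <- c(NA_real_, NA_real_)
  contains_all <- function(cx, cy, r) {
    max(sqrt((x - cx)^2 + (y - cy)^2)) <= r + tol
  }
  consider <- function(cx, cy, r) {
    if (r < best_r && contains_all(cx, cy, r)) {
      best_r <<- r; best_c <<- c(cx, cy)
    }
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      cx <- (x[i] + x[j]) / 2; cy <- (y[i] + y[j]) / 2
      consider(cx, cy, sqrt((x[i] - cx)^2 + (y[i] - cy)^2))
    }
  }
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      for (j in seq.int(i + 1L, n - 1L)) {
        for (k in seq.int(j + 1L, n)) {
          cc <- circumcircle(x[c(i, j, k)], y[c(i, j, k)])
          if (!is.null(cc)) consider(cc$center[1L], cc$center[2L], cc$radius)
        }
      }
    }
  }
  list(radius = best_r, center = best_c)
}

# Circumcircle of three points; NULL when (near-)collinear, in which case the
# diameter candidates already cover the configuration.
circumcircle <- function(x, y) {
  ax <- x[1L]; ay <- y[1L]; bx <- x[2L]; by <- y[2L]; cx <- x[3L]; cy <- y[3L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  span2 <- max((bx - ax)^2 + (by - ay)^2, (cx - ax)^2 + (cy - ay)^2,
               (cx - bx)^2 + (cy - by)^2)
  if (abs(d) < 1e-12 * max(span2, 1)) return(NULL)
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}
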
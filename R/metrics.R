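# Registration quality metrics: average perpendicular distance (mean
# nearest-point distance) and the Dice overlap of contour-enclosed areas.

#' Average perpendicular distance between point sets
#'
#' Directed APD: the mean over points of `mapped` of the minimum distance to
#' any point of `truth`. `symmetric = TRUE` averages both directions.
#' `to_segments = TRUE` measures distance to the segments of the truth
#' polyline (closed ring) instead of to its vertices.
#'
#' @param mapped n x 2 matrix (or contour) of evaluated points.
#' @param truth n x 2 matrix (or contour) of reference points.
#' @param symmetric average the two directed distances.
#' @param to_segments use point-to-segment distances on the truth ring.
#' @return scalar APD in the input length units.
#' @export
apd <- function(mapped, truth, symmetric = FALSE, to_segments = FALSE) {
  A <- if (inherits(mapped, "ssd_contour")) mapped$points else as_points_matrix(mapped)
  B <- if (inherits(truth, "ssd_contour")) truth$points else as_points_matrix(truth)
  if (!nrow(A) || !nrow(B)) stop("empty point set")
  fwd <- if (to_segments) mean(point_segment_dists(A, B))
         else mean(sqrt(apply(cross_sqdist(A, B), 1L, min)))
  if (!symmetric) return(fwd)
  rev <- if (to_segments) mean(point_segment_dists(B, A))
         else mean(sqrt(apply(cross_sqdist(B, A), 1L, min)))
  (fwd + rev) / 2
}

# min distance from each row of P to the closed polyline through rows of V
point_segment_dists <- function(P, V) {
  Vn <- rbind(V, V[1L, ])
  a <- Vn[-nrow(Vn), , drop = FALSE]
  d <- Vn[-1L, , drop = FALSE] - a
  len2 <- rowSums(d^2)
  vapply(seq_len(nrow(P)), function(k) {
    w <- sweep(a, 2L, P[k, ], "-")
    t <- pmin(pmax(-rowSums(w * d) / pmax(len2, .Machine$double.eps), 0), 1)
    sqrt(min(rowSums((w + t * d)^2)))
  }, 0)
}

#' Dice metric of two closed contours
#'
#' `DM = 2 S3 / (S1 + S2)` where S1, S2 are the polygon areas enclosed by the
#' contours and S3 their intersection area. Intersection is computed by
#' Sutherland-Hodgman clipping when either ring is convex (exact in that
#' case); for two non-convex rings a dense midpoint-grid estimate is used.
#'
#' @param contourA,contourB closed [contour()]s (or n x 2 matrices, taken as
#'   closed rings).
#' @return scalar in [0, 1].
#' @export
dice_metric <- function(contourA, contourB) {
  A <- polygon_ring(contourA)
  B <- polygon_ring(contourB)
  S1 <- abs(polygon_area(A))
  S2 <- abs(polygon_area(B))
  if (S1 == 0 || S2 == 0) stop("degenerate contour: zero enclosed area")
  S3 <- polygon_intersection_area(A, B)
  2 * S3 / (S1 + S2)
}

polygon_ring <- function(x) {
  P <- if (inherits(x, "ssd_contour")) {
    if (!x$closed) stop("dice_metric requires closed contours")
    x$points
  } else as_points_matrix(x)
  # cleanup pass: drop consecutive duplicates (simple repair)
  keep <- c(TRUE, rowSums(abs(diff(P))) > 0)
  P <- P[keep, , drop = FALSE]
  if (sum(abs(P[1L, ] - P[nrow(P), ])) == 0) P <- P[-nrow(P), , drop = FALSE]
  if (nrow(P) < 3L) stop("degenerate polygon after cleanup")
  if (polygon_area(P) < 0) P <- P[nrow(P):1L, , drop = FALSE]  # force CCW
  P
}

polygon_area <- function(P) {
  x <- P[, 1L]; y <- P[, 2L]
  j <- c(seq_len(nrow(P))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_is_convex <- function(P, rel_tol = 1e-9) {
  n <- nrow(P)
  nxt <- c(2:n, 1L)
  e <- P[nxt, , drop = FALSE] - P
  cr <- e[, 1L] * e[nxt, 2L] - e[, 2L] * e[nxt, 1L]
  scale <- max(abs(cr), .Machine$double.eps)
  all(cr >= -rel_tol * scale)
}

# Sutherland-Hodgman: clip subject polygon by a convex CCW clip polygon
clip_polygon_convex <- function(subject, clip) {
  n <- nrow(clip)
  out <- subject
  for (k in seq_len(n)) {
    if (nrow(out) < 3L) return(out[0L, , drop = FALSE])
    a <- clip[k, ]
    b <- clip[if (k == n) 1L else k + 1L, ]
    ex <- b[1L] - a[1L]; ey <- b[2L] - a[2L]
    side <- ex * (out[, 2L] - a[2L]) - ey * (out[, 1L] - a[1L])  # >=0 inside
    m <- nrow(out)
    nxt <- c(2:m, 1L)
    res <- matrix(0, 0L, 2L)
    for (v in seq_len(m)) {
      w <- nxt[v]
      cur_in <- side[v] >= 0
      nxt_in <- side[w] >= 0
      if (cur_in) res <- rbind(res, out[v, ])
      if (xor(cur_in, nxt_in)) {
        t <- side[v] / (side[v] - side[w])
        res <- rbind(res, out[v, ] + t * (out[w, ] - out[v, ]))
      }
    }
    out <- res
  }
  out
}

polygon_intersection_area <- function(A, B, grid_n = 700L) {
  # bbox shortcut
  if (max(A[, 1L]) <= min(B[, 1L]) || max(B[, 1L]) <= min(A[, 1L]) ||
      max(A[, 2L]) <= min(B[, 2L]) || max(B[, 2L]) <= min(A[, 2L]))
    return(0)
  if (polygon_is_convex(B)) {
    P <- clip_polygon_convex(A, B)
    if (nrow(P) < 3L) return(0)
    return(abs(polygon_area(P)))
  }
  if (polygon_is_convex(A)) {
    P <- clip_polygon_convex(B, A)
    if (nrow(P) < 3L) return(0)
    return(abs(polygon_area(P)))
  }
  # both non-convex: midpoint-grid estimate over the bbox overlap
  lo <- pmax(apply(A, 2L, min), apply(B, 2L, min))
  hi <- pmin(apply(A, 2L, max), apply(B, 2L, max))
  gx <- seq(lo[1L], hi[1L], length.out = grid_n + 1L)
  gy <- seq(lo[2L], hi[2L], length.out = grid_n + 1L)
  cx <- (gx[-1L] + gx[-length(gx)]) / 2
  cy <- (gy[-1L] + gy[-length(gy)]) / 2
  pts <- cbind(rep(cx, times = grid_n), rep(cy, each = grid_n))
  inside <- point_in_polygon(pts, A) & point_in_polygon(pts, B)
  mean(inside) * prod(hi - lo)
}

# even-odd rule, vectorized over query points
point_in_polygon <- function(pts, P) {
  n <- nrow(P)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- P[i, 1L]; yi <- P[i, 2L]
    xj <- P[j, 1L]; yj <- P[j, 2L]
    crosses <- ((yi > pts[, 2L]) != (yj > pts[, 2L])) &
      (pts[, 1L] < (xj - xi) * (pts[, 2L] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Registration metrics for a result
#'
#' Convenience wrapper reporting forward, reverse and symmetric APD (and the
#' Dice metric when single closed contours are supplied).
#'
#' @param mapped mapped model points (matrix or contour).
#' @param truth scene/ground-truth points (matrix or contour).
#' @param dice compute the Dice metric (both inputs must be closed rings).
#' @return list with `apd_forward`, `apd_reverse`, `apd_symmetric`, and
#'   optionally `dm`.
#' @export
registration_metrics <- function(mapped, truth, dice = FALSE) {
  out <- list(apd_forward = apd(mapped, truth),
              apd_reverse = apd(truth, mapped))
  out$apd_symmetric <- (out$apd_forward + out$apd_reverse) / 2
  if (dice) out$dm <- dice_metric(mapped, truth)
  out
}
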
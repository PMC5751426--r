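#' Estimate surface-structure descriptors (normal directions) of a contour
#'
#' For each point the chord between its two flanking neighbors approximates
#' the local tangent; rotating the chord by 90 degrees gives an (un-normalized)
#' normal-direction vector. Magnitude equals the chord length: it is kept,
#' because the structure-term gradient is linear in these vectors.
#'
#' @param ct a [contour()].
#' @param neighbors `"topological"` uses the ordered neighbors (k-1, k+1) with
#'   wraparound for closed contours; `"euclidean"` uses the two Euclidean
#'   nearest neighbors (for unordered input).
#' @return An object of class `ssd_descriptor`: list with `vectors` (n x 2
#'   normals), `chords` (n x 2 rows `H_k = s_j - s_i`), and `pairs` (n x 2
#'   integer matrix of the neighbor indices (i, j) used per point).
#' @export
estimate_normals <- function(ct, neighbors = c("topological", "euclidean")) {
  neighbors <- match.arg(neighbors)
  P <- ct$points
  n <- nrow(P)
  if (n < 3L) stop("invalid contour: need at least 3 points")
  pairs <- neighbor_pairs(P, closed = ct$closed, mode = neighbors)
  H <- P[pairs[, 2L], , drop = FALSE] - P[pairs[, 1L], , drop = FALSE]
  deg <- which(rowSums(abs(H)) == 0)
  if (length(deg))
    stop("degenerate chord (duplicate neighbor pair) at point index ", deg[1L])
  structure(list(vectors = rotate90(H), chords = H, pairs = pairs),
            class = "ssd_descriptor")
}

# right-multiplication of row vectors by R = [[0,-1],[1,0]]
rotate90 <- function(H) cbind(H[, 2L], -H[, 1L])

neighbor_pairs <- function(P, closed, mode) {
  n <- nrow(P)
  if (mode == "topological") {
    if (closed) {
      i <- c(n, seq_len(n - 1L))
      j <- c(seq_len(n - 1L) + 1L, 1L)
    } else {
      # endpoints fall back to the one-sided chord
      i <- c(1L, seq_len(n - 1L))
      j <- c(2L, seq_len(n - 1L) + 1L)
      i[n] <- n - 1L; j[n] <- n
    }
    cbind(i, j, deparse.level = 0L)
  } else {
    D <- cross_sqdist(P, P)
    diag(D) <- Inf
    t(vapply(seq_len(n), function(k) sort(order(D[k, ])[1:2]), integer(2L)))
  }
}

#' Orient descriptor normals outward
#'
#' Flips each normal (and its generating chord) so that it points away from
#' the contour centroid. Registration is sensitive to sign flips between
#' corresponding structure vectors, so a consistent outward convention is
#' imposed before matching.
#'
#' @param desc an `ssd_descriptor` from [estimate_normals()].
#' @param ct the contour the descriptor was computed on.
#' @return The descriptor with rows of `vectors` and `chords` sign-flipped
#'   where needed; attribute `flipped` records the sign applied per row.
#' @export
orient_normals_outward <- function(desc, ct) {
  ctr <- contour_centroid(ct)
  radial <- sweep(ct$points, 2L, ctr)
  d <- rowSums(desc$vectors * radial)
  at_center <- rowSums(radial * radial) == 0
  if (any(at_center))
    warning("point coincident with centroid; orientation left unchanged at index ",
            which(at_center)[1L])
  sign <- ifelse(d < 0 & !at_center, -1, 1)
  desc$vectors <- desc$vectors * sign
  desc$chords <- desc$chords * sign
  attr(desc, "flipped") <- sign
  desc
}

#' Resample a contour with an interpolating periodic spline
#'
#' Fits a periodic (for closed contours) cubic interpolating spline through
#' the ordered points, parameterized uniformly by point index, and evaluates
#' `n_out` points uniformly spaced in the spline parameter. The spline passes
#' through every input point at integer parameter values.
#'
#' @param ct a [contour()].
#' @param n_out number of output points (>= 3).
#' @return A [contour()] with `n_out` points; `z`, `wall`, `closed` preserved.
#' @export
resample_contour_bspline <- function(ct, n_out) {
  if (n_out < 3L) stop("n_out must be at least 3")
  P <- ct$points
  n <- nrow(P)
  if (ct$closed) {
    t_in <- 0:n
    xs <- c(P[, 1L], P[1L, 1L])
    ys <- c(P[, 2L], P[1L, 2L])
    t_out <- seq(0, n, length.out = n_out + 1L)[seq_len(n_out)]
    x <- stats::spline(t_in, xs, method = "periodic", xout = t_out)$y
    y <- stats::spline(t_in, ys, method = "periodic", xout = t_out)$y
  } else {
    t_in <- seq_len(n) - 1L
    t_out <- seq(0, n - 1L, length.out = n_out)
    x <- stats::spline(t_in, P[, 1L], method = "natural", xout = t_out)$y
    y <- stats::spline(t_in, P[, 2L], method = "natural", xout = t_out)$y
  }
  contour(cbind(x, y), z = ct$z, wall = ct$wall, closed = ct$closed)
}

#' Interpolate a contour stack along the long axis
#'
#' Equalizes slice sampling between phases by the section-rotation scheme in
#' angular form: every slice is densified in-plane, the long axis is taken as
#' the vertical line through the mean of per-slice centroids, and for each of
#' `n_sections` equally spaced azimuthal half-planes the slice-wise
#' intersection radius is interpolated along z with a 1-D spline (cubic for
#' >= 4 slices, linear otherwise) and evaluated at the requested z levels.
#'
#' @param stack a [contour_stack()] with at least 2 slices.
#' @param target_z numeric vector of output slice coordinates, inside the
#'   stack's z range.
#' @param n_sections number of azimuthal sections (>= 8); default 64.
#' @param n_dense in-plane densification point count per slice.
#' @return A [contour_stack()] with `length(target_z)` slices of `n_sections`
#'   points each.
#' @export
interpolate_stack_along_axis <- function(stack, target_z, n_sections = 64L,
                                         n_dense = max(512L, 8L * n_sections)) {
  if (length(stack$contours) < 2L) stop("need at least 2 slices")
  if (n_sections < 8L) stop("n_sections must be at least 8")
  z <- stack_z(stack)
  if (any(target_z < min(z)) || any(target_z > max(z)))
    stop("extrapolation: target_z outside the stack's z range [",
         min(z), ", ", max(z), "]")
  for (ct in stack$contours)
    if (!ct$closed)
      stop("missing section: slice z=", ct$z,
           " is open and does not intersect every azimuthal section")
  dense <- lapply(stack$contours, resample_contour_bspline, n_out = n_dense)
  centroids <- t(vapply(dense, contour_centroid, numeric(2L)))
  ctr <- colMeans(centroids)
  phi <- seq(0, 2 * pi, length.out = n_sections + 1L)[seq_len(n_sections)]
  # radius of each slice at each section angle
  R <- vapply(dense, function(ct) {
    rel <- sweep(ct$points, 2L, ctr)
    ang <- atan2(rel[, 2L], rel[, 1L])
    rad <- sqrt(rowSums(rel^2))
    vapply(phi, function(a) {
      dev <- abs((ang - a + pi) %% (2 * pi) - pi)
      rad[which.min(dev)]
    }, 0)
  }, numeric(n_sections))          # n_sections x n_slices
  out <- lapply(target_z, function(zt) {
    r <- vapply(seq_len(n_sections), function(l) {
      if (length(z) >= 4L)
        stats::splinefun(z, R[l, ], method = "natural")(zt)
      else
        stats::approx(z, R[l, ], xout = zt)$y
    }, 0)
    contour(cbind(ctr[1L] + r * cos(phi), ctr[2L] + r * sin(phi)),
            z = zt, wall = stack$wall, closed = TRUE)
  })
  contour_stack(out, phase = stack$phase)
}

#' Smooth a contour with a Savitzky-Golay filter
#'
#' Applies a Savitzky-Golay polynomial filter to the x and y coordinate
#' sequences, with circular wraparound padding for closed contours so that the
#' seam is smoothed like any other stretch of boundary.
#'
#' @param ct a [contour()].
#' @param window odd filter window length (must be below the point count).
#' @param order polynomial order (< window).
#' @return The smoothed contour, same point count.
#' @export
smooth_contour_savgol <- function(ct, window = 7L, order = 2L) {
  n <- nrow(ct$points)
  if (window %% 2L != 1L) stop("window must be odd")
  if (order >= window) stop("order must be smaller than window")
  if (window >= n) stop("window must be smaller than the point count")
  half <- (window - 1L) %/% 2L
  sg <- function(v) {
    if (ct$closed) {
      ext <- c(v[(n - half + 1L):n], v, v[1:half])
      signal::sgolayfilt(ext, p = order, n = window)[(half + 1L):(half + n)]
    } else {
      signal::sgolayfilt(v, p = order, n = window)
    }
  }
  contour(cbind(sg(ct$points[, 1L]), sg(ct$points[, 2L])),
          z = ct$z, wall = ct$wall, closed = ct$closed)
}
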
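#' Construct a contour
#'
#' An ordered closed (or open) 2D boundary of one myocardial wall on a
#' short-axis slice. Points are continuous coordinates (pixels or mm); `z` is
#' the slice position along the long axis in the same length unit.
#'
#' @param points numeric n x 2 matrix of ordered (x, y) positions; consecutive
#'   points are neighbors along the boundary.
#' @param z scalar slice coordinate (default 0).
#' @param wall wall label, `"endo"` or `"epi"`.
#' @param closed logical; is the boundary a closed ring?
#' @return An object of class `ssd_contour`: a list with elements `points`,
#'   `z`, `wall`, `closed`.
#' @export
contour <- function(points, z = 0, wall = c("endo", "epi"), closed = TRUE) {
  wall <- match.arg(wall)
  points <- as_points_matrix(points)
  if (nrow(points) < 3L)
    stop("invalid contour: need at least 3 points, got ", nrow(points))
  if (!all(is.finite(points)))
    stop("invalid contour: non-finite coordinates")
  dup <- which(rowSums(abs(diff(points))) == 0)
  if (length(dup))
    stop("invalid contour: consecutive duplicate points at index ", dup[1L])
  if (closed && sum(abs(points[1L, ] - points[nrow(points), ])) == 0)
    stop("invalid contour: closed contours must not repeat the first point")
  if (!(is.numeric(z) && length(z) == 1L && is.finite(z)))
    stop("invalid contour: z must be a finite scalar")
  structure(list(points = points, z = z, wall = wall, closed = closed),
            class = "ssd_contour")
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be an n x 2 matrix")
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  points
}

#' @export
print.ssd_contour <- function(x, ...) {
  cat(sprintf("<contour: %d points, wall=%s, z=%g, %s>\n",
              nrow(x$points), x$wall, x$z,
              if (x$closed) "closed" else "open"))
  invisible(x)
}

contour_centroid <- function(ct) colMeans(ct$points)

#' Construct a stack of contours along the long axis
#'
#' @param contours list of [contour()] objects sharing a wall label, sorted by
#'   strictly increasing `z`.
#' @param phase cardiac phase label, `"ED"`, `"ES"` or `NA`.
#' @return An object of class `ssd_contour_stack`.
#' @export
contour_stack <- function(contours, phase = NA_character_) {
  if (!length(contours) || !all(vapply(contours, inherits, TRUE, "ssd_contour")))
    stop("contours must be a non-empty list of contour objects")
  z <- vapply(contours, function(ct) ct$z, 0)
  if (is.unsorted(z, strictly = TRUE))
    stop("contour stack requires strictly increasing z")
  wall <- unique(vapply(contours, function(ct) ct$wall, ""))
  if (length(wall) != 1L)
    stop("all contours in a stack must share one wall label")
  structure(list(contours = contours, phase = phase, wall = wall),
            class = "ssd_contour_stack")
}

#' @export
print.ssd_contour_stack <- function(x, ...) {
  cat(sprintf("<contour stack: %d slices, wall=%s, phase=%s, z in [%g, %g]>\n",
              length(x$contours), x$wall, x$phase,
              x$contours[[1L]]$z, x$contours[[length(x$contours)]]$z))
  invisible(x)
}

stack_z <- function(stack) vapply(stack$contours, function(ct) ct$z, 0)
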
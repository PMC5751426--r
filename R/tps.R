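# Thin-plate-spline machinery: phi(r) = -r^2 log(r^2) basis, control grid,
# left-null-space elastic parameterization, and the linear maps that carry
# model points and their structure descriptors as functions of theta.

# squared Euclidean cross-distances between row sets (m x 2, n x 2) -> m x n
cross_sqdist <- function(A, B) {
  d <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

# TPS radial basis on squared distances; phi(0) := 0 by continuity
tps_phi_sq <- function(r2) {
  out <- -r2 * log(r2)
  out[r2 == 0] <- 0
  out
}

#' TPS basis matrix
#'
#' `Phi[i, j] = phi(||m0_i - q_j||)` with `phi(r) = -r^2 log(r^2)` and
#' `phi(0) = 0`.
#'
#' @param M0 m x 2 model points.
#' @param Q c x 2 control points.
#' @return m x c basis matrix.
#' @export
tps_basis <- function(M0, Q) tps_phi_sq(cross_sqdist(as_points_matrix(M0),
                                                     as_points_matrix(Q)))

#' Regular control-point grid over the data
#'
#' Places a g x g grid spanning the joint bounding box of the supplied points,
#' padded by 5 percent per side.
#'
#' @param points n x 2 matrix (typically rbind of scene and model points).
#' @param g grid side (>= 2); the grid has `g^2` control points.
#' @return c x 2 matrix of control points, row-major over the grid.
#' @export
build_control_grid <- function(points, g) {
  if (g < 2L) stop("grid side g must be at least 2")
  P <- as_points_matrix(points)
  lo <- apply(P, 2L, min)
  hi <- apply(P, 2L, max)
  span <- hi - lo
  if (any(span == 0)) stop("zero-area bounding box: cannot place control grid")
  lo <- lo - 0.05 * span
  hi <- hi + 0.05 * span
  gx <- seq(lo[1L], hi[1L], length.out = g)
  gy <- seq(lo[2L], hi[2L], length.out = g)
  cbind(rep(gx, times = g), rep(gy, each = g))
}

#' Orthonormal left-null-space basis of [1|Q]
#'
#' Returns the c x (c-3) orthonormal basis `N` with `t(N) %*% cbind(1, Q) = 0`,
#' computed from the full QR decomposition of `[1|Q]`. Writing the elastic TPS
#' weights as `W = N tau` enforces the side conditions (zero sum and zero
#' first moments of W over the control points) by construction.
#'
#' @param Q c x 2 control points, not all collinear, c >= 4.
#' @return c x (c-3) matrix with orthonormal columns.
#' @export
null_space_basis <- function(Q) {
  Q <- as_points_matrix(Q)
  cc <- nrow(Q)
  if (cc < 4L) stop("need at least 4 control points")
  X <- cbind(1, Q)
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("collinear control points: rank of [1|Q] is below 3")
  qr.Q(qrX, complete = TRUE)[, 4:cc, drop = FALSE]
}

#' Assemble a TPS transformation model
#'
#' Bundles control points `Q`, basis `Phi`, bending matrix `K`, null-space
#' basis `N` and the m x c design matrix `[1|M0, Phi N]` whose product with
#' the stacked parameter `theta = [A; tau]` gives the mapped points.
#'
#' @param M0 m x 2 model points (the moving set, undeformed).
#' @param Q c x 2 control points, e.g. from [build_control_grid()].
#' @return An object of class `ssd_tps_model`.
#' @export
tps_model <- function(M0, Q) {
  M0 <- as_points_matrix(M0)
  Q <- as_points_matrix(Q)
  N <- null_space_basis(Q)
  Phi <- tps_basis(M0, Q)
  K <- tps_phi_sq(cross_sqdist(Q, Q))
  design <- cbind(1, M0, Phi %*% N)
  structure(list(M0 = M0, Q = Q, Phi = Phi, K = K, N = N, design = design,
                 c = nrow(Q)),
            class = "ssd_tps_model")
}

#' @export
print.ssd_tps_model <- function(x, ...) {
  cat(sprintf("<TPS model: %d model points, %d control points>\n",
              nrow(x$M0), x$c))
  invisible(x)
}

#' Stack transformation parameters
#'
#' `theta` is the c x 2 vertical stack of the 3 x 2 affine block `A` over the
#' (c-3) x 2 elastic block `tau`; the elastic weights are `W = N tau`.
#'
#' @param A 3 x 2 affine block (rows: intercept, x-coefficient,
#'   y-coefficient; columns: x and y output).
#' @param tau (c-3) x 2 elastic block.
#' @return c x 2 parameter matrix.
#' @export
theta_params <- function(A, tau) {
  A <- as.matrix(A); tau <- as.matrix(tau)
  if (!all(dim(A) == c(3L, 2L))) stop("A must be 3 x 2")
  if (ncol(tau) != 2L) stop("tau must have 2 columns")
  rbind(A, tau)
}

#' Identity transformation parameters for a TPS model
#' @param model an `ssd_tps_model` (or a control-point count `c`).
#' @return c x 2 theta with identity affine block and zero elastic block.
#' @export
theta_identity <- function(model) {
  cc <- if (inherits(model, "ssd_tps_model")) model$c else as.integer(model)
  theta_params(matrix(c(0, 1, 0, 0, 0, 1), 3L, 2L), matrix(0, cc - 3L, 2L))
}

theta_tau <- function(theta) theta[-(1:3), , drop = FALSE]
theta_W <- function(model, theta) model$N %*% theta_tau(theta)

#' Apply the TPS transformation
#'
#' @param model an `ssd_tps_model`.
#' @param theta c x 2 parameters from [theta_params()].
#' @return m x 2 mapped points `design %*% theta`.
#' @export
tps_transform <- function(model, theta) {
  if (!all(dim(theta) == c(model$c, 2L)))
    stop("theta must be ", model$c, " x 2")
  model$design %*% theta
}

#' Row-difference matrix carrying model structure descriptors
#'
#' Builds the m x c matrix whose k-th row is `T_k = B_j - B_i`, the difference
#' of the design rows of the neighbor pair (i, j) of model point k, with the
#' same optional outward-orientation sign flips as the scene descriptors. The
#' mapped descriptor is then the exactly linear `V_M = T theta R`.
#'
#' @param model an `ssd_tps_model`.
#' @param pairs n x 2 integer matrix of neighbor index pairs (from
#'   [estimate_normals()] on the model contour(s), offset to design rows).
#' @param sign optional per-row sign vector (+1/-1) from outward orientation.
#' @return m x c matrix `T`.
#' @export
model_row_diffs <- function(model, pairs, sign = NULL) {
  Tm <- model$design[pairs[, 2L], , drop = FALSE] -
    model$design[pairs[, 1L], , drop = FALSE]
  if (!is.null(sign)) Tm <- Tm * sign
  Tm
}

#' Mapped model structure descriptors
#'
#' @param Tmat m x c row-difference matrix from [model_row_diffs()].
#' @param theta c x 2 parameters.
#' @return m x 2 matrix `V_M = T theta R`, identical to re-estimating normals
#'   on the transformed points under the frozen neighbor pairing.
#' @export
mapped_normals <- function(Tmat, theta) rotate90(Tmat %*% theta)

#' TPS bending energy
#'
#' `trace(t(W) Kb W)` with `W = N tau` and `Kb = -K`: the classical
#' thin-plate smoothness functional, non-negative on the side-condition
#' subspace. The sign matters: the quadratic form of the basis kernel
#' `phi(r) = -r^2 log(r^2)` itself is negative definite on that subspace, so
#' the bending matrix must enter the energy with the opposite sign for the
#' lambda term to act as a penalty rather than an unbounded reward.
#'
#' @param model an `ssd_tps_model`.
#' @param theta c x 2 parameters.
#' @return scalar bending energy (>= 0).
#' @export
bending_energy <- function(model, theta) {
  W <- theta_W(model, theta)
  -sum(W * (model$K %*% W))
}

# gradient of (lambda/2) * bending_energy with respect to tau
bending_grad_tau <- function(model, tau, lambda)
  -lambda * crossprod(model$N, model$K %*% (model$N %*% tau))

#' Serialize / restore a fitted transform
#'
#' @param theta c x 2 parameters; `model` the TPS model; `g` grid side used.
#' @param path file to write (JSON).
#' @return `write_theta_json` returns `path` invisibly; `read_theta_json`
#'   returns a list with `theta`, `Q`, `grid_side`.
#' @export
write_theta_json <- function(theta, model, g, path) {
  obj <- list(A = theta[1:3, , drop = FALSE],
              tau = theta_tau(theta),
              Q = model$Q,
              grid_side = g)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_theta_json
#' @export
read_theta_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(theta = theta_params(obj$A, obj$tau),
       Q = as.matrix(obj$Q), grid_side = obj$grid_side)
}
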
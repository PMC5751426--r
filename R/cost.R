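# Registration objective: L2 discrepancy between Gaussian mixtures of point
# positions and of structure descriptors, plus bending-energy regularization.

#' Registration cost configuration
#'
#' @param sigma Gaussian kernel scale (length units), shared by the position
#'   and structure kernels. `NULL` defaults to 0.1 x the scene bounding-box
#'   diagonal at problem construction.
#' @param beta weight of the structure-descriptor term (>= 0).
#' @param lambda weight of the bending-energy regularizer (>= 0).
#' @param sigma_v optional distinct kernel scale for the structure block;
#'   `NULL` means use `sigma` (the printed objective shares one scale).
#' @param grid_side control-grid side g (c = g^2 control points).
#' @param anneal if `TRUE`, optimization runs a 3-stage coarse-to-fine
#'   schedule over kernel scales (sigma, sigma/2, sigma/4).
#' @param normalize_scene_normals if `TRUE`, scene chords are rescaled to the
#'   mean chord length to reduce sensitivity to uneven point spacing.
#' @return A list of class `ssd_cost_config`.
#' @export
cost_config <- function(sigma = NULL, beta = 1, lambda = 0.01, sigma_v = NULL,
                        grid_side = 10L, anneal = FALSE,
                        normalize_scene_normals = FALSE) {
  if (!is.null(sigma) && (!is.finite(sigma) || sigma <= 0))
    stop("sigma must be a positive finite scalar")
  if (!is.finite(beta) || beta < 0) stop("beta must be finite and >= 0")
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be finite and >= 0")
  structure(list(sigma = sigma, beta = beta, lambda = lambda,
                 sigma_v = sigma_v, grid_side = as.integer(grid_side),
                 anneal = isTRUE(anneal),
                 normalize_scene_normals = isTRUE(normalize_scene_normals)),
            class = "ssd_cost_config")
}

as_contour_list <- function(x) {
  if (inherits(x, "ssd_contour")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "ssd_contour"))) x
  else list(contour(x))
}

#' Assemble a registration problem
#'
#' Builds everything the cost and its gradients need: scene points and
#' outward-oriented structure descriptors, the TPS model on a control grid
#' spanning the joint scene/model bounding box, and the frozen model
#' row-difference matrix `T` (neighbor pairing taken on the undeformed model
#' and never re-estimated, which keeps the mapped descriptors exactly linear
#' in theta). Multiple contours (e.g. endocardium plus epicardium of one
#' slice) are concatenated, with neighbor pairing confined to each contour.
#'
#' @param scene a [contour()], list of contours, or n x 2 matrix: the fixed
#'   (ED) point set.
#' @param model0 same, the moving (ES) point set.
#' @param config an [cost_config()].
#' @return An object of class `ssd_problem` with elements `S`, `V_S`, `H`
#'   (scene chords), `M0`, `tps`, `Tmat`, `config` (sigma resolved), and the
#'   scene/model contour lists.
#' @export
registration_problem <- function(scene, model0, config = cost_config()) {
  scene <- as_contour_list(scene)
  model0 <- as_contour_list(model0)
  S <- do.call(rbind, lapply(scene, function(ct) ct$points))
  M0 <- do.call(rbind, lapply(model0, function(ct) ct$points))

  sdesc <- lapply(scene, function(ct)
    orient_normals_outward(estimate_normals(ct), ct))
  H <- do.call(rbind, lapply(sdesc, function(d) d$chords))
  if (config$normalize_scene_normals) {
    len <- sqrt(rowSums(H^2))
    H <- H * (mean(len) / len)
  }

  if (is.null(config$sigma)) {
    bb <- apply(S, 2L, range)
    config$sigma <- 0.1 * sqrt(sum((bb[2L, ] - bb[1L, ])^2))
  }
  if (is.null(config$sigma_v)) config$sigma_v <- config$sigma

  Q <- build_control_grid(rbind(S, M0), config$grid_side)
  tps <- tps_model(M0, Q)

  # frozen neighbor pairing + outward orientation on the undeformed model
  offset <- 0L
  Tparts <- vector("list", length(model0))
  for (k in seq_along(model0)) {
    ct <- model0[[k]]
    d <- orient_normals_outward(estimate_normals(ct), ct)
    Tparts[[k]] <- model_row_diffs(tps, d$pairs + offset,
                                   sign = attr(d, "flipped"))
    offset <- offset + nrow(ct$points)
  }

  structure(list(S = S, V_S = rotate90(H), H = H, M0 = M0, tps = tps,
                 Tmat = do.call(rbind, Tparts), config = config,
                 scene = scene, model0 = model0),
            class = "ssd_problem")
}

#' @export
print.ssd_problem <- function(x, ...) {
  cat(sprintf(
    "<registration problem: n=%d scene, m=%d model, c=%d control points, sigma=%.4g, beta=%g, lambda=%g>\n",
    nrow(x$S), nrow(x$M0), x$tps$c, x$config$sigma, x$config$beta,
    x$config$lambda))
  invisible(x)
}

#' Normalized Gaussian kernel cross-sum between two point sets
#'
#' `(1 / (|Xa| |Xb|)) * sum_ij exp(-||a_i - b_j||^2 / sigma^2)`: the
#' closed-form L2 inner product of two equal-weight Gaussian mixtures, up to a
#' common constant.
#'
#' @param Xa,Xb point-row matrices (same column count).
#' @param sigma kernel scale (> 0).
#' @return scalar; symmetric in `Xa`, `Xb`.
#' @export
gaussian_kernel_sum <- function(Xa, Xb, sigma) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  if (!nrow(Xa) || !nrow(Xb)) stop("empty point set")
  if (sigma <= 0) stop("sigma must be positive")
  mean(exp(-cross_sqdist(Xa, Xb) / sigma^2))
}

#' Closed-form integral of a product of two isotropic 2D Gaussians
#'
#' Evaluates the identity
#' `integral phi(x | mu1, s1) phi(x | mu2, s2) dx = phi(0 | mu1 - mu2, s1 + s2)`
#' where `phi(x | mu, s)` is the 2D normal density with mean `mu` and
#' covariance `s I` (`s` a variance parameter). This is the algebraic step
#' that turns the mixture L2 distance into the exponential sums of the cost;
#' it is exposed so the kernel algebra can be validated against quadrature.
#'
#' @param mu1,mu2 length-2 means.
#' @param s1,s2 positive variance parameters.
#' @return scalar value of the right-hand side.
#' @export
gaussian_product_integral <- function(mu1, s1, mu2, s2) {
  if (s1 <= 0 || s2 <= 0) stop("variance parameters must be positive")
  d2 <- sum((mu1 - mu2)^2)
  s <- s1 + s2
  exp(-d2 / (2 * s)) / (2 * pi * s)
}

# isotropic 2D normal density, used by tests as the quadrature integrand
gauss2d_density <- function(x, y, mu, s)
  exp(-((x - mu[1L])^2 + (y - mu[2L])^2) / (2 * s)) / (2 * pi * s)

# kernel blocks shared by cost and reporting
cost_blocks <- function(problem, theta) {
  cfg <- problem$config
  M <- tps_transform(problem$tps, theta)
  U <- problem$Tmat %*% theta            # pre-rotation mapped descriptors
  s2 <- cfg$sigma^2
  sv2 <- cfg$sigma_v^2
  m <- nrow(M); n <- nrow(problem$S)
  list(
    M = M, U = U, m = m, n = n,
    mm = sum(exp(-cross_sqdist(M, M) / s2)) / m^2,
    ms = sum(exp(-cross_sqdist(M, problem$S) / s2)) / (m * n),
    uu = sum(exp(-cross_sqdist(U, U) / sv2)) / m^2,
    uv = sum(exp(-cross_sqdist(U, problem$H) / sv2)) / (m * n),
    bend = bending_energy(problem$tps, theta)
  )
}

#' Registration cost (the optimized objective)
#'
#' The L2 mixture discrepancy with the theta-independent scene self-terms
#' removed:
#' `J = (1/m^2) sum_ij k(m_i, m_j) - (2/mn) sum_ij k(m_i, s_j)
#'    + (beta/m^2) sum_ij k(u_i, u_j) - (2 beta/mn) sum_ij k(u_i, v_j)
#'    + (lambda/2) trace(t(W) K W)`
#' with `k(a, b) = exp(-||a-b||^2 / sigma^2)`, mapped points
#' `M = design theta` and mapped descriptors `V_M = T theta R`. Descriptor
#' distances are evaluated on the pre-rotation rows (`T theta` against the
#' scene chords), which the orthogonal rotation leaves unchanged.
#'
#' @param problem an [registration_problem()].
#' @param theta c x 2 parameters.
#' @return scalar cost.
#' @export
cost_J <- function(problem, theta) {
  b <- cost_blocks(problem, theta)
  cfg <- problem$config
  b$mm - 2 * b$ms + cfg$beta * (b$uu - 2 * b$uv) + cfg$lambda / 2 * b$bend
}

#' Full (un-truncated) L2 mixture discrepancy
#'
#' Adds the theta-independent scene self-terms back to [cost_J()]; used for
#' reporting and for verifying that the optimized objective differs from the
#' full discrepancy only by a constant.
#'
#' @inheritParams cost_J
#' @return scalar.
#' @export
cost_full_L2 <- function(problem, theta) {
  cfg <- problem$config
  n <- nrow(problem$S)
  ss <- sum(exp(-cross_sqdist(problem$S, problem$S) / cfg$sigma^2)) / n^2
  vv <- sum(exp(-cross_sqdist(problem$H, problem$H) / cfg$sigma_v^2)) / n^2
  cost_J(problem, theta) + ss + cfg$beta * vv
}
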
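# Shared fixture builders: analytic shapes with exact oracles, plus small
# random registration problems for gradient checks.

circle_contour <- function(r = 1, n = 64L, center = c(0, 0), z = 0,
                           wall = "endo") {
  a <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  contour(cbind(center[1L] + r * cos(a), center[2L] + r * sin(a)),
          z = z, wall = wall)
}

# smooth closed contour with random low-order Fourier perturbation
random_smooth_contour <- function(n = 64L, r = 1, amp = 0.15, seed = 0L,
                                  center = c(0, 0)) {
  set.seed(seed)
  a <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  rad <- r * (1 + amp * (sin(2 * a + runif(1, 0, 2 * pi)) * runif(1) +
                           cos(3 * a + runif(1, 0, 2 * pi)) * runif(1)))
  contour(cbind(center[1L] + rad * cos(a), center[2L] + rad * sin(a)))
}

# small random registration problem with a perturbed theta for gradient tests
random_problem <- function(seed, m = 40L, n = 50L, g = 4L, beta = 1,
                           lambda = 0.05, tau_scale = 0.02) {
  scene <- random_smooth_contour(n = n, r = 10, seed = seed)
  model <- random_smooth_contour(n = m, r = 8, seed = seed + 1000L,
                                 center = c(0.5, -0.3))
  pr <- registration_problem(scene, model,
                             cost_config(beta = beta, lambda = lambda, grid_side = g))
  set.seed(seed + 2000L)
  th <- theta_identity(pr$tps)
  th[1L, ] <- th[1L, ] + stats::rnorm(2L, sd = 0.3)
  th[-(1:3), ] <- matrix(stats::rnorm(2L * (pr$tps$c - 3L)), ncol = 2L) * tau_scale
  list(problem = pr, theta = th)
}

# central finite-difference gradient of cost_J
fd_grad <- function(problem, theta, h = 1e-6) {
  g <- theta * 0
  for (r in seq_len(nrow(theta))) {
    for (cc in 1:2) {
      tp <- theta; tm <- theta
      tp[r, cc] <- tp[r, cc] + h
      tm[r, cc] <- tm[r, cc] - h
      g[r, cc] <- (cost_J(problem, tp) - cost_J(problem, tm)) / (2 * h)
    }
  }
  g
}

# single-point degenerate problem (beta = lambda = 0 uses only positions)
one_point_problem <- function(s = c(0, 0), m0 = c(0, 0), sigma = 1) {
  Q <- rbind(c(-2, -2), c(2, -2), c(-2, 2), c(2, 2))
  tps <- tps_model(matrix(m0, 1L), Q)
  structure(list(S = matrix(s, 1L), V_S = matrix(0, 1L, 2L),
                 H = matrix(0, 1L, 2L), M0 = matrix(m0, 1L), tps = tps,
                 Tmat = matrix(0, 1L, tps$c),
                 config = cost_config(sigma = sigma, beta = 0, lambda = 0)),
            class = "ssd_problem")
}

combined_points <- function(contours) do.call(rbind, lapply(contours, `[[`, "points"))

# annulus pair with the ground-truth contraction + small random TPS warp
warped_annulus_fixture <- function(seed, n_points = 48L, contraction = 0.7,
                                   max_disp = 1.5, warp_g = 4L) {
  spec <- annulus_spec(n_points = n_points, noise_sd = 0, seed = seed)
  base <- make_annulus_pair(spec, warp_spec(contraction))
  rw <- random_true_warp(base$model_ideal, g = warp_g, max_disp = max_disp,
                         seed = seed)
  make_annulus_pair(spec, warp_spec(contraction, theta_true = rw$theta_true,
                                    seed = seed), tps = rw$tps)
}
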
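test_that("analytic gradients match central finite differences", {
  for (seed in c(41L, 42L, 43L)) {
    rp <- random_problem(seed, m = 30L, n = 35L, g = 4L)
    g <- grad_J(rp$problem, rp$theta)
    fd <- fd_grad(rp$problem, rp$theta)
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
  }
  # position-only problem (beta = 0) exercises grad_Jd alone
  rp0 <- random_problem(44L, beta = 0)
  expect_equal(grad_Jv(rp0$problem, rp0$theta),
               matrix(0, rp0$problem$tps$c, 2L))
  fd0 <- fd_grad(rp0$problem, rp0$theta)
  expect_lt(max(abs(grad_J(rp0$problem, rp0$theta) - fd0)) / max(abs(fd0)),
            1e-5)
})

test_that("a coincident single point with identity theta is stationary", {
  pr <- one_point_problem(s = c(0, 0), m0 = c(0, 0), sigma = 1)
  th <- theta_identity(pr$tps)
  g <- grad_Jd(pr, th, parts = TRUE)
  expect_equal(attr(g, "G"), matrix(0, 1L, 2L))
  expect_equal(unclass(g), matrix(0, pr$tps$c, 2L), ignore_attr = TRUE)
})

test_that("the elastic gradient block isolates the regularizer", {
  # scene moved far away: every kernel term is numerically zero, leaving
  # only the bending gradient in the elastic rows
  scene <- circle_contour(r = 2, n = 24L, center = c(1e4, 1e4))
  model <- circle_contour(r = 2, n = 24L)
  pr <- registration_problem(scene, model,
                             cost_config(sigma = 1, beta = 0, lambda = 0.3,
                                         grid_side = 4L))
  set.seed(45)
  th <- theta_identity(pr$tps)
  tau <- matrix(rnorm(2L * (pr$tps$c - 3L)), ncol = 2L) * 0.01
  th[-(1:3), ] <- tau
  g <- grad_J(pr, th)
  reg_oracle <- -0.3 * crossprod(pr$tps$N, pr$tps$K %*% (pr$tps$N %*% tau))
  expect_lt(max(abs(g[-(1:3), ] - reg_oracle)), 1e-8)
})

test_that("per-point gradient collapses to the full gradient for m = 1", {
  pr <- one_point_problem(s = c(0.7, -0.4), m0 = c(0.2, 0.1), sigma = 0.8)
  set.seed(46)
  th <- theta_identity(pr$tps)
  th[1L, ] <- rnorm(2L, sd = 0.2)
  expect_equal(grad_f_point(pr, th, 1L), grad_J(pr, th), tolerance = 1e-12)
  expect_error(grad_f_point(pr, th, 2L), "out of range")
})

test_that("per-point gradients recombine to the full-batch gradient", {
  rp <- random_problem(47L, m = 25L, n = 28L)
  pr <- rp$problem; th <- rp$theta
  m <- nrow(pr$M0)
  gsum <- Reduce(`+`, lapply(seq_len(m), function(i) grad_f_point(pr, th, i)))
  f3 <- grad_f_point(pr, th, 1L, parts = TRUE)$df3
  recombined <- (gsum - m * f3) / m + f3   # regularizer counted once
  expect_lt(max(abs(recombined - grad_J(pr, th))), 1e-8)

  # per_sample_reg scales only the regularizer addend
  p1 <- grad_f_point(pr, th, 3L, parts = TRUE)
  p2 <- grad_f_point(pr, th, 3L, per_sample_reg = TRUE, parts = TRUE)
  expect_equal(p2$df3, p1$df3 / m)
  expect_equal(p2$df1, p1$df1)
})

test_that("each per-point addend matches finite differences of its term", {
  rp <- random_problem(48L, m = 12L, n = 15L, g = 4L)
  pr <- rp$problem; th <- rp$theta
  i <- 5L
  cfg <- pr$config
  n <- nrow(pr$S); m <- nrow(pr$M0)
  term_funs <- list(
    df1 = function(t) {
      M <- tps_transform(pr$tps, t)
      sum(exp(-colSums((M[i, ] - t(M))^2) / cfg$sigma^2)) / m
    },
    df2 = function(t) {
      M <- tps_transform(pr$tps, t)
      -2 * sum(exp(-colSums((M[i, ] - t(pr$S))^2) / cfg$sigma^2)) / n
    },
    df3 = function(t) cfg$lambda / 2 * bending_energy(pr$tps, t),
    df4 = function(t) {
      U <- pr$Tmat %*% t
      cfg$beta * sum(exp(-colSums((U[i, ] - t(U))^2) / cfg$sigma_v^2)) / m
    },
    df5 = function(t) {
      U <- pr$Tmat %*% t
      -2 * cfg$beta *
        sum(exp(-colSums((U[i, ] - t(pr$H))^2) / cfg$sigma_v^2)) / n
    })
  parts <- grad_f_point(pr, th, i, parts = TRUE)
  h <- 1e-6
  for (nm in names(term_funs)) {
    fd <- th * 0
    for (r in seq_len(nrow(th))) for (cc in 1:2) {
      tp <- th; tm <- th
      tp[r, cc] <- tp[r, cc] + h; tm[r, cc] <- tm[r, cc] - h
      fd[r, cc] <- (term_funs[[nm]](tp) - term_funs[[nm]](tm)) / (2 * h)
    }
    denom <- max(abs(fd), 1e-8)
    expect_lt(max(abs(parts[[nm]] - fd)) / denom, 1e-5)
  }
})

test_that("SGD is stationary at an optimum, descends, and is deterministic", {
  pr <- one_point_problem(s = c(0, 0), m0 = c(0, 0), sigma = 1)
  th <- theta_identity(pr$tps)
  res <- sgd_optimize(pr, th, sgd_config(epochs = 5L, seed = 0L))
  expect_lt(max(abs(res$theta - th)), 1e-12)
  expect_lt(diff(range(res$trace)), 1e-12)

  pair <- warped_annulus_fixture(seed = 3L, n_points = 32L)
  cfg <- cost_config(grid_side = 6L)
  prob <- registration_problem(pair$scene, pair$model, cfg)
  s1 <- sgd_optimize(prob, cfg = sgd_config(epochs = 15L, seed = 0L))
  expect_lt(s1$trace[length(s1$trace)], s1$trace[1L])

  s2 <- sgd_optimize(prob, cfg = sgd_config(epochs = 15L, seed = 0L))
  expect_identical(s1$theta, s2$theta)
  s3 <- sgd_optimize(prob, cfg = sgd_config(epochs = 15L, seed = 99L))
  J1 <- min(s1$trace); J3 <- min(s3$trace)
  expect_lt(abs(J1 - J3) / abs(J1), 0.05)
})

test_that("Quasi-Newton drives a regularizer-dominated problem to tau = 0", {
  scene <- circle_contour(r = 2, n = 24L, center = c(1e4, 1e4))
  model <- circle_contour(r = 2, n = 24L)
  pr <- registration_problem(scene, model,
                             cost_config(sigma = 1, beta = 0, lambda = 10,
                                         grid_side = 4L))
  set.seed(49)
  th0 <- theta_identity(pr$tps)
  th0[-(1:3), ] <- matrix(rnorm(2L * (pr$tps$c - 3L)), ncol = 2L) * 0.05
  res <- qn_optimize(pr, th0, pgtol = 1e-9)
  expect_true(res$converged)
  # the exact minimizer is tau = 0; the optimizer stops when the quadratic
  # objective reaches machine-level flatness, several orders below the start
  expect_lt(max(abs(res$theta[-(1:3), ])), 1e-4 * max(abs(th0[-(1:3), ])))
})

test_that("Quasi-Newton refines the SGD optimum on the annulus fixture", {
  pair <- warped_annulus_fixture(seed = 2L, n_points = 32L)
  cfg <- cost_config(grid_side = 6L)
  prob <- registration_problem(pair$scene, pair$model, cfg)
  s <- sgd_optimize(prob, cfg = sgd_config(epochs = 15L, seed = 0L))
  q <- qn_optimize(prob, s$theta)
  expect_lte(cost_J(prob, q$theta), min(s$trace) + 1e-12)
})

test_that("register is a no-op on identical contours and recovers warps", {
  ct <- list(circle_contour(r = 20, n = 40L), circle_contour(r = 30, n = 40L, wall = "epi"))
  res <- register(ct, ct, cost_config(grid_side = 6L), mode = "qn")
  S <- combined_points(ct)
  bbox_diag <- sqrt(sum((apply(S, 2L, max) - apply(S, 2L, min))^2))
  expect_lt(apd(res$mapped, S), 1e-3 * bbox_diag)
  expect_lt(max(abs(res$theta - theta_identity(res$problem$tps))), 1e-3)

  pair <- warped_annulus_fixture(seed = 1L)
  S <- combined_points(pair$scene)
  M0 <- combined_points(pair$model)
  res <- register(pair$scene, pair$model, cost_config(grid_side = 10L),
                  mode = "qn")
  expect_lt(apd(res$mapped, S), 0.1 * apd(M0, S))
  expect_lte(res$final_cost, res$initial_cost)
})

test_that("registration results are deterministic given the seed", {
  pair <- warped_annulus_fixture(seed = 4L, n_points = 24L)
  r1 <- register(pair$scene, pair$model, cost_config(grid_side = 5L),
                 mode = "sgd_qn", sgd = sgd_config(epochs = 8L, seed = 7L))
  r2 <- register(pair$scene, pair$model, cost_config(grid_side = 5L),
                 mode = "sgd_qn", sgd = sgd_config(epochs = 8L, seed = 7L))
  expect_identical(r1$theta, r2$theta)
  expect_identical(r1$cost_trace, r2$cost_trace)
})
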
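test_that("contour validation rejects degenerate input", {
  expect_error(contour(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(contour(rbind(c(0, 0), c(0, 0), c(1, 1))), "duplicate")
  expect_error(contour(rbind(c(0, 0), c(1, 1), c(NaN, 0))), "finite")
})

test_that("normal estimation rotates the neighbor chord by 90 degrees", {
  # neighbors B=(0,0), C=(2,0) flanking A=(1,1): chord (2,0), normal (0,-2)
  ct <- contour(rbind(c(0, 0), c(1, 1), c(2, 0)))
  d <- estimate_normals(ct)
  expect_equal(d$chords[2L, ], c(2, 0))
  expect_equal(d$vectors[2L, ], c(0, -2))
  expect_equal(sum(d$vectors[2L, ] * d$chords[2L, ]), 0)
})

test_that("normals of a regular polygon align with the radius", {
  ct <- circle_contour(r = 3, n = 64L)
  d <- estimate_normals(ct)
  cosang <- rowSums(d$vectors * ct$points) /
    (sqrt(rowSums(d$vectors^2)) * sqrt(rowSums(ct$points^2)))
  expect_true(all(abs(cosang) > 0.999))
})

test_that("normals are perpendicular to chords and rotation-equivariant", {
  ct <- random_smooth_contour(n = 200L, seed = 7L)
  d <- estimate_normals(ct)
  # explicit per-point dot-product oracle
  dots <- vapply(seq_len(200L), function(k)
    sum(d$vectors[k, ] * d$chords[k, ]), 0)
  expect_lt(max(abs(dots)), 1e-12)
  expect_equal(sqrt(rowSums(d$vectors^2)), sqrt(rowSums(d$chords^2)))

  phi <- 0.83
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L)
  ct_rot <- contour(ct$points %*% R, z = ct$z, wall = ct$wall)
  d_rot <- estimate_normals(ct_rot)
  expect_lt(max(abs(d_rot$vectors - d$vectors %*% R)), 1e-8)
})

test_that("degenerate neighbor chords are reported with their index", {
  ct <- contour(rbind(c(0, 0), c(1, 0), c(0, 0), c(-1, 0)))
  expect_error(estimate_normals(ct), "degenerate chord.*2")
})

test_that("euclidean neighbor mode matches topological on ordered contours", {
  ct <- circle_contour(r = 2, n = 48L)
  d1 <- estimate_normals(ct, neighbors = "topological")
  d2 <- estimate_normals(ct, neighbors = "euclidean")
  expect_equal(abs(d1$vectors), abs(d2$vectors), tolerance = 1e-12)
})

test_that("outward orientation points normals away from the centroid", {
  ct <- circle_contour(r = 2, n = 32L)
  d <- orient_normals_outward(estimate_normals(ct), ct)
  expect_true(all(rowSums(d$vectors * ct$points) > 0))
  # idempotence on already-outward normals
  d2 <- orient_normals_outward(d, ct)
  expect_identical(d2$vectors, d$vectors)

  # star-shaped contour: brute-force sign oracle per point
  a <- seq(0, 2 * pi, length.out = 61L)[1:60]
  star <- contour(cbind((2 + 0.7 * cos(5 * a)) * cos(a),
                        (2 + 0.7 * cos(5 * a)) * sin(a)))
  ds <- orient_normals_outward(estimate_normals(star), star)
  ctr <- colMeans(star$points)
  sign_oracle <- sign(rowSums(ds$vectors * sweep(star$points, 2L, ctr)))
  expect_true(all(sign_oracle >= 0))
  # perpendicularity survives the flips
  expect_lt(max(abs(rowSums(ds$vectors * ds$chords))), 1e-10)
})

test_that("periodic spline resampling interpolates and converges", {
  sq <- contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  rq <- resample_contour_bspline(sq, 4L)
  expect_lt(max(abs(rq$points - sq$points)), 1e-6)

  ci <- circle_contour(r = 10, n = 32L)
  rs <- resample_contour_bspline(ci, 128L)
  expect_lt(max(abs(sqrt(rowSums(rs$points^2)) - 10)), 0.01 * 10)

  same <- resample_contour_bspline(ci, 32L)
  expect_lt(max(abs(same$points - ci$points)), 1e-6)

  expect_error(resample_contour_bspline(ci, 2L), "n_out")

  # normals of the resampled circle approach the radial direction as the
  # input sampling is refined (output density fixed)
  ang_err <- vapply(c(12L, 24L, 48L), function(n_in) {
    r <- resample_contour_bspline(circle_contour(r = 1, n = n_in), 128L)
    d <- orient_normals_outward(estimate_normals(r), r)
    u <- d$vectors / sqrt(rowSums(d$vectors^2))
    v <- r$points / sqrt(rowSums(r$points^2))
    max(acos(pmin(1, rowSums(u * v))))
  }, 0)
  expect_true(all(diff(ang_err) < 0))
})

test_that("stack interpolation is exact for constant and linear profiles", {
  st <- contour_stack(lapply(0:2, function(z)
    circle_contour(r = 5, n = 64L, center = c(1, 2), z = z)))
  it <- interpolate_stack_along_axis(st, c(0.5, 1.5), n_sections = 32L)
  expect_length(it$contours, 2L)
  for (ct in it$contours) {
    r <- sqrt(rowSums(sweep(ct$points, 2L, c(1, 2))^2))
    expect_lt(max(abs(r - 5)), 1e-6)
  }

  # cone: radius 1 + z, target slice at z = 0.5 has radius 1.5
  cone <- contour_stack(lapply(c(0, 1, 2), function(z)
    circle_contour(r = 1 + z, n = 256L, z = z)))
  ic <- interpolate_stack_along_axis(cone, 0.5, n_sections = 32L)
  r <- sqrt(rowSums(ic$contours[[1L]]$points^2))
  expect_lt(max(abs(r - 1.5)) / 1.5, 0.01)
})

test_that("stack interpolation enforces its contract", {
  st <- contour_stack(lapply(0:3, function(z)
    circle_contour(r = 4, n = 32L, z = z)))
  it <- interpolate_stack_along_axis(st, c(0.2, 1.1, 2.9), n_sections = 16L)
  expect_length(it$contours, 3L)
  expect_equal(vapply(it$contours, function(ct) nrow(ct$points), 0L),
               rep(16L, 3L))
  expect_error(interpolate_stack_along_axis(st, 5), "extrapolation")
  open_ct <- contour(rbind(c(0, 0), c(1, 0), c(2, 1)), z = 4, closed = FALSE)
  st2 <- contour_stack(c(st$contours, list(open_ct)))
  expect_error(interpolate_stack_along_axis(st2, 1), "missing section")
})

test_that("Savitzky-Golay smoothing preserves polynomials and reduces noise", {
  ln <- contour(cbind(seq(0, 1, length.out = 50L), seq(0, 2, length.out = 50L)),
                closed = FALSE)
  expect_lt(max(abs(smooth_contour_savgol(ln, 7L, 2L)$points - ln$points)),
            1e-10)

  set.seed(11)
  ci <- circle_contour(r = 1, n = 100L)
  noisy <- contour(ci$points + matrix(rnorm(200L, sd = 0.05), ncol = 2L))
  sm <- smooth_contour_savgol(noisy, 9L, 2L)
  dev <- function(ct) mean(abs(sqrt(rowSums(ct$points^2)) - 1))
  expect_lt(dev(sm), dev(noisy))

  out <- smooth_contour_savgol(noisy, 3L, 2L)
  expect_equal(nrow(out$points), 100L)
  expect_error(smooth_contour_savgol(noisy, 101L, 2L), "window")
  expect_error(smooth_contour_savgol(noisy, 4L, 2L), "odd")
})
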
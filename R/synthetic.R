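# Synthetic paired ED/ES myocardial contours with known ground-truth
# deformation. Analytic circles/annuli stand in for segmented anatomy: the
# registration consumes only ordered 2D contours, and analytic shapes give
# exact oracles for every geometric quantity.

#' Specification of a synthetic myocardial annulus
#'
#' @param center (x, y) center of the annulus.
#' @param r_endo,r_epi endocardial / epicardial radii (0 < r_endo < r_epi).
#'   Defaults 20 and 30 length units, a typical mid-ventricular short-axis
#'   pair in mm.
#' @param n_points points per contour (>= 16).
#' @param noise_sd isotropic Gaussian point jitter SD (truncated at 3 SD),
#'   applied after warping.
#' @param seed RNG seed.
#' @return list of class `ssd_annulus_spec`.
#' @export
annulus_spec <- function(center = c(0, 0), r_endo = 20, r_epi = 30,
                         n_points = 64L, noise_sd = 0, seed = 0L) {
  if (!(r_endo > 0 && r_epi > r_endo)) stop("need 0 < r_endo < r_epi")
  if (n_points < 16L) stop("n_points must be at least 16")
  structure(list(center = center, r_endo = r_endo, r_epi = r_epi,
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ssd_annulus_spec")
}

#' Specification of the ED-to-ES ground-truth deformation
#'
#' @param contraction radial scale factor toward the center applied to the ED
#'   contours to obtain ES (`0 < contraction <= 1`); 0.7 emulates a typical
#'   systolic radial contraction.
#' @param theta_true optional exact c x 2 TPS parameters (with the model they
#'   are defined on, see [apply_true_warp()]) composed after the contraction
#'   for parameter-recovery experiments.
#' @param seed RNG seed.
#' @return list of class `ssd_warp_spec`.
#' @export
warp_spec <- function(contraction = 0.7, theta_true = NULL, seed = 0L) {
  if (!(contraction > 0 && contraction <= 1))
    stop("contraction must be in (0, 1]")
  structure(list(contraction = contraction, theta_true = theta_true,
                 seed = as.integer(seed)),
            class = "ssd_warp_spec")
}

truncated_jitter <- function(n, sd) {
  if (sd == 0) return(matrix(0, n, 2L))
  j <- matrix(stats::rnorm(2L * n, sd = sd), n, 2L)
  pmin(pmax(j, -3 * sd), 3 * sd)
}

circle_points <- function(center, r, n) {
  a <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  cbind(center[1L] + r * cos(a), center[2L] + r * sin(a))
}

#' Generate a paired ED/ES annulus fixture
#'
#' ED is a pair of concentric circles (endo/epi) with optional jitter; ES is
#' the radially contracted copy, optionally composed with an exact TPS warp,
#' with independent jitter. Exact point correspondence is returned, so
#' residual registration error can be measured against a known floor.
#'
#' @param spec an [annulus_spec()].
#' @param warp a [warp_spec()]; if `warp$theta_true` is given, `tps` must be
#'   the `ssd_tps_model` it is defined on (built on the noise-free contracted
#'   points).
#' @param tps optional TPS model for `theta_true` (see [apply_true_warp()]).
#' @return list with `scene` (ED: list of endo/epi contours), `model` (ES:
#'   list of endo/epi contours), `scene_ideal`, `model_ideal` (noise-free
#'   point matrices in correspondence order), `correspondence` (index map,
#'   identity by construction).
#' @export
make_annulus_pair <- function(spec, warp = warp_spec(), tps = NULL) {
  r_es <- c(spec$r_endo, spec$r_epi) * warp$contraction
  if (r_es[2L] <= r_es[1L] || r_es[1L] <= 0)
    stop("contraction violates the radius ordering")
  ed_endo <- circle_points(spec$center, spec$r_endo, spec$n_points)
  ed_epi <- circle_points(spec$center, spec$r_epi, spec$n_points)
  es_endo <- sweep(sweep(ed_endo, 2L, spec$center) * warp$contraction,
                   2L, spec$center, "+")
  es_epi <- sweep(sweep(ed_epi, 2L, spec$center) * warp$contraction,
                  2L, spec$center, "+")
  if (!is.null(warp$theta_true)) {
    if (is.null(tps)) stop("theta_true requires the tps model it is defined on")
    es <- apply_true_warp(rbind(es_endo, es_epi), warp, tps)
    es_endo <- es[seq_len(spec$n_points), , drop = FALSE]
    es_epi <- es[spec$n_points + seq_len(spec$n_points), , drop = FALSE]
  }
  with_seed(spec$seed, {
    ed_endo_n <- ed_endo + truncated_jitter(spec$n_points, spec$noise_sd)
    ed_epi_n <- ed_epi + truncated_jitter(spec$n_points, spec$noise_sd)
    es_endo_n <- es_endo + truncated_jitter(spec$n_points, spec$noise_sd)
    es_epi_n <- es_epi + truncated_jitter(spec$n_points, spec$noise_sd)
  })
  list(scene = list(endo = contour(ed_endo_n, wall = "endo"),
                    epi = contour(ed_epi_n, wall = "epi")),
       model = list(endo = contour(es_endo_n, wall = "endo"),
                    epi = contour(es_epi_n, wall = "epi")),
       scene_ideal = rbind(ed_endo, ed_epi),
       model_ideal = rbind(es_endo, es_epi),
       correspondence = seq_len(2L * spec$n_points))
}

#' Apply an exact ground-truth warp
#'
#' Composes the radial contraction of `warp` (already applied by the caller
#' when generating ES from ED) with the exact TPS transform
#' `tps_transform(tps, warp$theta_true)`. The supplied points must be the
#' rows the TPS model was built on.
#'
#' @param points m x 2 matrix, equal to `tps$M0`.
#' @param warp a [warp_spec()] with non-NULL `theta_true`.
#' @param tps the `ssd_tps_model` the parameters are defined on.
#' @return m x 2 warped points.
#' @export
apply_true_warp <- function(points, warp, tps) {
  if (is.null(warp$theta_true)) stop("warp has no theta_true")
  points <- as_points_matrix(points)
  if (!isTRUE(all.equal(points, tps$M0, tolerance = 1e-12)))
    stop("theta_true is defined on a different point set than supplied")
  if (!all(dim(warp$theta_true) == c(tps$c, 2L)))
    stop("theta_true dimensions do not match the tps model")
  tps_transform(tps, warp$theta_true)
}

#' Small random elastic ground-truth warp for recovery experiments
#'
#' Builds a coarse TPS model on the supplied points and draws a random
#' elastic parameter scaled so the maximum displacement is `max_disp`.
#'
#' @param points m x 2 base points.
#' @param g control-grid side for the warp (coarse, default 4).
#' @param max_disp maximum displacement magnitude of the warp.
#' @param seed RNG seed.
#' @return list with `tps` and a [warp_spec()]-compatible `theta_true`.
#' @export
random_true_warp <- function(points, g = 4L, max_disp = 1, seed = 0L) {
  points <- as_points_matrix(points)
  tps <- tps_model(points, build_control_grid(points, g))
  tau <- with_seed(seed, matrix(stats::rnorm((tps$c - 3L) * 2L), tps$c - 3L, 2L))
  theta <- theta_identity(tps)
  theta[-(1:3), ] <- tau
  disp <- tps_transform(tps, theta) - points
  scale <- max_disp / max(sqrt(rowSums(disp^2)))
  theta[-(1:3), ] <- tau * scale
  list(tps = tps, theta_true = theta)
}

ellipsoid_profile <- function(z, z_lo, z_hi) {
  # smooth apex-to-base cap: radius factor of an ellipsoidal shell, kept
  # away from zero so every slice has a valid annulus
  u <- (z - z_lo) / (z_hi - z_lo)
  sqrt(pmax(1 - 0.6 * u^2, 0.2))
}

#' Generate a paired ED/ES contour-stack fixture
#'
#' Per-slice annuli whose radii follow a smooth ellipsoidal-cap profile along
#' z; the ES stack is radially contracted and may have a different slice
#' count, emulating phase-dependent slice sampling for the long-axis
#' interpolation pipeline.
#'
#' @param spec an [annulus_spec()] (base radii; jitter applied per slice).
#' @param warp a [warp_spec()] (only `contraction` is used).
#' @param z_levels_ED,z_levels_ES slice coordinates of the two phases (>= 2
#'   each).
#' @return list with `ed`, `es` (each a list of endo/epi
#'   [contour_stack()]s) and `profile`, the analytic radius function
#'   `profile(z, r_base, phase)`.
#' @export
make_stack_pair <- function(spec, warp = warp_spec(),
                            z_levels_ED = seq(0, 60, length.out = 9L),
                            z_levels_ES = seq(0, 60, length.out = 7L)) {
  if (length(z_levels_ED) < 2L || length(z_levels_ES) < 2L)
    stop("need at least 2 slices per phase")
  z_lo <- min(z_levels_ED, z_levels_ES)
  z_hi <- max(z_levels_ED, z_levels_ES)
  prof <- function(z, r_base, phase = c("ED", "ES")) {
    phase <- match.arg(phase)
    k <- if (phase == "ES") warp$contraction else 1
    k * r_base * ellipsoid_profile(z, z_lo, z_hi)
  }
  build <- function(z_levels, phase, wall, r_base, seed_off) {
    cts <- lapply(seq_along(z_levels), function(k) {
      z <- z_levels[k]
      P <- circle_points(spec$center, prof(z, r_base, phase), spec$n_points)
      P <- P + with_seed(spec$seed + seed_off + k,
                         truncated_jitter(spec$n_points, spec$noise_sd))
      contour(P, z = z, wall = wall)
    })
    contour_stack(cts, phase = phase)
  }
  list(ed = list(endo = build(z_levels_ED, "ED", "endo", spec$r_endo, 0L),
                 epi = build(z_levels_ED, "ED", "epi", spec$r_epi, 100L)),
       es = list(endo = build(z_levels_ES, "ES", "endo", spec$r_endo, 200L),
                 epi = build(z_levels_ES, "ES", "epi", spec$r_epi, 300L)),
       profile = prof)
}
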
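# Closed-form gradients of the registration objective with respect to the
# stacked TPS parameter theta = [A; tau]. Descriptor terms are differentiated
# on the pre-rotation coordinates (u_i = T_i theta, scene chords H_j): the
# 90-degree rotation is orthogonal, so every norm in the objective is
# unchanged and the printed formulas apply verbatim.

#' Gradient of the position block (plus regularizer)
#'
#' Assembles
#' `dJd/dtheta = [ t([1|M0]) G ; t(Phi N) G + lambda t(N) K N tau ]`
#' where `G = dJd/dM` collects both occurrences of each mapped point in the
#' symmetric self-term and its occurrence in the cross-term.
#'
#' @param problem an [registration_problem()].
#' @param theta c x 2 parameters.
#' @param parts if `TRUE`, attach `G` as an attribute.
#' @return c x 2 gradient matrix.
#' @export
grad_Jd <- function(problem, theta, parts = FALSE) {
  cfg <- problem$config
  M <- tps_transform(problem$tps, theta)
  S <- problem$S
  m <- nrow(M); n <- nrow(S)
  s2 <- cfg$sigma^2
  Wmm <- exp(-cross_sqdist(M, M) / s2)
  Ems <- exp(-cross_sqdist(M, S) / s2)
  G <- (-4 / (m^2 * s2)) * (rowSums(Wmm) * M - Wmm %*% M) +
    (4 / (m * n * s2)) * (rowSums(Ems) * M - Ems %*% S)
  tau <- theta_tau(theta)
  reg <- bending_grad_tau(problem$tps, tau, cfg$lambda)
  g <- crossprod(problem$tps$design, G)
  g[-(1:3), ] <- g[-(1:3), ] + reg
  if (parts) attr(g, "G") <- G
  g
}

#' Gradient of the structure-descriptor block
#'
#' `(beta/m^2) dJ1v/dtheta - (2 beta/mn) dJ2v/dtheta` with
#' `dJ1v = sum_ij k(u_i, u_j) (-2/sigma_v^2) t(T_i - T_j)(T_i - T_j) theta`
#' and
#' `dJ2v = sum_ij k(u_i, v_j) (-2/sigma_v^2) t(T_i)(T_i theta - H_j)`.
#'
#' @inheritParams grad_Jd
#' @return c x 2 gradient matrix (zero when `beta == 0`).
#' @export
grad_Jv <- function(problem, theta) {
  cfg <- problem$config
  if (cfg$beta == 0) return(matrix(0, problem$tps$c, 2L))
  Tmat <- problem$Tmat
  U <- Tmat %*% theta
  H <- problem$H
  m <- nrow(U); n <- nrow(H)
  sv2 <- cfg$sigma_v^2
  Wv <- exp(-cross_sqdist(U, U) / sv2)
  Ev <- exp(-cross_sqdist(U, H) / sv2)
  # sum_ij w_ij t(T_i - T_j)(U_i - U_j) = 2 [t(T)(r * U) - t(T)(Wv U)]
  dJ1 <- (-4 / sv2) * crossprod(Tmat, rowSums(Wv) * U - Wv %*% U)
  dJ2 <- (-2 / sv2) * crossprod(Tmat, rowSums(Ev) * U - Ev %*% H)
  (cfg$beta / m^2) * dJ1 - (2 * cfg$beta / (m * n)) * dJ2
}

#' Full gradient of the registration cost
#' @inheritParams grad_Jd
#' @return c x 2 matrix `grad_Jd + grad_Jv`, the closed-form gradient of
#'   [cost_J()].
#' @export
grad_J <- function(problem, theta) grad_Jd(problem, theta) + grad_Jv(problem, theta)

#' Per-point (stochastic) gradient
#'
#' The gradient of `f(theta, i)`, the part of the objective influenced by one
#' moving model point, as the sum of five addends: the self-kernel term (with
#' both the direct and the through-other-centers occurrences of point i), the
#' scene cross term, the full bending regularizer, and the two descriptor
#' terms.
#'
#' @inheritParams grad_Jd
#' @param i model point index (1-based).
#' @param per_sample_reg if `TRUE`, the regularizer addend is divided by m so
#'   that one epoch of per-point steps applies the same total regularization
#'   as one full-batch step.
#' @param parts if `TRUE`, return a list of the five addends instead of their
#'   sum.
#' @return c x 2 gradient matrix (or list of five such matrices).
#' @export
grad_f_point <- function(problem, theta, i, per_sample_reg = FALSE,
                         parts = FALSE) {
  m <- nrow(problem$M0)
  if (i < 1L || i > m) stop("model point index out of range")
  cfg <- problem$config
  tps <- problem$tps
  M <- tps_transform(tps, theta)
  S <- problem$S
  n <- nrow(S)
  s2 <- cfg$sigma^2
  B_i <- tps$design[i, ]

  dM <- rep(M[i, ], each = m) - M                 # m x 2 rows m_i - m_j
  w <- exp(-rowSums(dM^2) / s2)
  df1 <- (-2 / (m * s2)) * outer(B_i, colSums(w * dM)) +
    (2 / (m * s2)) * crossprod(tps$design, w * dM)

  dS <- rep(M[i, ], each = n) - S
  e <- exp(-rowSums(dS^2) / s2)
  df2 <- (4 / (n * s2)) * outer(B_i, colSums(e * dS))

  df3 <- rbind(matrix(0, 3L, 2L),
               bending_grad_tau(tps, theta_tau(theta), cfg$lambda))
  if (per_sample_reg) df3 <- df3 / m

  if (cfg$beta > 0) {
    sv2 <- cfg$sigma_v^2
    U <- problem$Tmat %*% theta
    T_i <- problem$Tmat[i, ]
    dU <- rep(U[i, ], each = m) - U
    wv <- exp(-rowSums(dU^2) / sv2)
    df4 <- (-2 * cfg$beta / (m * sv2)) *
      (outer(T_i, colSums(wv * dU)) - crossprod(problem$Tmat, wv * dU))
    dH <- rep(U[i, ], each = n) - problem$H
    ev <- exp(-rowSums(dH^2) / sv2)
    df5 <- (4 * cfg$beta / (n * sv2)) * outer(T_i, colSums(ev * dH))
  } else {
    df4 <- df5 <- matrix(0, tps$c, 2L)
  }

  if (parts) list(df1 = df1, df2 = df2, df3 = df3, df4 = df4, df5 = df5)
  else df1 + df2 + df3 + df4 + df5
}
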
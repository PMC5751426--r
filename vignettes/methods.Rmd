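---
title: "Methods: surface-structure-descriptor point-set registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface-structure-descriptor point-set registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(ssdreg)
```

## Problem

Left-ventricle (LV) motion between the cardiac phases is estimated by
registering the end-systole (ES) boundary contours onto the end-diastole (ED)
contours of the same short-axis slice. Each phase contributes an ordered,
closed 2-D point set per wall (endocardium and epicardium). The ED set is the
fixed *scene* $S = \{s_k\}_{k=1}^n$; the ES set is the moving *model*
$M^0 = \{m_i^0\}_{i=1}^m$. The output is a smooth non-rigid map $T_\theta$
such that $T_\theta(M^0) \approx S$, together with per-point displacement
vectors.

## Surface-structure descriptors

Point positions alone make registration of smooth, nearly concentric
contours poorly constrained. Each point is therefore augmented with a
*surface-structure descriptor*: the un-normalized normal direction obtained
by rotating the chord between its two flanking neighbors by 90°,

$$ v_k = H_k R, \qquad H_k = s_{k+1} - s_{k-1}, \qquad
   R = \begin{pmatrix} 0 & -1 \\ 1 & 0 \end{pmatrix}, $$

with wraparound on closed contours (`estimate_normals()`). The magnitude
(the chord length, i.e. the local sampling density) is deliberately kept:
the descriptor term of the objective is linear in these vectors, and the
un-normalized form keeps its gradient exact and simple. Descriptors are
sign-normalized to point outward from the contour centroid
(`orient_normals_outward()`) so corresponding normals on the two phases
cannot anti-align.

Under the deformation the model descriptors are transported by the *frozen
pairing* of the initial model: with $T_i$ the row-difference operator
picking the two neighbors of point $i$ in the TPS design matrix,
$u_i(\theta) = (T\theta R)_i$. The pairing and the outward sign flips are
fixed at $\theta$-evaluation time from $M^0$, which makes the whole
objective a smooth function of $\theta$.

## Transformation model

$T_\theta$ is a thin-plate spline over a $g \times g$ control grid $Q$
(default $g = 10$) covering the joint bounding box of both point sets with
5% padding:

$$ T_\theta(x) = A^\top \tilde x + W^\top \phi(x), \qquad
   \phi_j(x) = -\|x - q_j\|^2 \log \|x - q_j\|^2 . $$

The classical TPS side conditions $[1\,|\,Q]^\top W = 0$ are enforced *by
construction*: $W = N\tau$, where the columns of $N$ form an orthonormal
basis of the left null space of $[1\,|\,Q]$ (computed from a full QR
decomposition). The unconstrained parameter is
$\theta = [A;\tau] \in \mathbb{R}^{c \times 2}$ with $c = g^2$, so the affine
part and the elastic part never fight over the same degrees of freedom, and
every optimizer step stays feasible.

## Objective

Both point sets are represented as isotropic Gaussian mixtures (one
component per point, uniform weights) and compared with the $L_2$ distance
between densities, which has a closed form: the integral of a product of two
Gaussians with variances $\sigma_1^2, \sigma_2^2$ is a Gaussian in the
distance between their means (`gaussian_product_integral()`). Dropping the
$\theta$-free scene self-terms leaves the minimized objective
(`cost_J()`):

$$ J(\theta) = \frac{1}{m^2}\sum_{ij} e^{-\|m_i - m_j\|^2/\sigma^2}
 - \frac{2}{mn}\sum_{ik} e^{-\|m_i - s_k\|^2/\sigma^2}
 + \beta\left[\frac{1}{m^2}\sum_{ij} e^{-\|u_i - u_j\|^2/\sigma_v^2}
 - \frac{2}{mn}\sum_{ik} e^{-\|u_i - v_k\|^2/\sigma_v^2}\right]
 + \frac{\lambda}{2}\,\mathrm{tr}\, W^\top (-K) W $$

with $m_i = T_\theta(m_i^0)$. `cost_full_L2()` adds the constant scene
terms; the two differ by a $\theta$-independent constant (a tested
invariant). Defaults: $\sigma$ = 0.1 × scene bounding-box diagonal,
$\sigma_v = \sigma$, $\beta = 1$, $\lambda = 0.01$. An optional
coarse-to-fine annealing runs the stages $\sigma, \sigma/2, \sigma/4$.

### Sign convention of the bending energy

The TPS kernel matrix $K_{ij} = \phi(\|q_i - q_j\|)$ with
$\phi(r) = -r^2\log r^2$ is *negative* definite on the side-condition
subspace (numerically, all eigenvalues of $N^\top K N$ are below zero). A
penalty $+\mathrm{tr}\,W^\top K W$ would therefore be unbounded below and
reward rough warps — line searches diverge to $-\infty$. This package
defines the bending energy with the sign that makes it a true smoothness
penalty,

$$ E_b(\tau) = \mathrm{tr}\,\tau^\top N^\top(-K)N\,\tau \;\ge\; 0, $$

and uses the matching sign $-\lambda N^\top K N \tau$ in the analytic
gradient. `bending_energy()` is non-negative and invariant to the choice of
orthonormal null-space basis (both tested).

## Gradients and optimization

The gradient of every kernel block is closed-form (`grad_J()`); it is
validated against central finite differences to < 1e-5 relative error over
random problems in the test suite. Two optimizers share these gradients:

* **SGD** (`sgd_optimize()`): per-point stochastic updates using
  `grad_f_point()`, the gradient of the single-point objective $f(\theta,i)$
  whose five addends separate the model self term, the cross term, the
  regularizer, and the two descriptor terms. Averaging the per-point
  gradients with the regularizer counted *once* reproduces the full-batch
  gradient exactly (a tested identity). The step size decays as
  $\eta_t = \eta_0/(1 + 0.01\,t)$; by default $\eta_0$ is calibrated so the
  first parameter step moves points by about $10^{-3}$ of the bounding-box
  diagonal, which keeps the update scale independent of the control-grid
  resolution (the radial basis values grow with the domain, so a fixed
  $\eta_0$ would not transfer across grid sizes). The loop stops after three
  consecutive epochs with relative cost change below tolerance and always
  returns the best parameters seen.
* **Quasi-Newton** (`qn_optimize()`): limited-memory BFGS (`stats::optim`,
  L-BFGS-B) on the flattened parameters, with an iteration budget that
  scales with the parameter count (`max(500, 2c)`). Failures (line-search
  breakdown, non-finite values) are caught and *reported* in the result —
  never raised — because divergence in high-dimensional parameter spaces is
  an expected, handled state.

`register()` chains them (`mode = "sgd_qn"`, the default) or runs
Quasi-Newton alone (`mode = "qn"`). The stochastic stage matters at dense
control grids (e.g. $50^2$): from a cold start the full-batch quadratic
model is poor and QN alone may stall, while SGD's noisy per-point updates
reliably find the basin first. A QN step is only accepted if it converged or
did not increase the cost.

## Geometry utilities

* `resample_contour_bspline()`: interpolating periodic cubic spline,
  uniform index parameterization, for equalizing point counts.
* `interpolate_stack_along_axis()`: section-rotation slice equalization in
  angular form. Every slice is densified in-plane; the long axis is the
  vertical line through the mean of per-slice centroids; for each of
  `n_sections` equally-spaced azimuths the slice-wise radius is
  interpolated along $z$ (cubic for ≥ 4 slices, else linear) and evaluated
  at the requested levels. Extrapolation beyond the stack and open (missing)
  sections are errors.
* `smooth_contour_savgol()`: Savitzky–Golay smoothing with circular padding
  so the seam is treated like any other stretch of boundary.

## Metrics

* `apd()`: average perpendicular distance — mean nearest-point distance
  from mapped points to the reference (directed by default; symmetric and
  point-to-segment variants available).
* `dice_metric()`: $2S_3/(S_1+S_2)$ on contour-enclosed areas. The
  intersection uses exact Sutherland–Hodgman clipping whenever either ring
  is convex (which covers LV-like contours) and a dense midpoint-grid
  estimate when both are non-convex, since no polygon-clipping package is
  assumed.

## Synthetic ground truth

`make_annulus_pair()` generates concentric endo/epi circles (defaults:
radii 20 and 30 length units, 64 points, a typical mid-ventricular pair in
mm) and a radially contracted ES copy (default contraction 0.7), optionally
composed with an exact TPS warp from `random_true_warp()` and truncated
Gaussian jitter. Because the warp is applied through the package's own
transform, recovery experiments have exact point-level ground truth.
`make_stack_pair()` extends this along $z$ with an ellipsoidal-cap radius
profile and phase-dependent slice counts, exercising the slice-equalization
path. These generators are deliberately idealized: they validate the
estimator's behavior under known deformations, not clinical performance.

## Design decisions on open points

* **Slice equalization scheme.** The section-rotation construction is
  implemented in its angular form (azimuthal radius interpolation about the
  centroid axis) rather than by rotating planes, which is equivalent for
  star-shaped LV contours and keeps every interpolated section closed.
* **Descriptor normalization.** Descriptors are kept un-normalized by
  default. Normalizing to unit length would discard sampling-density
  information and make the descriptor gradient nonlinear;
  `cost_config(normalize_scene_normals = TRUE)` exposes the alternative.
* **Walls are registered jointly.** Both walls of a slice enter one
  combined point set under a single transform, so the myocardium deforms
  coherently; per-wall metrics are still reported by `run_pipeline()`.

## Worked example

```{r example}
spec <- annulus_spec(n_points = 48, noise_sd = 0, seed = 1)
base <- make_annulus_pair(spec, warp_spec(contraction = 0.7))
rw <- random_true_warp(base$model_ideal, g = 4, max_disp = 1.5, seed = 1)
pair <- make_annulus_pair(spec, warp_spec(0.7, theta_true = rw$theta_true,
                                          seed = 1), tps = rw$tps)

scene_pts <- do.call(rbind, lapply(pair$scene, `[[`, "points"))
model_pts <- do.call(rbind, lapply(pair$model, `[[`, "points"))
apd(model_pts, scene_pts)            # pre-registration error

res <- register(pair$scene, pair$model, cost_config(grid_side = 10),
                mode = "qn")
res$converged
apd(res$mapped, scene_pts)           # post-registration error
```

```{r plot, echo = FALSE}
plot(scene_pts, asp = 1, pch = 1, col = "grey40",
     xlab = "x", ylab = "y", main = "ES contours registered onto ED")
points(model_pts, pch = 4, col = "tomato")
points(res$mapped, pch = 20, col = "royalblue")
legend("topright", pch = c(1, 4, 20), col = c("grey40", "tomato", "royalblue"),
       legend = c("scene (ED)", "model (ES)", "mapped"), bty = "n")
```
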
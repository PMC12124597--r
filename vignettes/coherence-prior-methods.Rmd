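---
title: "Coherence-prior artifact removal: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence-prior artifact removal: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(risp)
```

## The problem and the model

Photoacoustic tomography reconstructs an initial-pressure map from
time-resolved pressure traces recorded by an array of `N` ultrasound
elements. When the array is sparse or covers a limited angle, analytic
reconstructions (delay-and-sum, universal back-projection) are exact
nowhere and every absorber leaks streaks across the field of view.
Model-based iterative reconstruction fixes this at the price of repeated
forward-model solves; this package implements the alternative of
refining an already-reconstructed image under a data-derived structural
prior, so the acoustic model is never touched after the initial
reconstructions.

The prior exploits configuration sensitivity. Reconstruct the same
channel data `k` times, each time from a random subset of `s < N`
elements, giving images `R_1, ..., R_k`. At a pixel holding a true
absorber the subset images agree; at a streak pixel they fluctuate,
because the streak geometry depends on which elements participate.
Per-pixel coherence

$$D = \frac{(R_1 + \cdots + R_k)^2}{k\,(R_1^2 + \cdots + R_k^2)} \in [0, 1]$$

(Cauchy–Schwarz gives the bound; equality requires all values equal and
nonzero) quantifies that agreement. `D` is converted to a probability
map in two steps: multiplication by the cumulative-Gaussian integral

$$P = D \int_{v_{\min}}^{D} \Phi(v \mid \mu, \sigma)\,dv,
\qquad \mu = \tfrac{v_{\max}+v_{\min}}{2},\ \sigma = \tfrac{v_{\max}-v_{\min}}{6},$$

which pushes the distribution toward its extremes (strong coherent
pixels toward 1, weak ones toward 0, without discarding weak-but-stable
signal), followed by min–max normalization to `Pnorm` in `[0, 1]`. The
`sigma` convention spans the coherence range with six standard
deviations, so `Phi` transitions across essentially the whole observed
range of `D`.

The refinement minimizes, over images `R_op` started at the normalized
full-array reconstruction `R_N`,

$$\lambda_{con}\,\lVert R_N - R_{op}\rVert_F^2 +
  \lambda_{reg}\,\lVert (1 - P_{norm}) \odot R_{op}\rVert_F^2 .$$

The objective is convex and separable per pixel with unique minimizer
`lambda_con R_N / (lambda_con + lambda_reg (1 - Pnorm)^2)` — a
prior-modulated shrinkage: never amplification, full preservation where
`Pnorm = 1`, shrinkage by `lambda_con / (lambda_con + lambda_reg)` where
`Pnorm = 0`. The iterative optimizer exists because at the parameter
sets used in practice (small learning rate, 50–150 iterations) the
refinement is deliberately early-stopped, which caps the per-pixel
displacement and acts as an additional implicit regularizer; the
analytic minimizer is kept as a test oracle
(`closed_form_solution()`).

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `s` | ~`N/10` | subset size; small enough that subsets differ markedly, large enough that each reconstructs recognizable structure |
| `k` | 50 (2D ring preset: 100) | number of subsets; averaging depth of the coherence statistic |
| `lambda_con`, `lambda_reg` | 0.1 / 0.9 (2D ring preset: 0.2 / 0.8) | convex weights of anchoring vs suppression |
| `learning_rate` | 0.001 | adaptive-step scale; with `num_iters` bounds total per-pixel displacement |
| `num_iters` | 50 (2D ring preset: 150) | early-stopping point |
| `adam_beta1/2`, `adam_eps` | 0.9 / 0.999 / 1e-8 | standard first/second-moment constants |

`risp_preset()` bundles the three reference acquisition setups
(`"hemisphere-3d"`, `"ring-2d"`, `"synthetic-matrix-3d"`), whose weights
always satisfy `lambda_con + lambda_reg = 1`.

## Optimizer: why AMSGrad by default

The named optimizer for this family of methods is Adam. On this convex
quadratic objective, however, plain Adam does not settle: once the
iterate reaches the minimizer the gradients vanish, the second-moment
estimate decays exponentially, and the effective step size re-inflates,
kicking the iterate into a small limit cycle (observed here at amplitude
near `lr/10`; a known non-convergence phenomenon of Adam on convex
problems). Since the refinement contract is "converge to the unique
minimizer as iterations grow", the default `variant = "amsgrad"` keeps a
running maximum of the bias-corrected second moment — identical behavior
in the early, practically relevant iterations, and provably monotone
step bounds afterwards. `variant = "adam"` provides the plain update.

Two printed-formula ambiguities are resolved on the side of the stated
losses, each with a compatibility switch:

* the data-consistency gradient is implemented with the descent sign
  `2 (R_op - R_N)` (the sign that decreases the loss);
* the regularization gradient defaults to the exact derivative
  `2 (1 - Pnorm)^2 R_op` of the stated loss; the linearized variant
  `2 (1 - Pnorm) R_op` (also a descent direction) is available as
  `grad_rg_mode = "as-printed"`.

## Numerical conventions

* **Coordinates.** SI meters throughout; voxel centers at
  `origin + index * spacing` (0-based index); R arrays are indexed
  1-based, column-major, axis 1 = x.
* **Forward model.** Circular (2D) / spherical (3D) mean transform:
  voxel mass is accumulated into half-open nearest-bin distance shells
  of width `c/fs`, normalized by the exact annulus area / shell volume,
  then differentiated in time by central differences. It is linear,
  produces the bipolar wideband pulse shape and genuine sparse-view
  streaks, and replaces full-wave simulation at desk scale. One
  consequence worth knowing: the simulated pulse is antisymmetric about
  the arrival time, so *raw DAS* interpolates a null exactly at a point
  source (the flanking lobes carry the energy); the UBP filter
  `2p - 2t dp/dt` restores an extremum at arrival and UBP images peak at
  the source.
* **Back-projection weights.** Uniform (no solid-angle factor), with
  `1/|elements|` normalization. Element-exchangeable weights make the
  full-array reconstruction exactly the mean of reconstructions over any
  disjoint element partition, which is what justifies interpreting
  cross-subset agreement as coherence. Subset images are deliberately
  *not* renormalized individually.
* **Subsets.** Drawn uniformly without replacement within a subset,
  independently across subsets (overlap allowed); a disjoint-partition
  mode exists. Plans are pure functions of `(N, s, k, seed)`.
* **Degenerate cases.** Pixels with zero energy across all subsets get
  `D = 0` (no signal; the regularizer then suppresses them). A constant
  coherence or prior field yields `Pnorm = 1` everywhere with a warning:
  a non-discriminating prior must not suppress anything. Floating-point
  overshoot of the Cauchy–Schwarz bound is clamped so `D` is exactly in
  `[0, 1]`. The step function in the prior integral is taken inclusive
  at its upper limit (`u(0) = 1`), a measure-zero choice fixed for
  determinism.
* **Normalization.** `R_N` and the refined image live on a magnitude
  scale: absolute value, then min–max to `[0, 1]` (records kept for
  inversion; a signed mode exists). Metrics are computed after
  independent per-image normalization of the same kind.
* **Metrics.** PSNR with peak 1; mean local SSIM with a uniform 7-wide
  window per axis (population moments, valid interior positions,
  `C1 = 1e-4`, `C2 = 9e-4`); CNR as `20 log10(|Δmean|/sd_noise)` with a
  `10 log10` power variant; line correlations along explicit voxel
  paths.

## What the synthetic generator does and does not emulate

The fixture generator produces disk phantoms (exact rasterization,
additive overlaps) and seeded random-walk vessel phantoms with Gaussian
tube profiles, on ring or Fibonacci-scheme hemispherical arrays (the
hemisphere keeps a configurable element-free aperture cap for
illumination). This exercises every pipeline stage with realistic
sparse-view streaks. It does **not** emulate acoustic heterogeneity,
attenuation, element directivity, finite element size, transducer
impulse response, or quantitatively calibrated pressure amplitudes —
so green tests demonstrate the method's mechanics and its artifact
suppression on idealized data, not performance on any particular
scanner.

The bundled demonstration (`ring_demo_config()`) scales the 2D ring
study down to a 64-element ring, a 128 × 128 grid at 0.2 mm, 30 subsets
of 8 elements, and the 2D-ring refinement parameters; it runs in
seconds. The test suite uses 16–65 voxel grids per axis so the whole
suite stays under a minute.

## Known limitations

* The prior is only as good as the subset reconstructions: in extremely
  sparse or strongly limited-angle setups the artifacts dominate every
  subset and become "coherent", so the method's premise fails.
* Large filled homogeneous absorbers are represented mostly by their
  edges in derivative-based reconstructions; interiors get low coherence
  and are attenuated. Thin, vessel-like structures are the favorable
  target class.
* The multiplicative DAS variant sometimes paired with this method is
  not implemented; plain DAS is.
* The demo compares against the simulation's own phantom; no measured
  data ships with the package (the HDF5 reader is the entry point for
  real acquisitions).
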
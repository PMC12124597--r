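# risp

Coherence-prior artifact removal for photoacoustic tomography.

Sparse or limited-view detector arrays cannot satisfy exact reconstruction
conditions, so delay-and-sum (DAS) and universal back-projection (UBP)
images of photoacoustic data carry streak artifacts. The observation this
package operationalizes: **true absorbers reconstruct consistently no
matter which detector elements are used, while artifacts fluctuate with
the detection configuration.** That makes artifacts identifiable without
ever solving the acoustic forward model during the iteration.

## Method

Given channel data from `N` elements, draw `k` random subsets of
`s < N` elements and reconstruct one image `R_i` per subset. Per-pixel
coherence of the stack is

```
D = (R_1 + ... + R_k)^2 / (k (R_1^2 + ... + R_k^2))   in [0, 1],
```

which is 1 exactly where all subset reconstructions agree (true signal)
and small where they fluctuate (streaks, noise). The coherence is
sharpened into a probability map by weighting with a Gaussian-CDF
integral over the coherence range (`mu = (vmax + vmin)/2`,
`sigma = (vmax - vmin)/6`):

```
P = D * integral_vmin^D  Phi(v | mu, sigma) dv,
Pnorm = (P - min P) / (max P - min P)
```

`Pnorm` then steers a convex quadratic refinement of the normalized
full-array reconstruction `R_N`, minimizing

```
lambda_con * || R_N - R_op ||_F^2  +  lambda_reg * || (1 - Pnorm) . R_op ||_F^2
```

with an adaptive first-order optimizer (AMSGrad-stabilized Adam) started
at `R_op = R_N`. Low-probability pixels are shrunk toward zero;
high-probability pixels stay anchored to the measured image. The
objective is separable with unique minimizer
`lambda_con R_N / (lambda_con + lambda_reg (1 - Pnorm)^2)`, which the
package also exposes as an analytic oracle for testing.

The package is self-contained: ring and hemispherical array geometries,
disk/vessel phantoms, an analytic circular/spherical-mean forward model,
DAS/UBP reconstruction, the prior and optimizer, PSNR/SSIM/CNR/line-
correlation metrics, and HDF5/TIFF/NIfTI I/O.

## Worked example

The bundled demo reconstructs a three-disk phantom seen by a sparse
64-element ring (128 x 128 grid, 0.2 mm spacing), builds the prior from
30 random 8-element subsets, and refines with `lambda_con = 0.2`,
`lambda_reg = 0.8`, 150 iterations:

```r
library(risp)
res <- run_all(ring_demo_config(), "demo-out")
str(res$report)
#> $ recon :List of 3        # plain UBP vs ground-truth phantom
#>  ..$ psnr_db                   : num 16.74
#>  ..$ ssim                      : num 0.04888
#>  ..$ background_energy_fraction: num 0.4387
#> $ risp  :List of 3        # after the coherence-prior refinement
#>  ..$ psnr_db                   : num 16.82
#>  ..$ ssim                      : num 0.2935
#>  ..$ background_energy_fraction: num 0.2277
```

The refinement halves the fraction of image energy lying outside the
true absorbers (0.44 to 0.23), raises SSIM six-fold, and nudges PSNR up —
streaks are suppressed while the anchored disks survive. `demo-out/`
holds the channel data (`channel_data.h5`), the normalized UBP image,
prior and refined image (float32 TIFF), the loss trace (CSV), the subset
plan and metric report (JSON).

A thin command-line dispatcher over the same functions ships in
`inst/cli/risp` (subcommands `simulate`, `reconstruct`, `prior`,
`optimize`, `metrics`, `run-all`).

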
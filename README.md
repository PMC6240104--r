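# matirf

Near-surface 3D super-resolution reconstruction for multi-angle
evanescent-wave (variable-angle TIRF) microscopy combined with structured
illumination (TIRF-SIM), in R. The package is aimed at microscopists and
image-analysis developers who record (or simulate) two kinds of raw data
from the same field:

* a **nine-frame TIRF-SIM set** (3 pattern orientations × 3 phases) that
  yields a lateral super-resolution image, and
* a **multi-angle TIRF stack** — images at a series of supercritical
  incidence angles, optionally replicated over azimuthal beam directions
  ("ring" illumination) — that encodes fluorophore depth in the
  inter-angle intensity decay,

and want per-pixel depth maps and near-surface volumes with
tens-of-nanometer axial accuracy over the first ~600 nm above the
coverslip.

## The model

Beyond the critical angle θc = arcsin(n₂/n₁), the evanescent excitation
decays exponentially with depth:

    I(θ, z) = I₀(θ) · exp(−z / d(θ)),   d(θ) = λ / (4π √(n₁² sin²θ − n₂²))

Discretizing depth into M bins gives a K×M system matrix
A[k, m] = I₀(θk)·exp(−z_m/d(θk)). For every pixel inside a binary mask
(derived from the SIM reconstruction), the background-subtracted
per-angle intensities b are inverted by non-negative, sparsity-regularized
least squares,

    min_{f ≥ 0}  ½‖A f − b‖² + μ‖f‖₁ ,

solved by ADMM (projected-gradient and NNLS solvers ship as
cross-checks). The per-pixel mean depth h = Σ z_m f_m / Σ f_m and the
axial profiles f form the depth map and the reconstructed volume. The
lateral channel uses the standard SIM band algebra: phase-mixing
separation, pattern estimation by whitened band cross-correlation, and
generalized Wiener combination on a twofold finer grid.

A full synthetic-data generator (microtubule networks, surface-labeled
microspheres, line pairs, beads, with Gaussian noise at controlled SNR)
plus a validation harness (Monte-Carlo depth-RMSE grids, spherical-cap
fitting, line-pair resolution tests) make every claim testable without an
instrument. See the methods vignette (`vignettes/matirf-methods.Rmd`) for
the assumptions and numerical choices.

## Worked example

Simulate a near-surface microtubule network, image it at 20 angles
(61.5°–71°, 4 azimuths, SNR 30), and reconstruct:

```r
library(matirf)

cfg    <- optical_config()        # 488 nm, NA 1.49, n1 1.518, n2 1.33, 52 nm px
angles <- angle_sequence(61.5, 0.5, 20, n_azimuth = 4L)
scene  <- make_microtubule_scene(4, extent_nm = 96 * 52,
                                 z_range_nm = c(0, 300), seed = 42)
stack  <- render_matirf_stack(scene, angles, cfg,
                              noise = noise_model(snr = 30, seed = 7),
                              npx = 96)
result <- run_pipeline(stack)     # mask -> background -> ADMM -> depth map
print(result$depth_map)
depth_rmse(result$depth_map, scene, cfg$pixel_nm, stack$psf_fwhm_nm)
```

which prints

```
depth_map: 478 in-mask pixels; mean h = 99.18 nm (range  14.06-278.24 )
[1] 12.95582
```

i.e. 478 pixels survived the Otsu mask, their mean reconstructed depth is
99 nm (the filaments wander between 0 and 300 nm), and the per-pixel
depth error against the generator's ground truth is about 13 nm RMSE at
this SNR and depth range. `render_depth(result$depth_map)` turns the map
into the usual hue-codes-depth, brightness-codes-intensity rendering, and
`assemble_volume(result$field)` produces the x–y–z stack.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/matirf.R simulate --preset sphere --seed 1 --out data/
Rscript inst/cli/matirf.R pipeline --in data/matirf.tif --out out/
```

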
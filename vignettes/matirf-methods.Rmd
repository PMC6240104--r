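---
title: "Methods: multi-angle evanescent-wave depth reconstruction with structured illumination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-angle evanescent-wave depth reconstruction with structured illumination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matirf)
```

## The imaging model

Total internal reflection at the coverslip–sample interface produces an
evanescent excitation field that decays exponentially with depth $z$:

$$ I(\theta, z) = I_0(\theta)\, e^{-z / d(\theta)}, \qquad
   d(\theta) = \frac{\lambda}{4\pi\sqrt{n_1^2 \sin^2\theta - n_2^2}} $$

for incidence angles beyond the critical angle
$\theta_c = \arcsin(n_2/n_1)$. Steeper incidence gives a shallower field,
so a series of images at increasing $\theta$ encodes the axial position of
every fluorophore in the first few hundred nanometers above the glass. With
the default optics (488 nm excitation, $n_1 = 1.518$, $n_2 = 1.33$,
$\theta_c \approx 61.2°$) the penetration depth runs from roughly 374 nm at
61.5° down to 72 nm at 71°, which is why a 20-angle sweep over that range is
the package's default acquisition geometry.

The interface intensity $I_0(\theta)$ uses the s-polarized Fresnel
transmission, $4\cos^2\theta / (1 - (n_2/n_1)^2)$, matching instruments that
rotate both beams to s-polarization; a `unit` mode ($I_0 \equiv 1$) is
available because the reconstruction is deliberately insensitive to the
absolute excitation efficiency, and some instruments calibrate it away.

Discretizing depth into $M$ bins (default 0–600 nm in 10 nm steps — the
usable evanescent volume at a quarter of the method's nominal ~40 nm axial
resolution) gives the $K \times M$ system matrix
$A_{km} = I_0(\theta_k) e^{-z_m/d(\theta_k)}$. This matrix is severely
ill-conditioned (condition number $\sim 10^{17}$ for the default grids):
the inversion is only meaningful with non-negativity and sparsity
constraints, which is the core of the method.

## Lateral channel: TIRF-SIM

Nine raw frames — three sinusoidal illumination orientations (0°, 60°,
120°) times three phases (0, $2\pi/3$, $4\pi/3$) — are reduced to a
lateral super-resolution image by the standard band algebra: per
orientation the three phase-stepped spectra mix the center band
$\tilde S(f)H(f)$ and two shifted bands
$\tfrac{m}{2}e^{\pm i\varphi_0}\tilde S(f \mp k)H(f)$ through an invertible
$3\times3$ system. Design choices:

* **Nominal phases.** Phase steps are taken as exactly 0, $2\pi/3$,
  $4\pi/3$ with a single global phase $\varphi_0$ estimated per
  orientation; piezo-calibrated phase stepping justifies this over
  per-frame phase optimization.
* **Pattern estimation by whitened cross-correlation.** The wave vector is
  the peak of the cross-correlation between the center and shifted bands.
  Both bands are first Wiener-whitened ($H/(H^2 + 0.1^2)$); without
  whitening the correlation is dominated by low-frequency image content and
  the peak is unreliable on sparse scenes. The integer peak is refined to
  subpixel precision by direct maximization of the correlation magnitude,
  and $\varphi_0$ and $m$ follow from an OTF-ratio-weighted complex
  amplitude ratio over the band overlap, which is unbiased for any object
  spectrum. A single point emitter carries no pattern-frequency
  information (its modulation collapses to a constant phase factor), so
  estimation requires structured scenes; for calibration phantoms rendered
  by this package the known pattern can be supplied directly
  (`pattern_from_rawset()`).
* **Generalized Wiener combination.** Bands are moved to their true
  frequency positions on a twofold finer grid (26 nm pixels from 52 nm raw)
  and combined as $\sum_b H_b D_b / (\sum_b H_b^2 + w^2)$ with $w = 0.1$
  by default.
* **Apodization.** The combined spectrum is tapered by
  $(1 - f/f_{apo})^{1/2}$ to the extended cutoff
  $f_{apo} = |k| + 2\mathrm{NA}/\lambda_{em}$. A plain triangular taper
  ($\gamma = 1$) was found too aggressive: on the noiseless 100 nm
  line-pair phantom it leaves only a 14% dip between the peaks, below the
  20% Rayleigh-like criterion, while the square-root taper preserves a 40%
  dip with no visible ringing and the same strict support bound (spectrum
  energy beyond $f_{apo}$ stays below $10^{-6}$ of the total). The
  exponent is exposed (`apod_gamma`).
* **OTF model.** The detection OTF defaults to the Gaussian matching the
  renderer's PSF (FWHM $\lambda_{em}/2\mathrm{NA}$ with a 20 nm Stokes
  shift), zeroed beyond the diffraction cutoff; the ideal circular-pupil
  OTF is available. The ~3% truncation discontinuity at the cutoff is
  absorbed by the apodization.

## Mask and background

The super-resolution image is thresholded (Otsu by default) into a binary
mask that keeps in-focus structure and discards diffraction-limited
background; on the raw grid a pixel is in-mask if *any* of its four SR
subpixels passes (conservative, favors coverage). Externally produced
masks — e.g. from a trained segmentation tool — can be supplied instead.

The local background is the median of off-mask pixels in coarse window
tiles (default 32 px ≈ 1.7 μm), bilinearly interpolated under the mask and
subtracted, with negatives clamped to zero (the inversion needs
non-negative data). Two robustness rules matter in practice, both found on
the microsphere phantom where a naive estimator subtracts the structure's
own halo and corrupts the inter-angle ratios that carry the depth signal:

* the mask is dilated by `guard_px = 6` pixels (≈ 2 PSF FWHM) before
  background pixels are sampled;
* a tile contributes only if at least 30% of its pixels are clean,
  otherwise it is filled from the nearest clean tile.

Background subtraction is idempotent and preserves the inter-angle
intensity order of point sources, which is the quantity the inversion
actually uses.

## Axial channel: the non-negative sparse inversion

Per masked pixel, the vector $b$ of background-subtracted intensities over
angles is inverted against $A$:

$$ \min_{f \ge 0} \tfrac12 \lVert A f - b\rVert_2^2 + \mu \lVert f\rVert_1 $$

Axial profiles of membranes and filaments are sparse on a 10 nm grid, and
the $\ell_1$ term also suppresses the noise mass that the non-negativity
constraint would otherwise rectify into deep bins.

* **Column normalization.** Columns of $A$ are $\ell_2$-normalized
  internally (compensated on output); this improves conditioning and fixes
  the scale on which $\mu$ acts.
* **ADMM.** The default solver splits $f = g$ with $g \ge 0$
  soft-thresholded, uses over-relaxation ($\alpha = 1.8$), residual-balanced
  penalty adaptation ($\rho \times 2 / \div 2$ when the scaled residual
  ratio exceeds 10), and stops when both scaled residuals fall below
  $10^{-6}$ or at 500 iterations. On the exponential system matrix the
  formal residual criterion can stall even though the objective and the
  depth estimate have long converged; non-convergence is therefore reported
  as a per-pixel flag and QC map rather than an error. Pixels are
  independent subproblems; the batched implementation keeps each pixel's
  trajectory self-contained, so results are bit-identical under any pixel
  ordering.
* **Choosing $\mu$.** Two modes. `relative`: $\mu = 0.01 \cdot \lVert A^T
  b\rVert_\infty$ per pixel, brightness-invariant, the right choice when no
  noise estimate exists. `sigma` (used by the pipeline whenever the
  background step has estimated the noise): the universal soft-threshold
  level $\sigma\sqrt{2\log M}$, with $\sigma$ the additive-noise standard
  deviation estimated by the MAD of clean off-mask residuals. The sigma
  rule adapts to per-pixel brightness automatically — on dim pixels it
  prunes the spurious deep-bin mass that otherwise biases the mean depth
  upward by tens of nanometers, while on bright pixels it is negligible.
  For noiseless data it reduces to plain non-negative least squares.
* **Cross-checks.** A projected accelerated gradient solver and an
  active-set NNLS solver ship alongside; ADMM agrees with the NNLS optimum
  to $10^{-6}$ of the data energy on random instances and with the
  gradient solver to $10^{-4}$ relative objective.

The per-pixel depth statistic is the intensity-weighted mean
$h = \sum_m z_m f_m / \sum_m f_m$; an ROI-pooled variant
(`roi_mean_depth()`) pools profiles before reducing, for quoting one depth
per structure. Stacking the $f_m$ maps gives the near-surface volume, whose
depth-sum reproduces the intensity map exactly.

## The synthetic-data generator

The generator emulates the study conditions the reconstruction is
validated against:

* **Microtubule networks**: cubic-spline-smoothed random walks sampled as
  point emitters every 20 nm with 25 nm radial jitter and smoothly varying
  depth; gamma-distributed brightness.
* **Surface-labeled microspheres**: emitters uniform on the lower cap of a
  4.86 μm sphere touching the coverslip, truncated at 500 nm depth (beyond
  the excitation volume). The default density of 800 labels/μm² renders a
  visually continuous shell at 52 nm pixels.
* **Line pairs and beads**: resolution and localization targets.

Image formation is scalar: emitters are excited by $I(\theta, z)$ (times
the sinusoidal pattern for SIM frames), placed with subpixel accuracy
through a normalized Gaussian detection PSF, and corrupted by additive
white Gaussian noise with $\sigma = \max(\text{noiseless pixel})/\mathrm{SNR}$.
Frames at different azimuthal beam directions share the noiseless image and
differ only in noise, so ring averaging is a pure $1/\sqrt{n}$ noise
reduction — the scalar model has no azimuthal inhomogeneity to average
away. Negative noisy pixels are stored unclipped to preserve noise
statistics for the solvers.

What the generator does **not** model — and what passing its tests
therefore does not establish about real data: Poisson/EMCCD gain noise,
photobleaching, sample motion, refractive-index mismatch between the
assumed and true $n_2$, aberrated or spatially varying PSFs, azimuthal
field inhomogeneity, and out-of-focus background from deep structure.
The experimental depth error reported for instrument data (tens of
nanometers over 0–500 nm) is dominated by exactly these unmodeled terms;
the simulation reproduces the *trends* (error grows with depth, shrinks
with SNR) and the near-coverslip accuracy floor.

## Validation harness and problem sizes

`rmse_vs_snr_curve()` Monte-Carlos a single emitter per cell (rendered on a
17 px field, ROI-pooled over the PSF support, inverted, reduced to $h$) and
reports RMSE with per-cell standard errors; all reports carry their seeds
and are bit-reproducible. The package's own validation runs use 100
realizations for the headline near-coverslip cell and 30 per cell for the
3×3 depth×SNR trend grid; the sphere pipeline runs on a 5 μm (96 px) field
with 20 angles × 4 azimuths; line-pair reconstructions use 128 px fields.
These sizes keep a full validation pass in the minutes range on one core
while leaving every acceptance margin comfortably resolved.

`fit_sphere_cap()` fits $h(x,y) = R - \sqrt{R^2 - r^2}$ by
Levenberg–Marquardt with the contact point free, over in-mask pixels with
$h \le 500$ nm. `line_pair_resolved()` applies the two-maxima/20%-dip
criterion to the profile perpendicular to the lines;
`fwhm()` linearly interpolates half-maximum crossings.

## Known limitations

* Depth accuracy on extended structures is limited by lateral PSF mixing:
  neighboring columns at different depths blend, biasing $h$ toward the
  brighter (shallower) contributor near steep slopes. On the sphere
  phantom this leaves a ~2% diameter bias floor even noiselessly.
* The reconstruction assumes the supplied $n_2$; errors propagate directly
  into $d(\theta)$ and hence into every depth.
* Pattern parameters cannot be estimated from unstructured or point-like
  scenes (supply the known pattern for calibration phantoms).
* The ADMM convergence flag is conservative on the ill-conditioned default
  grids; consult the QC map rather than treating every unconverged pixel
  as invalid.
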
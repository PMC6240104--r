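#' Gaussian additive noise model
#'
#' Additive white Gaussian noise at a controlled peak signal-to-noise ratio.
#' The noise standard deviation is `(maximum noiseless pixel over all frames
#' of a rendered set) / snr`, so `snr` is the peak-SNR of the brightest
#' structure in the set.
#'
#' @param snr peak-signal to noise-sd ratio (> 0); `Inf` for noiseless.
#' @param seed integer seed for the noise stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(snr = 30, seed = 1L) {
  stopifnot(is.numeric(snr), snr > 0)
  structure(list(kind = "gaussian", snr = snr, seed = as.integer(seed)),
            class = "noise_model")
}

default_psf_fwhm <- function(config, stokes_nm = 20) {
  (config$wavelength_nm + stokes_nm) / (2 * config$na)
}

# additively paint emitters into nf frames; weights is n_emitters x nf.
# Continuous emitter positions; truncated separable Gaussian patch per
# emitter, normalized to unit sum over its support.
paint_frames <- function(scene, weights, npx, pixel_nm, sigma_nm) {
  nf <- ncol(weights)
  frames <- array(0, dim = c(npx, npx, nf))
  if (nrow(scene) == 0) return(frames)
  sig_px <- sigma_nm / pixel_nm
  half <- max(1L, ceiling(4 * sig_px))
  # pixel-center coordinates: pixel i spans [(i-1), i]*pixel, center (i-0.5)
  colc <- scene$x_nm / pixel_nm + 0.5  # fractional col index of emitter
  rowc <- scene$y_nm / pixel_nm + 0.5
  for (e in seq_len(nrow(scene))) {
    ic <- round(rowc[e]); jc <- round(colc[e])
    ri <- max(1L, ic - half):min(npx, ic + half)
    cj <- max(1L, jc - half):min(npx, jc + half)
    if (!length(ri) || !length(cj)) next
    gy <- exp(-((ri - rowc[e])^2) / (2 * sig_px^2))
    gx <- exp(-((cj - colc[e])^2) / (2 * sig_px^2))
    patch <- outer(gy, gx)
    patch <- patch / sum(patch)
    w <- weights[e, ]
    frames[ri, cj, ] <- frames[ri, cj, , drop = FALSE] +
      array(as.vector(patch) %o% w, dim = c(length(ri), length(cj), nf))
  }
  frames
}

add_gaussian_noise <- function(frames, noise) {
  if (is.null(noise) || !is.finite(noise$snr)) {
    return(list(frames = frames, sigma = 0))
  }
  sigma <- max(frames) / noise$snr
  frames <- withr::with_seed(noise$seed, {
    frames + array(stats::rnorm(length(frames), 0, sigma), dim = dim(frames))
  })
  list(frames = frames, sigma = sigma)
}

#' Render a multi-angle TIRF stack
#'
#' Forward model of the axial channel: for each polar incidence angle the
#' scene's emitters are excited by the evanescent field
#' `I(theta, z) = I0(theta) exp(-z/d(theta))`, imaged through a Gaussian
#' detection PSF, and (optionally) corrupted by additive white Gaussian noise
#' with sd `max(noiseless pixel)/snr`. The image formation is scalar: frames
#' recorded at different azimuthal beam directions share the same noiseless
#' image and differ only in their noise realization, which is what makes
#' azimuthal (ring) averaging a pure noise-reduction step in this model.
#'
#' Negative pixels arising from the additive noise are kept; clipping is a
#' display-time decision.
#'
#' @param scene a [scene()].
#' @param angle_grid an [angle_grid()]; frames are ordered azimuth-fastest,
#'   angle-major.
#' @param config an [optical_config()].
#' @param noise a [noise_model()] or `NULL` for noiseless.
#' @param psf_fwhm_nm detection PSF FWHM (nm); default
#'   `(wavelength + 20)/(2 NA)` (20 nm Stokes shift).
#' @param npx field size in raw pixels (square).
#' @param intensity_model interface-intensity model, see
#'   [interface_intensity()].
#' @return An object of class `matirf_stack`: list with `frames`
#'   (npx x npx x K*n_azimuth array), `angle_grid`, `config`, `noise`,
#'   `noise_sigma`, `psf_fwhm_nm`, `intensity_model`, `scene_provenance`.
#' @export
render_matirf_stack <- function(scene, angle_grid, config, noise = NULL,
                                psf_fwhm_nm = NULL, npx = 256,
                                intensity_model = c("fresnel", "unit")) {
  intensity_model <- match.arg(intensity_model)
  stopifnot(inherits(scene, "scene"), inherits(angle_grid, "angle_grid"),
            inherits(config, "optical_config"))
  if (!is.null(noise) && !inherits(noise, "noise_model"))
    stop("noise must be a noise_model or NULL")
  .check_supercritical(angle_grid$theta_deg, config)
  theta <- angle_grid$theta_deg
  naz <- angle_grid$n_azimuth
  sigma_nm <- (if (is.null(psf_fwhm_nm)) default_psf_fwhm(config)
               else psf_fwhm_nm) / (2 * sqrt(2 * log(2)))
  i0 <- interface_intensity(theta, config, intensity_model)
  d <- penetration_depth(theta, config)
  # excitation weight per emitter per angle
  w <- scene$brightness *
    t(i0 * exp(outer(-1 / d, scene$z_nm)))        # n_emitters x K
  if (nrow(scene) == 0) w <- matrix(0, 0, length(theta))
  base <- paint_frames(scene, w, npx, config$pixel_nm, sigma_nm)
  # replicate per azimuth: azimuth-fastest, angle-major frame order
  frames <- base[, , rep(seq_along(theta), each = naz), drop = FALSE]
  ns <- add_gaussian_noise(frames, noise)
  structure(list(frames = ns$frames, angle_grid = angle_grid,
                 config = config, noise = noise, noise_sigma = ns$sigma,
                 psf_fwhm_nm = if (is.null(psf_fwhm_nm))
                   default_psf_fwhm(config) else psf_fwhm_nm,
                 intensity_model = intensity_model,
                 scene_provenance = attr(scene, "provenance")),
            class = "matirf_stack")
}

#' @export
print.matirf_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("matirf_stack:", d[3], "frames of", d[1], "x", d[2], "px (",
      length(x$angle_grid$theta_deg), "angles x",
      x$angle_grid$n_azimuth, "azimuths )\n")
  if (!is.null(x$noise))
    cat("  gaussian noise, SNR =", x$noise$snr, ", sigma =",
        format(x$noise_sigma, digits = 4), "\n")
  invisible(x)
}

#' Render a nine-frame SIM raw set
#'
#' Forward model of the lateral channel: two counter-propagating evanescent
#' waves interfere to produce a sinusoidal illumination pattern
#' `I(theta, z) [1 + m cos(2 pi k.r + phi)]` at the emitter, for three pattern
#' orientations (0, 60, 120 degrees) times three phases (0, 2pi/3, 4pi/3).
#' Each frame is imaged through the Gaussian detection PSF; noise is added as
#' in [render_matirf_stack()]. Frame order is phase-fastest,
#' orientation-major.
#'
#' @param scene a [scene()].
#' @param config an [optical_config()].
#' @param pattern_freq_fraction pattern spatial frequency as a fraction of
#'   the detection cutoff `2 NA / lambda_em` (0 < fraction <= 1).
#' @param modulation pattern modulation depth m in (0, 1].
#' @param tirf_theta_deg incidence angle of the interfering beams; default
#'   0.5 degrees above the critical angle.
#' @param noise a [noise_model()] or `NULL`.
#' @param psf_fwhm_nm detection PSF FWHM (nm); default as in
#'   [render_matirf_stack()].
#' @param npx field size in raw pixels.
#' @param orientations_deg three pattern orientations (degrees).
#' @param intensity_model interface-intensity model.
#' @return An object of class `sim_rawset`: `frames` (npx x npx x 9),
#'   `pattern` (list with `k_cyc_nm` 3x2 matrix of wave vectors,
#'   `phases`, `modulation`, `orientations_deg`), `tirf_theta_deg`, `config`,
#'   `noise`, `noise_sigma`, `psf_fwhm_nm`.
#' @export
render_sim_rawset <- function(scene, config, pattern_freq_fraction = 0.9,
                              modulation = 0.9, tirf_theta_deg = NULL,
                              noise = NULL, psf_fwhm_nm = NULL, npx = 256,
                              orientations_deg = c(0, 60, 120),
                              intensity_model = c("fresnel", "unit")) {
  intensity_model <- match.arg(intensity_model)
  stopifnot(inherits(scene, "scene"), inherits(config, "optical_config"),
            length(orientations_deg) == 3)
  if (!(pattern_freq_fraction > 0 && pattern_freq_fraction <= 1))
    stop("pattern_freq_fraction must be in (0, 1]")
  if (!(modulation > 0 && modulation <= 1))
    stop("modulation m must be in (0, 1]")
  if (is.null(tirf_theta_deg))
    tirf_theta_deg <- critical_angle(config$n1, config$n2) + 0.5
  .check_supercritical(tirf_theta_deg, config)
  if (is.null(psf_fwhm_nm)) psf_fwhm_nm <- default_psf_fwhm(config)
  sigma_nm <- psf_fwhm_nm / (2 * sqrt(2 * log(2)))
  lambda_em <- config$wavelength_nm + 20
  cutoff <- 2 * config$na / lambda_em           # cycles/nm, detection cutoff
  kmag <- pattern_freq_fraction * cutoff
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  kvec <- kmag * cbind(cos(deg2rad(orientations_deg)),
                       sin(deg2rad(orientations_deg)))  # 3 x 2 (kx, ky)
  exc <- evanescent_profile(tirf_theta_deg, scene$z_nm, config,
                            intensity_model)
  w <- matrix(0, nrow(scene), 9)
  f <- 0
  for (o in 1:3) for (p in 1:3) {
    f <- f + 1
    arg <- 2 * pi * (kvec[o, 1] * scene$x_nm + kvec[o, 2] * scene$y_nm) +
      phases[p]
    w[, f] <- scene$brightness * exc * (1 + modulation * cos(arg))
  }
  frames <- paint_frames(scene, w, npx, config$pixel_nm, sigma_nm)
  ns <- add_gaussian_noise(frames, noise)
  structure(list(frames = ns$frames,
                 pattern = list(k_cyc_nm = kvec, phases = phases,
                                modulation = modulation,
                                orientations_deg = orientations_deg,
                                freq_fraction = pattern_freq_fraction),
                 tirf_theta_deg = tirf_theta_deg, config = config,
                 noise = noise, noise_sigma = ns$sigma,
                 psf_fwhm_nm = psf_fwhm_nm,
                 intensity_model = intensity_model,
                 scene_provenance = attr(scene, "provenance")),
            class = "sim_rawset")
}

#' @export
print.sim_rawset <- function(x, ...) {
  d <- dim(x$frames)
  cat("sim_rawset: 9 frames of", d[1], "x", d[2], "px; |k| =",
      format(sqrt(sum(x$pattern$k_cyc_nm[1, ]^2)), digits = 4),
      "cyc/nm, m =", x$pattern$modulation, "\n")
  invisible(x)
}
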
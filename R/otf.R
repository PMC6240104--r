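#' Detection OTF model
#'
#' Radially symmetric incoherent detection OTF used by band separation,
#' pattern estimation and Wiener combination. Two shapes are available:
#' `"gaussian"` (the OTF of a Gaussian PSF with the given FWHM, set to zero
#' beyond the diffraction cutoff `2 NA / lambda_em`) and `"diffraction"`
#' (the ideal incoherent OTF of a circular pupil). The Gaussian shape is the
#' default because it matches the Gaussian detection PSF of the renderer.
#'
#' @param config an [optical_config()].
#' @param shape `"gaussian"` or `"diffraction"`.
#' @param psf_fwhm_nm PSF FWHM for the Gaussian shape; default
#'   `(wavelength + 20)/(2 NA)`.
#' @param stokes_nm Stokes shift used for the emission wavelength (nm).
#' @return An object of class `otf_model` with fields `cutoff` (cycles/nm),
#'   `eval` (vectorized function of radial frequency in cycles/nm), `shape`.
#' @export
otf_model <- function(config, shape = c("gaussian", "diffraction"),
                      psf_fwhm_nm = NULL, stokes_nm = 20) {
  shape <- match.arg(shape)
  lambda_em <- config$wavelength_nm + stokes_nm
  cutoff <- 2 * config$na / lambda_em
  if (is.null(psf_fwhm_nm)) psf_fwhm_nm <- lambda_em / (2 * config$na)
  sig <- psf_fwhm_nm / (2 * sqrt(2 * log(2)))
  eval_fun <- if (shape == "gaussian") {
    function(f) ifelse(f < cutoff, exp(-2 * pi^2 * sig^2 * f^2), 0)
  } else {
    function(f) {
      v <- pmin(f / cutoff, 1)
      ifelse(f < cutoff, (2 / pi) * (acos(v) - v * sqrt(1 - v^2)), 0)
    }
  }
  structure(list(cutoff = cutoff, eval = eval_fun, shape = shape,
                 psf_fwhm_nm = psf_fwhm_nm, lambda_em = lambda_em),
            class = "otf_model")
}

#' @export
print.otf_model <- function(x, ...) {
  cat("otf_model (", x$shape, "): cutoff =", format(x$cutoff, digits = 4),
      "cyc/nm (", format(1 / x$cutoff, digits = 4), "nm )\n")
  invisible(x)
}

# signed FFT frequency indices for length n (R fft layout, DC first)
fft_freq_idx <- function(n) {
  l <- 0:(n - 1)
  ifelse(l < ceiling(n / 2), l, l - n)
}

# matrix of radial frequencies (cycles/nm) for an n x n image, offset by
# (kx, ky) cycles/nm; rows = y frequency, cols = x frequency
freq_radius <- function(n, pixel_nm, kx = 0, ky = 0) {
  f1 <- fft_freq_idx(n) / (n * pixel_nm)
  fy <- matrix(f1 + ky, n, n)
  fx <- matrix(f1 + kx, n, n, byrow = TRUE)
  sqrt(fx^2 + fy^2)
}
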
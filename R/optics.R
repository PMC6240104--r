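#' Optical configuration
#'
#' Bundle of the physical constants shared by every stage of the pipeline:
#' excitation wavelength, objective numerical aperture, refractive indices of
#' the immersion/coverslip side (`n1`) and the sample medium (`n2`), and the
#' raw pixel size in sample space.
#'
#' Total internal reflection requires `n2 < n1`; the numerical aperture cannot
#' exceed `n1`. Defaults correspond to a 1.49-NA oil-immersion TIRF objective
#' (standard immersion oil, n1 = 1.518) imaging an aqueous sample (n2 = 1.33)
#' at 488 nm with 52 nm pixels. `n2` should be overridden with the measured
#' refractive index of each sample.
#'
#' @param wavelength_nm excitation wavelength in vacuum (nm).
#' @param na objective numerical aperture.
#' @param n1 refractive index on the illumination side (immersion/coverslip).
#' @param n2 refractive index of the sample medium; must be `< n1`.
#' @param pixel_nm raw image pixel size in sample space (nm).
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' critical_angle(cfg$n1, cfg$n2)
#' @export
optical_config <- function(wavelength_nm = 488, na = 1.49,
                           n1 = 1.518, n2 = 1.33, pixel_nm = 52) {
  stopifnot(is.numeric(wavelength_nm), wavelength_nm > 0,
            is.numeric(pixel_nm), pixel_nm > 0,
            is.numeric(na), na > 0)
  if (!(n2 < n1))
    stop("total internal reflection requires n2 < n1 (got n2 = ", n2,
         ", n1 = ", n1, ")")
  if (na > n1)
    stop("numerical aperture cannot exceed n1 (got na = ", na,
         ", n1 = ", n1, ")")
  structure(list(wavelength_nm = wavelength_nm, na = na, n1 = n1, n2 = n2,
                 pixel_nm = pixel_nm),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("optical_config: lambda =", x$wavelength_nm, "nm, NA =", x$na,
      ", n1 =", x$n1, ", n2 =", x$n2, ", pixel =", x$pixel_nm, "nm\n")
  cat("  critical angle:", format(critical_angle(x$n1, x$n2), digits = 5),
      "deg\n")
  invisible(x)
}

#' Polar incidence-angle grid
#'
#' Ordered set of supercritical polar incidence angles, optionally replicated
#' over several azimuthal beam directions (ring illumination). All angles must
#' exceed the critical angle of the configuration they are used with; that is
#' checked where the grid meets a configuration (e.g. [build_system_matrix()]).
#'
#' @param theta_deg strictly increasing polar angles (degrees).
#' @param n_azimuth azimuthal directions recorded per polar angle (>= 1).
#' @return An object of class `angle_grid`.
#' @seealso [angle_sequence()] for the start/step/count constructor.
#' @export
angle_grid <- function(theta_deg, n_azimuth = 1L) {
  theta_deg <- as.numeric(theta_deg)
  stopifnot(length(theta_deg) >= 1, all(is.finite(theta_deg)),
            n_azimuth >= 1)
  if (is.unsorted(theta_deg, strictly = TRUE))
    stop("theta_deg must be strictly increasing")
  if (any(theta_deg >= 90))
    stop("incidence angles must be below 90 degrees")
  structure(list(theta_deg = theta_deg, n_azimuth = as.integer(n_azimuth)),
            class = "angle_grid")
}

#' Angle grid from start/step/count
#'
#' Convenience constructor mirroring how variable-angle acquisitions are
#' specified on the instrument: a start angle, an angular step and a count
#' (e.g. 20 angles with a 0.50 degree step starting from 61.64 degrees).
#'
#' @param start_deg first polar angle (degrees).
#' @param step_deg angular step (degrees, > 0).
#' @param n number of angles (>= 2).
#' @param n_azimuth azimuthal directions per polar angle.
#' @return An `angle_grid`.
#' @export
angle_sequence <- function(start_deg, step_deg, n, n_azimuth = 1L) {
  stopifnot(step_deg > 0, n >= 2)
  angle_grid(start_deg + step_deg * (seq_len(n) - 1), n_azimuth)
}

#' Axial depth grid
#'
#' Uniform grid of depth-bin centers for the axial inverse problem. Depth is
#' measured from the coverslip-sample interface (z = 0) into the sample.
#' The default 0-600 nm range with 10 nm bins covers the usable evanescent
#' depth volume at a quarter of the method's nominal axial resolution.
#'
#' @param z_max_nm deepest bin center (nm).
#' @param bin_nm bin width (nm).
#' @param z_min_nm shallowest bin center (nm, >= 0).
#' @return An object of class `axial_grid` with fields `z_nm` and `bin_nm`.
#' @export
axial_grid <- function(z_max_nm = 600, bin_nm = 10, z_min_nm = 0) {
  stopifnot(z_min_nm >= 0, bin_nm > 0, z_max_nm >= z_min_nm)
  z <- seq(z_min_nm, z_max_nm, by = bin_nm)
  structure(list(z_nm = z, bin_nm = bin_nm), class = "axial_grid")
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Critical angle of total internal reflection
#'
#' @param n1 refractive index on the illumination side.
#' @param n2 refractive index of the sample medium (`n2 < n1`).
#' @return The critical angle `asin(n2/n1)` in degrees.
#' @examples
#' critical_angle(1.518, 1.33)  # ~61.2 deg, aqueous sample under oil immersion
#' @export
critical_angle <- function(n1, n2) {
  if (!(n2 > 0 && n2 < n1))
    stop("no total internal reflection possible: need 0 < n2 < n1")
  rad2deg(asin(n2 / n1))
}

.check_supercritical <- function(theta_deg, config) {
  thc <- critical_angle(config$n1, config$n2)
  bad <- theta_deg <= thc | theta_deg >= 90
  if (any(bad))
    stop("incidence angle(s) outside (critical angle, 90): ",
         paste(format(theta_deg[bad], digits = 6), collapse = ", "),
         " (critical angle = ", format(thc, digits = 6), " deg)")
  invisible(thc)
}

#' Evanescent-wave penetration depth
#'
#' Depth at which the evanescent intensity decays to 1/e of its value at the
#' interface: `d = lambda / (4 pi sqrt(n1^2 sin^2(theta) - n2^2))`. Strictly
#' decreasing in the incidence angle; diverges as the angle approaches the
#' critical angle from above.
#'
#' @param theta_deg incidence angle(s), degrees, strictly between the critical
#'   angle and 90.
#' @param config an [optical_config()].
#' @return Penetration depth(s) in nm.
#' @export
penetration_depth <- function(theta_deg, config) {
  .check_supercritical(theta_deg, config)
  s <- config$n1 * sin(deg2rad(theta_deg))
  config$wavelength_nm / (4 * pi * sqrt(s^2 - config$n2^2))
}

#' Evanescent intensity at the interface
#'
#' Relative intensity of the evanescent field at z = 0 for s-polarized
#' illumination: `I0 = 4 cos^2(theta) / (1 - (n2/n1)^2)` (Fresnel transmission
#' into the evanescent field). Equals 4 exactly at the critical angle and
#' falls to 0 at grazing incidence. With `model = "unit"` the interface
#' intensity is taken as 1 at every angle, which is useful when the absolute
#' excitation efficiency is unknown and only the exponential depth decay is
#' modeled.
#'
#' @param theta_deg incidence angle(s), degrees, supercritical.
#' @param config an [optical_config()].
#' @param model `"fresnel"` (s-polarized, default) or `"unit"`.
#' @return Relative intensity at z = 0 (dimensionless).
#' @export
interface_intensity <- function(theta_deg, config,
                                model = c("fresnel", "unit")) {
  model <- match.arg(model)
  thc <- critical_angle(config$n1, config$n2)
  bad <- theta_deg < thc | theta_deg >= 90
  if (any(bad))
    stop("incidence angle(s) outside [critical angle, 90): ",
         paste(format(theta_deg[bad], digits = 6), collapse = ", "))
  if (model == "unit") return(rep(1, length(theta_deg)))
  4 * cos(deg2rad(theta_deg))^2 / (1 - (config$n2 / config$n1)^2)
}

#' Evanescent intensity profile
#'
#' Excitation intensity at depth z for a supercritical incidence angle:
#' `I(theta, z) = I0(theta) * exp(-z / d(theta))`.
#'
#' @param theta_deg scalar incidence angle (degrees, supercritical).
#' @param z_nm depth(s) above the coverslip (nm, >= 0).
#' @param config an [optical_config()].
#' @param model interface-intensity model, see [interface_intensity()].
#' @return Intensity value(s), same length as `z_nm`.
#' @export
evanescent_profile <- function(theta_deg, z_nm, config,
                               model = c("fresnel", "unit")) {
  stopifnot(length(theta_deg) == 1)
  if (any(z_nm < 0)) stop("depth z_nm must be >= 0")
  i0 <- interface_intensity(theta_deg, config, model)
  d <- penetration_depth(theta_deg, config)
  i0 * exp(-z_nm / d)
}

#' Angle-by-depth system matrix of the axial inverse problem
#'
#' Discretizes the evanescent forward model onto an angle grid (rows) and an
#' axial grid (columns): `A[k, m] = I0(theta_k) * exp(-z_m / d(theta_k))`.
#' Each row decays with depth; for a fixed depth bin the normalized response
#' `A[k, m] / A[k, 1]` decreases with the incidence angle (shallower
#' penetration at steeper incidence), which is the signal the depth inversion
#' exploits.
#'
#' @param angle_grid an [angle_grid()].
#' @param axial_grid an [axial_grid()].
#' @param config an [optical_config()].
#' @param normalized if `TRUE`, the matrix is scaled by the maximum of its
#'   first column so the peak z = 0 response is 1.
#' @param model interface-intensity model, see [interface_intensity()].
#' @return An object of class `system_matrix` with fields `a` (K x M matrix),
#'   `angle_grid`, `axial_grid`, `normalized`, `model`, and `condition`
#'   (2-norm condition number of `a`).
#' @export
build_system_matrix <- function(angle_grid, axial_grid, config,
                                normalized = FALSE,
                                model = c("fresnel", "unit")) {
  model <- match.arg(model)
  stopifnot(inherits(angle_grid, "angle_grid"),
            inherits(axial_grid, "axial_grid"),
            inherits(config, "optical_config"))
  .check_supercritical(angle_grid$theta_deg, config)
  theta <- angle_grid$theta_deg
  z <- axial_grid$z_nm
  i0 <- interface_intensity(theta, config, model)
  d <- penetration_depth(theta, config)
  a <- i0 * exp(outer(-1 / d, z))        # K x M
  if (normalized) a <- a / max(a[, 1])
  structure(list(a = a, angle_grid = angle_grid, axial_grid = axial_grid,
                 normalized = normalized, model = model,
                 condition = kappa(a, exact = length(z) <= 200)),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat("system_matrix:", nrow(x$a), "angles x", ncol(x$a), "depth bins",
      sprintf("(theta %.2f-%.2f deg, z %g-%g nm, %s I0%s)\n",
              min(x$angle_grid$theta_deg), max(x$angle_grid$theta_deg),
              min(x$axial_grid$z_nm), max(x$axial_grid$z_nm), x$model,
              if (x$normalized) ", normalized" else ""))
  cat("  condition number:", format(x$condition, digits = 4), "\n")
  invisible(x)
}
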
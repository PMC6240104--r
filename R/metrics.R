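#' Ground-truth depth map of a scene
#'
#' Rasterizes the scene's emitter depths onto the pixel grid as either the
#' PSF-weighted mean depth contributing to each pixel (`"weighted"`,
#' default — the truth a profile-reconstructing method should recover) or
#' the depth of the nearest emitter (`"nearest"`).
#'
#' @param scene a [scene()].
#' @param npx image side (raw pixels).
#' @param pixel_nm pixel size (nm).
#' @param psf_fwhm_nm PSF FWHM used for the weighting.
#' @param truth `"weighted"` or `"nearest"`.
#' @return Matrix of per-pixel true depth (nm); `NA` where no emitter
#'   contributes.
#' @export
scene_depth_truth <- function(scene, npx, pixel_nm, psf_fwhm_nm,
                              truth = c("weighted", "nearest")) {
  truth <- match.arg(truth)
  sig <- psf_fwhm_nm / (2 * sqrt(2 * log(2)))
  if (truth == "weighted") {
    w <- paint_frames(scene, matrix(scene$brightness, ncol = 1), npx,
                      pixel_nm, sig)[, , 1]
    wz <- paint_frames(scene, matrix(scene$brightness * scene$z_nm,
                                     ncol = 1), npx, pixel_nm, sig)[, , 1]
    out <- wz / w
    out[w <= max(w) * 1e-6] <- NA_real_
    out
  } else {
    out <- matrix(NA_real_, npx, npx)
    cc <- (seq_len(npx) - 0.5) * pixel_nm
    for (i in seq_len(npx)) for (j in seq_len(npx)) {
      d2 <- (scene$x_nm - cc[j])^2 + (scene$y_nm - cc[i])^2
      e <- which.min(d2)
      if (d2[e] < (3 * sig)^2) out[i, j] <- scene$z_nm[e]
    }
    out
  }
}

#' Depth RMSE against scene ground truth
#'
#' Root mean square error of the reconstructed per-pixel mean depth against
#' the scene's ground-truth depth, over in-mask pixels where both are
#' defined.
#'
#' @param dmap a [depth_map()].
#' @param scene the generating [scene()].
#' @param pixel_nm raw pixel size (nm).
#' @param psf_fwhm_nm PSF FWHM for the ground-truth weighting.
#' @param truth see [scene_depth_truth()].
#' @return RMSE in nm.
#' @export
depth_rmse <- function(dmap, scene, pixel_nm, psf_fwhm_nm,
                       truth = c("weighted", "nearest")) {
  stopifnot(inherits(dmap, "depth_map"))
  if (!any(dmap$mask)) stop("empty mask")
  ht <- scene_depth_truth(scene, nrow(dmap$h), pixel_nm, psf_fwhm_nm,
                          truth)
  sel <- dmap$mask & is.finite(dmap$h) & is.finite(ht)
  if (!any(sel)) stop("no pixels with both reconstructed and true depth")
  sqrt(mean((dmap$h[sel] - ht[sel])^2))
}

# one Monte-Carlo depth estimate: render a single emitter, pool the
# PSF-support ROI per angle, invert
.point_depth_estimate <- function(z_nm, snr, agrid, config, axgrid, params,
                                  seed, roi_half = 4L, npx = 17L,
                                  a = NULL) {
  sc <- make_point_scene(z_nm = z_nm, extent_nm = npx * config$pixel_nm)
  st <- render_matirf_stack(sc, agrid, config,
                            noise = if (is.finite(snr))
                              noise_model(snr, seed) else NULL,
                            npx = npx)
  if (is.null(a)) a <- build_system_matrix(agrid, axgrid, config)
  ctr <- (npx + 1) %/% 2
  ri <- max(1, ctr - roi_half):min(npx, ctr + roi_half)
  b <- apply(st$frames[ri, ri, , drop = FALSE], 3, sum)
  # the ROI sum of w^2 iid noise pixels has sd w * sigma
  sigma_roi <- st$noise_sigma * length(ri)
  depth_from_profile(solve_pixel(b, a, params, sigma = sigma_roi), axgrid)
}

#' Monte-Carlo depth-accuracy grid
#'
#' Repeatedly simulates a single fluorophore at each (true depth, SNR) cell,
#' runs the depth inversion, and reports the RMSE of the recovered mean
#' depth from the true depth, with a per-cell standard error. Reproduces
#' the simulation design behind the method's accuracy analysis: accuracy
#' degrades with depth and improves with SNR.
#'
#' @param snr_list SNR values (may include `Inf` for noiseless).
#' @param depth_list true depths (nm).
#' @param angle_grid an [angle_grid()].
#' @param n_reps noise realizations per cell (>= 30 for reported cells).
#' @param seed base seed; realization r of a cell uses an offset seed, so
#'   the whole grid is reproducible.
#' @param config an [optical_config()].
#' @param axial_grid an [axial_grid()].
#' @param params a [solver_params()].
#' @return An object of class `rmse_report`: `rmse` (depth x SNR matrix,
#'   nm), `se` (standard errors), `n_reps`, `seed`, `depth_list`,
#'   `snr_list`.
#' @export
rmse_vs_snr_curve <- function(snr_list = 30, depth_list = c(0, 200, 400),
                              angle_grid = angle_sequence(61.5, 0.5, 20),
                              n_reps = 100, seed = 1L,
                              config = optical_config(),
                              axial_grid = matirf::axial_grid(),
                              params = solver_params(mu_mode = "sigma")) {
  stopifnot(n_reps >= 30)
  a <- build_system_matrix(angle_grid, axial_grid, config)
  rmse <- se <- matrix(NA_real_, length(depth_list), length(snr_list),
                       dimnames = list(paste0("z", depth_list),
                                       paste0("snr", snr_list)))
  cell <- 0L
  for (di in seq_along(depth_list)) for (si in seq_along(snr_list)) {
    cell <- cell + 1L
    err2 <- vapply(seq_len(n_reps), function(r) {
      h <- .point_depth_estimate(depth_list[di], snr_list[si], angle_grid,
                                 config, axial_grid, params,
                                 seed = seed + 7919L * cell + r, a = a)
      (h - depth_list[di])^2
    }, numeric(1))
    rmse[di, si] <- sqrt(mean(err2))
    se[di, si] <- stats::sd(err2) / (2 * sqrt(n_reps) * max(rmse[di, si],
                                                            1e-9))
  }
  structure(list(rmse = rmse, se = se, n_reps = n_reps, seed = seed,
                 depth_list = depth_list, snr_list = snr_list),
            class = "rmse_report")
}

#' @export
print.rmse_report <- function(x, ...) {
  cat("rmse_report (", x$n_reps, "reps, seed", x$seed, "), RMSE in nm:\n")
  print(round(x$rmse, 2))
  invisible(x)
}

#' Spherical-cap fit of a depth map
#'
#' Least-squares fit of the coverslip-attached sphere model
#' `h(x, y) = R - sqrt(R^2 - r^2)`, `r^2 = (x - x0)^2 + (y - y0)^2`, to the
#' in-mask pixels of a depth map with `h <= h_max_nm`. Used to recover the
#' diameter of a surface-labeled calibration microsphere.
#'
#' @param dmap a [depth_map()].
#' @param pixel_nm raw pixel size (nm).
#' @param h_max_nm depth cut for pixels entering the fit.
#' @return An object of class `sphere_fit`: `radius_nm`, `diameter_um`,
#'   `center_nm` (x0, y0), `residual_rms_nm`, `n_pixels`.
#' @export
fit_sphere_cap <- function(dmap, pixel_nm, h_max_nm = 500) {
  stopifnot(inherits(dmap, "depth_map"))
  sel <- which(dmap$mask & is.finite(dmap$h) & dmap$h <= h_max_nm,
               arr.ind = TRUE)
  if (nrow(sel) < 20) stop("fewer than 20 valid pixels for the sphere fit")
  h <- dmap$h[sel]
  x <- (sel[, 2] - 0.5) * pixel_nm
  y <- (sel[, 1] - 0.5) * pixel_nm
  w <- dmap$intensity[sel]
  x0 <- sum(w * x) / sum(w); y0 <- sum(w * y) / sum(w)
  r2 <- (x - x0)^2 + (y - y0)^2
  ok <- h > 1
  r0 <- stats::median((r2[ok] + h[ok]^2) / (2 * h[ok]))
  df <- data.frame(h = h, x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      h ~ R - sqrt(pmax(R^2 - (x - cx)^2 - (y - cy)^2, 0)),
      data = df, start = list(R = r0, cx = x0, cy = y0),
      lower = c(R = 1, cx = -Inf, cy = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("sphere-cap fit failed: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(radius_nm = unname(co["R"]),
                 diameter_um = unname(2 * co["R"] / 1000),
                 center_nm = unname(co[c("cx", "cy")]),
                 residual_rms_nm = sqrt(mean(stats::resid(fit)^2)),
                 n_pixels = nrow(sel)),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "sphere_fit: diameter %.3f um (R = %.1f nm), residual RMS %.1f nm over %d px\n",
    x$diameter_um, x$radius_nm, x$residual_rms_nm, x$n_pixels))
  invisible(x)
}

# perpendicular intensity profile of an image whose lines run along `axis`
.line_profile <- function(img, axis = c("y", "x"), band_frac = 0.5) {
  axis <- match.arg(axis)
  if (axis == "x") img <- t(img)   # lines along x -> transpose
  n <- nrow(img)
  keep <- round(n / 2 + c(-1, 1) * n * band_frac / 2)
  colMeans(img[max(1, keep[1]):min(n, keep[2]), , drop = FALSE])
}

# parabolic subpixel refinement of a discrete peak position
.subpixel_peak <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(i)
  d <- (v[i - 1] - v[i + 1]) / (2 * (v[i - 1] - 2 * v[i] + v[i + 1]))
  i + d
}

#' Two-line resolution test on a reconstructed image
#'
#' Takes the intensity profile perpendicular to a rendered line pair and
#' applies a Rayleigh-like criterion: the pair is resolved iff the profile
#' shows two local maxima whose valley dips by at least `min_dip_fraction`
#' below the lower peak.
#'
#' @param img an `sr_image`, or a plain matrix.
#' @param pixel_nm pixel size of `img` (taken from an `sr_image`
#'   automatically).
#' @param axis axis the lines run along (`"y"` default).
#' @param min_dip_fraction required relative dip (default 0.2).
#' @return List with `resolved` (flag), `separation_nm` (distance of the two
#'   peaks, `NA` if unresolved), `dip` (achieved relative dip).
#' @export
line_pair_resolved <- function(img, pixel_nm = NULL, axis = c("y", "x"),
                               min_dip_fraction = 0.2) {
  if (inherits(img, "sr_image")) {
    if (is.null(pixel_nm)) pixel_nm <- img$pixel_nm
    img <- img$image
  }
  if (is.null(pixel_nm)) stop("pixel_nm required for a plain matrix")
  prof <- .line_profile(img, axis)
  prof <- pmax(prof, 0)
  if (max(prof) <= 0 || stats::sd(prof) < 1e-12 * max(abs(prof)))
    return(list(resolved = FALSE, separation_nm = NA_real_, dip = 0))
  n <- length(prof)
  locmax <- which(prof > c(-Inf, utils::head(prof, -1)) &
                    prof >= c(utils::tail(prof, -1), -Inf))
  locmax <- locmax[prof[locmax] > 0.1 * max(prof)]
  if (length(locmax) < 2)
    return(list(resolved = FALSE, separation_nm = NA_real_, dip = 0))
  top <- locmax[order(prof[locmax], decreasing = TRUE)][1:2]
  top <- sort(top)
  valley <- min(prof[top[1]:top[2]])
  dip <- 1 - valley / min(prof[top])
  sep <- abs(.subpixel_peak(prof, top[2]) -
               .subpixel_peak(prof, top[1])) * pixel_nm
  list(resolved = dip >= min_dip_fraction, separation_nm = sep, dip = dip)
}

#' Full width at half maximum of a single-peaked profile
#'
#' Linear-interpolated FWHM. A profile with more than one local maximum
#' above half maximum is rejected (use [line_pair_resolved()] for pairs).
#'
#' @param profile numeric intensity profile (baseline near zero).
#' @param x positions of the samples (nm); defaults to `0, 1, 2, ...`
#'   (FWHM then in samples).
#' @return FWHM in the units of `x`.
#' @export
fwhm <- function(profile, x = seq_along(profile) - 1) {
  stopifnot(length(profile) == length(x), length(profile) >= 3)
  pk <- which.max(profile)
  half <- profile[pk] / 2
  above <- profile > half
  locmax <- which(profile > c(-Inf, utils::head(profile, -1)) &
                    profile >= c(utils::tail(profile, -1), -Inf) &
                    above)
  if (length(locmax) > 1)
    stop("profile has multiple peaks above half maximum; ",
         "use line_pair_resolved()")
  li <- max(which(!above[seq_len(pk)]), 0)
  ri <- pk - 1 + min(which(!above[pk:length(profile)]), Inf)
  if (li == 0 || !is.finite(ri))
    stop("profile does not fall below half maximum on both sides")
  xl <- x[li] + (half - profile[li]) / (profile[li + 1] - profile[li]) *
    (x[li + 1] - x[li])
  xr <- x[ri - 1] + (half - profile[ri - 1]) /
    (profile[ri] - profile[ri - 1]) * (x[ri] - x[ri - 1])
  xr - xl
}
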
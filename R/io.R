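#' Write a multi-angle or SIM stack to TIFF + JSON sidecar
#'
#' Frames are stored as a multi-page 32-bit float TIFF (values linearly
#' mapped to [0, 1]; the affine restore parameters live in the sidecar), and
#' all metadata — angle grid, optical configuration, noise record, pattern
#' parameters, provenance — as a JSON sidecar next to it. Page order is
#' azimuth-fastest/angle-major for multi-angle stacks and
#' phase-fastest/orientation-major for SIM sets.
#'
#' @param stack a `matirf_stack` or `sim_rawset`.
#' @param path output path; `.tif` is appended if missing, the sidecar is
#'   `<path>.json`.
#' @return Invisibly, the TIFF path.
#' @export
write_stack <- function(stack, path) {
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  sidecar <- paste0(sub("\\.tiff?$", "", path), ".json")
  fr <- stack$frames
  off <- min(fr)
  scl <- max(fr) - off
  if (scl == 0) scl <- 1
  pages <- lapply(seq_len(dim(fr)[3]), function(i) (fr[, , i] - off) / scl)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(kind = if (inherits(stack, "sim_rawset")) "sim" else "matirf",
               n_frames = dim(fr)[3], npx = dim(fr)[1],
               offset = off, scale = scl,
               config = unclass(stack$config),
               noise = if (!is.null(stack$noise)) unclass(stack$noise),
               noise_sigma = stack$noise_sigma,
               psf_fwhm_nm = stack$psf_fwhm_nm,
               intensity_model = stack$intensity_model,
               scene_provenance = stack$scene_provenance)
  if (inherits(stack, "sim_rawset")) {
    meta$pattern <- list(k_cyc_nm = stack$pattern$k_cyc_nm,
                         phases = stack$pattern$phases,
                         modulation = stack$pattern$modulation,
                         orientations_deg = stack$pattern$orientations_deg,
                         freq_fraction = stack$pattern$freq_fraction)
    meta$tirf_theta_deg <- stack$tirf_theta_deg
  } else {
    meta$angles_deg <- stack$angle_grid$theta_deg
    meta$n_azimuth <- stack$angle_grid$n_azimuth
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' Validates the sidecar against the TIFF (frame count, kind) and rebuilds
#' the corresponding object.
#'
#' @param path TIFF path (with or without extension).
#' @return A `matirf_stack` or `sim_rawset` according to the sidecar.
#' @export
read_stack <- function(path) {
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  sidecar <- paste0(sub("\\.tiff?$", "", path), ".json")
  if (!file.exists(sidecar))
    stop("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_frames)
    stop("sidecar lists ", meta$n_frames, " frames but the TIFF has ",
         length(pages), " pages")
  fr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    fr[, , i] <- p * meta$scale + meta$offset
  }
  cfg <- do.call(optical_config, meta$config[c("wavelength_nm", "na", "n1",
                                               "n2", "pixel_nm")])
  noise <- if (!is.null(meta$noise))
    noise_model(meta$noise$snr, meta$noise$seed)
  common <- list(frames = fr, config = cfg, noise = noise,
                 noise_sigma = meta$noise_sigma %||% 0,
                 psf_fwhm_nm = meta$psf_fwhm_nm,
                 intensity_model = meta$intensity_model %||% "fresnel",
                 scene_provenance = meta$scene_provenance)
  if (identical(meta$kind, "sim")) {
    if (length(pages) != 9)
      stop("a SIM raw set must have 9 pages, found ", length(pages))
    structure(c(common,
                list(pattern = list(
                  k_cyc_nm = matrix(unlist(meta$pattern$k_cyc_nm), 3, 2),
                  phases = meta$pattern$phases,
                  modulation = meta$pattern$modulation,
                  orientations_deg = meta$pattern$orientations_deg,
                  freq_fraction = meta$pattern$freq_fraction),
                  tirf_theta_deg = meta$tirf_theta_deg)),
              class = "sim_rawset")
  } else {
    ag <- angle_grid(meta$angles_deg, meta$n_azimuth)
    if (length(pages) != length(ag$theta_deg) * ag$n_azimuth)
      stop("page count does not match angles x azimuths in the sidecar")
    structure(c(common, list(angle_grid = ag)), class = "matirf_stack")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scene to CSV
#'
#' @param scene a [scene()].
#' @param path CSV path.
#' @return Invisibly, the path.
#' @export
write_scene <- function(scene, path) {
  utils::write.csv(as.data.frame(scene), path, row.names = FALSE)
  invisible(path)
}

#' Read a scene from CSV
#'
#' @param path CSV with columns x_nm, y_nm, z_nm, brightness.
#' @param extent_nm lateral field size; default the data's bounding size.
#' @return A [scene()].
#' @export
read_scene <- function(path, extent_nm = NULL) {
  d <- utils::read.csv(path)
  if (is.null(extent_nm)) extent_nm <- max(d$x_nm, d$y_nm)
  scene(d$x_nm, d$y_nm, d$z_nm, d$brightness, extent_nm,
        provenance = list(generator = "csv", path = path))
}

#' Write a depth map (and optional volume) to 32-bit TIFFs
#'
#' Writes `<base>_h.tif` (mean depth, nm), `<base>_intensity.tif`,
#' `<base>_mask.tif` (0/255) and, when requested, one multi-page
#' `<base>_volume.tif` of axial slices, plus `<base>.json` with the axial
#' grid and normalization constants.
#'
#' @param dmap a [depth_map()].
#' @param base output path base (no extension).
#' @param volume also write the per-slice volume.
#' @return Invisibly, `base`.
#' @export
write_depth_map <- function(dmap, base, volume = FALSE) {
  wr <- function(m, path) {
    m[!is.finite(m)] <- 0
    off <- min(m); scl <- max(m) - off
    if (scl == 0) scl <- 1
    tiff::writeTIFF((m - off) / scl, path, bits.per.sample = 32L)
    c(offset = off, scale = scl)
  }
  nh <- wr(dmap$h, paste0(base, "_h.tif"))
  ni <- wr(dmap$intensity, paste0(base, "_intensity.tif"))
  tiff::writeTIFF(dmap$mask * 1, paste0(base, "_mask.tif"),
                  bits.per.sample = 8L)
  meta <- list(z_nm = dmap$axial_grid$z_nm, bin_nm = dmap$axial_grid$bin_nm,
               h_norm = as.list(nh), intensity_norm = as.list(ni))
  if (volume) {
    vol <- assemble_volume(dmap)
    off <- min(vol); scl <- max(vol) - off
    if (scl == 0) scl <- 1
    tiff::writeTIFF(lapply(seq_len(dim(vol)[3]),
                           function(s) (vol[, , s] - off) / scl),
                    paste0(base, "_volume.tif"), bits.per.sample = 32L)
    meta$volume_norm <- list(offset = off, scale = scl)
  }
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(base)
}

#' Read a run configuration from YAML or JSON
#'
#' Builds the objects a pipeline run needs from a flat configuration block:
#' optics (`wavelength_nm`, `na`, `n1`, `n2`, `pixel_nm`), angles (either
#' `angles` as a list or `angle_start_deg`/`angle_step_deg`/`n_angles`,
#' plus `n_azimuth`), axial grid (`z_max_nm`, `z_step_nm`), solver
#' (`mu`, `rho`, `max_iter`, `tol`, `solver`), masking (`mask_method`,
#' `mask_threshold`, `background_window_px`), `wiener_w`, and `seed`.
#' Missing fields take the package defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A list with `config`, `angle_grid`, `axial_grid`, `solver`,
#'   `mask_method`, `mask_threshold`, `background_window_px`, `wiener_w`,
#'   `seed`, and `raw` (the parsed file).
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  g <- function(name, default) raw[[name]] %||% default
  cfg <- optical_config(g("wavelength_nm", 488), g("na", 1.49),
                        g("n1", 1.518), g("n2", 1.33), g("pixel_nm", 52))
  ag <- if (!is.null(raw$angles))
    angle_grid(unlist(raw$angles), g("n_azimuth", 1L))
  else angle_sequence(g("angle_start_deg", 61.5), g("angle_step_deg", 0.5),
                      g("n_angles", 20L), g("n_azimuth", 1L))
  list(config = cfg, angle_grid = ag,
       axial_grid = axial_grid(g("z_max_nm", 600), g("z_step_nm", 10)),
       solver = solver_params(g("mu", 0.01), g("rho", 1),
                              g("max_iter", 500), g("tol", 1e-6),
                              g("solver", "admm")),
       mask_method = g("mask_method", "otsu"),
       mask_threshold = g("mask_threshold", 0.2),
       background_window_px = g("background_window_px", 32),
       wiener_w = g("wiener_w", 0.1),
       seed = g("seed", 1L), raw = raw)
}
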
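# small polynomial rolling hash of a string; stamps outputs with a config id
.config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full near-surface 3D reconstruction pipeline
#'
#' Chains the stages of the method: TIRF-SIM lateral reconstruction of the
#' nine-frame raw set, binary mask from the super-resolution image,
#' azimuthal averaging of the multi-angle stack, local background
#' subtraction and segmentation, per-pixel depth inversion, depth-map
#' assembly and color-coded rendering. When `out_dir` is given, every
#' intermediate plus a provenance JSON (parameters, seed, config hash,
#' per-stage timing, solver statistics) is written there.
#'
#' @param matirf a `matirf_stack` (the axial channel).
#' @param simraw a `sim_rawset` (the lateral channel), or `NULL` to derive
#'   the mask from the averaged multi-angle stack itself.
#' @param axial_grid an [axial_grid()].
#' @param solver a [solver_params()]; the default uses the
#'   noise-calibrated l1 weight (`mu_mode = "sigma"`), falling back to the
#'   relative weight when no noise estimate is available.
#' @param wiener_w Wiener parameter of the SIM reconstruction.
#' @param mask_method,mask_threshold see [make_mask()].
#' @param background_window_px see [subtract_background()].
#' @param colormap see [render_depth()].
#' @param out_dir optional output directory.
#' @param verbose print per-stage progress and timing.
#' @return A list with `sr` (the SIM reconstruction, or `NULL`), `mask`,
#'   `segmented`, `field`, `depth_map`, `rendering`, `timing`, `provenance`.
#' @export
run_pipeline <- function(matirf, simraw = NULL,
                         axial_grid = matirf::axial_grid(),
                         solver = solver_params(mu_mode = "sigma"),
                         wiener_w = 0.1,
                         mask_method = "otsu", mask_threshold = 0.2,
                         background_window_px = 32,
                         colormap = "viridis", out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(matirf, "matirf_stack"))
  timing <- c()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- tic()
  sr <- NULL
  if (!is.null(simraw)) {
    say("SIM reconstruction ...")
    sr <- sim_reconstruct(simraw, wiener_w = wiener_w)
    timing["sim_recon"] <- tic() - t0
  }
  t0 <- tic()
  say("azimuthal averaging ...")
  avg <- azimuthal_average(matirf)
  timing["azimuthal_average"] <- tic() - t0
  t0 <- tic()
  say("mask ...")
  mask <- if (!is.null(sr)) {
    make_mask(sr, method = mask_method, threshold = mask_threshold,
              raw_npx = dim(avg$frames)[1])
  } else {
    make_mask(apply(avg$frames, c(1, 2), mean), method = mask_method,
              threshold = mask_threshold)
  }
  timing["mask"] <- tic() - t0
  t0 <- tic()
  say("background subtraction ...")
  seg <- subtract_background(avg, mask, background_window_px)
  timing["background"] <- tic() - t0
  t0 <- tic()
  say("depth inversion over %d pixels ...", sum(mask$mask))
  a <- build_system_matrix(avg$angle_grid, axial_grid, avg$config,
                           model = avg$intensity_model)
  field <- solve_volume(seg, a, solver)
  timing["depth_inversion"] <- tic() - t0
  dmap <- depth_map(field)
  rendering <- render_depth(dmap, colormap = colormap)
  prov <- list(config = unclass(matirf$config),
               angles_deg = matirf$angle_grid$theta_deg,
               n_azimuth = matirf$angle_grid$n_azimuth,
               z_nm = axial_grid$z_nm,
               solver = unclass(solver), wiener_w = wiener_w,
               mask_method = mask_method, mask_threshold = mask_threshold,
               background_window_px = background_window_px,
               noise = if (!is.null(matirf$noise)) unclass(matirf$noise),
               scene_provenance = matirf$scene_provenance,
               solver_stats = list(
                 median_iterations = stats::median(field$iterations),
                 max_iterations = max(field$iterations),
                 unconverged = sum(!field$converged)),
               timing_s = as.list(timing))
  prov$config_hash <- .config_hash(jsonlite::toJSON(
    prov[setdiff(names(prov), "timing_s")], auto_unbox = TRUE, digits = NA))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(sr)) {
      img <- sr$image
      off <- min(img); scl <- max(img) - off
      tiff::writeTIFF((img - off) / ifelse(scl == 0, 1, scl),
                      file.path(out_dir, "sr.tif"), bits.per.sample = 32L)
    }
    tiff::writeTIFF(mask$mask * 1, file.path(out_dir, "mask.tif"),
                    bits.per.sample = 8L)
    write_depth_map(dmap, file.path(out_dir, "depth"), volume = TRUE)
    write_rendering(rendering, file.path(out_dir, "rendering.tif"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (verbose)
    say("done; stage timings (s): %s",
        paste(names(timing), round(timing, 2), sep = "=", collapse = " "))
  list(sr = sr, mask = mask, segmented = seg, field = field,
       depth_map = dmap, rendering = rendering, timing = timing,
       provenance = prov)
}
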
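#' Emitter scene
#'
#' A scene is a set of point fluorophores in sample space: lateral positions
#' (nm), depth above the coverslip (nm, z = 0 at the interface) and a
#' non-negative brightness per emitter, plus the lateral field extent and a
#' provenance record (generator, parameters, seed) so every rendered stack is
#' reproducible from its metadata.
#'
#' @param x_nm,y_nm,z_nm emitter coordinates (nm); `z_nm >= 0`.
#' @param brightness per-emitter brightness (photons, arbitrary scale).
#' @param extent_nm lateral field size (scalar, square field).
#' @param provenance named list recording how the scene was generated.
#' @return An object of class `scene` (a data frame of emitters with
#'   attributes `extent_nm` and `provenance`).
#' @export
scene <- function(x_nm, y_nm, z_nm, brightness = 1, extent_nm,
                  provenance = list()) {
  n <- length(x_nm)
  brightness <- rep_len(brightness, n)
  stopifnot(length(y_nm) == n, length(z_nm) == n, extent_nm > 0)
  if (n > 0) {
    stopifnot(all(is.finite(x_nm)), all(is.finite(y_nm)),
              all(is.finite(z_nm)), all(is.finite(brightness)))
    if (any(z_nm < 0)) stop("emitter depth z_nm must be >= 0")
    if (any(brightness < 0)) stop("brightness must be non-negative")
    inside <- x_nm >= 0 & x_nm <= extent_nm & y_nm >= 0 & y_nm <= extent_nm
    if (!all(inside)) stop(sum(!inside), " emitter(s) outside the field")
  }
  structure(data.frame(x_nm = x_nm, y_nm = y_nm, z_nm = z_nm,
                       brightness = brightness),
            extent_nm = extent_nm, provenance = provenance,
            class = c("scene", "data.frame"))
}

#' @export
print.scene <- function(x, ...) {
  p <- attr(x, "provenance")
  cat("scene:", nrow(x), "emitters in a", attr(x, "extent_nm"), "nm field",
      if (!is.null(p$generator)) paste0("(", p$generator, ")"), "\n")
  if (nrow(x) > 0)
    cat("  z range:", format(range(x$z_nm), digits = 4), "nm\n")
  invisible(x)
}

# run expr with a private, seeded RNG stream; global RNG state untouched
with_scene_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

#' Random 3D microtubule-like scene
#'
#' Generates smoothly curved filaments emulating a near-surface microtubule
#' network: each filament is a cubic-spline-smoothed random walk across the
#' field whose depth varies smoothly within `z_range_nm`, sampled as point
#' emitters every `bead_spacing_nm` with Gaussian radial jitter of the order
#' of the filament radius.
#'
#' @param n_filaments number of filaments (>= 1).
#' @param extent_nm lateral field size (nm).
#' @param z_range_nm length-2 depth range (nm) the filaments explore.
#' @param seed integer seed; the scene is deterministic given the seed.
#' @param bead_spacing_nm arc-length spacing of emitters along a filament.
#' @param jitter_nm sd of the Gaussian positional jitter (filament radius).
#' @param brightness mean emitter brightness.
#' @return A [scene()].
#' @export
make_microtubule_scene <- function(n_filaments, extent_nm,
                                   z_range_nm = c(0, 400), seed = 1L,
                                   bead_spacing_nm = 20, jitter_nm = 25,
                                   brightness = 1) {
  stopifnot(n_filaments >= 1, extent_nm > 0, length(z_range_nm) == 2,
            all(z_range_nm >= 0), diff(z_range_nm) >= 0)
  with_scene_seed(seed, {
    xs <- ys <- zs <- list()
    for (f in seq_len(n_filaments)) {
      # control points: a gentle random walk spanning the field
      nctl <- 8
      start <- stats::runif(2, 0.1, 0.9) * extent_nm
      dir <- stats::runif(1, 0, 2 * pi)
      step <- extent_nm / (nctl - 1)
      ctl <- matrix(NA_real_, nctl, 2)
      ctl[1, ] <- start
      for (i in 2:nctl) {
        dir <- dir + stats::rnorm(1, 0, 0.5)
        ctl[i, ] <- ctl[i - 1, ] + step * c(cos(dir), sin(dir))
      }
      zc <- stats::runif(nctl, z_range_nm[1], z_range_nm[2])
      # cubic smoothing through control points at dense parameter values
      t0 <- seq(0, 1, length.out = nctl)
      len <- sum(sqrt(rowSums(diff(ctl)^2)))
      nb <- max(2L, ceiling(len / bead_spacing_nm))
      tt <- seq(0, 1, length.out = nb)
      sx <- stats::spline(t0, ctl[, 1], xout = tt)$y
      sy <- stats::spline(t0, ctl[, 2], xout = tt)$y
      sz <- stats::spline(t0, zc, xout = tt)$y
      sx <- sx + stats::rnorm(nb, 0, jitter_nm)
      sy <- sy + stats::rnorm(nb, 0, jitter_nm)
      sz <- sz + stats::rnorm(nb, 0, jitter_nm / 2)
      keep <- sx >= 0 & sx <= extent_nm & sy >= 0 & sy <= extent_nm
      xs[[f]] <- sx[keep]; ys[[f]] <- sy[keep]
      zs[[f]] <- pmin(pmax(sz[keep], z_range_nm[1]), z_range_nm[2])
    }
    n <- length(unlist(xs))
    scene(unlist(xs), unlist(ys), pmax(unlist(zs), 0),
          brightness = brightness * stats::rgamma(n, shape = 20, rate = 20),
          extent_nm = extent_nm,
          provenance = list(generator = "microtubule",
                            n_filaments = n_filaments,
                            z_range_nm = z_range_nm, seed = seed,
                            bead_spacing_nm = bead_spacing_nm,
                            jitter_nm = jitter_nm))
  })
}

#' Surface-labeled microsphere scene
#'
#' Emitters uniformly distributed on the lower cap of a sphere resting on the
#' coverslip (contact point at z = 0), emulating a surface-labeled silica
#' microsphere ground-truth sample. Only labels with
#' `z(r) = R - sqrt(R^2 - r^2) <= z_cap_max_nm` are kept, since deeper parts
#' of the sphere are outside the evanescent excitation volume.
#'
#' @param diameter_um sphere diameter (micrometers); 4.86 um matches a common
#'   calibration sphere lot.
#' @param extent_nm lateral field size (nm); the sphere is centered.
#' @param surface_density_per_um2 label density on the sphere surface.
#' @param z_cap_max_nm maximum depth of retained labels (nm).
#' @param seed integer seed.
#' @param brightness per-emitter brightness.
#' @return A [scene()].
#' @export
make_sphere_scene <- function(diameter_um = 4.86, extent_nm = 6000,
                              surface_density_per_um2 = 300,
                              z_cap_max_nm = 500, seed = 1L,
                              brightness = 1) {
  stopifnot(diameter_um > 0, extent_nm > 0, surface_density_per_um2 > 0)
  r_nm <- diameter_um * 1000 / 2
  if (z_cap_max_nm > r_nm) {
    warning("z_cap_max_nm exceeds the sphere radius; clipping to R")
    z_cap_max_nm <- r_nm
  }
  with_scene_seed(seed, {
    # uniform sampling on the cap: cos(polar angle from bottom pole) uniform
    # cap from the bottom pole up to polar angle alpha where z = zmax
    cos_amin <- (r_nm - z_cap_max_nm) / r_nm
    area_um2 <- 2 * pi * r_nm * z_cap_max_nm / 1e6  # spherical cap area
    n <- stats::rpois(1, surface_density_per_um2 * area_um2)
    u <- stats::runif(n, cos_amin, 1)   # cos(alpha), uniform on the cap
    z <- r_nm * (1 - u)
    rr <- sqrt(pmax(r_nm^2 - (r_nm - z)^2, 0))
    phi <- stats::runif(n, 0, 2 * pi)
    cx <- extent_nm / 2
    x <- cx + rr * cos(phi); y <- cx + rr * sin(phi)
    keep <- x >= 0 & x <= extent_nm & y >= 0 & y <= extent_nm
    scene(x[keep], y[keep], z[keep], brightness = brightness,
          extent_nm = extent_nm,
          provenance = list(generator = "sphere", diameter_um = diameter_um,
                            radius_nm = r_nm,
                            center_nm = c(cx, cx),
                            surface_density_per_um2 = surface_density_per_um2,
                            z_cap_max_nm = z_cap_max_nm, seed = seed))
  })
}

#' Parallel line-pair resolution phantom
#'
#' Two parallel dense emitter lines at a given lateral separation and a
#' constant depth: the standard target for testing whether a reconstruction
#' resolves a sub-diffraction separation.
#'
#' @param separation_nm center-to-center line separation (nm, >= 0);
#'   `0` degenerates to a single line.
#' @param extent_nm lateral field size (nm).
#' @param z_nm common depth of the lines (nm).
#' @param seed integer seed (used only for emitter brightness jitter when
#'   `brightness_jitter > 0`).
#' @param spacing_nm emitter spacing along each line.
#' @param length_frac line length as a fraction of the field.
#' @param brightness per-emitter brightness.
#' @param brightness_jitter sd of multiplicative brightness jitter.
#' @return A [scene()]; lines run parallel to the y axis, centered.
#' @export
make_line_pair_scene <- function(separation_nm, extent_nm = 8000, z_nm = 0,
                                 seed = 1L, spacing_nm = 5,
                                 length_frac = 0.6, brightness = 1,
                                 brightness_jitter = 0) {
  stopifnot(separation_nm >= 0, extent_nm > 0, z_nm >= 0)
  cx <- extent_nm / 2
  half <- extent_nm * length_frac / 2
  yy <- seq(cx - half, cx + half, by = spacing_nm)
  if (separation_nm > 0) {
    x <- c(rep(cx - separation_nm / 2, length(yy)),
           rep(cx + separation_nm / 2, length(yy)))
    y <- c(yy, yy)
  } else {
    x <- rep(cx, length(yy)); y <- yy
  }
  b <- rep(brightness, length(x))
  if (brightness_jitter > 0)
    b <- with_scene_seed(seed,
      b * pmax(1 + stats::rnorm(length(x), 0, brightness_jitter), 0.1))
  scene(x, y, rep(z_nm, length(x)), brightness = b, extent_nm = extent_nm,
        provenance = list(generator = "line_pair",
                          separation_nm = separation_nm, z_nm = z_nm,
                          seed = seed, spacing_nm = spacing_nm))
}

#' Single-emitter (bead) scene
#'
#' One point emitter, by default centered in the field: the scene used for
#' localization-accuracy Monte Carlo runs.
#'
#' @param z_nm emitter depth (nm).
#' @param extent_nm lateral field size (nm).
#' @param brightness emitter brightness.
#' @param x_nm,y_nm optional lateral position (defaults to field center).
#' @return A [scene()].
#' @export
make_point_scene <- function(z_nm = 0, extent_nm = 2000, brightness = 1,
                             x_nm = extent_nm / 2, y_nm = extent_nm / 2) {
  scene(x_nm, y_nm, z_nm, brightness = brightness, extent_nm = extent_nm,
        provenance = list(generator = "point", z_nm = z_nm))
}
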
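# shared fixtures: small optical configuration and deterministic scenes

default_cfg <- function() optical_config()

sweep_angles <- function(n_azimuth = 1L) {
  angle_sequence(61.5, 0.5, 20, n_azimuth = n_azimuth)
}

# random field of surface-attached beads; structured enough for pattern
# estimation
bead_scene <- function(n = 150, extent_nm = 128 * 52, z_nm = 0, seed = 3) {
  withr::with_seed(seed, {
    scene(stats::runif(n, 0.1, 0.9) * extent_nm,
          stats::runif(n, 0.1, 0.9) * extent_nm,
          rep(z_nm, n), stats::runif(n, 0.5, 1.5), extent_nm,
          provenance = list(generator = "beads", seed = seed))
  })
}

# analytic depth map of a spherical cap, for fit tests
cap_depth_map <- function(radius_nm = 2430, npx = 64, pixel_nm = 52,
                          center_px = (npx + 1) / 2, h_max = 500,
                          h_noise_sd = 0, seed = 1) {
  h <- int <- matrix(NA_real_, npx, npx)
  mask <- matrix(FALSE, npx, npx)
  for (i in seq_len(npx)) for (j in seq_len(npx)) {
    r <- sqrt((i - center_px)^2 + (j - center_px)^2) * pixel_nm
    if (r < radius_nm) {
      z <- radius_nm - sqrt(radius_nm^2 - r^2)
      if (z <= h_max) {
        h[i, j] <- z
        int[i, j] <- 1
        mask[i, j] <- TRUE
      }
    }
  }
  if (h_noise_sd > 0)
    h[mask] <- withr::with_seed(seed,
      pmax(h[mask] + stats::rnorm(sum(mask), 0, h_noise_sd), 0))
  ax <- axial_grid()
  structure(list(h = h, intensity = int, mask = mask, axial_grid = ax,
                 qc = list(), field = NULL),
            class = "depth_map")
}

objective_ls <- function(a, f, b) 0.5 * sum((a %*% f - b)^2)

random_nnls_instance <- function(kmax = 10, mmax = 20, noise_sd = 0.2) {
  k <- sample(3:kmax, 1)
  m <- sample(5:mmax, 1)
  a <- matrix(stats::runif(k * m), k, m)
  b <- pmax(as.numeric(a %*% pmax(stats::rnorm(m), 0)) +
              stats::rnorm(k, 0, noise_sd), 0)
  list(a = a, b = b)
}
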
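# fake raw set with analytically known pattern, bypassing the renderer
analytic_rawset <- function(n = 64, k_px = c(0.22, 0.08), m = 0.7,
                            phi0 = 0.9, seed = 1) {
  cfg <- default_cfg()
  s <- withr::with_seed(seed, {
    lo <- matrix(stats::rnorm(16 * 16), 16)
    # smooth random structure via zero-padded spectrum upsampling
    sp <- matrix(0 + 0i, n, n)
    sp[1:16, 1:16] <- stats::fft(lo)
    abs(Re(stats::fft(sp, inverse = TRUE)) / n^2) + 0.1
  })
  xg <- matrix(0:(n - 1), n, n, byrow = TRUE)
  yg <- matrix(0:(n - 1), n, n)
  arg <- 2 * pi * (k_px[1] * xg + k_px[2] * yg) + phi0
  frames <- array(0, dim = c(n, n, 9))
  for (o in 1:3) for (p in 1:3)
    frames[, , (o - 1) * 3 + p] <-
      s * (1 + m * cos(arg + (p - 1) * 2 * pi / 3))
  structure(list(frames = frames,
                 pattern = list(k_cyc_nm = matrix(rep(k_px / cfg$pixel_nm,
                                                      each = 3), 3, 2),
                                phases = c(0, 2 * pi / 3, 4 * pi / 3),
                                modulation = m,
                                orientations_deg = c(0, 60, 120),
                                freq_fraction = NA),
                 tirf_theta_deg = 63, config = cfg, noise = NULL,
                 noise_sigma = 0, psf_fwhm_nm = 170,
                 intensity_model = "fresnel", scene_provenance = NULL),
            structure_s = s, arg = arg,
            class = "sim_rawset")
}

test_that("band separation inverts the phase-mixing system exactly", {
  raw <- analytic_rawset()
  bands <- separate_bands(raw)
  m <- bands$mixing
  expect_equal(m %*% solve(m), diag(3) + 0i, tolerance = 1e-12)
  n <- bands$npx
  s <- attr(raw, "structure_s")
  xg <- matrix(0:(n - 1), n, n, byrow = TRUE)
  yg <- matrix(0:(n - 1), n, n)
  mod <- exp(2i * pi * (0.22 * xg + 0.08 * yg))
  expected_plus <- 0.35 * exp(1i * 0.9) * stats::fft(s * mod)
  expect_equal(bands$orientations[[1]]$plus, expected_plus,
               tolerance = 1e-9)
  expect_equal(bands$orientations[[1]]$center, stats::fft(s),
               tolerance = 1e-9)
  # amplitude ratio center : plus : minus = 1 : m/2 : m/2
  e <- function(x) sqrt(sum(Mod(x)^2))
  expect_equal(e(bands$orientations[[1]]$plus) /
                 e(bands$orientations[[1]]$center), 0.35,
               tolerance = 0.05)
  expect_error(separate_bands(raw, phases = c(0, 0, 2)), "singular|distinct")
})

test_that("vanishing modulation leaves only the center band", {
  cfg <- default_cfg()
  raw <- render_sim_rawset(bead_scene(60, 64 * 52), cfg, 0.9, 1e-9,
                           npx = 64)
  bands <- separate_bands(raw)
  ec <- sqrt(sum(Mod(bands$orientations[[1]]$center)^2))
  ep <- sqrt(sum(Mod(bands$orientations[[1]]$plus)^2))
  expect_lt(ep / ec, 1e-6)
  mean_spec <- stats::fft(apply(raw$frames, c(1, 2), mean))
  expect_equal(bands$orientations[[1]]$center, mean_spec, tolerance = 1e-6)
})

test_that("pattern estimation recovers k, phase and modulation on structured scenes", {
  cfg <- default_cfg()
  sc <- bead_scene(150, 128 * 52, seed = 3)
  raw <- render_sim_rawset(sc, cfg, 0.9, 0.8, npx = 128)
  pat <- estimate_pattern(raw)
  for (o in 1:3) {
    kt <- raw$pattern$k_cyc_nm[o, ]
    ke <- pat$k_cyc_nm[o, ]
    expect_lt(abs(sqrt(sum(ke^2)) / sqrt(sum(kt^2)) - 1), 0.005)
    dang <- (atan2(ke[2], ke[1]) - atan2(kt[2], kt[1])) * 180 / pi
    expect_lt(abs(dang), 0.5)
    expect_equal(pat$modulation[o], 0.8, tolerance = 0.02)
  }
  noisy <- render_sim_rawset(sc, cfg, 0.9, 0.8,
                             noise = noise_model(30, 7), npx = 128)
  pat2 <- estimate_pattern(noisy)
  expect_true(all(pat2$modulation > 0.7 & pat2$modulation < 0.9))
})

test_that("pure noise frames are rejected as pattern-free", {
  cfg <- default_cfg()
  dim_pt <- make_point_scene(z_nm = 0, extent_nm = 64 * 52,
                             brightness = 1e-9)
  raw <- render_sim_rawset(dim_pt, cfg, 0.9, 0.8,
                           noise = noise_model(1e-4, 2), npx = 64)
  expect_error(estimate_pattern(raw), "pattern not detected")
})

test_that("wiener combination sharpens a point source by at least 40 percent", {
  cfg <- default_cfg()
  sc <- make_point_scene(z_nm = 0, extent_nm = 128 * 52)
  raw <- render_sim_rawset(sc, cfg, 0.9, 0.8, npx = 128)
  sr <- sim_reconstruct(raw, pattern = pattern_from_rawset(raw))
  wf <- apply(raw$frames, c(1, 2), mean)
  ctr <- which(sr$image == max(sr$image), arr.ind = TRUE)[1, ]
  f_sr <- fwhm(pmax(sr$image[ctr[1], ], 0),
               (seq_len(ncol(sr$image)) - 1) * sr$pixel_nm)
  ctr2 <- which(wf == max(wf), arr.ind = TRUE)[1, ]
  f_wf <- fwhm(wf[ctr2[1], ], (seq_len(ncol(wf)) - 1) * cfg$pixel_nm)
  expect_lt(f_sr / f_wf, 0.6)
  expect_lt(f_sr, 100)   # sub-100-nm lateral FWHM at these optics
  expect_error(wiener_combine(separate_bands(raw),
                              pattern_from_rawset(raw), otf_model(cfg),
                              wiener_w = 0), "wiener_w")
})

test_that("a uniform plane reconstructs flat and spectrum stays within support", {
  cfg <- default_cfg()
  ext <- 128 * 52
  g <- seq(30, ext - 30, by = 60)
  n <- length(g)^2
  u <- scene(rep(g, times = length(g)), rep(g, each = length(g)),
             rep(0, n), rep(1, n), ext)
  raw <- render_sim_rawset(u, cfg, 0.9, 0.9, npx = 128)
  sr <- sim_reconstruct(raw, pattern = pattern_from_rawset(raw))
  ctr <- sr$image[60:196, 60:196]
  expect_lt(stats::sd(ctr) / mean(ctr), 0.01)
  # apodization contract: energy beyond the extended cutoff is negligible
  sp <- Mod(stats::fft(sr$image))^2
  fr <- matirf:::freq_radius(nrow(sr$image), sr$pixel_nm)
  expect_lt(sum(sp[fr >= sr$effective_cutoff]) / sum(sp), 1e-6)
})

test_that("reconstruction degrades gracefully to deconvolved wide-field as m -> 0", {
  cfg <- default_cfg()
  raw <- render_sim_rawset(bead_scene(120, 128 * 52, seed = 4), cfg,
                           0.9, 1e-6, npx = 128)
  sr <- wiener_combine(separate_bands(raw), pattern_from_rawset(raw),
                       otf_model(cfg))
  wf <- widefield_wiener(apply(raw$frames, c(1, 2), mean), cfg$pixel_nm,
                         otf_model(cfg), n_copies = 3,
                         f_apo = sr$effective_cutoff)
  expect_gt(stats::cor(as.vector(sr$image), as.vector(wf$image)), 0.999)
})

test_that("wave-vector recovery stays within 1 percent over seeded noisy runs", {
  cfg <- default_cfg()
  errs <- sapply(1:20, function(s) {
    sc <- bead_scene(120, 128 * 52, seed = 100 + s)
    raw <- render_sim_rawset(sc, cfg, 0.9, 0.8,
                             noise = noise_model(30, 200 + s), npx = 128)
    pat <- estimate_pattern(raw)
    max(abs(sqrt(rowSums(pat$k_cyc_nm^2)) /
              sqrt(rowSums(raw$pattern$k_cyc_nm^2)) - 1))
  })
  expect_lt(max(errs), 0.01)
})
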
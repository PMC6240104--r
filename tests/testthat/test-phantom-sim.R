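test_that("microtubule scenes are seeded, bounded and depth-constrained", {
  sc <- make_microtubule_scene(1, 5000, z_range_nm = c(100, 100), seed = 2)
  expect_true(all(sc$z_nm == 100))
  a <- make_microtubule_scene(5, 8000, seed = 7)
  b <- make_microtubule_scene(5, 8000, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$x_nm >= 0 & a$x_nm <= 8000))
  expect_true(all(a$z_nm >= 0))
  # emitters roughly every bead_spacing along each filament
  expect_gt(nrow(a), 5 * 8000 / 20 * 0.3)
})

test_that("sphere scenes sample the lower cap of the stated sphere", {
  sc <- make_sphere_scene(4.86, 6000, 300, 500, seed = 4)
  r_nm <- 2430
  ctr <- attr(sc, "provenance")$center_nm
  rr2 <- (sc$x_nm - ctr[1])^2 + (sc$y_nm - ctr[2])^2
  # on-sphere constraint and cap geometry z(r) = R - sqrt(R^2 - r^2)
  expect_equal(rr2 + (sc$z_nm - r_nm)^2, rep(r_nm^2, nrow(sc)),
               tolerance = 1e-6)
  expect_true(all(sc$z_nm <= 500 + 1e-9))
  expect_lt(min(sc$z_nm), 5)   # labels near the contact point reach z ~ 0
  expect_equal(r_nm - sqrt(r_nm^2 - 1000^2), 215.2991, tolerance = 1e-4)
  expect_warning(make_sphere_scene(1, 3000, 300, z_cap_max_nm = 5000),
                 "clipping")
})

test_that("line-pair scenes have the requested separation and degenerate cleanly", {
  sc <- make_line_pair_scene(100, extent_nm = 6000)
  xs <- sort(unique(sc$x_nm))
  expect_length(xs, 2)
  expect_equal(diff(xs), 100)
  sc0 <- make_line_pair_scene(0, extent_nm = 6000)
  expect_length(unique(sc0$x_nm), 1)
  expect_error(make_line_pair_scene(-10), "separation")
})

test_that("multi-angle rendering follows the evanescent forward model", {
  cfg <- default_cfg()
  ag <- angle_grid(c(63, 68))
  sc0 <- make_point_scene(z_nm = 0, extent_nm = 33 * 52)
  st0 <- render_matirf_stack(sc0, ag, cfg, npx = 33)
  i0 <- interface_intensity(c(63, 68), cfg)
  expect_equal(max(st0$frames[, , 1]) / max(st0$frames[, , 2]),
               i0[1] / i0[2], tolerance = 1e-9)
  sc2 <- make_point_scene(z_nm = 200, extent_nm = 33 * 52)
  st2 <- render_matirf_stack(sc2, ag, cfg, npx = 33)
  d <- penetration_depth(c(63, 68), cfg)
  for (k in 1:2)
    expect_equal(max(st2$frames[, , k]) / max(st0$frames[, , k]),
                 exp(-200 / d[k]), tolerance = 1e-9)
})

test_that("noise realizations have the declared SNR-referenced sigma", {
  cfg <- default_cfg()
  ag <- sweep_angles()
  sc <- make_point_scene(z_nm = 0, extent_nm = 128 * 52)
  clean <- render_matirf_stack(sc, ag, cfg, npx = 128)
  noisy <- render_matirf_stack(sc, ag, cfg, noise = noise_model(30, 5),
                               npx = 128)
  sig_emp <- stats::sd(noisy$frames - clean$frames)
  expect_equal(sig_emp, max(clean$frames) / 30, tolerance = 0.05)
  # negatives are kept, not clipped
  expect_lt(min(noisy$frames), 0)
})

test_that("rendering is deterministic and linear in the scene", {
  cfg <- default_cfg()
  ag <- angle_grid(c(63, 68), n_azimuth = 2L)
  sc <- bead_scene(40, 64 * 52, seed = 9)
  s1 <- render_matirf_stack(sc, ag, cfg, noise = noise_model(20, 3), npx = 64)
  s2 <- render_matirf_stack(sc, ag, cfg, noise = noise_model(20, 3), npx = 64)
  expect_identical(s1$frames, s2$frames)
  a <- sc[1:20, ]; b <- sc[21:40, ]
  for (part in list(a, b)) {
    attr(part, "extent_nm") <- attr(sc, "extent_nm")
  }
  mk <- function(d) scene(d$x_nm, d$y_nm, d$z_nm, d$brightness, 64 * 52)
  ra <- render_matirf_stack(mk(a), ag, cfg, npx = 64)
  rb <- render_matirf_stack(mk(b), ag, cfg, npx = 64)
  rab <- render_matirf_stack(mk(sc), ag, cfg, npx = 64)
  expect_equal(rab$frames, ra$frames + rb$frames, tolerance = 1e-9)
})

test_that("total frame energy decreases with angle for a scene above the coverslip", {
  cfg <- default_cfg()
  ag <- sweep_angles()
  sc <- make_point_scene(z_nm = 150, extent_nm = 33 * 52)
  st <- render_matirf_stack(sc, ag, cfg, npx = 33,
                            intensity_model = "unit")
  tot <- apply(st$frames, 3, sum)
  expect_true(all(diff(tot) < 0))
})

test_that("SIM raw sets carry the sinusoidal pattern with exact phase structure", {
  cfg <- default_cfg()
  sc <- bead_scene(60, 64 * 52, seed = 2)
  raw <- render_sim_rawset(sc, cfg, 0.9, 0.9, npx = 64)
  expect_equal(dim(raw$frames)[3], 9)
  # phases cancel: sum of the 3 phase frames equals 3x the unmodulated image
  raw0 <- render_sim_rawset(sc, cfg, 0.9, 1e-9, npx = 64)
  for (o in 1:3) {
    s3 <- raw$frames[, , (o - 1) * 3 + 1] + raw$frames[, , (o - 1) * 3 + 2] +
      raw$frames[, , (o - 1) * 3 + 3]
    expect_equal(s3, 3 * raw0$frames[, , (o - 1) * 3 + 1],
                 tolerance = 1e-7)
  }
  # vanishing modulation: all 9 frames collapse to the uniform-TIRF image
  expect_equal(max(abs(sweep(raw0$frames, c(1, 2),
                             raw0$frames[, , 1]))), 0, tolerance = 1e-6)
  expect_error(render_sim_rawset(sc, cfg, 0.9, 1.5), "modulation")
  expect_error(render_sim_rawset(sc, cfg, 1.5, 0.9), "fraction")
})

test_that("azimuthal replicates average down noise by about 1/sqrt(n)", {
  cfg <- default_cfg()
  ag4 <- angle_grid(c(63, 66), n_azimuth = 4L)
  sc <- make_point_scene(z_nm = 0, extent_nm = 96 * 52)
  clean <- render_matirf_stack(sc, angle_grid(c(63, 66)), cfg, npx = 96)
  noisy <- render_matirf_stack(sc, ag4, cfg, noise = noise_model(10, 8),
                               npx = 96)
  avg <- azimuthal_average(noisy)
  sig_in <- noisy$noise_sigma
  sig_out <- stats::sd(avg$frames[, , 1] - clean$frames[, , 1])
  expect_equal(sig_out, sig_in / 2, tolerance = 0.1)
})
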
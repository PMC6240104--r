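test_that("single-bin truths are recovered within half a depth bin", {
  cfg <- default_cfg()
  a <- build_system_matrix(sweep_angles(), axial_grid(), cfg)
  ax <- a$axial_grid
  for (m in c(1, 21, 41)) {
    pr <- solve_pixel(a$a[, m], a, solver_params(mu = 0, max_iter = 2000))
    expect_lt(abs(depth_from_profile(pr, ax) - ax$z_nm[m]), ax$bin_nm / 2)
  }
  pr0 <- solve_pixel(rep(0, 20), a)
  expect_equal(pr0$f, rep(0, 61))
  expect_true(pr0$converged)
  expect_error(solve_pixel(c(1, NA, rep(1, 18)), a), "non-finite")
  expect_error(solve_pixel(1:5, a), "number of angles")
})

test_that("ADMM matches the NNLS oracle objective on random instances", {
  withr::with_seed(1, {
    worst <- 0
    for (i in 1:100) {
      inst <- random_nnls_instance()
      p_admm <- solve_pixel(inst$b, inst$a,
                            solver_params(mu = 0, max_iter = 2000))
      p_nnls <- solve_pixel(inst$b, inst$a,
                            solver_params(mu = 0, solver = "nnls"))
      gap <- (objective_ls(inst$a, p_admm$f, inst$b) -
                objective_ls(inst$a, p_nnls$f, inst$b)) /
        (0.5 * sum(inst$b^2))
      worst <- max(worst, abs(gap))
    }
    expect_lt(worst, 1e-6)
  })
})

test_that("projected gradient agrees with ADMM and solves the scalar case in closed form", {
  withr::with_seed(2, {
    worst <- 0
    for (i in 1:50) {
      inst <- random_nnls_instance()
      p1 <- solve_pixel(inst$b, inst$a,
                        solver_params(mu = 0.01, max_iter = 2000))
      p2 <- solve_gradient_descent(inst$b, inst$a,
                                   solver_params(mu = 0.01, tol = 1e-8))
      rel <- abs(p1$objective - p2$objective) / max(p2$objective, 1e-12)
      worst <- max(worst, rel)
    }
    expect_lt(worst, 1e-4)
  })
  pg0 <- solve_gradient_descent(0, matrix(2), solver_params())
  expect_equal(pg0$f, 0)
  # K = M = 1: f = max(b/a - mu_abs/a, 0) on the normalized-column scale
  a <- matrix(2); b <- 3; mu <- 0.1
  pg <- solve_gradient_descent(b, a, solver_params(mu = mu, tol = 1e-10))
  expect_equal(pg$f, max(b - mu * b, 0) / 2, tolerance = 1e-6)
})

test_that("mean depth reduces profiles as an intensity-weighted average", {
  ax <- axial_grid(600, 10)
  f <- numeric(61); f[21] <- 2
  expect_equal(depth_from_profile(f, ax), 200)
  expect_equal(depth_from_profile(rep(1, 61), ax), 300)
  f2 <- numeric(61); f2[c(11, 31)] <- 1
  expect_equal(depth_from_profile(f2, ax), 200)
  expect_true(is.na(depth_from_profile(numeric(61), ax)))
})

test_that("volume solving equals per-pixel solving and is order independent", {
  cfg <- default_cfg()
  ag <- sweep_angles()
  ax <- axial_grid()
  a <- build_system_matrix(ag, ax, cfg)
  sc <- bead_scene(25, 48 * 52, seed = 12)
  st <- render_matirf_stack(sc, ag, cfg, noise = noise_model(40, 5),
                            npx = 48)
  mask <- make_mask(apply(st$frames, c(1, 2), mean))
  seg <- subtract_background(st, mask)
  prm <- solver_params(mu_mode = "sigma")
  field <- solve_volume(seg, a, prm)
  px <- field$pixels[3, ]
  m1 <- matrix(FALSE, 48, 48); m1[px[1], px[2]] <- TRUE
  single <- solve_volume(seg, a, prm, mask = m1)
  b <- sapply(seq_along(ag$theta_deg),
              function(k) seg$frames[, , k][px[1], px[2]])
  pr <- solve_pixel(b, a, solver_params(mu_mode = "sigma"),
                    sigma = mean(seg$noise_sigma_hat))
  expect_identical(single$f[, 1], pr$f)
  # permuting the column order of the batched core is bit-identical
  an <- matirf:::.normalize_columns(a$a)
  bmat <- sapply(seq_len(nrow(field$pixels))[1:10], function(j)
    sapply(seq_along(ag$theta_deg),
           function(k) seg$frames[, , k][field$pixels[j, 1],
                                         field$pixels[j, 2]]))
  perm <- c(4, 9, 1, 7, 2, 10, 3, 6, 8, 5)
  o1 <- matirf:::.admm_core(an$an, bmat, rep(0.05, 10), 1, 300, 1e-6)
  o2 <- matirf:::.admm_core(an$an, bmat[, perm], rep(0.05, 10), 1, 300,
                            1e-6)
  expect_identical(o1$f[, perm], o2$f)
  expect_error(solve_volume(seg, a, mask = matrix(FALSE, 48, 48)),
               "empty mask")
})

test_that("reconstructed volumes conserve intensity and localize single bins", {
  cfg <- default_cfg()
  ag <- sweep_angles()
  a <- build_system_matrix(ag, axial_grid(), cfg)
  sc <- make_point_scene(z_nm = 200, extent_nm = 32 * 52)
  st <- render_matirf_stack(sc, ag, cfg, npx = 32)
  mask <- make_mask(apply(st$frames, c(1, 2), mean))
  seg <- subtract_background(st, mask)
  field <- solve_volume(seg, a, solver_params(mu = 0.01))
  dm <- depth_map(field)
  vol <- assemble_volume(field)
  zsum <- apply(vol, c(1, 2), sum)
  expect_equal(zsum[dm$mask], dm$intensity[dm$mask], tolerance = 1e-12)
  # a z = 200 emitter concentrates near bin 21
  ctr <- which(dm$intensity == max(dm$intensity, na.rm = TRUE),
               arr.ind = TRUE)[1, ]
  prof <- vol[ctr[1], ctr[2], ]
  expect_lt(abs(attr(vol, "z_nm")[which.max(prof)] - 200), 20)
})

test_that("depth accuracy on a near-coverslip microtubule network is within 10 nm", {
  cfg <- default_cfg()
  ext <- 96 * 52
  sc <- make_microtubule_scene(4, ext, z_range_nm = c(0, 50), seed = 5)
  ag <- sweep_angles(n_azimuth = 4L)
  st <- render_matirf_stack(sc, ag, cfg, noise = noise_model(30, 9),
                            npx = 96)
  res <- run_pipeline(st)
  rmse <- depth_rmse(res$depth_map, sc, cfg$pixel_nm, st$psf_fwhm_nm)
  expect_lt(rmse, 10)
})
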
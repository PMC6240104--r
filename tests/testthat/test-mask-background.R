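test_that("azimuthal averaging is the identity at n_azimuth 1 and exact on constants", {
  cfg <- default_cfg()
  sc <- make_point_scene(z_nm = 0, extent_nm = 32 * 52)
  st <- render_matirf_stack(sc, angle_grid(c(63, 66)), cfg, npx = 32)
  expect_identical(azimuthal_average(st)$frames, st$frames)
  st4 <- render_matirf_stack(sc, angle_grid(c(63, 66), n_azimuth = 4L),
                             cfg, npx = 32)
  # noiseless replicates are identical, so their mean is exact
  avg <- azimuthal_average(st4)
  expect_equal(avg$frames[, , 1], st4$frames[, , 1], tolerance = 1e-12)
  expect_equal(dim(avg$frames)[3], 2)
  bad <- st4
  bad$frames <- bad$frames[, , 1:7]
  expect_error(azimuthal_average(bad), "inconsistent")
})

test_that("otsu masking separates a two-level image and flags blank input", {
  img <- matrix(0, 40, 40)
  img[10:20, 10:20] <- 100
  m <- make_mask(img)
  expect_identical(m$mask, img == 100)
  expect_warning(m0 <- make_mask(matrix(0, 20, 20)), "blank")
  expect_false(any(m0$mask))
})

test_that("fixed-threshold masks shrink monotonically with the threshold", {
  withr::with_seed(5, {
    img <- matrix(stats::runif(64^2), 64)
  })
  m1 <- make_mask(img, method = "fixed", threshold = 0.3)$mask
  m2 <- make_mask(img, method = "fixed", threshold = 0.6)$mask
  expect_true(all(m1[m2]))       # higher threshold never grows the mask
  expect_lt(sum(m2), sum(m1))
})

test_that("SR-grid masks reduce 2x2 blocks by any-OR onto the raw grid", {
  fine <- matrix(0, 8, 8)
  fine[3, 5] <- 10                      # one hot SR pixel
  sr <- structure(list(image = fine, pixel_nm = 26), class = "sr_image")
  m <- make_mask(sr, method = "fixed", threshold = 0.5)
  expect_equal(dim(m$mask), c(4, 4))
  expect_true(m$mask[2, 3])
  expect_equal(sum(m$mask), 1)
})

test_that("background subtraction removes a constant offset and preserves structure", {
  cfg <- default_cfg()
  ag <- angle_grid(c(63, 66))
  sc <- make_point_scene(z_nm = 0, extent_nm = 64 * 52)
  st <- render_matirf_stack(sc, ag, cfg, npx = 64)
  truth <- st$frames
  mask <- make_mask(apply(st$frames, c(1, 2), mean))
  st$frames <- st$frames + 0.7          # constant background
  seg <- subtract_background(st, mask)
  expect_equal(seg$frames[, , 1][mask$mask], truth[, , 1][mask$mask],
               tolerance = 1e-6)
  expect_true(all(seg$frames[, , 1][!mask$mask] == 0))
  # zero background, exact mask: output equals input on the mask
  st0 <- render_matirf_stack(sc, ag, cfg, npx = 64)
  seg0 <- subtract_background(st0, mask)
  expect_equal(seg0$frames[, , 2][mask$mask], truth[, , 2][mask$mask],
               tolerance = 1e-6)
})

test_that("a pure-offset frame reduces to zeros and a full mask falls back gracefully", {
  cfg <- default_cfg()
  st <- render_matirf_stack(make_point_scene(z_nm = 0,
                                             extent_nm = 64 * 52),
                            angle_grid(63), cfg, npx = 64)
  st$frames[] <- 3.2                    # no structure at all
  mask <- matrix(FALSE, 64, 64); mask[30:34, 30:34] <- TRUE
  seg <- subtract_background(st, mask)
  expect_true(all(seg$frames == 0))
  full <- matrix(TRUE, 64, 64)
  expect_warning(segf <- subtract_background(st, full), "entire frame")
  expect_true(all(is.finite(segf$frames)))
})

test_that("background subtraction is idempotent", {
  cfg <- default_cfg()
  sc <- bead_scene(30, 64 * 52, seed = 6)
  st <- render_matirf_stack(sc, angle_grid(c(63, 66)), cfg,
                            noise = noise_model(20, 3), npx = 64)
  mask <- make_mask(apply(st$frames, c(1, 2), mean))
  seg1 <- subtract_background(st, mask)
  st2 <- st
  st2$frames <- seg1$frames
  seg2 <- subtract_background(st2, mask)
  expect_lt(max(abs(seg2$frames - seg1$frames)), 1e-9)
})

test_that("subtraction preserves the inter-angle intensity order of a peak", {
  cfg <- default_cfg()
  ag <- sweep_angles()
  sc <- make_point_scene(z_nm = 150, extent_nm = 64 * 52)
  st <- render_matirf_stack(sc, ag, cfg, noise = noise_model(50, 4),
                            npx = 64)
  mask <- make_mask(apply(st$frames, c(1, 2), mean))
  seg <- subtract_background(st, mask)
  ctr <- which(apply(st$frames, c(1, 2), mean) ==
                 max(apply(st$frames, c(1, 2), mean)), arr.ind = TRUE)[1, ]
  peaks_raw <- st$frames[ctr[1], ctr[2], ]
  peaks_seg <- seg$frames[ctr[1], ctr[2], ]
  expect_equal(order(peaks_raw), order(peaks_seg))
})
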
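#' Azimuthal (ring) averaging of a multi-angle stack
#'
#' Averages, per polar incidence angle, the frames recorded at different
#' azimuthal beam directions. Ring illumination exists to homogenize
#' azimuthal inhomogeneity of the evanescent field; after averaging the
#' stack carries one frame per polar angle with noise reduced by roughly
#' `1/sqrt(n_azimuth)`.
#'
#' @param stack a `matirf_stack` (azimuth-fastest, angle-major frame order).
#' @return A `matirf_stack` with `n_azimuth = 1`.
#' @export
azimuthal_average <- function(stack) {
  stopifnot(inherits(stack, "matirf_stack"))
  k <- length(stack$angle_grid$theta_deg)
  naz <- stack$angle_grid$n_azimuth
  if (dim(stack$frames)[3] != k * naz)
    stop("frame count inconsistent with angle grid (", dim(stack$frames)[3],
         " frames for ", k, " angles x ", naz, " azimuths)")
  if (naz == 1L) return(stack)
  d <- dim(stack$frames)
  out <- array(0, dim = c(d[1], d[2], k))
  for (a in seq_len(k)) {
    idx <- (a - 1) * naz + seq_len(naz)
    out[, , a] <- apply(stack$frames[, , idx, drop = FALSE], c(1, 2), mean)
  }
  stack$frames <- out
  stack$angle_grid <- angle_grid(stack$angle_grid$theta_deg, 1L)
  if (!is.null(stack$noise_sigma))
    stack$noise_sigma <- stack$noise_sigma / sqrt(naz)
  stack
}

#' Binary spatial mask from a super-resolution image
#'
#' Thresholds a (typically SIM super-resolution) image to a binary mask that
#' selects the in-focus structures and discards diffraction-limited
#' background, then maps it onto the raw pixel grid. When the source image
#' is twice as dense as the raw grid, each raw pixel is in-mask if any of
#' its 2 x 2 source pixels passes the threshold (conservative: favors
#' coverage of dim structure edges).
#'
#' @param sr an `sr_image`, or a plain matrix already on the target grid.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold for `"fixed"`: the threshold as a fraction of the image
#'   maximum; ignored for `"otsu"`.
#' @param raw_npx side length of the raw pixel grid the mask must match;
#'   defaults to half the source size for an `sr_image` and the source size
#'   for a matrix.
#' @return An object of class `binary_mask`: `mask` (logical matrix),
#'   `threshold_value` (on the source-image scale), `method`, `source`.
#' @export
make_mask <- function(sr, method = c("otsu", "fixed"), threshold = 0.2,
                      raw_npx = NULL) {
  method <- match.arg(method)
  img <- if (inherits(sr, "sr_image")) sr$image else as.matrix(sr)
  src <- if (inherits(sr, "sr_image")) "sr_image" else "matrix"
  if (is.null(raw_npx))
    raw_npx <- if (inherits(sr, "sr_image")) nrow(img) %/% 2L else nrow(img)
  if (!all(is.finite(img))) stop("source image must be finite")
  if (max(img) <= min(img)) {
    warning("blank source image: empty mask")
    return(structure(list(mask = matrix(FALSE, raw_npx, raw_npx),
                          threshold_value = NA_real_, method = method,
                          source = src),
                     class = "binary_mask"))
  }
  thr <- if (method == "otsu") {
    EBImage::otsu(img, range = range(img))
  } else {
    min(img) + threshold * (max(img) - min(img))
  }
  fine <- img > thr
  fac <- nrow(fine) / raw_npx
  mask <- if (fac == 1) {
    fine
  } else if (fac == 2) {
    # 2x2 any-OR block reduction
    m <- fine[seq(1, nrow(fine), 2), seq(1, ncol(fine), 2)] |
      fine[seq(2, nrow(fine), 2), seq(1, ncol(fine), 2)] |
      fine[seq(1, nrow(fine), 2), seq(2, ncol(fine), 2)] |
      fine[seq(2, nrow(fine), 2), seq(2, ncol(fine), 2)]
    m
  } else stop("source grid must equal or double the raw grid")
  structure(list(mask = mask, threshold_value = thr, method = method,
                 source = src),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask:", sum(x$mask), "of", length(x$mask), "pixels (",
      format(100 * mean(x$mask), digits = 3), "% ),", x$method,
      "threshold", format(x$threshold_value, digits = 4), "\n")
  invisible(x)
}

# local background: median of off-mask pixels per window tile, NA-filled,
# bilinearly interpolated to full resolution; the mask is dilated by
# guard_px first so PSF halos and dim structure edges just outside the
# mask do not contaminate the background sample
.local_background <- function(frame, mask, window_px, min_frac = 0.3) {
  n <- nrow(frame)
  nt <- max(1L, floor(n / window_px))
  br <- floor(seq(0, n, length.out = nt + 1))
  centers <- (utils::head(br, -1) + utils::tail(br, -1) + 1) / 2
  med <- matrix(NA_real_, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    ri <- (br[i] + 1):br[i + 1]; cj <- (br[j] + 1):br[j + 1]
    v <- frame[ri, cj][!mask[ri, cj]]
    # a tile mostly covered by (dilated) structure gives an unreliable
    # sample; leave it NA and fill from the nearest clean tile
    if (length(v) >= min_frac * length(ri) * length(cj))
      med[i, j] <- stats::median(v)
  }
  if (all(is.na(med))) return(NULL)
  # fill tiles fully covered by the mask from their nearest valid tile
  if (anyNA(med)) {
    valid <- which(!is.na(med), arr.ind = TRUE)
    nas <- which(is.na(med), arr.ind = TRUE)
    for (r in seq_len(nrow(nas))) {
      d2 <- (valid[, 1] - nas[r, 1])^2 + (valid[, 2] - nas[r, 2])^2
      med[nas[r, 1], nas[r, 2]] <- med[valid[which.min(d2), , drop = FALSE]]
    }
  }
  if (nt == 1) return(matrix(med[1, 1], n, n))
  px <- pmin(pmax(seq_len(n), centers[1]), centers[nt])
  g <- expand.grid(y = px, x = px)
  bg <- pracma::interp2(centers, centers, med, g$x, g$y, method = "linear")
  matrix(bg, n, n)
}

#' Local background subtraction and segmentation of a multi-angle stack
#'
#' For each frame, estimates the local background as the median of off-mask
#' pixels in a coarse sliding window (bilinearly interpolated under the
#' mask), subtracts it, clamps negative residuals to zero (the depth
#' inversion needs non-negative data), and zeroes every off-mask pixel.
#' Background bleeds misleading depth information into the inversion, which
#' is why segmentation precedes it.
#'
#' @param stack a `matirf_stack`, normally azimuth-averaged.
#' @param mask a [make_mask()] result (or a logical matrix).
#' @param window_px background window size in raw pixels.
#' @param guard_px radius (pixels) by which the mask is dilated before
#'   background pixels are sampled, so PSF halos and dim structure just
#'   below the threshold do not inflate the background estimate.
#' @return An object of class `segmented_stack`: `frames` (masked,
#'   background-subtracted), `background` (per-frame maps), `angle_grid`,
#'   `config`, `mask`, and `noise_sigma_hat` (per-frame noise sd estimated
#'   by the median absolute deviation of clean off-mask residuals; used by
#'   the noise-calibrated solver regularization).
#' @export
subtract_background <- function(stack, mask, window_px = 32,
                                guard_px = 6) {
  stopifnot(inherits(stack, "matirf_stack"))
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  d <- dim(stack$frames)
  if (!all(dim(m) == d[1:2]))
    stop("mask shape does not match the frames")
  mguard <- if (guard_px > 0)
    EBImage::dilate(m * 1, EBImage::makeBrush(2 * guard_px + 1,
                                              "disc")) > 0
  else m
  frames <- stack$frames
  bg <- array(0, dim = d)
  sigma_hat <- numeric(d[3])
  for (f in seq_len(d[3])) {
    b <- .local_background(frames[, , f], mguard, window_px)
    if (is.null(b)) {
      warning("mask covers the entire frame; using global 1st-percentile background")
      b <- matrix(stats::quantile(frames[, , f], 0.01), d[1], d[2])
    }
    resid <- frames[, , f] - b
    clean <- resid[!mguard]
    sigma_hat[f] <- if (length(clean) > 20) stats::mad(clean) else NA_real_
    out <- resid
    out[out < 0] <- 0
    out[!m] <- 0
    frames[, , f] <- out
    bg[, , f] <- b
  }
  structure(list(frames = frames, background = bg,
                 angle_grid = stack$angle_grid, config = stack$config,
                 mask = m, noise_sigma_hat = sigma_hat),
            class = "segmented_stack")
}

#' @export
print.segmented_stack <- function(x, ...) {
  cat("segmented_stack:", dim(x$frames)[3], "frames,", sum(x$mask),
      "in-mask pixels\n")
  invisible(x)
}
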
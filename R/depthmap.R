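#' Solve the axial inverse problem over all masked pixels
#'
#' Applies the per-pixel solver to every in-mask pixel of a segmented
#' multi-angle stack. Pixels are independent subproblems (the "distributed"
#' structure of the inversion): the result does not depend on the order in
#' which pixels are processed. The ADMM path runs all pixels through a
#' batched core with per-pixel penalty adaptation and per-pixel convergence.
#'
#' @param seg a `segmented_stack` from [subtract_background()] (or a
#'   `matirf_stack` with a `mask` argument).
#' @param a a `system_matrix` whose angle grid matches the stack.
#' @param params a [solver_params()]; with `mu_mode = "sigma"` the l1
#'   weight is the universal threshold `sigma sqrt(2 log M)` per pixel,
#'   using the stack's estimated noise sd.
#' @param mask optional logical matrix overriding `seg$mask`.
#' @param sigma additive-noise sd for the sigma mode; default the mean of
#'   `seg$noise_sigma_hat`.
#' @return An object of class `axial_field`: `f` (M x P matrix of
#'   non-negative profiles), `pixels` (P x 2 row/col indices), `dim`
#'   (image size), `axial_grid`, `iterations`, `converged` (per pixel).
#' @export
solve_volume <- function(seg, a, params = solver_params(), mask = NULL,
                         sigma = NULL) {
  stopifnot(inherits(a, "system_matrix"))
  frames <- seg$frames
  if (is.null(mask)) mask <- seg$mask
  if (is.null(mask)) stop("no mask available")
  if (inherits(mask, "binary_mask")) mask <- mask$mask
  d <- dim(frames)
  k <- length(a$angle_grid$theta_deg)
  if (d[3] != k)
    stop("stack has ", d[3], " frames but the system matrix has ", k,
         " angles (azimuth-average first?)")
  if (!isTRUE(all.equal(seg$angle_grid$theta_deg, a$angle_grid$theta_deg)))
    stop("angle grids of the stack and system matrix differ")
  pix <- which(mask, arr.ind = TRUE)
  p <- nrow(pix)
  if (p == 0) stop("empty mask")
  bmat <- matrix(0, k, p)
  for (f in seq_len(k)) bmat[f, ] <- frames[, , f][pix]
  bmat[bmat < 0] <- 0
  if (any(!is.finite(bmat))) stop("non-finite intensities in the stack")
  m <- ncol(a$a)
  nc <- .normalize_columns(a$a)
  if (is.null(sigma) && !is.null(seg$noise_sigma_hat))
    sigma <- mean(seg$noise_sigma_hat, na.rm = TRUE)
  mu_abs <- if (identical(params$mu_mode, "sigma") &&
                !is.null(sigma) && is.finite(sigma)) {
    # universal soft-threshold level on the unit-column scale
    rep(sigma * sqrt(2 * log(m)), p)
  } else {
    params$mu * apply(abs(crossprod(nc$an, bmat)), 2, max)
  }
  nonzero <- colSums(bmat) > 0
  fmat <- matrix(0, m, p)
  iters <- integer(p)
  conv <- rep(TRUE, p)
  if (any(nonzero)) {
    if (params$solver == "admm") {
      out <- .admm_core(nc$an, bmat[, nonzero, drop = FALSE],
                        mu_abs[nonzero], params$rho, params$max_iter,
                        params$tol)
      fmat[, nonzero] <- out$f / nc$scale
      iters[nonzero] <- out$iterations
      conv[nonzero] <- out$converged
    } else {
      idx <- which(nonzero)
      for (j in idx) {
        pr <- solve_pixel(bmat[, j], a, params)
        fmat[, j] <- pr$f
        iters[j] <- if (is.na(pr$iterations)) 0L else pr$iterations
        conv[j] <- pr$converged
      }
    }
  }
  structure(list(f = fmat, pixels = pix, dim = d[1:2],
                 axial_grid = a$axial_grid, iterations = iters,
                 converged = conv),
            class = "axial_field")
}

#' @export
print.axial_field <- function(x, ...) {
  cat("axial_field:", ncol(x$f), "pixel profiles over",
      nrow(x$f), "depth bins;",
      sum(!x$converged), "unconverged\n")
  invisible(x)
}

#' Intensity-weighted mean depth of an axial profile
#'
#' `h = sum(z_m f_m) / sum(f_m)`: the mean depth above the coverslip of the
#' reconstructed axial distribution.
#'
#' @param profile an `axial_profile`, or a numeric vector of axial weights.
#' @param axial_grid the [axial_grid()] the profile lives on.
#' @return Mean depth in nm; `NA` (flagged) when the profile is all zero.
#' @export
depth_from_profile <- function(profile, axial_grid) {
  f <- if (inherits(profile, "axial_profile")) profile$f else
    as.numeric(profile)
  stopifnot(length(f) == length(axial_grid$z_nm))
  s <- sum(f)
  if (s <= 0) return(NA_real_)
  sum(axial_grid$z_nm * f) / s
}

#' Depth map from an axial field
#'
#' Reduces per-pixel axial profiles to the pipeline's product: a 2D map of
#' intensity-weighted mean depth `h`, an integrated-intensity map, the mask
#' of valid pixels, and QC maps (iterations, convergence). Pixels whose
#' profile is identically zero are flagged `NA` in `h`.
#'
#' @param field an `axial_field` from [solve_volume()].
#' @return An object of class `depth_map`: `h` (nm, `NA` off-mask and on
#'   flagged pixels), `intensity`, `mask`, `axial_grid`, `qc` (list of
#'   `iterations` and `converged` maps), `field` (the input, kept for
#'   volume assembly).
#' @export
depth_map <- function(field) {
  stopifnot(inherits(field, "axial_field"))
  h <- int <- matrix(NA_real_, field$dim[1], field$dim[2])
  mask <- matrix(FALSE, field$dim[1], field$dim[2])
  mask[field$pixels] <- TRUE
  s <- colSums(field$f)
  hv <- as.numeric(crossprod(field$f, field$axial_grid$z_nm)) / s
  hv[s <= 0] <- NA_real_
  h[field$pixels] <- hv
  int[field$pixels] <- s
  itmap <- matrix(NA_integer_, field$dim[1], field$dim[2])
  itmap[field$pixels] <- field$iterations
  convmap <- matrix(NA, field$dim[1], field$dim[2])
  convmap[field$pixels] <- field$converged
  structure(list(h = h, intensity = int, mask = mask,
                 axial_grid = field$axial_grid,
                 qc = list(iterations = itmap, converged = convmap),
                 field = field),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  v <- x$h[x$mask]
  cat("depth_map:", sum(x$mask), "in-mask pixels; mean h =",
      format(mean(v, na.rm = TRUE), digits = 4), "nm (range",
      paste(format(range(v, na.rm = TRUE), digits = 4), collapse = "-"),
      ")\n")
  invisible(x)
}

#' Mean depth pooled over a region of interest
#'
#' Pools the axial profiles of all (or a subset of) in-mask pixels into one
#' profile and returns its intensity-weighted mean depth: the reduction used
#' when a single depth value is quoted for a whole structure.
#'
#' @param field an `axial_field` (or a `depth_map`, whose field is used).
#' @param roi optional logical matrix selecting pixels.
#' @return Mean depth (nm) of the pooled profile.
#' @export
roi_mean_depth <- function(field, roi = NULL) {
  if (inherits(field, "depth_map")) field <- field$field
  stopifnot(inherits(field, "axial_field"))
  sel <- if (is.null(roi)) rep(TRUE, ncol(field$f)) else roi[field$pixels]
  pooled <- rowSums(field$f[, sel, drop = FALSE])
  depth_from_profile(pooled, field$axial_grid)
}

#' Assemble the reconstructed near-surface volume
#'
#' Expands an axial field into a 3D stack of x-y sections, one per depth
#' bin: slice m is the image of the profile weights `f_m`. Summing the
#' volume over depth reproduces the integrated-intensity map exactly.
#'
#' @param field an `axial_field` (or `depth_map`).
#' @return A 3D array (rows x cols x depth bins) with attribute `z_nm`.
#' @export
assemble_volume <- function(field) {
  if (inherits(field, "depth_map")) field <- field$field
  stopifnot(inherits(field, "axial_field"))
  m <- nrow(field$f)
  vol <- array(0, dim = c(field$dim, m))
  for (s in seq_len(m)) {
    sl <- matrix(0, field$dim[1], field$dim[2])
    sl[field$pixels] <- field$f[s, ]
    vol[, , s] <- sl
  }
  attr(vol, "z_nm") <- field$axial_grid$z_nm
  vol
}
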
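#' Color-coded depth rendering
#'
#' Encodes depth as hue and signal strength as brightness: each in-mask
#' pixel's color is the colormap value of its mean depth (clipped to
#' `z_range_nm`) multiplied by its normalized integrated intensity.
#' Off-mask and zero-intensity pixels are black.
#'
#' @param dmap a [depth_map()].
#' @param colormap `"viridis"` (perceptually uniform, default) or `"jet"`
#'   (classic rainbow depth coding).
#' @param z_range_nm length-2 depth range mapped onto the colormap; default
#'   the axial grid range.
#' @param gamma gamma applied to the intensity scaling.
#' @return An object of class `depth_rendering`: `rgb` (rows x cols x 3
#'   array in [0, 1]), `colormap`, `z_range_nm`.
#' @export
render_depth <- function(dmap, colormap = c("viridis", "jet"),
                         z_range_nm = NULL, gamma = 1) {
  colormap <- match.arg(colormap)
  stopifnot(inherits(dmap, "depth_map"))
  if (is.null(z_range_nm)) z_range_nm <- range(dmap$axial_grid$z_nm)
  if (diff(z_range_nm) <= 0) stop("degenerate z_range_nm")
  pal <- if (colormap == "viridis")
    grDevices::hcl.colors(256, "viridis")
  else grDevices::colorRampPalette(
    c("darkblue", "blue", "cyan", "green", "yellow", "orange", "red"))(256)
  ramp <- grDevices::colorRamp(pal)
  d <- dim(dmap$h)
  rgb <- array(0, dim = c(d, 3))
  sel <- dmap$mask & is.finite(dmap$h) & is.finite(dmap$intensity) &
    dmap$intensity > 0
  if (any(sel)) {
    hv <- pmin(pmax(dmap$h[sel], z_range_nm[1]), z_range_nm[2])
    t <- (hv - z_range_nm[1]) / diff(z_range_nm)
    cols <- ramp(t) / 255
    iv <- dmap$intensity[sel]
    iv <- (iv / max(iv))^gamma
    for (c in 1:3) {
      plane <- matrix(0, d[1], d[2])
      plane[sel] <- cols[, c] * iv
      rgb[, , c] <- plane
    }
  }
  structure(list(rgb = rgb, colormap = colormap, z_range_nm = z_range_nm),
            class = "depth_rendering")
}

#' Write a depth rendering to an RGB TIFF
#'
#' @param rendering a [render_depth()] result.
#' @param path output TIFF path.
#' @return Invisibly, the path.
#' @export
write_rendering <- function(rendering, path) {
  stopifnot(inherits(rendering, "depth_rendering"))
  tiff::writeTIFF(rendering$rgb, path, bits.per.sample = 8L)
  invisible(path)
}
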
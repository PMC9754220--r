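# Fovea alignment and interpolation of scattered raster samples onto the
# regular and radial analysis grids.

#' Regular analysis grid specification
#'
#' A square grid of `n_nodes` x `n_nodes` nodes centered on the fovea,
#' spanning `[-extent_mm, extent_mm]` in both axes (default 300 nodes over
#' +/- 3 mm, i.e. 0.02 mm spacing).
#'
#' @param n_nodes nodes per axis.
#' @param extent_mm half-width of the grid (mm).
#' @return an object of class `"grid_spec"` with node coordinates.
#' @export
grid_spec <- function(n_nodes = 300L, extent_mm = 3) {
  stopifnot(n_nodes >= 2L, extent_mm > 0)
  nodes <- seq(-extent_mm, extent_mm, length.out = n_nodes)
  structure(list(n_nodes = as.integer(n_nodes), extent_mm = extent_mm,
                 nodes = nodes, spacing = nodes[2] - nodes[1]),
            class = "grid_spec")
}

#' Locate the foveal center
#'
#' The foveal center is the arg-min of a smoothed total retinal thickness
#' map: TRT samples are interpolated to a coarse regular grid, smoothed
#' with an isotropic truncated Gaussian kernel (`sigma` mm, cut at 3 sigma),
#' and minimized over the central 2 x 2 mm window. Ties are broken by the
#' smallest distance to the raster center, then lexicographically in
#' (x, y).
#'
#' @param scan a scan data.frame with `x_mm`, `y_mm`, `TRT` columns
#'   (device frame).
#' @param sigma Gaussian smoothing bandwidth (mm).
#' @param coarse_spacing spacing (mm) of the localization grid.
#' @param window half-width (mm) of the central search window.
#' @return numeric `c(x, y)` position of the foveal center (device frame,
#'   mm).
#' @export
find_fovea <- function(scan, sigma = 0.15, coarse_spacing = 0.05,
                       window = 1) {
  ras <- as_raster(scan, "TRT")
  gx <- seq(min(ras$x), max(ras$x), by = coarse_spacing)
  gy <- seq(min(ras$y), max(ras$y), by = coarse_spacing)
  q <- expand.grid(x = gx, y = gy)
  Z <- matrix(interp_bilinear(ras$x, ras$y, ras$values$TRT, q$x, q$y),
              length(gx), length(gy))
  Zs <- gauss_smooth(Z, coarse_spacing, sigma)
  cw <- abs(gx) <= window
  rw <- abs(gy) <= window
  sub <- Zs[cw, rw, drop = FALSE]
  if (all(is.na(sub))) stop("fovea localization failed: central window empty")
  sx <- gx[cw]; sy <- gy[rw]
  m <- min(sub, na.rm = TRUE)
  idx <- which(sub - m <= 1e-9, arr.ind = TRUE)
  px <- sx[idx[, 1]]; py <- sy[idx[, 2]]
  ord <- order(px^2 + py^2, px, py)
  c(x = px[ord[1]], y = py[ord[1]])
}

#' Normalize an eye to the fovea-centered right-eye frame
#'
#' Subtracts the foveal center from all sample coordinates and mirrors
#' left (OS) eyes in x, so that downstream analysis always works in a
#' fovea-centered frame with +x nasal and +y superior. Thickness values
#' are untouched.
#'
#' @param scan a scan data.frame; its `eye` attribute (or the `eye`
#'   argument) determines mirroring.
#' @param center `c(x, y)` foveal center from [find_fovea()].
#' @param eye `"OD"` or `"OS"`; defaults to the scan's `eye` attribute.
#' @return the normalized scan (attributes preserved, plus `normalized`).
#' @export
normalize_eye <- function(scan, center = c(0, 0), eye = NULL) {
  if (is.null(eye)) eye <- attr(scan, "eye")
  if (is.null(eye)) eye <- "OD"
  stopifnot(eye %in% c("OD", "OS"))
  out <- scan
  out$x_mm <- scan$x_mm - center[[1]]
  out$y_mm <- scan$y_mm - center[[2]]
  if (eye == "OS") out$x_mm <- -out$x_mm
  for (a in c("subject_id", "eye", "protocol", "truth")) {
    attr(out, a) <- attr(scan, a)
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Interpolate scattered raster samples onto a regular grid
#'
#' Piecewise-linear (separable bilinear) interpolation of one layer's
#' samples onto a [grid_spec()] grid. Samples must form a complete regular
#' raster (all supported acquisition protocols do, before and after
#' normalization); nodes outside the sampled extent are `NA` (no
#' extrapolation). Interpolation is exact at sample positions and for
#' affine thickness fields.
#'
#' @param samples a (normalized) scan data.frame.
#' @param grid a [grid_spec()].
#' @param layer column to interpolate (default `"TRT"`).
#' @return an object of class `"thickness_map"`: list with `layer`, `grid`
#'   and the `n_nodes` x `n_nodes` matrix `values` (x runs over rows,
#'   y over columns).
#' @export
interpolate_map <- function(samples, grid = grid_spec(), layer = "TRT") {
  if (!layer %in% names(samples)) stop("unknown layer: ", layer)
  if (nrow(samples) < 3L) stop("need at least 3 samples")
  ras <- as_raster(samples, layer)
  q <- expand.grid(x = grid$nodes, y = grid$nodes)
  v <- interp_bilinear(ras$x, ras$y, ras$values[[layer]], q$x, q$y)
  if (any(v[!is.na(v)] < 0)) v[v < 0 & !is.na(v)] <- 0
  structure(list(layer = layer, grid = grid,
                 values = matrix(v, grid$n_nodes, grid$n_nodes)),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat("<thickness_map>", x$layer, ":", x$grid$n_nodes, "x", x$grid$n_nodes,
      "nodes over +/-", x$grid$extent_mm, "mm;",
      sum(is.na(x$values)), "missing nodes\n")
  invisible(x)
}

#' Resample TRT onto the radial foveal-pit grid
#'
#' Interpolates total retinal thickness along 24 angular directions (15
#' degree steps, 0 degrees = nasal = +x, counterclockwise in the right-eye
#' frame) at radii 0, 0.1, ..., 2 mm. The center value (r = 0) is shared
#' across directions.
#'
#' @param samples a normalized (fovea-centered) scan data.frame.
#' @param n_angles number of directions.
#' @param r_max,dr radial extent and spacing (mm).
#' @return an object of class `"radial_profile"`: list with `angles_deg`,
#'   `radii_mm` and the `n_angles` x `n_radii` matrix `trt`.
#' @export
radial_resample <- function(samples, n_angles = 24L, r_max = 2, dr = 0.1) {
  ras <- as_raster(samples, "TRT")
  angles <- seq(0, 360, length.out = n_angles + 1L)[seq_len(n_angles)]
  radii <- seq(0, r_max, by = dr)
  th <- rep(angles * pi / 180, times = length(radii))
  rr <- rep(radii, each = n_angles)
  v <- interp_bilinear(ras$x, ras$y, ras$values$TRT,
                       rr * cos(th), rr * sin(th))
  if (anyNA(v)) {
    bad <- which(is.na(v))
    stop("radial grid not covered by samples at ", length(bad),
         " node(s), e.g. r = ", rr[bad[1]], " mm, theta = ",
         round(th[bad[1]] * 180 / pi), " deg")
  }
  trt <- matrix(v, n_angles, length(radii))
  trt[, 1] <- trt[1, 1]  # shared center
  structure(list(angles_deg = angles, radii_mm = radii, trt = trt),
            class = "radial_profile")
}
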
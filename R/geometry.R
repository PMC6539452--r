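#' Pinhole XFCT system geometry
#'
#' Geometry of the benchtop scanner: a fan beam travelling along +x, the
#' rotation centre at the world origin, a rectangular tungsten pinhole at 90
#' degrees from the beam axis, and a linear photon-counting detector behind
#' it. Defaults follow the bench values: pinhole 75 mm from the rotation
#' centre, detector 63.5 mm behind the pinhole, 256 pixels of 0.5 mm x 2 mm
#' and a 0.5 mm x 2 mm aperture. All lengths in mm.
#'
#' The slice is modelled in-plane: the 2 mm pixel/aperture height only enters
#' through the solid-angle of the aperture, never as a third image dimension.
#'
#' @param pinhole_to_center,pinhole_to_detector distances in mm
#' @param detector_pixels number of detector pixels
#' @param pixel_width,pixel_height detector pixel size in mm
#' @param aperture_width,aperture_height pinhole aperture size in mm
#' @param detector_side_angle angle of the pinhole axis from the beam axis in
#'   degrees (fixed at 90 in this design)
#' @param source_to_center nominal source distance in mm; the incident beam
#'   is modelled as parallel within the slice, so this value is documentation
#'   of the bench layout rather than a model parameter
#' @return Object of class `xfct_geometry`.
#' @export
system_geometry <- function(pinhole_to_center = 75,
                            pinhole_to_detector = 63.5,
                            detector_pixels = 256,
                            pixel_width = 0.5,
                            pixel_height = 2,
                            aperture_width = 0.5,
                            aperture_height = 2,
                            detector_side_angle = 90,
                            source_to_center = 500) {
  stopifnot(pinhole_to_center > 0, pinhole_to_detector > 0,
            detector_pixels >= 1, pixel_width > 0, pixel_height > 0,
            aperture_width > 0, aperture_height > 0, source_to_center > 0)
  if (detector_side_angle != 90) {
    stop("only the 90-degree side-detector layout is supported")
  }
  structure(list(pinhole_to_center = pinhole_to_center,
                 pinhole_to_detector = pinhole_to_detector,
                 detector_pixels = as.integer(detector_pixels),
                 pixel_width = pixel_width,
                 pixel_height = pixel_height,
                 aperture_width = aperture_width,
                 aperture_height = aperture_height,
                 detector_side_angle = detector_side_angle,
                 source_to_center = source_to_center),
            class = "xfct_geometry")
}

#' @export
print.xfct_geometry <- function(x, ...) {
  cat("<xfct_geometry>\n")
  cat(sprintf("  pinhole %g mm from centre, detector %g mm behind pinhole\n",
              x$pinhole_to_center, x$pinhole_to_detector))
  cat(sprintf("  %d pixels x %g mm (FOV diameter %.1f mm)\n",
              x$detector_pixels, x$pixel_width, fov_diameter(x)))
  invisible(x)
}

#' Reconstruction / simulation voxel grid
#'
#' Square-pixel 2D grid in world mm. Voxel centres sit at
#' `origin + (index - 0.5) * pixel_size` (half-pixel-centre convention).
#'
#' @param n_x,n_y number of voxels along x and y
#' @param pixel_size voxel side in mm
#' @param center world coordinates of the grid centre (default the rotation
#'   centre)
#' @return Object of class `xfct_grid` with the origin at the lower-left
#'   corner.
#' @export
voxel_grid <- function(n_x = 128, n_y = n_x, pixel_size = 0.5, center = c(0, 0)) {
  stopifnot(n_x >= 1, n_y >= 1, pixel_size > 0, length(center) == 2)
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 pixel_size = pixel_size,
                 origin = c(center[1] - n_x * pixel_size / 2,
                            center[2] - n_y * pixel_size / 2)),
            class = "xfct_grid")
}

#' Voxel centre coordinates of a grid
#'
#' @param grid an `xfct_grid`
#' @return List with vectors `x` and `y` of voxel-centre coordinates (mm).
#' @export
grid_centers <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$n_x) - 0.5) * grid$pixel_size,
       y = grid$origin[2] + (seq_len(grid$n_y) - 0.5) * grid$pixel_size)
}

#' Detector pixel centre coordinates
#'
#' Transverse coordinate of each pixel centre along the detector line,
#' centred on the pinhole axis.
#'
#' @param geom an `xfct_geometry`
#' @return Numeric vector of length `detector_pixels` (mm).
#' @export
detector_pixel_centers <- function(geom) {
  n <- geom$detector_pixels
  (seq_len(n) - (n + 1) / 2) * geom$pixel_width
}

#' Diameter of the field of view imaged onto the detector
#'
#' Object-plane diameter whose pinhole image spans the whole detector:
#' detector length scaled by the pinhole magnification.
#'
#' @param geom an `xfct_geometry`
#' @return Diameter in mm.
#' @export
fov_diameter <- function(geom) {
  geom$detector_pixels * geom$pixel_width *
    geom$pinhole_to_center / geom$pinhole_to_detector
}

#' Pinhole response: solid-angle coupling of a point to a detector pixel
#'
#' Fraction of the unit sphere around an emitting point, expressed relative
#' to 4 pi, subtended by directions that pass through the ideal (infinitely
#' thin) rectangular aperture *and* land on the requested pixel. The
#' aperture's image from the point is a penumbra rectangle on the detector;
#' the per-pixel value is the total aperture solid angle times the 1D overlap
#' fraction of that penumbra with the pixel. Coordinates are apparatus-frame:
#' beam along +x, pinhole at `(0, -pinhole_to_center)`.
#'
#' @param voxel_xy emitting point `(x, y)` in mm
#' @param pixel_index 1-based detector pixel index, or `NULL` for the full
#'   per-pixel vector
#' @param geom an `xfct_geometry`
#' @return Dimensionless solid-angle fraction(s).
#' @export
pinhole_response <- function(voxel_xy, pixel_index = NULL, geom) {
  stopifnot(length(voxel_xy) == 2, inherits(geom, "xfct_geometry"))
  L1 <- geom$pinhole_to_center
  L2 <- geom$pinhole_to_detector
  tv <- voxel_xy[2] + L1
  n <- geom$detector_pixels
  out <- numeric(n)
  if (tv > 1e-6) {
    uc <- -voxel_xy[1] * L2 / tv
    wimg <- geom$aperture_width * (tv + L2) / tv
    r2 <- voxel_xy[1]^2 + tv^2
    omega <- geom$aperture_width * geom$aperture_height * (tv / sqrt(r2)) /
      (4 * pi * r2)
    edges <- (seq_len(n + 1) - 1 - n / 2) * geom$pixel_width
    ov <- pmin(edges[-1], uc + wimg / 2) - pmax(edges[-(n + 1)], uc - wimg / 2)
    out <- omega * pmax(ov, 0) / wimg
  }
  if (is.null(pixel_index)) out else out[pixel_index]
}

#' Compton scatter angle of a voxel as seen through the pinhole
#'
#' Angle between the incident beam direction at the voxel and the direction
#' from the voxel to the pinhole aperture.
#'
#' @param voxel_xy point `(x, y)` in mm (apparatus frame unless
#'   `pinhole_xy` is supplied)
#' @param beam_direction unit (or any nonzero) incident direction vector
#' @param geom an `xfct_geometry`
#' @param pinhole_xy optional explicit pinhole position, overriding the
#'   apparatus-frame default `(0, -pinhole_to_center)`
#' @return Angle in radians, in `[0, pi]`.
#' @export
scatter_angle <- function(voxel_xy, beam_direction = c(1, 0), geom,
                          pinhole_xy = NULL) {
  stopifnot(length(voxel_xy) == 2, length(beam_direction) == 2)
  if (is.null(pinhole_xy)) pinhole_xy <- c(0, -geom$pinhole_to_center)
  u <- pinhole_xy - voxel_xy
  b <- beam_direction / sqrt(sum(beam_direction^2))
  ct <- sum(u * b) / sqrt(sum(u^2))
  acos(min(max(ct, -1), 1))
}

#' Representative scatter angle of each detector pixel
#'
#' Each pixel's line of sight through the pinhole is intersected with the
#' incident-beam midline (the line through the rotation centre along the
#' beam); the scatter angle at that intersection is taken as the single
#' representative angle for all photons counted by the pixel. This is the
#' per-pixel angle used to evaluate the relative scattered-photon numbers.
#'
#' @param geom an `xfct_geometry`
#' @return Numeric vector of angles in radians, one per pixel.
#' @export
pixel_scatter_angles <- function(geom) {
  L1 <- geom$pinhole_to_center
  L2 <- geom$pinhole_to_detector
  u <- detector_pixel_centers(geom)
  # ray pixel -> pinhole extended to the beam midline y = 0
  x_mid <- -u * L1 / L2
  vapply(x_mid, function(x) scatter_angle(c(x, 0), c(1, 0), geom), numeric(1))
}

#' Optical depth of a line segment through an attenuation map
#'
#' Exact incremental (Siddon-style) traversal: the sum over traversed voxels
#' of `mu * intersection length`. Segments (or parts of segments) outside the
#' grid contribute nothing.
#'
#' @param start,end world points `(x, y)` in mm
#' @param mu_map matrix (`n_x` x `n_y`) of linear attenuation in 1/cm
#' @param grid the `xfct_grid` the map lives on
#' @return Dimensionless optical depth.
#' @export
trace_line_integral <- function(start, end, mu_map, grid) {
  stopifnot(length(start) == 2, length(end) == 2,
            nrow(mu_map) == grid$n_x, ncol(mu_map) == grid$n_y)
  cpp_line_depth(mu_map, grid$pixel_size, grid$origin[1], grid$origin[2],
                 start[1], start[2], end[1], end[2])
}

#' Voxels traversed by a line segment
#'
#' @inheritParams trace_line_integral
#' @return Data frame with 1-based voxel indices `ix`, `iy` and the chord
#'   `length_mm` inside each voxel; the lengths sum to the in-grid chord.
#' @export
trace_ray <- function(start, end, grid) {
  r <- cpp_trace_cells(grid$n_x, grid$n_y, grid$pixel_size,
                       grid$origin[1], grid$origin[2],
                       start[1], start[2], end[1], end[2])
  data.frame(ix = r$ix, iy = r$iy, length_mm = r$length_mm)
}

#' View angles of an acquisition
#'
#' Object rotation angle of each view, equally spaced over the angular range.
#'
#' @param n_views number of views
#' @param angular_range full range in degrees (default 360)
#' @return Angles in radians.
#' @export
view_angles <- function(n_views, angular_range = 360) {
  (seq_len(n_views) - 1) * (angular_range / n_views) * pi / 180
}
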
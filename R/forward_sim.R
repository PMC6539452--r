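#' Acquisition protocol of the three-bin fluorescence scan
#'
#' Defaults follow the bench protocol: 45 projections over a full rotation
#' at 10 s exposure per angle (7.5 min per slice), counted into the three
#' contiguous energy bins.
#'
#' @param n_views number of projections (default 45)
#' @param angular_range degrees spanned by the views (default 360)
#' @param exposure_per_view seconds per view (default 10)
#' @param source_fluence incident photons per mm^2 per second at the rotation
#'   centre. The absolute tube output is not part of the model contract
#'   (calibration removes the scale); the default is chosen so that the
#'   default calibration phantom yields peak fluorescence-bin expectations of
#'   roughly 1e3 counts per pixel-view, i.e. phantom-study-like statistics.
#' @param scatter_scale relative strength of the Compton background; the
#'   default puts the scatter level in the fluorescence bin at the same order
#'   as the fluorescence peak, as seen in raw bench projections
#' @param bins list of three `xfct_energy_bin` (default 33-39/39-45/45-51)
#' @return Object of class `xfct_protocol`.
#' @export
acquisition_protocol <- function(n_views = 45, angular_range = 360,
                                 exposure_per_view = 10,
                                 source_fluence = 1e8,
                                 scatter_scale = 2.5,
                                 bins = default_energy_bins()) {
  stopifnot(n_views >= 1, exposure_per_view > 0, source_fluence > 0,
            scatter_scale >= 0, length(bins) == 3)
  structure(list(n_views = as.integer(n_views), angular_range = angular_range,
                 exposure_per_view = exposure_per_view,
                 source_fluence = source_fluence,
                 scatter_scale = scatter_scale, bins = bins),
            class = "xfct_protocol")
}

#' @export
print.xfct_protocol <- function(x, ...) {
  cat(sprintf("<xfct_protocol> %d views / %g deg, %g s per view (%.2g min total)\n",
              x$n_views, x$angular_range, x$exposure_per_view,
              x$n_views * x$exposure_per_view / 60))
  invisible(x)
}

# relative per-bin scattered-photon weights on a theta lookup grid,
# normalized to the middle bin at 90 degrees (the simulator's scatter_scale
# then directly scales the 90-degree middle-bin level)
.scatter_weight_table <- function(spectrum, bins, n_theta = 181) {
  theta <- seq(0, pi, length.out = n_theta)
  w <- vapply(bins, function(b) bin_scatter_weight(spectrum, b, theta),
              numeric(n_theta))
  ref <- w[(n_theta + 1) %/% 2, 2]
  if (ref > 0) w <- w / ref
  list(theta = theta, w = w)
}

#' Simulate a three-bin pinhole XFCT acquisition
#'
#' Single-scatter forward model of the slice acquisition. For every view and
#' voxel the incident fluence is attenuated along the beam to the voxel
#' (single effective incident energy), then
#' \itemize{
#'   \item fluorescence: the Gd concentration emits K-alpha photons
#'     isotropically; they are attenuated at 42.98 keV on the way to the
#'     pinhole and distributed over detector pixels by the pinhole response.
#'     Fluorescence is counted only in the middle (39-45 keV) bin.
#'   \item Compton scatter: every voxel scatters with an electron-density
#'     weight (bulk density relative to water) into the per-voxel scatter
#'     angle towards the pinhole; the per-bin yield follows the
#'     Klein-Nishina-weighted spectral integral and the escaping photon is
#'     attenuated at the bin-centre energy. Scatter is counted in all bins.
#' }
#' Poisson noise is applied per (bin, view, pixel) when `noise` is on. The
#' noiseless fluorescence-only and scatter-only components are retained in
#' the result as ground truth for correction studies.
#'
#' @param truth an `xfct_truth` from [rasterize()]
#' @param geom an `xfct_geometry`
#' @param spectrum incident spectrum (default 140 kVp tube + 0.4 mm Cu)
#' @param protocol an `xfct_protocol`
#' @param seed RNG seed for the Poisson draw (optional)
#' @param noise logical; `FALSE` returns expectations
#' @return Object of class `xfct_sinograms`: `counts` is a
#'   `(3, n_views, detector_pixels)` array; `expected`, `fluorescence` and
#'   `scatter` hold the noiseless components; plus acquisition metadata.
#' @export
simulate_xfct <- function(truth, geom = system_geometry(),
                          spectrum = spectrum_tube(140, 0.4),
                          protocol = acquisition_protocol(),
                          seed = NULL, noise = TRUE) {
  stopifnot(inherits(truth, "xfct_truth"), inherits(geom, "xfct_geometry"),
            inherits(protocol, "xfct_protocol"))
  grid <- truth$grid
  lines <- gd_fluorescence_lines()
  e_inc <- effective_energy(spectrum, above_keV = lines$k_edge)
  e_xrf <- lines$lines$energy_keV[1]
  bins <- protocol$bins
  bin_mid <- vapply(bins, function(b) (b$e_min + b$e_max) / 2, numeric(1))
  mu_inc <- mu_map(truth, e_inc)
  mu_xrf <- mu_map(truth, e_xrf)
  mu_b <- lapply(bin_mid, function(E) mu_map(truth, E))
  wt <- .scatter_weight_table(spectrum, bins)

  base <- protocol$source_fluence * protocol$exposure_per_view *
    grid$pixel_size^2
  q_em <- truth$concentration * 1e-3 * base * xrf_yield_factor(lines, bins[[2]])
  q_sc <- truth$density * protocol$scatter_scale * 1e-3 * base
  angles <- view_angles(protocol$n_views, protocol$angular_range)
  sim <- cpp_sim_xfct(q_em, q_sc, mu_inc, mu_xrf,
                      mu_b[[1]], mu_b[[2]], mu_b[[3]],
                      grid$pixel_size, grid$origin[1], grid$origin[2],
                      angles, geom$pinhole_to_center, geom$pinhole_to_detector,
                      geom$detector_pixels, geom$pixel_width,
                      geom$aperture_width, geom$aperture_height,
                      wt$theta, wt$w)
  np <- geom$detector_pixels
  expected <- array(0, dim = c(3, protocol$n_views, np))
  for (b in 1:3) expected[b, , ] <- sim$scatter[[b]]
  expected[2, , ] <- expected[2, , ] + sim$fluorescence
  counts <- expected
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    counts <- array(stats::rpois(length(expected), expected), dim = dim(expected))
  }
  structure(list(counts = counts, expected = expected,
                 fluorescence = sim$fluorescence, scatter = sim$scatter,
                 bins = bins, geometry = geom, protocol = protocol,
                 grid = grid, spectrum = spectrum, e_inc = e_inc,
                 e_xrf = e_xrf, seed = seed, noise = noise),
            class = "xfct_sinograms")
}

#' @export
print.xfct_sinograms <- function(x, ...) {
  cat(sprintf("<xfct_sinograms> 3 bins x %d views x %d pixels (%s)\n",
              dim(x$counts)[2], dim(x$counts)[3],
              if (x$noise) "Poisson counts" else "noiseless expectations"))
  cat(sprintf("  peak fluorescence-bin expectation %.3g counts\n",
              max(x$expected[2, , ])))
  invisible(x)
}

#' Simulate a transmission (CT) scan of the slice
#'
#' Parallel-beam line integrals of the attenuation map at the effective
#' energy of the (filtered, low-kVp) transmission spectrum, with
#' Beer-Lambert transmission and optional Poisson counting noise. The
#' transmission scan uses many more views than the fluorescence scan, as the
#' bench CBCT does (600 projections there; 180 parallel views here by
#' default).
#'
#' @param truth an `xfct_truth`
#' @param spectrum transmission spectrum (default 65 kVp tube + 0.1 mm Cu)
#' @param n_views parallel views over 180 degrees (default 180)
#' @param counts_per_ray unattenuated photons per detector bin (default 2e4;
#'   the transmission tube runs at much lower power than the fluorescence
#'   tube, and its dose is ~3 orders of magnitude below the XFCT dose)
#' @param seed RNG seed
#' @param noise logical
#' @return Object of class `xfct_ct_sinogram` with the log-transformed
#'   sinogram `mu_sinogram` (optical depth per ray; noisy rays with zero
#'   counts are floored at one count), plus ray geometry and metadata.
#' @export
simulate_transmission <- function(truth, spectrum = spectrum_tube(65, 0.1),
                                  n_views = 180, counts_per_ray = 2e4,
                                  seed = NULL, noise = TRUE) {
  stopifnot(inherits(truth, "xfct_truth"))
  grid <- truth$grid
  e_eff <- effective_energy(spectrum)
  mu <- mu_map(truth, e_eff)
  angles <- view_angles(n_views, 180)
  nr <- grid$n_x
  offsets <- (seq_len(nr) - (nr + 1) / 2) * grid$pixel_size
  depths <- cpp_parallel_sinogram(mu, grid$pixel_size,
                                  grid$origin[1], grid$origin[2],
                                  angles, offsets)
  counts <- NULL
  mu_sino <- depths
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    expected <- counts_per_ray * exp(-depths)
    counts <- matrix(stats::rpois(length(expected), expected), nrow = n_views)
    mu_sino <- -log(pmax(counts, 1) / counts_per_ray)
  }
  structure(list(mu_sinogram = mu_sino, depths = depths, counts = counts,
                 counts_per_ray = counts_per_ray, angles = angles,
                 offsets = offsets, e_eff = e_eff, grid = grid,
                 spectrum = spectrum, seed = seed, noise = noise),
            class = "xfct_ct_sinogram")
}

#' @export
print.xfct_ct_sinogram <- function(x, ...) {
  cat(sprintf("<xfct_ct_sinogram> %d views x %d rays at %.1f keV (%s)\n",
              nrow(x$mu_sinogram), ncol(x$mu_sinogram), x$e_eff,
              if (x$noise) sprintf("%g counts/ray", x$counts_per_ray)
              else "noiseless"))
  invisible(x)
}
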
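# shared small-scale fixtures: a 32 mm field with a shorter detector keeps
# the property tests fast while exercising the same geometry code paths

small_geometry <- function() system_geometry(detector_pixels = 64)

small_grid <- function(n = 64) voxel_grid(n, n, 0.5)

small_cal_phantom <- function(concentrations = c(0, 2, 5, 10, 15, 20)) {
  calibration_phantom(concentrations, insertion_radius = 2.5,
                      ring_radius = 10, background_radius = 15)
}

small_protocol <- function(n_views = 16, ...) {
  acquisition_protocol(n_views = n_views, ...)
}

# a bare ground-truth object with prescribed concentration / density maps
# (vacuum attenuation unless masses are supplied); used for single-voxel and
# superposition checks where the analytic expectation must be exact
bare_truth <- function(grid, concentration = NULL, density = NULL) {
  zero <- matrix(0, grid$n_x, grid$n_y)
  if (is.null(concentration)) concentration <- zero
  if (is.null(density)) density <- zero
  structure(list(concentration = concentration,
                 masses = list(water = density, pmma = zero,
                               bone_cortical = zero, nagdf4 = zero),
                 density = density, grid = grid, spec = NULL),
            class = "xfct_truth")
}

disc_mask <- function(grid, radius, center = c(0, 0)) {
  ctr <- grid_centers(grid)
  1 * (outer(ctr$x - center[1], ctr$y - center[2],
             function(a, b) a^2 + b^2) <= radius^2)
}

flat_spectrum <- function(e_min, e_max, n = 50, fluence = 1) {
  structure(list(energies = seq(e_min, e_max, length.out = n),
                 fluence = rep(fluence, n),
                 description = "flat test spectrum"),
            class = "xfct_spectrum")
}

# per-voxel emission scale (counts per mg/mL) implied by a protocol, the
# absolute-units bridge between simulated concentration and MLEM output
emission_scale <- function(protocol, grid) {
  protocol$source_fluence * protocol$exposure_per_view * grid$pixel_size^2 *
    1e-3 * xrf_yield_factor(gd_fluorescence_lines(),
                            default_energy_bins()[[2]])
}
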
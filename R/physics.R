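#' Physical constants used by the Compton model
#'
#' Classical electron radius and electron rest energy.
#'
#' @return Named list with `r0_cm` (classical electron radius, cm) and
#'   `mec2_keV` (electron rest energy, keV).
#' @export
scatter_constants <- function() {
  list(r0_cm = 2.8179403262e-13, mec2_keV = 510.99895)
}

#' Klein-Nishina differential Compton cross-section per unit polar angle
#'
#' Differential cross-section for Compton scattering of an unpolarized photon
#' of energy `E` into polar angle `theta`, integrated over azimuth (hence the
#' `2 pi sin(theta)` factor): the distribution of scatter angles used both by
#' the forward simulator and by the energy-bin scatter correction.
#'
#' @param E photon energy in keV (scalar or vector, > 0)
#' @param theta scatter angle in radians, in `[0, pi]` (scalar or vector)
#' @return Cross-section per radian in cm^2; zero at `theta = 0` and
#'   `theta = pi` where `sin(theta)` vanishes.
#' @examples
#' klein_nishina(60, pi / 2)
#' # the E -> 0 limit integrates to the Thomson cross-section (8/3) pi r0^2
#' integrate(function(t) klein_nishina(0.1, t), 0, pi)$value
#' @export
klein_nishina <- function(E, theta) {
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("'E' must be a positive, finite energy in keV")
  }
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > pi)) {
    stop("'theta' must lie in [0, pi]")
  }
  k <- scatter_constants()
  alpha <- E / k$mec2_keV
  ct <- cos(theta)
  onemc <- 1 - ct
  denom <- 1 + alpha * onemc
  term1 <- (1 / denom)^2
  term2 <- (1 + ct^2) / 2
  term3 <- 1 + alpha^2 * onemc^2 / ((1 + ct^2) * denom)
  2 * pi * k$r0_cm^2 * sin(theta) * term1 * term2 * term3
}

#' Define a detector energy bin
#'
#' @param e_min,e_max bin edges in keV, `e_min < e_max`
#' @param label optional text label
#' @return An object of class `xfct_energy_bin`.
#' @export
energy_bin <- function(e_min, e_max, label = sprintf("%g-%g keV", e_min, e_max)) {
  stopifnot(is.numeric(e_min), is.numeric(e_max), is.finite(e_min), is.finite(e_max))
  if (e_min >= e_max) stop("'e_min' must be smaller than 'e_max'")
  structure(list(e_min = e_min, e_max = e_max, label = label),
            class = "xfct_energy_bin")
}

#' The three contiguous acquisition bins of the photon-counting detector
#'
#' The middle bin (39-45 keV) records the Gd K-alpha fluorescence; the two
#' side bins bracket it and are used for scatter estimation.
#'
#' @return List of three `xfct_energy_bin` objects: 33-39, 39-45, 45-51 keV.
#' @export
default_energy_bins <- function() {
  list(energy_bin(33, 39), energy_bin(39, 45), energy_bin(45, 51))
}

#' Gadolinium K-fluorescence emission lines
#'
#' K-edge at 50.2 keV; K-alpha1 at 42.98 keV and K-alpha2 at 42.28 keV with
#' the usual ~2:1 intensity ratio. K-beta lines are deliberately omitted:
#' they fall in the 45-51 keV side bin and are not counted as signal.
#'
#' @param fluorescence_yield K-shell fluorescence yield omega_K; the default
#'   0.93 is the standard literature value for Gd. The absolute value is
#'   removed by concentration calibration and only sets the simulated scale.
#' @return Object of class `xfct_lines` with fields `k_edge`, `lines`
#'   (data.frame of `energy_keV`, `intensity` summing to 1) and
#'   `fluorescence_yield`.
#' @export
gd_fluorescence_lines <- function(fluorescence_yield = 0.93) {
  stopifnot(fluorescence_yield > 0, fluorescence_yield <= 1)
  structure(list(
    k_edge = 50.2,
    lines = data.frame(energy_keV = c(42.98, 42.28),
                       intensity = c(0.645, 0.355)),
    fluorescence_yield = fluorescence_yield
  ), class = "xfct_lines")
}

#' Per-bin fluorescence emission weight
#'
#' Fraction of K-shell vacancies that produce a photon counted in `bin`:
#' the fluorescence yield times the summed relative intensity of the lines
#' whose energy falls inside the bin. For the Gd defaults both K-alpha lines
#' lie in the 39-45 keV bin, so that bin gets the full yield.
#'
#' @param lines an `xfct_lines` object, see [gd_fluorescence_lines()]
#' @param bin an `xfct_energy_bin`
#' @return Dimensionless emission weight.
#' @export
xrf_yield_factor <- function(lines, bin) {
  stopifnot(inherits(lines, "xfct_lines"), inherits(bin, "xfct_energy_bin"))
  inside <- lines$lines$energy_keV >= bin$e_min & lines$lines$energy_keV < bin$e_max
  lines$fluorescence_yield * sum(lines$lines$intensity[inside])
}

#' Monoenergetic incident spectrum
#'
#' @param energy_keV the single photon energy
#' @param fluence relative fluence (default 1)
#' @return An `xfct_spectrum` object with a one-point grid.
#' @export
spectrum_mono <- function(energy_keV, fluence = 1) {
  stopifnot(energy_keV > 0, fluence >= 0)
  structure(list(energies = energy_keV, fluence = fluence,
                 description = sprintf("monoenergetic %g keV", energy_keV)),
            class = "xfct_spectrum")
}

#' Analytic filtered X-ray tube spectrum
#'
#' Kramers' bremsstrahlung shape `(kvp - E) / E` multiplied by the
#' Beer-Lambert transmission of a copper filter, evaluated on a regular
#' energy grid. This is the stand-in for the measured tube spectra: 140 kVp
#' with 0.4 mm Cu for the fluorescence scan, 65 kVp with 0.1 mm Cu for the
#' transmission scan. Characteristic tungsten anode lines are not modelled.
#'
#' @param kvp tube voltage in kV (maximum photon energy in keV)
#' @param filter_mm_cu copper filter thickness in mm
#' @param e_min low cut of the grid in keV (default 20, the lower limit of
#'   the embedded attenuation tables; the Cu filter removes almost everything
#'   below it anyway)
#' @param n_points grid size
#' @return An `xfct_spectrum` object (unnormalized relative fluence per keV).
#' @export
spectrum_tube <- function(kvp, filter_mm_cu = 0, e_min = 20, n_points = 241) {
  stopifnot(kvp > e_min)
  E <- seq(e_min, kvp, length.out = n_points)
  fl <- pmax(kvp - E, 0) / E
  if (filter_mm_cu > 0) {
    cu <- material_table("copper")
    mu <- mass_attenuation(cu, E) * cu$density     # 1/cm
    fl <- fl * exp(-mu * filter_mm_cu / 10)
  }
  structure(list(energies = E, fluence = fl,
                 description = sprintf("tube %g kVp + %g mm Cu", kvp, filter_mm_cu)),
            class = "xfct_spectrum")
}

#' Fluence-weighted effective energy of a spectrum
#'
#' @param spectrum an `xfct_spectrum`
#' @param above_keV optional lower cut; e.g. the Gd K-edge to obtain the
#'   effective energy of the fluorescence-stimulating part of the beam
#' @return Energy in keV.
#' @export
effective_energy <- function(spectrum, above_keV = NULL) {
  stopifnot(inherits(spectrum, "xfct_spectrum"))
  E <- spectrum$energies
  fl <- spectrum$fluence
  if (!is.null(above_keV)) {
    keep <- E >= above_keV
    if (!any(keep) || sum(fl[keep]) <= 0) {
      stop("spectrum has no fluence above ", above_keV, " keV")
    }
    E <- E[keep]; fl <- fl[keep]
  }
  sum(E * fl) / sum(fl)
}

#' Relative number of photons scattered into an energy bin
#'
#' Quadrature of `I0(E) * f_KN(E, theta)` over the bin, on the spectrum's own
#' energy grid (trapezoid rule, with the bin edges inserted by linear
#' interpolation). These are the relative per-bin scattered-photon numbers
#' whose ratios drive the side-band scatter estimate.
#'
#' @param spectrum an `xfct_spectrum`
#' @param bin an `xfct_energy_bin`
#' @param theta scatter angle in radians (scalar or vector)
#' @return Nonnegative weight (vectorized over `theta`); zero when the bin is
#'   outside the spectral support.
#' @export
bin_scatter_weight <- function(spectrum, bin, theta) {
  stopifnot(inherits(spectrum, "xfct_spectrum"), inherits(bin, "xfct_energy_bin"))
  E <- spectrum$energies
  fl <- spectrum$fluence
  if (length(E) == 0) stop("empty spectrum")
  if (length(E) == 1) {
    # delta spectrum: collapses to a single Klein-Nishina evaluation
    if (E >= bin$e_min && E < bin$e_max) {
      return(fl * klein_nishina(E, theta))
    }
    return(rep(0, length(theta)))
  }
  lo <- max(bin$e_min, min(E))
  hi <- min(bin$e_max, max(E))
  if (lo >= hi) return(rep(0, length(theta)))
  keep <- E > lo & E < hi
  Eg <- c(lo, E[keep], hi)
  fg <- c(stats::approx(E, fl, xout = lo)$y, fl[keep],
          stats::approx(E, fl, xout = hi)$y)
  vapply(theta, function(th) {
    y <- fg * klein_nishina(Eg, rep(th, length(Eg)))
    sum(diff(Eg) * (y[-1] + y[-length(y)]) / 2)
  }, numeric(1))
}

# cache for the parsed CSV tables
.table_cache <- new.env(parent = emptyenv())

#' Embedded mass-attenuation table for a reference material
#'
#' Tables are plain-CSV fixtures shipped with the package, transcribed from
#' the public NIST tabulations on a coarse 20-150 keV grid, with the Gd
#' K-edge (50.2396 keV) represented by bracketing grid points so that
#' interpolation never crosses the discontinuity.
#'
#' @param material one of `"water"`, `"pmma"`, `"bone_cortical"`,
#'   `"gadolinium"`, `"nagdf4"`, `"copper"`
#' @return Object of class `xfct_material` with fields `material`, `energies`
#'   (keV), `mu_rho` (cm^2/g), `photoelectric` (cm^2/g or NA), `density`
#'   (reference density, g/cm^3) and `k_edge` (keV or NA).
#' @export
material_table <- function(material = c("water", "pmma", "bone_cortical",
                                        "gadolinium", "nagdf4", "copper")) {
  material <- match.arg(material)
  if (!is.null(.table_cache[[material]])) return(.table_cache[[material]])
  path <- system.file("extdata", paste0(material, ".csv"), package = "xfct")
  if (path == "") stop("no embedded table for material '", material, "'")
  header <- readLines(path, n = 2)
  density <- as.numeric(sub(".*density_g_per_cm3:\\s*", "", header[2]))
  tab <- utils::read.csv(path, comment.char = "#")
  kedge <- if (material %in% c("gadolinium", "nagdf4")) 50.2396 else NA_real_
  out <- structure(list(material = material,
                        energies = tab$energy_keV,
                        mu_rho = tab$mu_over_rho_cm2_per_g,
                        photoelectric = tab$photoelectric_cm2_per_g,
                        density = density,
                        k_edge = kedge),
                   class = "xfct_material")
  assign(material, out, envir = .table_cache)
  out
}

# log-log interpolation of one tabulated coefficient column, split at the
# K edge so the discontinuity is never bridged
.loglog_interp <- function(energies, values, E, k_edge = NA_real_) {
  interp_one <- function(e) {
    idx <- seq_along(energies)
    if (!is.na(k_edge)) {
      idx <- if (e < k_edge) which(energies < k_edge) else which(energies > k_edge)
    }
    Eg <- energies[idx]; Vg <- values[idx]
    if (e < min(Eg) - 1e-9 || e > max(Eg) + 1e-9) {
      stop("energy ", e, " keV outside the tabulated range [",
           min(Eg), ", ", max(Eg), "]")
    }
    e <- min(max(e, min(Eg)), max(Eg))
    exp(stats::approx(log(Eg), log(Vg), xout = log(e))$y)
  }
  vapply(E, interp_one, numeric(1))
}

#' Mass attenuation coefficient of a material at arbitrary energy
#'
#' Log-log interpolation within the embedded table, split at the K edge.
#'
#' @param table an `xfct_material` from [material_table()]
#' @param E energy in keV (vectorized)
#' @return mu/rho in cm^2/g.
#' @export
mass_attenuation <- function(table, E) {
  stopifnot(inherits(table, "xfct_material"))
  .loglog_interp(table$energies, table$mu_rho, E, table$k_edge)
}

#' Linear attenuation coefficient of a material mixture
#'
#' Mixture rule `mu = density * sum_k w_k (mu/rho)_k(E)` over mass fractions.
#'
#' @param materials list of `xfct_material` tables (or a single table)
#' @param mass_fractions nonnegative weights summing to 1 (recycled to 1 for
#'   a single material)
#' @param density bulk density of the mixture in g/cm^3
#' @param E energy in keV (vectorized)
#' @return mu in 1/cm.
#' @export
attenuation_coefficient <- function(materials, mass_fractions = 1, density, E) {
  if (inherits(materials, "xfct_material")) materials <- list(materials)
  stopifnot(length(materials) == length(mass_fractions),
            all(mass_fractions >= 0), density >= 0)
  if (abs(sum(mass_fractions) - 1) > 1e-8) {
    stop("mass fractions must sum to 1")
  }
  mr <- rep(0, length(E))
  for (k in seq_along(materials)) {
    if (mass_fractions[k] > 0) {
      mr <- mr + mass_fractions[k] * mass_attenuation(materials[[k]], E)
    }
  }
  density * mr
}

#' @export
print.xfct_spectrum <- function(x, ...) {
  cat("<xfct_spectrum>", x$description, "\n")
  cat(sprintf("  %d grid points, %.3g-%.3g keV, effective energy %.1f keV\n",
              length(x$energies), min(x$energies), max(x$energies),
              effective_energy(x)))
  invisible(x)
}

#' @export
print.xfct_material <- function(x, ...) {
  cat("<xfct_material>", x$material,
      sprintf("(density %.3g g/cm^3, %d energies %g-%g keV)\n",
              x$density, length(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}
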
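#' Per-pixel relative scattered-photon weights for the three bins
#'
#' For each detector pixel the representative scatter angle (pixel sight line
#' through the pinhole intersected with the incident-beam midline, see
#' [pixel_scatter_angles()]) is evaluated, and the relative number of
#' scattered photons expected in each energy bin is computed as the
#' Klein-Nishina-weighted integral of the incident spectrum over the bin.
#'
#' @param geom an `xfct_geometry`
#' @param spectrum the incident spectrum
#' @param bins list of three energy bins
#' @return Matrix `detector_pixels` x 3 of nonnegative weights.
#' @export
scatter_bin_weights <- function(geom, spectrum, bins = default_energy_bins()) {
  theta <- pixel_scatter_angles(geom)
  vapply(bins, function(b) bin_scatter_weight(spectrum, b, theta),
         numeric(length(theta)))
}

#' Estimate the Compton background in the fluorescence bin from the side bins
#'
#' Side-band estimate: the middle-bin scatter is the average of the two side
#' bins scaled by the theoretical per-bin ratios,
#' `Sca = ( (r2/r1) Ns1 + (r2/r3) Ns3 ) / 2`, per view and pixel.
#'
#' @param counts a `(3, n_views, n_pixels)` counts array, or an
#'   `xfct_sinograms` object
#' @param weights `n_pixels` x 3 matrix of relative scattered-photon numbers
#'   (see [scatter_bin_weights()]); side-bin weights must be strictly
#'   positive
#' @return Matrix `n_views` x `n_pixels` of estimated middle-bin scatter.
#' @export
estimate_scatter <- function(counts, weights) {
  if (inherits(counts, "xfct_sinograms")) counts <- counts$counts
  stopifnot(length(dim(counts)) == 3, dim(counts)[1] == 3,
            ncol(weights) == 3, nrow(weights) == dim(counts)[3])
  if (any(weights[, c(1, 3)] <= 0)) {
    stop("side-bin scatter weights must be strictly positive")
  }
  r1 <- weights[, 2] / weights[, 1]
  r3 <- weights[, 2] / weights[, 3]
  ns1 <- counts[1, , , drop = TRUE]
  ns3 <- counts[3, , , drop = TRUE]
  if (is.null(dim(ns1))) {                 # single-view acquisitions
    ns1 <- matrix(ns1, nrow = 1); ns3 <- matrix(ns3, nrow = 1)
  }
  (sweep(ns1, 2, r1, `*`) + sweep(ns3, 2, r3, `*`)) / 2
}

#' Scatter-correct a three-bin sinogram set
#'
#' Applies the side-band estimate and subtracts it from the middle
#' (fluorescence) bin: `N_XRF = Ns(39-45) - Sca(39-45)`. Negative results
#' are Poisson-fluctuation artifacts and are clamped at zero so that the
#' corrected sinogram can be fed to MLEM.
#'
#' @param sinograms an `xfct_sinograms`
#' @param spectrum incident spectrum used for the theoretical bin ratios
#'   (defaults to the spectrum stored in `sinograms`)
#' @param geom geometry (defaults to the one stored in `sinograms`)
#' @return Object of class `xfct_corrected` with `n_xrf` and
#'   `scatter_estimate` (`n_views` x `n_pixels`), plus the per-pixel weights.
#' @export
correct <- function(sinograms, spectrum = NULL, geom = NULL) {
  stopifnot(inherits(sinograms, "xfct_sinograms"))
  if (is.null(spectrum)) spectrum <- sinograms$spectrum
  if (is.null(geom)) geom <- sinograms$geometry
  w <- scatter_bin_weights(geom, spectrum, sinograms$bins)
  sca <- estimate_scatter(sinograms$counts, w)
  ns2 <- sinograms$counts[2, , , drop = TRUE]
  if (is.null(dim(ns2))) ns2 <- matrix(ns2, nrow = 1)
  structure(list(n_xrf = pmax(ns2 - sca, 0), scatter_estimate = sca,
                 weights = w, geometry = geom, grid = sinograms$grid,
                 protocol = sinograms$protocol, spectrum = spectrum,
                 e_inc = sinograms$e_inc, e_xrf = sinograms$e_xrf),
            class = "xfct_corrected")
}

#' @export
print.xfct_corrected <- function(x, ...) {
  cat(sprintf("<xfct_corrected> %d views x %d pixels, peak N_XRF %.3g\n",
              nrow(x$n_xrf), ncol(x$n_xrf), max(x$n_xrf)))
  invisible(x)
}
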
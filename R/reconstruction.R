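#' Build the attenuation-weighted pinhole system matrix
#'
#' Forward-model weight of voxel j in measurement i = (view, pixel):
#' the pinhole solid-angle response times the Beer-Lambert factors of the
#' incident path (entry point A to voxel B, at the effective incident
#' energy) and of the emission path (voxel B to exit point C towards the
#' pinhole, at the K-alpha energy). Entries below `1e-8` of the maximum are
#' dropped and the matrix is stored sparse.
#'
#' @param mu_inc,mu_xrf attenuation maps (1/cm) at the incident effective
#'   energy and at the fluorescence energy, on `grid`
#' @param geom an `xfct_geometry`
#' @param angles view angles in radians (e.g. [view_angles()])
#' @param grid the reconstruction `xfct_grid`
#' @return Object of class `xfct_sysmat`: sparse `dgCMatrix` `A` of dimension
#'   `(n_views * detector_pixels) x (n_x * n_y)` (measurements view-major),
#'   plus geometry metadata.
#' @export
build_system_matrix <- function(mu_inc, mu_xrf, geom, angles, grid) {
  stopifnot(inherits(geom, "xfct_geometry"), inherits(grid, "xfct_grid"),
            nrow(mu_inc) == grid$n_x, ncol(mu_inc) == grid$n_y,
            all(dim(mu_inc) == dim(mu_xrf)),
            all(mu_inc >= 0), all(mu_xrf >= 0))
  tr <- cpp_system_matrix(mu_inc, mu_xrf, grid$pixel_size,
                          grid$origin[1], grid$origin[2], angles,
                          geom$pinhole_to_center, geom$pinhole_to_detector,
                          geom$detector_pixels, geom$pixel_width,
                          geom$aperture_width, geom$aperture_height)
  keep <- tr$x > 1e-8 * max(tr$x)
  A <- Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep], x = tr$x[keep],
                            dims = c(length(angles) * geom$detector_pixels,
                                     grid$n_x * grid$n_y))
  structure(list(A = A, grid = grid, geometry = geom, angles = angles),
            class = "xfct_sysmat")
}

#' @export
print.xfct_sysmat <- function(x, ...) {
  cat(sprintf("<xfct_sysmat> %d x %d, %d nonzeros (%.2f%% dense)\n",
              nrow(x$A), ncol(x$A), length(x$A@x),
              100 * length(x$A@x) / prod(dim(x$A))))
  invisible(x)
}

#' MLEM emission reconstruction
#'
#' Multiplicative maximum-likelihood expectation-maximization update
#' `f_j <- f_j / (sum_i a_ij) * sum_i a_ij g_i / (sum_j' a_ij' f_j')`,
#' iterated from a uniform positive start. Nonnegativity is preserved by
#' construction; voxels with zero sensitivity are frozen at zero. The
#' Poisson log-likelihood of the data under the current estimate is recorded
#' at every iteration.
#'
#' @param g measurement vector (view-major, as produced by [correct()]'s
#'   `n_xrf` flattened row-wise), or an `xfct_corrected` object; must be
#'   nonnegative
#' @param sysmat an `xfct_sysmat` (or a bare matrix / sparse Matrix)
#' @param n_iter number of iterations (default 100)
#' @param f_init optional positive initial image (default uniform 1)
#' @param rel_tol optional early-stopping threshold on the relative image
#'   change (default 0: run all `n_iter` iterations)
#' @return Object of class `xfct_recon` with the image `f` (matrix when the
#'   grid is known, else a vector), the per-iteration `loglik` trace and the
#'   iteration count.
#' @export
mlem <- function(g, sysmat, n_iter = 100, f_init = NULL, rel_tol = 0) {
  grid <- NULL
  if (inherits(g, "xfct_corrected")) g <- as.vector(t(g$n_xrf))
  if (inherits(sysmat, "xfct_sysmat")) {
    grid <- sysmat$grid
    A <- sysmat$A
  } else {
    A <- sysmat
  }
  stopifnot(length(g) == nrow(A), all(g >= 0), n_iter >= 1)
  eps <- 1e-12
  sens <- as.vector(Matrix::colSums(A))
  live <- sens > 0
  f <- if (is.null(f_init)) rep(1, ncol(A)) else as.vector(f_init)
  stopifnot(length(f) == ncol(A), all(f[live] > 0))
  f[!live] <- 0
  loglik <- numeric(n_iter)
  it_done <- n_iter
  for (it in seq_len(n_iter)) {
    yhat <- as.vector(A %*% f)
    loglik[it] <- sum(g * log(pmax(yhat, eps)) - yhat)
    ratio <- g / pmax(yhat, eps)
    upd <- as.vector(Matrix::crossprod(A, ratio))
    f_new <- f
    f_new[live] <- f[live] * upd[live] / sens[live]
    delta <- sum(abs(f_new - f)) / max(sum(abs(f)), eps)
    f <- f_new
    if (rel_tol > 0 && delta < rel_tol) { it_done <- it; break }
  }
  out <- structure(list(f = f, loglik = loglik[seq_len(it_done)],
                        n_iter = it_done, grid = grid),
                   class = "xfct_recon")
  if (!is.null(grid)) out$f <- matrix(f, grid$n_x, grid$n_y)
  out
}

#' @export
print.xfct_recon <- function(x, ...) {
  cat(sprintf("<xfct_recon> %d iterations, max %.4g, final loglik %.6g\n",
              x$n_iter, max(x$f), x$loglik[length(x$loglik)]))
  invisible(x)
}

# frequency-domain Ram-Lak kernel from the exact band-limited real-space
# ramp filter (sampling interval tau)
.ramp_kernel_fft <- function(m, tau) {
  h <- numeric(m)
  k <- c(0:(m / 2), -(m / 2 - 1):-1)
  h[1] <- 1 / (4 * tau^2)
  odd <- which(k %% 2 != 0)
  h[odd] <- -1 / (pi * k[odd] * tau)^2
  Re(stats::fft(h))
}

#' Filtered backprojection of a parallel-beam transmission sinogram
#'
#' Ram-Lak (ramp) filtering in the frequency domain followed by
#' linear-interpolated backprojection; reconstructs the effective linear
#' attenuation map in 1/cm.
#'
#' @param ct an `xfct_ct_sinogram` from [simulate_transmission()], or a bare
#'   `n_views` x `n_rays` matrix of optical depths (then `angles` and
#'   `offsets` must be supplied)
#' @param grid reconstruction grid (defaults to the grid stored in `ct`)
#' @param angles,offsets ray geometry when `ct` is a bare matrix
#' @return Matrix (`n_x` x `n_y`) of mu in 1/cm.
#' @export
fbp_slice <- function(ct, grid = NULL, angles = NULL, offsets = NULL) {
  if (inherits(ct, "xfct_ct_sinogram")) {
    if (is.null(grid)) grid <- ct$grid
    angles <- ct$angles
    offsets <- ct$offsets
    sino <- ct$mu_sinogram
  } else {
    sino <- ct
    stopifnot(!is.null(grid), !is.null(angles), !is.null(offsets))
  }
  stopifnot(all(is.finite(sino)))
  nv <- nrow(sino); nr <- ncol(sino)
  tau <- (offsets[2] - offsets[1]) / 10            # ray spacing in cm
  m <- 2^ceiling(log2(2 * nr))
  H <- .ramp_kernel_fft(m, tau)
  filt <- matrix(0, nv, nr)
  for (v in seq_len(nv)) {
    p <- c(sino[v, ], rep(0, m - nr))
    q <- Re(stats::fft(stats::fft(p) * H, inverse = TRUE)) / m
    filt[v, ] <- q[seq_len(nr)] * tau
  }
  ctr <- grid_centers(grid)
  xs <- ctr$x / 10; ys <- ctr$y / 10               # cm
  off <- offsets / 10
  img <- matrix(0, grid$n_x, grid$n_y)
  # ray offset axis is (-sin a, cos a), matching the forward projector
  for (v in seq_len(nv)) {
    tt <- outer(-xs * sin(angles[v]), ys * cos(angles[v]), `+`)
    img <- img + matrix(stats::approx(off, filt[v, ], xout = as.vector(tt),
                                      rule = 2)$y, grid$n_x, grid$n_y)
  }
  img * pi / nv
}

#' Three-material decomposition of the slice
#'
#' Assigns every voxel a mixture of water, cortical bone and NaGdF4 from the
#' transmission attenuation map and the uncorrected fluorescence image, so
#' that attenuation maps at arbitrary energies can be synthesized for the
#' system matrix. Bone is segmented by thresholding the effective linear
#' attenuation (default threshold: midway between water and cortical bone at
#' the transmission energy). Soft tissue is modelled as water with a
#' water-equivalent density scaled to reproduce the measured attenuation
#' (so PMMA, which is somewhat more attenuating than water, is handled
#' gracefully). The Gd density comes from the uncorrected fluorescence
#' image divided by `gd_scale` (image units per mg/mL); without a scale
#' estimate the Gd contribution is left out of the map.
#'
#' @param ct_mu transmission attenuation map (1/cm) on `grid`
#' @param xfct_image uncorrected fluorescence image (matrix or `xfct_recon`)
#' @param grid the shared `xfct_grid`
#' @param e_ct effective energy (keV) of the transmission map
#' @param bone_threshold linear-attenuation threshold for bone (1/cm);
#'   default the water/bone midpoint at `e_ct`. A threshold above the map
#'   maximum yields an empty bone mask with a warning.
#' @param gd_scale image units per mg/mL, or `NULL`
#' @return Object of class `xfct_decomp` with `bone_mask`, `gd_mg_ml`,
#'   `water_density`, `bone_density` and `e_ct`.
#' @export
decompose_materials <- function(ct_mu, xfct_image, grid, e_ct,
                                bone_threshold = NULL, gd_scale = NULL) {
  if (inherits(xfct_image, "xfct_recon")) xfct_image <- xfct_image$f
  stopifnot(all(dim(ct_mu) == c(grid$n_x, grid$n_y)),
            all(dim(xfct_image) == dim(ct_mu)))
  w <- material_table("water"); b <- material_table("bone_cortical")
  s <- material_table("nagdf4")
  mrw <- mass_attenuation(w, e_ct)
  mrb <- mass_attenuation(b, e_ct)
  mu_water <- mrw * 1.0
  mu_bone <- mrb * b$density
  if (is.null(bone_threshold)) bone_threshold <- (mu_water + mu_bone) / 2
  if (bone_threshold > max(ct_mu)) {
    warning("bone threshold above the attenuation map range; empty bone mask")
  }
  object <- ct_mu > 0.5 * mu_water
  bone_mask <- object & (ct_mu > bone_threshold)
  gd <- matrix(0, grid$n_x, grid$n_y)
  if (!is.null(gd_scale) && gd_scale > 0) {
    gd <- pmax(xfct_image, 0) / gd_scale
    gd[!object] <- 0
  }
  gd_frac <- 157.25 / 257.24
  m_salt <- gd * 1e-3 / gd_frac
  water_density <- pmax(ct_mu - m_salt * mass_attenuation(s, e_ct), 0) / mrw
  water_density[bone_mask | !object] <- 0
  bone_density <- matrix(0, grid$n_x, grid$n_y)
  bone_density[bone_mask] <- ct_mu[bone_mask] / mrb
  structure(list(bone_mask = bone_mask, gd_mg_ml = gd,
                 water_density = water_density, bone_density = bone_density,
                 e_ct = e_ct),
            class = "xfct_decomp")
}

#' Attenuation map synthesized from a material decomposition
#'
#' @param decomp an `xfct_decomp`
#' @param E energy in keV
#' @return Matrix of mu in 1/cm.
#' @export
decomposition_mu <- function(decomp, E) {
  stopifnot(inherits(decomp, "xfct_decomp"))
  gd_frac <- 157.25 / 257.24
  decomp$water_density * mass_attenuation(material_table("water"), E) +
    decomp$bone_density * mass_attenuation(material_table("bone_cortical"), E) +
    (decomp$gd_mg_ml * 1e-3 / gd_frac) *
      mass_attenuation(material_table("nagdf4"), E)
}

#' Quantitative scatter- and attenuation-corrected reconstruction
#'
#' The full reconstruction pipeline of the slice:
#' \enumerate{
#'   \item side-band scatter correction of the three-bin sinograms;
#'   \item uncorrected MLEM with the vacuum (pinhole-response-only) matrix;
#'   \item three-material decomposition using the transmission map and, if a
#'     calibration is supplied, a provisional concentration scale fitted on
#'     the uncorrected image;
#'   \item attenuation-weighted system matrix and final MLEM;
#'   \item optional concentration calibration of the final image.
#' }
#' The decomposition / matrix / MLEM loop runs `n_outer` times (default 1,
#' the single sequential pass of the bench procedure).
#'
#' @param sinograms an `xfct_sinograms`
#' @param ct_mu transmission attenuation map on the reconstruction grid
#' @param e_ct its effective energy in keV
#' @param n_iter MLEM iterations per pass (default 100)
#' @param n_outer decomposition passes (default 1)
#' @param calibration optional list with `rois` (list of `center`, `radius`)
#'   and `concentrations` (mg/mL) to fit the concentration scale
#' @param geom,spectrum override the stored geometry/spectrum
#' @return List with `image` (calibrated mg/mL when a calibration was given,
#'   else the raw final image), `raw`, `uncorrected`, `fit`
#'   (`xfct_calibration` or NULL), `decomp` and `corrected`.
#' @export
reconstruct_quantitative <- function(sinograms, ct_mu, e_ct, n_iter = 100,
                                     n_outer = 1, calibration = NULL,
                                     geom = NULL, spectrum = NULL) {
  stopifnot(inherits(sinograms, "xfct_sinograms"))
  if (is.null(geom)) geom <- sinograms$geometry
  if (is.null(spectrum)) spectrum <- sinograms$spectrum
  grid <- sinograms$grid
  protocol <- sinograms$protocol
  angles <- view_angles(protocol$n_views, protocol$angular_range)
  corrected <- correct(sinograms, spectrum, geom)
  g <- as.vector(t(corrected$n_xrf))
  zero <- matrix(0, grid$n_x, grid$n_y)
  A0 <- build_system_matrix(zero, zero, geom, angles, grid)
  f0 <- mlem(g, A0, n_iter = n_iter)
  roi_means <- function(img) {
    vapply(calibration$rois,
           function(r) roi_stats(img, grid, r)$mean, numeric(1))
  }
  scale_from <- function(img) {
    if (is.null(calibration)) return(NULL)
    fit <- fit_calibration(roi_means(img), calibration$concentrations)
    if (fit$slope > 0) fit$slope else NULL
  }
  f <- f0
  decomp <- NULL
  gd_scale <- scale_from(f0$f)
  for (pass in seq_len(n_outer)) {
    decomp <- decompose_materials(ct_mu, f$f, grid, e_ct, gd_scale = gd_scale)
    A <- build_system_matrix(decomposition_mu(decomp, sinograms$e_inc),
                             decomposition_mu(decomp, sinograms$e_xrf),
                             geom, angles, grid)
    f <- mlem(g, A, n_iter = n_iter)
    gd_scale <- scale_from(f$f)
  }
  fit <- NULL
  image <- f$f
  if (!is.null(calibration)) {
    fit <- fit_calibration(roi_means(f$f), calibration$concentrations)
    image <- apply_calibration(f$f, fit)
  }
  list(image = image, raw = f, uncorrected = f0, fit = fit,
       decomp = decomp, corrected = corrected)
}
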
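#' Circular region of interest
#'
#' @param center `(x, y)` in mm
#' @param radius radius in mm
#' @return List usable as an ROI by [roi_stats()] and [cnr()].
#' @export
roi_disc <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  list(center = center, radius = radius)
}

# logical mask of voxel centres inside an ROI disc
.roi_mask <- function(grid, roi) {
  ctr <- grid_centers(grid)
  outer(ctr$x - roi$center[1], ctr$y - roi$center[2],
        function(a, b) a^2 + b^2) <= roi$radius^2
}

#' Mean, standard deviation and pixel count inside an ROI
#'
#' Plain statistics over voxels whose centre falls inside the disc; the
#' standard deviation is the sample SD (n - 1 denominator).
#'
#' @param image image matrix on `grid`
#' @param grid an `xfct_grid`
#' @param roi a [roi_disc()]
#' @return List with `mean`, `sd`, `n`.
#' @export
roi_stats <- function(image, grid, roi) {
  stopifnot(all(dim(image) == c(grid$n_x, grid$n_y)))
  m <- .roi_mask(grid, roi)
  if (!any(m)) stop("ROI contains no voxel centres")
  v <- image[m]
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Least-squares concentration calibration
#'
#' Ordinary least squares of per-insertion mean image values against the
#' known Gd concentrations; the coefficient of determination r-square is
#' `1 - SS_res / SS_tot`.
#'
#' @param means per-insertion mean image values
#' @param concentrations matching Gd concentrations in mg/mL (at least 3
#'   distinct points)
#' @return Object of class `xfct_calibration` with `slope` (image units per
#'   mg/mL), `intercept`, `r_square` and per-point `residuals`.
#' @export
fit_calibration <- function(means, concentrations) {
  stopifnot(length(means) == length(concentrations))
  if (length(means) < 3) stop("need at least 3 calibration points")
  if (length(unique(concentrations)) < 2) {
    stop("degenerate design: all concentrations identical")
  }
  fit <- stats::lm(means ~ concentrations)
  res <- stats::residuals(fit)
  ss_tot <- sum((means - mean(means))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_square = r2, residuals = unname(res),
                 concentrations = concentrations, means = means),
            class = "xfct_calibration")
}

#' @export
print.xfct_calibration <- function(x, ...) {
  cat(sprintf("<xfct_calibration> slope %.4g / (mg/mL), intercept %.4g, r-square %.4f\n",
              x$slope, x$intercept, x$r_square))
  invisible(x)
}

#' Convert an image to mg/mL with a fitted calibration
#'
#' Subtracts the intercept and divides by the slope. Negative values are
#' kept (clamp only for display).
#'
#' @param image image matrix
#' @param fit an `xfct_calibration`
#' @return Calibrated image in mg/mL.
#' @export
apply_calibration <- function(image, fit) {
  stopifnot(inherits(fit, "xfct_calibration"), fit$slope > 0)
  (image - fit$intercept) / fit$slope
}

#' Contrast-to-noise ratio of a target region
#'
#' `CNR = (mean_target - mean_background) / SD_background` with the
#' background mean and (sample) SD pooled over the pixels of all background
#' ROIs.
#'
#' @param image image matrix on `grid`
#' @param grid an `xfct_grid`
#' @param target_roi a [roi_disc()]
#' @param background_rois list of [roi_disc()]s
#' @return Dimensionless CNR; `Inf` (with a warning) when the background SD
#'   is exactly zero.
#' @export
cnr <- function(image, grid, target_roi, background_rois) {
  stopifnot(all(dim(image) == c(grid$n_x, grid$n_y)), length(background_rois) >= 1)
  tmean <- roi_stats(image, grid, target_roi)$mean
  bg <- unlist(lapply(background_rois, function(r) image[.roi_mask(grid, r)]))
  if (length(bg) < 2) stop("background ROIs contain fewer than 2 voxels")
  s <- stats::sd(bg)
  if (s == 0) {
    warning("zero background SD; CNR is infinite")
    return(Inf * sign(tmean - mean(bg)))
  }
  (tmean - mean(bg)) / s
}

#' Rose-criterion detectability limit
#'
#' Least-squares line `CNR = a * c + b` through the measured CNR values and
#' the concentration at which it crosses the detection threshold
#' (Rose criterion: CNR > 4).
#'
#' @param cnr_values CNR per concentration (finite values only are used)
#' @param concentrations mg/mL
#' @param threshold detection threshold (default 4)
#' @return Detectability limit in mg/mL.
#' @export
detectability_limit <- function(cnr_values, concentrations, threshold = 4) {
  keep <- is.finite(cnr_values)
  stopifnot(sum(keep) >= 2)
  fit <- stats::lm(cnr_values[keep] ~ concentrations[keep])
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (a <= 0) stop("non-positive CNR slope: no detectability crossing")
  (threshold - b) / a
}

#' Target and background ROI sets for the calibration phantom
#'
#' Sampling discs centred on each insertion plus background discs in the
#' PMMA between and inside the insertion ring.
#'
#' @param spec the calibration `xfct_phantom`
#' @param radius sampling-disc radius in mm (default 2.4, inside the 4 mm
#'   insertions to avoid partial-volume edges)
#' @return List with `targets` (one ROI per insertion, in insertion order)
#'   and `background` (ROIs in Gd-free background).
#' @export
calibration_rois <- function(spec, radius = 2.4) {
  stopifnot(inherits(spec, "xfct_phantom"), nrow(spec$insertions) >= 1)
  ins <- spec$insertions
  targets <- lapply(seq_len(nrow(ins)),
                    function(k) roi_disc(c(ins$x[k], ins$y[k]), radius))
  ring <- sqrt(ins$x^2 + ins$y^2)
  ang <- atan2(ins$y, ins$x)
  mid <- ang + diff(c(ang, ang[1] + 2 * pi))[1] / 2
  background <- c(list(roi_disc(c(0, 0), radius)),
                  lapply(seq_along(mid), function(k)
                    roi_disc(ring[k] * c(cos(mid[k]), sin(mid[k])), radius)))
  list(targets = targets, background = background)
}
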
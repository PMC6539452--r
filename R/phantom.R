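#' Describe a digital slice phantom
#'
#' A phantom is a homogeneous background body (disc or ellipse), a set of
#' circular Gd-solution insertions and optional cortical-bone discs. The
#' insertion solvent is water carrying dissolved/suspended NaGdF4 at the
#' stated elemental-Gd concentration (mg Gd per mL, converted to NaGdF4 mass
#' via the stoichiometric Gd mass fraction 157.25/257.24).
#'
#' @param background list with `material` ("pmma" or "water"), `density`
#'   (g/cm^3), and either `radius` (mm) or `semi_axes` (c(a, b) in mm) plus
#'   an optional `center`
#' @param insertions data frame with columns `x`, `y`, `radius` (mm),
#'   `concentration` (mg/mL Gd) and optionally `taper` (logical; radially
#'   tapered concentration with a flat core, for inhomogeneous hotspots)
#' @param bone_regions optional data frame with columns `x`, `y`, `radius`
#' @return Object of class `xfct_phantom`.
#' @export
phantom_spec <- function(background, insertions = NULL, bone_regions = NULL) {
  stopifnot(is.list(background), background$material %in% c("pmma", "water"),
            background$density > 0)
  if (is.null(background$center)) background$center <- c(0, 0)
  if (is.null(background$semi_axes)) {
    stopifnot(background$radius > 0)
    background$semi_axes <- c(background$radius, background$radius)
  }
  empty <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                      concentration = numeric(0), taper = logical(0))
  if (is.null(insertions) || nrow(insertions) == 0) insertions <- empty
  if (nrow(insertions) > 0) {
    if (is.null(insertions$taper)) insertions$taper <- FALSE
    stopifnot(all(insertions$radius > 0), all(insertions$concentration >= 0))
    .check_inside(insertions, background)
    .check_disjoint(rbind(insertions[c("x", "y", "radius")],
                          if (!is.null(bone_regions)) bone_regions[c("x", "y", "radius")]))
  }
  if (!is.null(bone_regions) && nrow(bone_regions) > 0) {
    stopifnot(all(bone_regions$radius > 0))
    .check_inside(bone_regions, background)
  } else {
    bone_regions <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))
  }
  structure(list(background = background, insertions = insertions,
                 bone_regions = bone_regions),
            class = "xfct_phantom")
}

.check_inside <- function(discs, background) {
  a <- background$semi_axes[1]; b <- background$semi_axes[2]
  dx <- discs$x - background$center[1]; dy <- discs$y - background$center[2]
  # conservative scaled-radius check, exact for circular backgrounds
  s <- sqrt((dx / (a - discs$radius))^2 + (dy / (b - discs$radius))^2)
  if (any(s > 1)) stop("insertion/bone disc extends outside the background body")
}

.check_disjoint <- function(discs) {
  n <- nrow(discs)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((discs$x[i] - discs$x[j])^2 + (discs$y[i] - discs$y[j])^2)
    if (d < discs$radius[i] + discs$radius[j]) {
      stop("phantom discs overlap")
    }
  }
  invisible(TRUE)
}

#' @export
print.xfct_phantom <- function(x, ...) {
  cat("<xfct_phantom>", x$background$material, "body,",
      nrow(x$insertions), "insertion(s),", nrow(x$bone_regions), "bone disc(s)\n")
  if (nrow(x$insertions) > 0) {
    cat("  Gd concentrations (mg/mL):",
        paste(signif(x$insertions$concentration, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Six-insertion concentration-calibration phantom
#'
#' PMMA cylinder with six water-filled insertions on a ring, at Gd
#' concentrations spanning the working range of the imaging study (0 to the
#' ~20 mg/mL stock solution), in increasing order around the ring.
#'
#' @param concentrations Gd concentrations in mg/mL (default
#'   `c(0, 2, 5, 10, 15, 20)`)
#' @param insertion_radius,ring_radius,background_radius layout in mm
#' @return An `xfct_phantom`.
#' @export
calibration_phantom <- function(concentrations = c(0, 2, 5, 10, 15, 20),
                                insertion_radius = 4, ring_radius = 15,
                                background_radius = 24) {
  n <- length(concentrations)
  ang <- (seq_len(n) - 1) * 2 * pi / n
  phantom_spec(
    background = list(material = "pmma", density = 1.19,
                      radius = background_radius),
    insertions = data.frame(x = ring_radius * cos(ang),
                            y = ring_radius * sin(ang),
                            radius = insertion_radius,
                            concentration = concentrations)
  )
}

# preset peak concentrations (mg/mL) for the mouse-like slice phantoms,
# matching the organ uptake levels of the animal study
.mouse_presets <- list(
  liver = list(peak = 7.94, body = c(14, 11),
               hotspots = data.frame(x = 3.5, y = 1, radius = 6),
               bones = data.frame(x = 0, y = -8, radius = 1.5)),
  kidney = list(peak = 2.51, body = c(14, 11),
                hotspots = data.frame(x = c(-5.5, 5.5), y = c(-2, -2), radius = 3),
                bones = data.frame(x = 0, y = -7.5, radius = 1.5)),
  leg_tumor = list(peak = 7.13, body = c(9, 8),
                   hotspots = data.frame(x = 2, y = 1, radius = 4),
                   bones = data.frame(x = -3.5, y = -2.5, radius = 1.2))
)

#' Mouse-like slice phantom with an inhomogeneous Gd hotspot
#'
#' Synthetic analogue of an axial small-animal slice: an elliptical water
#' body, one bone disc, and one or two radially tapered Gd hotspots whose
#' peak concentration defaults to the organ uptake observed in vivo
#' (noncancerous liver 7.94, kidney 2.51, hind-leg tumor 7.13 mg/mL).
#'
#' @param preset `"liver"`, `"kidney"` or `"leg_tumor"`
#' @param hotspot_concentration peak Gd concentration in mg/mL (default the
#'   preset value)
#' @param seed optional seed; when given, hotspot centres are jittered by up
#'   to 1 mm for variety between realizations
#' @return An `xfct_phantom`.
#' @export
mouse_slice_phantom <- function(preset = c("liver", "kidney", "leg_tumor"),
                                hotspot_concentration = NULL, seed = NULL) {
  preset <- match.arg(preset)
  p <- .mouse_presets[[preset]]
  if (is.null(hotspot_concentration)) hotspot_concentration <- p$peak
  stopifnot(hotspot_concentration >= 0)
  hs <- p$hotspots
  if (!is.null(seed)) {
    set.seed(seed)
    hs$x <- hs$x + stats::runif(nrow(hs), -1, 1)
    hs$y <- hs$y + stats::runif(nrow(hs), -1, 1)
  }
  hs$concentration <- hotspot_concentration
  hs$taper <- TRUE
  phantom_spec(
    background = list(material = "water", density = 1.0, semi_axes = p$body),
    insertions = hs,
    bone_regions = p$bones
  )
}

# subpixel sample positions along one axis: ss samples per voxel, voxel-major
.subsample_axis <- function(origin, n, ps, ss) {
  origin + rep(0:(n - 1), each = ss) * ps + ((seq_len(ss) - 0.5) / ss) * ps
}

# collapse an (nx*ss) x (ny*ss) indicator to per-voxel coverage fractions
.block_mean <- function(inside, ss, nx, ny) {
  m <- colMeans(array(inside, dim = c(ss, nx, ny * ss)), dims = 1)  # nx x ny*ss
  t(colMeans(array(t(m), dim = c(ss, ny, nx)), dims = 1))           # nx x ny
}

# area-weighted antialiased coverage fraction of a disc over the grid
.disc_coverage <- function(grid, cx, cy, r, ss = 4) {
  xs <- .subsample_axis(grid$origin[1], grid$n_x, grid$pixel_size, ss)
  ys <- .subsample_axis(grid$origin[2], grid$n_y, grid$pixel_size, ss)
  inside <- outer(xs - cx, ys - cy, function(a, b) a^2 + b^2 <= r^2)
  .block_mean(inside, ss, grid$n_x, grid$n_y)
}

.ellipse_coverage <- function(grid, cx, cy, a, b, ss = 4) {
  xs <- .subsample_axis(grid$origin[1], grid$n_x, grid$pixel_size, ss)
  ys <- .subsample_axis(grid$origin[2], grid$n_y, grid$pixel_size, ss)
  inside <- outer((xs - cx) / a, (ys - cy) / b, function(u, v) u^2 + v^2 <= 1)
  .block_mean(inside, ss, grid$n_x, grid$n_y)
}

# flat-core radially tapered profile: full value inside r0 = R/2, quadratic
# falloff to zero at R; evaluated at voxel centres so the map peak equals the
# requested peak exactly
.taper_profile <- function(grid, cx, cy, R, peak) {
  ctr <- grid_centers(grid)
  r <- sqrt(outer(ctr$x - cx, ctr$y - cy, function(a, b) a^2 + b^2))
  r0 <- R / 2
  w <- ifelse(r <= r0, 1,
              ifelse(r < R, 1 - ((r - r0) / (R - r0))^2, 0))
  peak * w
}

#' Rasterize a phantom onto a voxel grid
#'
#' Produces the ground truth used by the simulator and as the oracle in
#' closed-loop tests: the Gd concentration map (mg/mL, area-weighted
#' antialiased discs), per-material mass maps, and the bulk density map.
#' Solution voxels use additive densities (water 1.0 plus the dissolved
#' NaGdF4 mass). Attenuation maps at any energy follow from
#' [mu_map()].
#'
#' @param spec an `xfct_phantom`
#' @param grid an `xfct_grid`
#' @param supersample antialiasing subsamples per voxel edge (default 4)
#' @return Object of class `xfct_truth` with fields `concentration` (mg/mL
#'   Gd), `masses` (list of per-material mass per unit volume, g/cm^3),
#'   `density`, `grid`, `spec`.
#' @export
rasterize <- function(spec, grid, supersample = 4) {
  stopifnot(inherits(spec, "xfct_phantom"), inherits(grid, "xfct_grid"))
  ext_lo <- grid$origin
  ext_hi <- grid$origin + c(grid$n_x, grid$n_y) * grid$pixel_size
  ins <- spec$insertions
  if (nrow(ins) > 0) {
    if (any(ins$x - ins$radius < ext_lo[1] | ins$x + ins$radius > ext_hi[1] |
            ins$y - ins$radius < ext_lo[2] | ins$y + ins$radius > ext_hi[2])) {
      stop("insertion extends outside the voxel grid")
    }
  }
  bg <- spec$background
  cov_bg <- .ellipse_coverage(grid, bg$center[1], bg$center[2],
                              bg$semi_axes[1], bg$semi_axes[2], supersample)
  zero <- matrix(0, grid$n_x, grid$n_y)
  cov_ins_tot <- zero
  conc <- zero
  for (k in seq_len(nrow(ins))) {
    ck <- .disc_coverage(grid, ins$x[k], ins$y[k], ins$radius[k], supersample)
    cov_ins_tot <- cov_ins_tot + ck
    if (isTRUE(ins$taper[k])) {
      conc <- conc + ck * .taper_profile(grid, ins$x[k], ins$y[k],
                                         ins$radius[k], ins$concentration[k])
    } else {
      conc <- conc + ck * ins$concentration[k]
    }
  }
  cov_bone <- zero
  for (k in seq_len(nrow(spec$bone_regions))) {
    b <- spec$bone_regions[k, ]
    cov_bone <- cov_bone + .disc_coverage(grid, b$x, b$y, b$radius, supersample)
  }
  cov_bg_eff <- pmax(cov_bg - cov_bone - cov_ins_tot, 0)
  gd_frac <- 157.25 / 257.24                       # Gd mass fraction of NaGdF4
  m_salt <- conc * 1e-3 / gd_frac                  # mg/mL Gd -> g/cm^3 NaGdF4
  m_water <- cov_ins_tot * 1.0
  m_pmma <- zero
  if (bg$material == "pmma") m_pmma <- cov_bg_eff * bg$density
  else m_water <- m_water + cov_bg_eff * bg$density
  m_bone <- cov_bone * material_table("bone_cortical")$density
  density <- m_water + m_pmma + m_bone + m_salt
  structure(list(concentration = conc,
                 masses = list(water = m_water, pmma = m_pmma,
                               bone_cortical = m_bone, nagdf4 = m_salt),
                 density = density, grid = grid, spec = spec),
            class = "xfct_truth")
}

#' Linear attenuation map of a rasterized phantom at a given energy
#'
#' Voxelwise mixture rule over the ground-truth material masses:
#' `mu(E) = sum_k m_k (mu/rho)_k(E)` in 1/cm.
#'
#' @param truth an `xfct_truth` from [rasterize()]
#' @param E energy in keV
#' @return Matrix (`n_x` x `n_y`) of mu in 1/cm.
#' @export
mu_map <- function(truth, E) {
  stopifnot(inherits(truth, "xfct_truth"), length(E) == 1)
  out <- matrix(0, truth$grid$n_x, truth$grid$n_y)
  for (mat in names(truth$masses)) {
    m <- truth$masses[[mat]]
    if (any(m > 0)) out <- out + m * mass_attenuation(material_table(mat), E)
  }
  out
}

#' @export
print.xfct_truth <- function(x, ...) {
  cat("<xfct_truth>", sprintf("%d x %d voxels of %g mm\n",
                              x$grid$n_x, x$grid$n_y, x$grid$pixel_size))
  cat(sprintf("  peak Gd %.3g mg/mL, total Gd %.3g mg per mm slice thickness\n",
              max(x$concentration),
              sum(x$concentration) * (x$grid$pixel_size / 10)^2))
  invisible(x)
}
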
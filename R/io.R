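#' Write a sinogram set to disk
#'
#' One 32-bit float TIFF per energy bin plus a JSON sidecar holding the
#' geometry, protocol, bins and seed, so a run can be inspected and reloaded
#' without the R session.
#'
#' @param sinograms an `xfct_sinograms`
#' @param dir output directory (created if needed)
#' @param stem file-name stem (default `"sinogram"`)
#' @return Invisibly, the written file paths.
#' @export
write_sinogram_set <- function(sinograms, dir, stem = "sinogram") {
  stopifnot(inherits(sinograms, "xfct_sinograms"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to write sinograms")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  scales <- numeric(3)
  for (b in 1:3) {
    p <- file.path(dir, sprintf("%s_bin%d.tif", stem, b))
    m <- sinograms$counts[b, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    scales[b] <- max(1, max(m))          # float TIFF stores [0, 1]
    tiff::writeTIFF(m / scales[b], p, bits.per.sample = 32L, reduce = FALSE)
    paths <- c(paths, p)
  }
  side <- file.path(dir, paste0(stem, ".json"))
  meta <- list(
    scales = scales,
    bins = lapply(sinograms$bins, function(b) c(b$e_min, b$e_max)),
    n_views = sinograms$protocol$n_views,
    angular_range = sinograms$protocol$angular_range,
    exposure_per_view = sinograms$protocol$exposure_per_view,
    source_fluence = sinograms$protocol$source_fluence,
    scatter_scale = sinograms$protocol$scatter_scale,
    geometry = unclass(sinograms$geometry),
    grid = unclass(sinograms$grid),
    spectrum = sinograms$spectrum$description,
    e_inc = sinograms$e_inc, e_xrf = sinograms$e_xrf,
    seed = sinograms$seed, noise = sinograms$noise)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

#' Read a sinogram set written by [write_sinogram_set()]
#'
#' @param dir directory containing the files
#' @param stem file-name stem
#' @return An `xfct_sinograms` (without the noiseless component breakdown,
#'   which is not serialized).
#' @export
read_sinogram_set <- function(dir, stem = "sinogram") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to read sinograms")
  }
  meta <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                              simplifyVector = TRUE)
  g <- meta$geometry
  geom <- system_geometry(g$pinhole_to_center, g$pinhole_to_detector,
                          g$detector_pixels, g$pixel_width, g$pixel_height,
                          g$aperture_width, g$aperture_height,
                          g$detector_side_angle, g$source_to_center)
  grid <- voxel_grid(meta$grid$n_x, meta$grid$n_y, meta$grid$pixel_size,
                     center = meta$grid$origin +
                       c(meta$grid$n_x, meta$grid$n_y) * meta$grid$pixel_size / 2)
  bm <- matrix(unlist(meta$bins), ncol = 2, byrow = !is.matrix(meta$bins))
  bins <- lapply(seq_len(nrow(bm)), function(i) energy_bin(bm[i, 1], bm[i, 2]))
  protocol <- acquisition_protocol(meta$n_views, meta$angular_range,
                                   meta$exposure_per_view, meta$source_fluence,
                                   meta$scatter_scale, bins)
  counts <- array(0, dim = c(3, meta$n_views, geom$detector_pixels))
  for (b in 1:3) {
    m <- tiff::readTIFF(file.path(dir, sprintf("%s_bin%d.tif", stem, b)))
    counts[b, , ] <- m * meta$scales[b]
  }
  structure(list(counts = counts, expected = NULL, fluorescence = NULL,
                 scatter = NULL, bins = bins, geometry = geom,
                 protocol = protocol, grid = grid,
                 spectrum = NULL, e_inc = meta$e_inc, e_xrf = meta$e_xrf,
                 seed = meta$seed, noise = meta$noise),
            class = "xfct_sinograms")
}

#' Write an image with a JSON sidecar
#'
#' 32-bit float TIFF plus grid / units / provenance metadata.
#'
#' @param image image matrix
#' @param path output TIFF path (sidecar gets the same path with `.json`)
#' @param grid the `xfct_grid`
#' @param units text describing the pixel units
#' @param extra optional named list merged into the sidecar
#' @return Invisibly, the TIFF path.
#' @export
write_image <- function(image, path, grid, units = "arbitrary", extra = list()) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to write images")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lo <- min(image, 0)
  scale <- max(1e-12, max(image) - lo)
  tiff::writeTIFF((image - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- c(list(n_x = grid$n_x, n_y = grid$n_y, pixel_size_mm = grid$pixel_size,
                 origin_mm = grid$origin, units = units,
                 scale = scale, offset = lo), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
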
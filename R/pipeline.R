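#' Default run configuration
#'
#' The configuration tree mirrors the bench study: 45-view three-bin
#' fluorescence scan of the six-insertion calibration phantom at 128 x 128 /
#' 0.5 mm, a 180-view transmission scan for the attenuation map, 100 MLEM
#' iterations and a single decomposition pass.
#'
#' @return Nested named list; see the fields for the accepted keys.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    noise = TRUE,
    grid = list(n_voxels = 128, pixel_size = 0.5),
    geometry = list(pinhole_to_center = 75, pinhole_to_detector = 63.5,
                    detector_pixels = 256, pixel_width = 0.5, pixel_height = 2,
                    aperture_width = 0.5, aperture_height = 2),
    spectrum = list(mode = "tube", kvp = 140, filter_mm_cu = 0.4,
                    energy_keV = NULL),
    protocol = list(n_views = 45, angular_range = 360, exposure_per_view = 10,
                    source_fluence = 1e8, scatter_scale = 2.5),
    ct = list(n_views = 180, counts_per_ray = 2e4, kvp = 65,
              filter_mm_cu = 0.1),
    phantom = list(preset = "calibration",
                   concentrations = c(0, 2, 5, 10, 15, 20),
                   hotspot_concentration = NULL),
    reconstruction = list(n_iter = 100, n_outer = 1),
    metrics = list(roi_radius = 2.4, rose_threshold = 4)
  )
}

# recursive merge of user config into defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected with the offending field path; omitted keys
#' take their defaults from [default_run_config()].
#'
#' @param path YAML file path, or `NULL` for the defaults
#' @return Validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user)
  }
  stopifnot(cfg$seed == as.integer(cfg$seed), cfg$grid$n_voxels >= 8)
  cfg
}

.config_spectrum <- function(sp) {
  if (identical(sp$mode, "mono")) spectrum_mono(sp$energy_keV)
  else spectrum_tube(sp$kvp, sp$filter_mm_cu)
}

.config_objects <- function(config) {
  g <- config$geometry
  geom <- system_geometry(g$pinhole_to_center, g$pinhole_to_detector,
                          g$detector_pixels, g$pixel_width, g$pixel_height,
                          g$aperture_width, g$aperture_height)
  grid <- voxel_grid(config$grid$n_voxels, config$grid$n_voxels, config$grid$pixel_size)
  p <- config$protocol
  protocol <- acquisition_protocol(p$n_views, p$angular_range,
                                   p$exposure_per_view, p$source_fluence,
                                   p$scatter_scale)
  spec <- if (identical(config$phantom$preset, "calibration")) {
    calibration_phantom(config$phantom$concentrations)
  } else {
    mouse_slice_phantom(config$phantom$preset,
                        config$phantom$hotspot_concentration,
                        seed = config$seed)
  }
  list(geom = geom, grid = grid, protocol = protocol, phantom = spec,
       spectrum = .config_spectrum(config$spectrum),
       ct_spectrum = spectrum_tube(config$ct$kvp, config$ct$filter_mm_cu))
}

#' Simulate and write sinograms and ground truth for a configuration
#'
#' @param config a configuration list from [read_run_config()]
#' @param out_dir output directory
#' @param resume reuse existing outputs instead of recomputing
#' @return Invisibly, a list with the simulated objects and file paths.
#' @export
run_simulate <- function(config, out_dir, resume = FALSE) {
  obj <- .config_objects(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- rasterize(obj$phantom, obj$grid)
  sino_json <- file.path(out_dir, "sinogram.json")
  if (resume && file.exists(sino_json) &&
      all(file.exists(file.path(out_dir, sprintf("sinogram_bin%d.tif", 1:3))))) {
    sino <- read_sinogram_set(out_dir)
    sino$spectrum <- obj$spectrum
  } else {
    sino <- simulate_xfct(truth, obj$geom, obj$spectrum, obj$protocol,
                          seed = config$seed * 1000 + 1, noise = config$noise)
    write_sinogram_set(sino, out_dir)
  }
  ct <- simulate_transmission(truth, obj$ct_spectrum, config$ct$n_views,
                              config$ct$counts_per_ray,
                              seed = config$seed * 1000 + 2,
                              noise = config$noise)
  write_image(truth$concentration,
              file.path(out_dir, "ground_truth_concentration.tif"),
              obj$grid, units = "mg/mL")
  invisible(list(truth = truth, sinograms = sino, ct = ct, objects = obj,
                 out_dir = out_dir))
}

#' Run the full demonstration pipeline
#'
#' Simulate -> scatter-correct -> transmission FBP -> quantitative MLEM ->
#' calibrate -> report. Writes sinograms, images (TIFF + JSON sidecars), a
#' metrics report (`report.json` and `report.txt`) and a run manifest with
#' file digests.
#'
#' @param config a configuration list from [read_run_config()]
#' @param out_dir output directory
#' @param resume reuse existing intermediate files where present
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  t0 <- Sys.time()
  sim <- run_simulate(config, out_dir, resume = resume)
  obj <- sim$objects
  grid <- obj$grid

  ct_mu <- fbp_slice(sim$ct)
  write_image(ct_mu, file.path(out_dir, "ct_mu.tif"), grid, units = "1/cm",
              extra = list(e_eff_keV = sim$ct$e_eff))

  is_cal <- identical(config$phantom$preset, "calibration")
  calibration <- NULL
  rois <- NULL
  if (is_cal) {
    rois <- calibration_rois(obj$phantom, config$metrics$roi_radius)
    calibration <- list(rois = rois$targets,
                        concentrations = config$phantom$concentrations)
  }
  rec <- reconstruct_quantitative(sim$sinograms, ct_mu, sim$ct$e_eff,
                                  n_iter = config$reconstruction$n_iter,
                                  n_outer = config$reconstruction$n_outer,
                                  calibration = calibration)
  write_image(rec$image, file.path(out_dir, "xfct_image.tif"), grid,
              units = if (is_cal) "mg/mL" else "arbitrary",
              extra = list(n_iter = config$reconstruction$n_iter,
                           loglik = rec$raw$loglik))

  report <- list(seed = config$seed,
                 mlem_iterations = rec$raw$n_iter,
                 loglik_final = rec$raw$loglik[length(rec$raw$loglik)])
  if (is_cal) {
    conc <- config$phantom$concentrations
    stats_t <- lapply(rois$targets, function(r) roi_stats(rec$image, grid, r))
    cnr_x <- vapply(rois$targets, function(r)
      cnr(rec$image, grid, r, rois$background), numeric(1))
    cnr_ct <- vapply(rois$targets, function(r)
      cnr(ct_mu, grid, r, rois$background), numeric(1))
    lim_x <- tryCatch(detectability_limit(cnr_x, conc,
                                          config$metrics$rose_threshold),
                      error = function(e) NA_real_)
    lim_ct <- tryCatch(detectability_limit(cnr_ct, conc,
                                           config$metrics$rose_threshold),
                       error = function(e) NA_real_)
    report <- c(report, list(
      concentrations_mg_ml = conc,
      insertion_means_mg_ml = vapply(stats_t, `[[`, numeric(1), "mean"),
      insertion_sds = vapply(stats_t, `[[`, numeric(1), "sd"),
      calibration = list(slope = rec$fit$slope, intercept = rec$fit$intercept,
                         r_square = rec$fit$r_square),
      cnr_xfct = cnr_x, cnr_ct = cnr_ct,
      detectability_limit_xfct_mg_ml = lim_x,
      detectability_limit_ct_mg_ml = lim_ct))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(.format_report(report), file.path(out_dir, "report.txt"))
  .write_manifest(config, out_dir, t0)
  invisible(report)
}

.format_report <- function(report) {
  out <- c(sprintf("seed: %d", report$seed),
           sprintf("MLEM iterations: %d", report$mlem_iterations))
  if (!is.null(report$calibration)) {
    out <- c(out,
             sprintf("calibration: slope %.4g, intercept %.4g, r-square %.4f",
                     report$calibration$slope, report$calibration$intercept,
                     report$calibration$r_square),
             "insertion concentrations (true -> recovered mg/mL):",
             sprintf("  %5.1f -> %6.2f   CNR(XFCT) %6.2f   CNR(CT) %6.2f",
                     report$concentrations_mg_ml, report$insertion_means_mg_ml,
                     report$cnr_xfct, report$cnr_ct),
             sprintf("detectability limit (Rose, CNR > 4): XFCT %.2f mg/mL, CT %.2f mg/mL",
                     report$detectability_limit_xfct_mg_ml,
                     report$detectability_limit_ct_mg_ml))
  }
  out
}

.write_manifest <- function(config, out_dir, t0) {
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  files <- setdiff(list.files(out_dir), "manifest.json")
  digests <- tools::md5sum(file.path(out_dir, files))
  names(digests) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("xfct")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = as.list(digests))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
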
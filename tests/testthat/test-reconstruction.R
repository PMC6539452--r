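test_that("vacuum system matrix equals the pinhole response", {
  grid <- small_grid(32)
  geom <- small_geometry()
  zero <- matrix(0, 32, 32)
  angles <- view_angles(2)
  sm <- build_system_matrix(zero, zero, geom, angles, grid)
  ctr <- grid_centers(grid)
  np <- geom$detector_pixels
  for (j in c(12 + 32 * 9, 20 + 32 * 20, 16 + 32 * 15)) {
    ix <- (j - 1) %% 32 + 1; iy <- (j - 1) %/% 32 + 1
    pr <- pinhole_response(c(ctr$x[ix], ctr$y[iy]), NULL, geom)
    col <- as.vector(sm$A[seq_len(np), j])
    # entries below the sparsity floor are dropped
    pr[pr <= 1e-8 * max(sm$A@x)] <- 0
    expect_equal(col, pr, tolerance = 1e-10)
  }
})

test_that("attenuated system-matrix entries follow hand Beer-Lambert factors", {
  grid <- small_grid(32)
  geom <- small_geometry()
  mu_val_inc <- 0.25; mu_val_xrf <- 0.31
  mu_inc <- matrix(mu_val_inc, 32, 32)
  mu_xrf <- matrix(mu_val_xrf, 32, 32)
  sm <- build_system_matrix(mu_inc, mu_xrf, geom, view_angles(1), grid)
  sm0 <- build_system_matrix(0 * mu_inc, 0 * mu_xrf, geom, view_angles(1), grid)
  ctr <- grid_centers(grid)
  ix <- 17; iy <- 17                       # voxel centre (0.25, 0.25)
  j <- ix + (iy - 1) * 32
  v <- c(ctr$x[ix], ctr$y[iy])
  # incident path from the grid edge (x = -8) to the voxel, in cm
  d_in <- (v[1] - (-8)) / 10
  # emission path from the voxel to the grid edge towards the pinhole (0,-75)
  tv <- (v[2] + 8) / (v[2] + 75)
  d_em <- tv * sqrt(v[1]^2 + (v[2] + 75)^2) / 10
  att <- exp(-mu_val_inc * d_in - mu_val_xrf * d_em)
  a <- as.vector(sm$A[, j]); a0 <- as.vector(sm0$A[, j])
  nz <- a0 > 0
  expect_equal(a[nz] / a0[nz], rep(att, sum(nz)), tolerance = 1e-9)
  # monotone: raising attenuation anywhere never increases any entry
  sm_hi <- build_system_matrix(mu_inc + 0.2, mu_xrf, geom, view_angles(1), grid)
  expect_true(all(as.matrix(sm_hi$A - sm$A) <= 1e-15))
})

test_that("MLEM has the identity fixed point and leaves consistent data unchanged", {
  A <- Matrix::Diagonal(4)
  g <- c(1, 2, 3, 4)
  r <- mlem(g, A, n_iter = 1)
  expect_equal(as.vector(r$f), g, tolerance = 1e-14)
  # a consistent measurement is a fixed point
  set.seed(8)
  A2 <- Matrix::Matrix(matrix(stats::runif(36, 0.1, 1), 6, 6))
  f_star <- stats::runif(6, 0.5, 2)
  g2 <- as.vector(A2 %*% f_star)
  r2 <- mlem(g2, A2, n_iter = 1, f_init = f_star)
  expect_equal(as.vector(r2$f), f_star, tolerance = 1e-12)
})

test_that("MLEM matches an independent brute-force implementation", {
  # 2x2-voxel, 4-measurement toy with a printed-out matrix
  A <- matrix(c(1.0, 0.2, 0.1, 0.05,
                0.3, 0.8, 0.15, 0.1,
                0.1, 0.15, 0.9, 0.25,
                0.05, 0.1, 0.3, 0.7), 4, 4, byrow = TRUE)
  set.seed(31)
  f_true <- c(4, 0.5, 2, 1)
  g <- stats::rpois(4, as.vector(A %*% f_true) * 50) / 50
  # straight-line oracle: explicit loops over the update formula
  brute <- rep(1, 4)
  for (it in 1:50) {
    fwd <- numeric(4)
    for (i in 1:4) for (jp in 1:4) fwd[i] <- fwd[i] + A[i, jp] * brute[jp]
    newf <- numeric(4)
    for (j in 1:4) {
      sens <- sum(A[, j])
      back <- 0
      for (i in 1:4) back <- back + A[i, j] * g[i] / fwd[i]
      newf[j] <- brute[j] * back / sens
    }
    brute <- newf
  }
  r <- mlem(g, Matrix::Matrix(A), n_iter = 50)
  expect_equal(as.vector(r$f), brute, tolerance = 1e-12)
  # Poisson log-likelihood is non-decreasing, image stays nonnegative
  expect_true(all(diff(r$loglik) > -1e-9))
  expect_true(all(r$f >= 0))
})

test_that("MLEM conserves counts at convergence on full-sensitivity systems", {
  set.seed(12)
  A <- Matrix::Matrix(matrix(stats::runif(20 * 12, 0.05, 1), 20, 12))
  g <- stats::rpois(20, 30)
  r <- mlem(g, A, n_iter = 200)
  expect_lt(abs(sum(A %*% r$f) - sum(g)) / sum(g), 0.005)
})

test_that("MLEM validates inputs and handles zero-sensitivity voxels", {
  A <- Matrix::Matrix(cbind(c(1, 1), c(0, 0)))   # second voxel unseen
  r <- mlem(c(2, 2), A, n_iter = 10)
  expect_equal(as.vector(r$f), c(2, 0))
  expect_error(mlem(c(-1, 1), A), "g >= 0")
})

test_that("filtered backprojection recovers a uniform disc and is linear", {
  grid <- voxel_grid(128, 128, 0.5)
  mu <- 0.2 * disc_mask(grid, 20)
  angles <- view_angles(180, 180)
  offsets <- (seq_len(128) - 64.5) * 0.5
  sino <- xfct:::cpp_parallel_sinogram(mu, 0.5, grid$origin[1], grid$origin[2],
                                       angles, offsets)
  img <- fbp_slice(sino, grid, angles, offsets)
  expect_equal(img[64, 64], 0.2, tolerance = 0.03)
  expect_lt(abs(img[64, 64] - 0.2), 0.006)
  expect_equal(fbp_slice(0 * sino, grid, angles, offsets),
               matrix(0, 128, 128))
  img2 <- fbp_slice(2 * sino, grid, angles, offsets)
  expect_equal(img2, 2 * img, tolerance = 1e-12)
})

test_that("material decomposition segments bone and fills soft tissue with water", {
  grid <- voxel_grid(128, 128, 0.5)
  ph <- mouse_slice_phantom("liver")
  tr <- rasterize(ph, grid)
  ct <- simulate_transmission(tr, seed = 7, noise = TRUE)
  mu_fbp <- fbp_slice(ct)
  dec <- decompose_materials(mu_fbp, matrix(0, 128, 128), grid, ct$e_eff)
  bone_truth <- rasterize(phantom_spec(ph$background,
                                       bone_regions = ph$bone_regions),
                          grid)$masses$bone_cortical > 0.5 * 1.92
  dice <- 2 * sum(dec$bone_mask & bone_truth) /
    (sum(dec$bone_mask) + sum(bone_truth))
  expect_gte(dice, 0.95)
  # synthesized map reproduces the measured attenuation in soft tissue
  soft <- !dec$bone_mask & mu_fbp > 0.15 & dec$gd_mg_ml == 0
  mu_back <- decomposition_mu(dec, ct$e_eff)
  expect_equal(mu_back[soft], mu_fbp[soft], tolerance = 1e-6)
})

test_that("decomposition of a bone-free water object warns and stays water-only", {
  grid <- small_grid()
  tr <- rasterize(phantom_spec(list(material = "water", density = 1,
                                    radius = 10)), grid)
  ct <- simulate_transmission(tr, n_views = 60, noise = FALSE)
  mu_fbp <- fbp_slice(ct)
  expect_warning(dec <- decompose_materials(mu_fbp, matrix(0, 64, 64), grid,
                                            ct$e_eff),
                 "empty bone mask")
  expect_equal(sum(dec$bone_mask), 0)
  expect_true(all(dec$gd_mg_ml == 0))
  inside <- disc_mask(grid, 8) > 0
  expect_equal(dec$water_density[inside], rep(1, sum(inside)), tolerance = 0.05)
})

test_that("attenuation correction moves a deep insertion towards its true value", {
  grid <- small_grid()
  geom <- small_geometry()
  spec <- phantom_spec(list(material = "water", density = 1, radius = 14),
                       data.frame(x = 0, y = 0, radius = 3, concentration = 20))
  tr <- rasterize(spec, grid)
  prot <- small_protocol(n_views = 24)
  s <- simulate_xfct(tr, geom, protocol = prot, noise = FALSE)
  g <- as.vector(t(correct(s)$n_xrf))
  angles <- view_angles(24)
  zero <- matrix(0, 64, 64)
  A_vac <- build_system_matrix(zero, zero, geom, angles, grid)
  A_att <- build_system_matrix(mu_map(tr, s$e_inc), mu_map(tr, s$e_xrf),
                               geom, angles, grid)
  scale <- emission_scale(prot, grid)
  roi <- roi_disc(c(0, 0), 1.8)
  m_vac <- roi_stats(mlem(g, A_vac, n_iter = 100)$f / scale, grid, roi)$mean
  m_att <- roi_stats(mlem(g, A_att, n_iter = 100)$f / scale, grid, roi)$mean
  expect_lt(abs(m_att - 20), abs(m_vac - 20))
  expect_lt(m_vac, 20)                    # ignoring attenuation biases low
  expect_equal(m_att, 20, tolerance = 0.05)
})

test_that("quantitative pipeline recovers insertion concentrations without noise", {
  grid <- small_grid()
  geom <- small_geometry()
  spec <- small_cal_phantom()
  tr <- rasterize(spec, grid)
  s <- simulate_xfct(tr, geom, protocol = small_protocol(n_views = 24),
                     noise = FALSE)
  ct <- simulate_transmission(tr, n_views = 90, noise = FALSE)
  ct_mu <- fbp_slice(ct)
  rois <- calibration_rois(spec, radius = 1.5)
  cal <- list(rois = rois$targets, concentrations = spec$insertions$concentration)
  rec <- suppressWarnings(
    reconstruct_quantitative(s, ct_mu, ct$e_eff, n_iter = 100,
                             calibration = cal))
  means <- vapply(rois$targets,
                  function(r) roi_stats(rec$image, grid, r)$mean, numeric(1))
  truth <- spec$insertions$concentration
  nz <- truth >= 2
  expect_true(all(abs(means[nz] - truth[nz]) / truth[nz] < 0.05))
  expect_gte(rec$fit$r_square, 0.999)
  # Gd-free phantom reconstructs to (almost) nothing
  s0 <- simulate_xfct(rasterize(small_cal_phantom(rep(0, 6)), grid), geom,
                      protocol = small_protocol(n_views = 24), noise = FALSE)
  rec0 <- suppressWarnings(
    reconstruct_quantitative(s0, ct_mu, ct$e_eff, n_iter = 50))
  expect_lt(mean(rec0$raw$f), 0.02 * mean(rec$raw$f))
})
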
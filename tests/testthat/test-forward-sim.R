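test_that("zero-concentration phantoms produce pure scatter in the middle bin", {
  grid <- small_grid()
  geom <- small_geometry()
  tr <- rasterize(small_cal_phantom(rep(0, 6)), grid)
  s <- simulate_xfct(tr, geom, protocol = small_protocol(), noise = FALSE)
  expect_true(all(s$fluorescence == 0))
  expect_equal(s$expected[2, , ], s$scatter[[2]])
})

test_that("a single emitting voxel in vacuum matches the hand product", {
  grid <- small_grid()
  geom <- small_geometry()
  conc <- matrix(0, 64, 64)
  conc[40, 28] <- 12                      # voxel centre (3.75, -2.25) mm
  tr <- bare_truth(grid, concentration = conc)
  prot <- small_protocol(n_views = 1)
  s <- simulate_xfct(tr, geom, protocol = prot, noise = FALSE)
  ctr <- grid_centers(grid)
  q <- 12 * emission_scale(prot, grid)
  expect_equal(s$counts[2, 1, ],
               q * pinhole_response(c(ctr$x[40], ctr$y[28]), NULL, geom),
               tolerance = 1e-12)
})

test_that("noiseless expectations are linear in fluence and in concentration", {
  grid <- small_grid()
  geom <- small_geometry()
  tr <- rasterize(small_cal_phantom(), grid)
  s1 <- simulate_xfct(tr, geom, protocol = small_protocol(n_views = 4),
                      noise = FALSE)
  s2 <- simulate_xfct(tr, geom,
                      protocol = small_protocol(n_views = 4,
                                                source_fluence = 2e8),
                      noise = FALSE)
  expect_equal(s2$expected, 2 * s1$expected, tolerance = 1e-10)
  # superposition over concentration maps at fixed (vacuum) attenuation
  ca <- matrix(0, 64, 64); ca[20:25, 30:35] <- 5
  cb <- matrix(0, 64, 64); cb[40:45, 20:24] <- 3
  prot <- small_protocol(n_views = 4)
  fa <- simulate_xfct(bare_truth(grid, ca), geom, protocol = prot,
                      noise = FALSE)$fluorescence
  fb <- simulate_xfct(bare_truth(grid, cb), geom, protocol = prot,
                      noise = FALSE)$fluorescence
  fab <- simulate_xfct(bare_truth(grid, ca + cb), geom, protocol = prot,
                       noise = FALSE)$fluorescence
  expect_equal(fab, fa + fb, tolerance = 1e-10)
})

test_that("Poisson sampling is seed-reproducible and unbiased", {
  grid <- small_grid()
  geom <- small_geometry()
  tr <- rasterize(small_cal_phantom(), grid)
  prot <- small_protocol(n_views = 2)
  sa <- simulate_xfct(tr, geom, protocol = prot, seed = 11, noise = TRUE)
  sb <- simulate_xfct(tr, geom, protocol = prot, seed = 11, noise = TRUE)
  sc <- simulate_xfct(tr, geom, protocol = prot, seed = 12, noise = TRUE)
  expect_identical(sa$counts, sb$counts)
  expect_false(identical(sa$counts, sc$counts))
  expect_true(all(sa$counts >= 0 & sa$counts == round(sa$counts)))
  # empirical mean of repeated draws approaches the expectation
  idx <- which(sa$expected == max(sa$expected), arr.ind = TRUE)[1, ]
  lambda <- sa$expected[idx[1], idx[2], idx[3]]
  set.seed(1)
  draws <- stats::rpois(200, lambda)
  expect_lt(abs(mean(draws) - lambda) / lambda, 4 / sqrt(200 * lambda))
})

test_that("self-attenuation never increases fluorescence expectations", {
  grid <- small_grid()
  geom <- small_geometry()
  conc <- matrix(0, 64, 64); conc[28:36, 28:36] <- 10
  water <- 0.5 * disc_mask(grid, 12)
  lo <- bare_truth(grid, conc, density = water)
  hi <- bare_truth(grid, conc, density = 2 * water)
  prot <- small_protocol(n_views = 4)
  flo <- simulate_xfct(lo, geom, protocol = prot, noise = FALSE)$fluorescence
  fhi <- simulate_xfct(hi, geom, protocol = prot, noise = FALSE)$fluorescence
  expect_true(all(fhi <= flo + 1e-12))
  expect_lt(max(fhi), max(flo))
})

test_that("fluorescence requires spectral support above the K edge", {
  grid <- small_grid()
  tr <- rasterize(small_cal_phantom(), grid)
  expect_error(simulate_xfct(tr, small_geometry(), spectrum = spectrum_mono(40),
                             protocol = small_protocol(), noise = FALSE),
               "above")
})

test_that("transmission follows Beer-Lambert and respects rotational symmetry", {
  grid <- small_grid()
  disc <- phantom_spec(list(material = "water", density = 1, radius = 10))
  tr <- rasterize(disc, grid)
  ct <- simulate_transmission(tr, n_views = 12, noise = FALSE)
  mu_w <- mass_attenuation(material_table("water"), ct$e_eff)
  central <- which.min(abs(ct$offsets))
  expect_equal(ct$mu_sinogram[1, central], mu_w * 2.0, tolerance = 0.01)
  # empty object: unit transmission everywhere
  ct0 <- simulate_transmission(bare_truth(grid), n_views = 4, noise = FALSE)
  expect_true(all(ct0$mu_sinogram == 0))
  # centred disc: views are interchangeable up to raster tolerance
  spread <- apply(ct$mu_sinogram, 2, function(col) diff(range(col)))
  expect_lt(max(spread) / max(ct$mu_sinogram), 0.02)
  # noisy rays are floored at one count before the log transform
  ctn <- simulate_transmission(tr, counts_per_ray = 5, seed = 3, noise = TRUE)
  expect_true(all(is.finite(ctn$mu_sinogram)))
})
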
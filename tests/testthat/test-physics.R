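test_that("Klein-Nishina cross-section vanishes at the poles and rejects bad input", {
  expect_equal(klein_nishina(60, 0), 0)
  expect_equal(klein_nishina(60, pi), 0)
  expect_error(klein_nishina(60, -0.1), "theta")
  expect_error(klein_nishina(60, pi + 0.1), "theta")
  expect_error(klein_nishina(-5, 1), "positive")
  expect_error(klein_nishina(0, 1), "positive")
  theta <- seq(0, pi, length.out = 200)
  expect_true(all(klein_nishina(60, theta) >= 0))
})

test_that("low-energy quadrature recovers the Thomson cross-section", {
  k <- scatter_constants()
  thomson <- (8 / 3) * pi * k$r0_cm^2
  q <- stats::integrate(function(t) klein_nishina(0.1, t), 0, pi,
                        rel.tol = 1e-10)$value
  expect_lt(abs(q - thomson) / thomson, 1e-3)
})

test_that("Compton hardening: cross-section decreases with energy at fixed angle", {
  E <- seq(10, 200, by = 5)
  for (th in c(0.3, pi / 2, 2.5)) {
    vals <- klein_nishina(E, rep(th, length(E)))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("bin scatter weight collapses for a delta spectrum and dies off support", {
  sp <- spectrum_mono(42)
  b2 <- default_energy_bins()[[2]]
  expect_equal(bin_scatter_weight(sp, b2, 1.1), klein_nishina(42, 1.1))
  expect_equal(bin_scatter_weight(sp, energy_bin(100, 110), 1.1), 0)
  expect_equal(bin_scatter_weight(flat_spectrum(33, 51), energy_bin(100, 110), 0.7),
               0)
})

test_that("bin scatter weight is quadrature-stable and additive over sub-bins", {
  th <- pi / 2
  coarse <- flat_spectrum(33, 51, n = 10)
  fine <- flat_spectrum(33, 51, n = 100)
  bins <- default_energy_bins()
  r_coarse <- bin_scatter_weight(coarse, bins[[2]], th) /
    bin_scatter_weight(coarse, bins[[1]], th)
  r_fine <- bin_scatter_weight(fine, bins[[2]], th) /
    bin_scatter_weight(fine, bins[[1]], th)
  expect_lt(abs(r_coarse - r_fine) / r_fine, 0.005)
  # partition additivity on the spectrum's own grid
  sp <- flat_spectrum(33, 51, n = 181)
  whole <- bin_scatter_weight(sp, energy_bin(39, 45), th)
  parts <- bin_scatter_weight(sp, energy_bin(39, 42), th) +
    bin_scatter_weight(sp, energy_bin(42, 45), th)
  expect_equal(parts, whole, tolerance = 1e-6)
})

test_that("attenuation lookup reproduces embedded table entries and mixes linearly", {
  w <- material_table("water")
  expect_equal(mass_attenuation(w, 50), 0.2269)
  expect_equal(attenuation_coefficient(w, 1, 1.0, 50), 0.2269)
  b <- material_table("bone_cortical")
  # degenerate mixture = single-material call
  expect_equal(attenuation_coefficient(list(w, b, material_table("pmma")),
                                       c(1, 0, 0), 1.0, 45),
               attenuation_coefficient(w, 1, 1.0, 45))
  # 50/50 water/bone hand sum at a tabulated grid point
  expect_equal(attenuation_coefficient(list(w, b), c(0.5, 0.5), 1.3, 40),
               1.3 * (0.2683 + 0.6655) / 2)
  expect_error(mass_attenuation(w, 500), "outside")
  expect_error(attenuation_coefficient(list(w, b), c(0.5, 0.6), 1, 40), "sum to 1")
})

test_that("mixture rule is linear in mass fractions", {
  mats <- list(material_table("water"), material_table("pmma"),
               material_table("bone_cortical"))
  set.seed(42)
  for (i in 1:20) {
    wa <- stats::runif(3); wa <- wa / sum(wa)
    wb <- stats::runif(3); wb <- wb / sum(wb)
    lam <- stats::runif(1)
    E <- stats::runif(1, 21, 149)
    mu_mix <- attenuation_coefficient(mats, lam * wa + (1 - lam) * wb, 1.1, E)
    expect_equal(mu_mix,
                 lam * attenuation_coefficient(mats, wa, 1.1, E) +
                   (1 - lam) * attenuation_coefficient(mats, wb, 1.1, E),
                 tolerance = 1e-10)
  }
})

test_that("Gd tables jump upward across the K edge", {
  for (m in c("gadolinium", "nagdf4")) {
    tab <- material_table(m)
    expect_gt(mass_attenuation(tab, 50.3), mass_attenuation(tab, 50.1))
    expect_gt(mass_attenuation(tab, 50.3) / mass_attenuation(tab, 50.1), 3)
  }
})

test_that("fluorescence yield factor counts only the lines inside the bin", {
  lines <- gd_fluorescence_lines()
  bins <- default_energy_bins()
  expect_equal(xrf_yield_factor(lines, bins[[2]]), 0.93)
  expect_equal(xrf_yield_factor(lines, bins[[1]]), 0)
  # half the line intensity in the bin, yield 0.5
  half <- gd_fluorescence_lines(fluorescence_yield = 0.5)
  expect_equal(xrf_yield_factor(half, energy_bin(42.5, 45)), 0.5 * 0.645)
})

test_that("tube spectrum model is nonnegative with support above the Gd K edge", {
  sp <- spectrum_tube(140, 0.4)
  expect_true(all(sp$fluence >= 0))
  expect_true(any(sp$fluence[sp$energies > 50.2] > 0))
  expect_true(all(diff(sp$energies) > 0))
  # harder filtration pushes the effective energy up
  expect_gt(effective_energy(spectrum_tube(140, 0.4)),
            effective_energy(spectrum_tube(140, 0.1)))
  expect_error(effective_energy(spectrum_mono(40), above_keV = 50.2), "above")
})
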
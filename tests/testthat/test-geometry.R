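test_that("field of view exceeds the object size and scales with magnification", {
  geom <- system_geometry()
  expect_equal(fov_diameter(geom), 256 * 0.5 * 75 / 63.5)
  unit <- system_geometry(pinhole_to_center = 60, pinhole_to_detector = 60)
  expect_equal(fov_diameter(unit), 256 * 0.5)
  half <- system_geometry(pinhole_to_detector = 63.5 / 2)
  expect_equal(fov_diameter(half), 2 * fov_diameter(geom))
})

test_that("scatter angle matches hand trigonometry", {
  geom <- system_geometry()
  expect_equal(scatter_angle(c(0, 0), c(1, 0), geom), pi / 2)
  expect_equal(scatter_angle(c(-75, 0), c(1, 0), geom), pi / 4)
  # beam pointing straight at the pinhole: forward scatter
  expect_equal(scatter_angle(c(0, 0), c(0, -1), geom), 0)
})

test_that("scatter angle is invariant under rigid rotation of the system", {
  geom <- system_geometry()
  set.seed(7)
  for (i in 1:10) {
    v <- stats::runif(2, -20, 20)
    a <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    base <- scatter_angle(v, c(1, 0), geom)
    rot <- scatter_angle(as.vector(R %*% v), as.vector(R %*% c(1, 0)), geom,
                         pinhole_xy = as.vector(R %*% c(0, -75)))
    expect_equal(rot, base, tolerance = 1e-12)
  }
})

test_that("pinhole response misses pixels far from the image point", {
  geom <- system_geometry()
  v <- c(3, 5)
  pr <- pinhole_response(v, NULL, geom)
  uc <- -3 * 63.5 / (5 + 75)
  img_pix <- floor((uc + 64) / 0.5) + 1
  expect_gt(pr[img_pix], 0)
  expect_equal(pr[img_pix + 3], 0)
  expect_equal(pr[img_pix - 3], 0)
})

test_that("pinhole response is mirror-symmetric and conserves the aperture solid angle", {
  geom <- system_geometry()
  v <- c(7.3, -2.1)
  pr <- pinhole_response(v, NULL, geom)
  pr_m <- pinhole_response(c(-v[1], v[2]), NULL, geom)
  expect_equal(pr, rev(pr_m), tolerance = 1e-12)
  tv <- v[2] + 75
  r2 <- v[1]^2 + tv^2
  omega <- 0.5 * 2 * (tv / sqrt(r2)) / (4 * pi * r2)
  expect_equal(sum(pr), omega, tolerance = 1e-12)
})

test_that("pinhole solid angle agrees with Monte-Carlo ray sampling", {
  geom <- system_geometry()
  v <- c(6, 10)                                 # off-axis voxel, z = 0
  total <- sum(pinhole_response(v, NULL, geom))
  # sample directions uniformly inside a cone that covers the aperture
  P <- c(0, -75, 0)
  axis <- c(P[1] - v[1], P[2] - v[2], 0)
  d0 <- sqrt(sum(axis^2)); axis <- axis / d0
  half_diag <- sqrt(0.25^2 + 1^2)
  theta_c <- atan(half_diag / d0) * 1.5
  e1 <- c(-axis[2], axis[1], 0)
  e2 <- c(0, 0, 1)
  set.seed(123)
  n <- 1e6
  ct <- stats::runif(n, cos(theta_c), 1)
  st <- sqrt(1 - ct^2)
  ph <- stats::runif(n, 0, 2 * pi)
  dir <- cbind(ct * axis[1] + st * (cos(ph) * e1[1] + sin(ph) * e2[1]),
               ct * axis[2] + st * (cos(ph) * e1[2] + sin(ph) * e2[2]),
               ct * axis[3] + st * (cos(ph) * e1[3] + sin(ph) * e2[3]))
  tt <- (P[2] - v[2]) / dir[, 2]                # aperture plane y = -75
  px <- v[1] + tt * dir[, 1]
  pz <- 0 + tt * dir[, 3]
  hit <- tt > 0 & abs(px) <= 0.25 & abs(pz) <= 1
  omega_mc <- mean(hit) * 2 * pi * (1 - cos(theta_c)) / (4 * pi)
  expect_equal(total, omega_mc, tolerance = 0.01)
})

test_that("line integrals are exact on uniform maps and vanish in vacuum", {
  grid <- voxel_grid(32, 32, 1)
  mu <- matrix(0.2, 32, 32)
  # chord through the full 32 mm grid: 0.2/cm * 3.2 cm
  expect_equal(trace_line_integral(c(-50, 3.2), c(50, 3.2), mu, grid), 0.64)
  expect_equal(trace_line_integral(c(-50, 3.2), c(50, 3.2), 0 * mu, grid), 0)
  expect_equal(trace_line_integral(c(5, 5), c(5, 5), mu, grid), 0)
  # segment entirely outside the grid
  expect_equal(trace_line_integral(c(-50, 40), c(50, 40), mu, grid), 0)
})

test_that("line integrals agree with dense midpoint sampling on random maps", {
  set.seed(99)
  grid <- voxel_grid(32, 32, 1)
  mu <- matrix(stats::runif(32 * 32, 0, 0.5), 32, 32)
  lookup <- function(x, y) {
    ix <- floor((x - grid$origin[1]) / grid$pixel_size) + 1
    iy <- floor((y - grid$origin[2]) / grid$pixel_size) + 1
    ok <- ix >= 1 & ix <= 32 & iy >= 1 & iy <= 32
    v <- numeric(length(x))
    v[ok] <- mu[cbind(ix[ok], iy[ok])]
    v
  }
  for (i in 1:50) {
    p0 <- stats::runif(2, -25, 25); p1 <- stats::runif(2, -25, 25)
    L <- sqrt(sum((p1 - p0)^2))
    if (L < 1) next
    tmid <- (seq_len(1e4) - 0.5) / 1e4
    xs <- p0[1] + tmid * (p1[1] - p0[1])
    ys <- p0[2] + tmid * (p1[2] - p0[2])
    dense <- sum(lookup(xs, ys)) * (L / 1e4) / 10
    exact <- trace_line_integral(p0, p1, mu, grid)
    if (dense > 1e-3) expect_lt(abs(exact - dense) / dense, 1e-3)
  }
})

test_that("line integrals are additive under segment splitting", {
  set.seed(5)
  grid <- voxel_grid(32, 32, 1)
  mu <- matrix(stats::runif(32 * 32, 0, 0.5), 32, 32)
  for (i in 1:20) {
    p0 <- stats::runif(2, -20, 20); p2 <- stats::runif(2, -20, 20)
    lam <- stats::runif(1)
    p1 <- p0 + lam * (p2 - p0)
    whole <- trace_line_integral(p0, p2, mu, grid)
    split <- trace_line_integral(p0, p1, mu, grid) +
      trace_line_integral(p1, p2, mu, grid)
    expect_equal(split, whole, tolerance = 1e-9)
  }
})

test_that("traced voxel chords sum to the in-grid chord length", {
  grid <- voxel_grid(32, 32, 1)
  r <- trace_ray(c(-10.3, -4.2), c(12.7, 9.9), grid)
  expect_equal(sum(r$length_mm), sqrt(23^2 + 14.1^2), tolerance = 1e-9)
  expect_true(all(r$ix >= 1 & r$ix <= 32 & r$iy >= 1 & r$iy <= 32))
})

test_that("view angles cover the angular range uniformly", {
  a <- view_angles(45)
  expect_length(a, 45)
  expect_equal(a[2] - a[1], 8 * pi / 180)
  expect_equal(view_angles(4, 180), c(0, 45, 90, 135) * pi / 180)
})
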
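test_that("OSA indexing and closed forms are honoured", {
  nm <- osa_index(c(0, 1, 2, 3, 4, 5, 12, 65))
  expect_equal(nm$n, c(0, 1, 1, 2, 2, 2, 4, 10))
  expect_equal(nm$m, c(0, -1, 1, -2, 0, 2, 0, 10))
  # piston is 1 everywhere; defocus is sqrt(3)(2 rho^2 - 1)
  expect_equal(zernike_eval(0, c(0, 0.5, 1), c(0, 1, 2)), rep(1, 3))
  expect_equal(zernike_eval(4, c(0, 1), c(0, 0)), sqrt(3) * c(-1, 1))
  s4 <- zernike_surface(4, 512)
  expect_equal(mean(s4$values[s4$mask]^2), 1, tolerance = 1e-3)
  expect_error(zernike_surface(66, 64), "0..65")
})

test_that("the 66 polynomials are orthonormal under disk quadrature", {
  # quadrature oracle: Gauss-Legendre in rho^2 (exact for the polynomial
  # radial parts) crossed with a uniform angular grid (exact for the
  # trigonometric parts); nodes via Golub-Welsch
  ngl <- 40
  i <- 1:(ngl - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, ngl, ngl)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  ev <- eigen(J, symmetric = TRUE)
  u <- (ev$values + 1) / 2                       # nodes on [0, 1]
  wu <- ev$vectors[1, ]^2                        # weights (sum to 1)
  nth <- 64
  th <- 2 * pi * (0:(nth - 1)) / nth
  rho <- sqrt(u)
  pts <- expand.grid(r = rho, t = th)
  B <- zernike_basis(pts$r, pts$t, 66L)
  w <- rep(wu, times = nth) / nth
  G <- crossprod(B * w, B)
  expect_lt(max(abs(G - diag(66))), 1e-3)
  # and the pixel-sampled version used by the fitter is close on a 512 grid
  n <- 512
  g <- wfpi:::pupil_grid(n, n, c((n - 1) / 2, (n - 1) / 2), (n - 1) / 2)
  Bpix <- zernike_basis(g$rho[g$disk], g$theta[g$disk], 66L)
  Gpix <- crossprod(Bpix) / sum(g$disk)
  expect_lt(max(abs(Gpix - diag(66))), 1e-2)
})

test_that("fitting inverts surface generation exactly in the noise-free case", {
  n <- 160
  cf_true <- numeric(66)
  cf_true[5] <- 0.57                        # defocus amplitude, um
  g <- wfpi:::pupil_grid(n, n, c((n - 1) / 2, (n - 1) / 2), 70)
  vals <- matrix(NA_real_, n, n)
  B <- zernike_basis(g$rho[g$disk], g$theta[g$disk], 66L)
  vals[g$disk] <- drop(B %*% cf_true)
  ph <- phase_map(vals, g$disk, 1e-5)
  cf <- fit_zernike(ph, c((n - 1) / 2, (n - 1) / 2), 70)
  expect_equal(cf[5], 0.57, tolerance = 1e-9)
  expect_lt(max(abs(cf[-5])), 1e-9)
  # two-term surface: coefficients and RMS follow Pythagoras
  cf_true2 <- numeric(66); cf_true2[4] <- 0.3; cf_true2[6] <- 0.4
  vals[g$disk] <- drop(B %*% cf_true2)
  cf2 <- fit_zernike(phase_map(vals, g$disk, 1e-5), c((n - 1) / 2, (n - 1) / 2), 70)
  expect_equal(as.numeric(cf2[c(4, 6)]), c(0.3, 0.4), tolerance = 1e-9)
  expect_equal(band_rms(cf2, "total"), 0.5, tolerance = 1e-6)
  # full random 66-term round trip
  set.seed(5)
  cf_r <- c(0, rnorm(65, sd = 0.1))
  vals[g$disk] <- drop(B %*% cf_r)
  cf3 <- fit_zernike(phase_map(vals, g$disk, 1e-5), c((n - 1) / 2, (n - 1) / 2), 70)
  expect_lt(max(abs(as.numeric(cf3)[-1] - cf_r[-1])), 1e-6)
  expect_lt(attr(cf3, "fit_rms"), 1e-9)
})

test_that("fit_zernike refuses circles too small for the basis", {
  ph <- zernike_surface(4, 40)
  expect_error(fit_zernike(ph, c(20, 20), 8), "too small|ill-conditioned")
})

test_that("band RMS partitions follow the OSA band definitions", {
  cf <- numeric(66); cf[5] <- 0.57
  expect_equal(band_rms(cf, "low"), 0.57)
  expect_equal(band_rms(cf, "medium"), 0)
  expect_equal(band_rms(cf, "high"), 0)
  cf2 <- numeric(66); cf2[7] <- 0.3; cf2[16] <- 0.4
  expect_equal(band_rms(cf2, "medium"), 0.3)
  expect_equal(band_rms(cf2, "high"), 0.4)
  expect_equal(band_rms(cf2, "total"), 0.5)
  set.seed(2)
  cfr <- rnorm(66)
  expect_equal(band_rms(cfr, "total"), sqrt(sum(cfr[4:66]^2)))
  # Parseval across the three bands
  expect_equal(band_rms(cfr, "total")^2,
               band_rms(cfr, "low")^2 + band_rms(cfr, "medium")^2 +
                 band_rms(cfr, "high")^2)
  expect_error(band_rms(cfr, "huge"), "arg")
})

test_that("second-order coefficients convert to sphero-cylindrical powers", {
  mk <- function(c3 = 0, c4 = 0, c5 = 0, r) {
    cf <- numeric(66); cf[4] <- c3; cf[5] <- c4; cf[6] <- c5
    structure(cf, pupil_radius = r, class = "zernike_coeffs")
  }
  sc <- to_sphero_cylinder(mk(c4 = -1.768, r = 3.5e-3))
  expect_equal(sc$M, 1.0, tolerance = 1e-3)
  expect_equal(sc$cylinder, 0)
  sc0 <- to_sphero_cylinder(mk(r = 2e-3))
  expect_equal(sc0$M, 0); expect_equal(sc0$cylinder, 0)
  sc5 <- to_sphero_cylinder(mk(c5 = 1, r = 2e-3))
  expect_equal(sc5$J0, -1.2247, tolerance = 1e-4)
  expect_equal(sc5$cylinder, -2.449, tolerance = 1e-3)
  expect_equal(sc5$axis, 90)
  expect_error(to_sphero_cylinder(mk(r = -1)), "pupil_radius")
})

test_that("axis is equivariant under rotation of the phase map", {
  cfg <- tiny_config(grid = 160L, pupil = 6e-3)
  for (th in c(10, 45, 120)) {
    ph <- phase_from_refraction(0, 2, th, cfg)
    a <- analyze_eye(ph)
    pl <- as_plus_cylinder(a$refraction)
    d <- abs(pl$axis - th) %% 180
    expect_lt(min(d, 180 - d), 0.5)
  }
})

test_that("largest inscribed circle matches geometry and a brute-force oracle", {
  n <- 48
  g <- wfpi:::pupil_grid(n, n, c(22, 25), 15)
  circ <- largest_inscribed_circle(g$disk)
  expect_equal(circ$center, c(22, 25), tolerance = 1)
  expect_equal(circ$radius, 15, tolerance = 1)
  sq <- matrix(FALSE, 40, 40); sq[11:30, 6:25] <- TRUE
  cs <- largest_inscribed_circle(sq)
  expect_equal(cs$radius, 10, tolerance = 1)
  # notched disk against exhaustive distance transform
  notched <- g$disk
  notched[20:28, 22:48] <- FALSE
  co <- largest_inscribed_circle(notched)
  bf <- brute_distance_max(notched)
  expect_equal(co$radius, bf$radius, tolerance = 1)
  expect_error(largest_inscribed_circle(matrix(FALSE, 4, 4)), "empty")
})

test_that("bilinear resampling preserves constants and affine ramps", {
  const <- phase_map(matrix(2.5, 64, 64), matrix(TRUE, 64, 64), 1e-5)
  down <- resample_phase(const, 16)
  expect_equal(range(down$values), c(2.5, 2.5), tolerance = 1e-12)
  ramp <- outer(seq(0, 1, length.out = 64), seq(0, 2, length.out = 64), `+`)
  r <- resample_phase(phase_map(ramp, matrix(TRUE, 64, 64), 1e-5), 32)
  oracle <- outer(seq(0, 1, length.out = 32), seq(0, 2, length.out = 32), `+`)
  expect_equal(r$values, oracle, tolerance = 1e-12)
  # smooth map down-up round trip stays close to the original
  set.seed(8)
  sm <- wfpi:::normalized_blur(matrix(rnorm(64 * 64), 64, 64),
                               matrix(TRUE, 64, 64), 6)
  ph <- phase_map(sm, matrix(TRUE, 64, 64), 1e-5)
  rt <- resample_phase(resample_phase(ph, 32), 64)
  expect_lt(sqrt(mean((rt$values - sm)^2, na.rm = TRUE)), 0.05 * sd(sm))
  expect_error(resample_phase(ph, 1), "degenerate")
})

test_that("masks are propagated conservatively when resampling", {
  g <- wfpi:::pupil_grid(64, 64, c(31.5, 31.5), 20)
  vals <- matrix(1, 64, 64); vals[!g$disk] <- NA
  ph <- phase_map(vals, g$disk, 1e-5)
  r <- resample_phase(ph, 32)
  # every valid output pixel must lie strictly inside the input disk
  gg <- wfpi:::pupil_grid(32, 32, c(31.5, 31.5) * 31 / 63, 20 * 31 / 63)
  expect_true(all(gg$rho[r$mask] <= 1.05))
})

test_that("pupil-plane sampling follows sensor pixel over magnification", {
  expect_equal(pupil_pixel_size(9e-6, 1.5), 6e-6)
  expect_error(pupil_pixel_size(9e-6, 0), "magnification")
})
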
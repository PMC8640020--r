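test_that("refraction-derived phases carry the exact second-order coefficients", {
  cfg <- tiny_config(grid = 160L, pupil = 7e-3)
  ph <- phase_from_refraction(1, 0, 0, cfg)
  cf <- attr(ph, "coeffs_um")
  expect_equal(cf[5], -1 * (3.5e-3)^2 / (4 * sqrt(3)) * 1e6, tolerance = 1e-9)
  expect_equal(cf[5], -1.768, tolerance = 1e-3)
  flat <- phase_from_refraction(0, 0, 0, cfg)
  expect_lt(diff(range(flat$values[flat$mask])), 1e-12)
  # +2 D cylinder at 45 degrees excites oblique astigmatism (c3) only
  cyl <- phase_from_refraction(0, 2, 45, cfg)
  cfc <- attr(cyl, "coeffs_um")
  expect_gt(abs(cfc[4]), 1e-3)
  expect_lt(abs(cfc[6]), 1e-12)
  # round trip through the analysis chain
  pl <- as_plus_cylinder(analyze_eye(cyl)$refraction)
  expect_equal(pl$cylinder, 2, tolerance = 1e-3)
  expect_equal(pl$axis, 45, tolerance = 0.1)
  expect_equal(pl$sphere, 0, tolerance = 1e-3)
})

test_that("deformable-mirror style maps hit the requested peak-to-valley", {
  cfg <- tiny_config()
  pup <- wfpi:::config_pupil(cfg)
  gg <- wfpi:::pupil_grid(cfg$grid, cfg$grid, pup$center, pup$radius_px)
  for (pv in c(0.35, 2.8)) {
    ph <- random_dm_phase(pv, seed = 4, config = cfg)
    expect_equal(diff(range(ph$values[gg$disk])), pv, tolerance = 1e-6)
  }
  a <- random_dm_phase(1.4, seed = 11, config = cfg)
  b <- random_dm_phase(1.4, seed = 11, config = cfg)
  expect_identical(a$values, b$values)
  expect_error(random_dm_phase(-1), "amplitude")
})

test_that("all 63 active modes vary across repeated random draws", {
  cfg <- tiny_config(grid = 64L)
  draws <- vapply(1:60, function(s)
    attr(random_dm_phase(1, seed = s, config = cfg), "coeffs_um"),
    numeric(66))
  v <- apply(draws, 1, stats::sd)
  expect_true(all(v[4:66] > 0))
  expect_true(all(v[1:3] == 0))           # piston and tip/tilt never excited
})

test_that("pattern textures stay within the requested amplitude band", {
  cfg <- tiny_config(grid = 160L, pupil = 7e-3)
  pup <- wfpi:::config_pupil(cfg)
  gg <- wfpi:::pupil_grid(cfg$grid, cfg$grid, pup$center, pup$radius_px)
  tex <- pattern_phase(c(200, 300), 0.5e-3, seed = 2, config = cfg)
  pv_nm <- diff(range(tex$values[gg$disk])) * 1000
  expect_gte(pv_nm, 200 - 1e-6)
  expect_lte(pv_nm, 300 + 1e-6)
  flat <- pattern_phase(0, 0.5e-3, seed = 2, config = cfg)
  expect_lt(diff(range(flat$values[flat$mask])), 1e-12)
  expect_error(pattern_phase(c(200, 2000)), "nm")
})

test_that("a 66-term fit cannot absorb a fine peak-and-valley texture", {
  cfg <- sim_config(grid = 256L, pupil_diameter = 7e-3, seed = 3)
  base <- phase_from_refraction(1, 0, 0, cfg)
  tex <- pattern_phase(c(240, 260), 0.5e-3, seed = 11, config = cfg)
  tot <- base
  tot$values <- base$values + tex$values
  a <- analyze_eye(tot, rim_guard = 2)
  sel <- wfpi:::pupil_grid(256, 256, a$circle$center, a$circle$radius)$disk
  retention <- a$difference_rms / stats::sd(tex$values[sel & tex$mask])
  expect_gt(retention, 0.8)
})

test_that("propagation conserves flux and reduces to the identity for flat phase", {
  cfg <- tiny_config()
  illum <- make_illumination(cfg)
  flat <- phase_from_refraction(0, 0, 0, cfg)
  pair <- propagate(flat, illum, cfg)
  expect_equal(unclass(as.matrix(pair$i1)), unclass(as.matrix(illum)),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (S in c(1, -4)) {
    p <- propagate(phase_from_refraction(S, 0, 0, cfg), illum, cfg)
    expect_equal(sum(p$i1), sum(illum), tolerance = 1e-9)
    expect_equal(sum(p$i2), sum(illum), tolerance = 1e-9)
    expect_equal(attr(p$i1, "plane_offset"), -cfg$delta_z)
    expect_equal(attr(p$i2, "plane_offset"), +cfg$delta_z)
  }
})

test_that("a tilt phase shifts both images by the expected opposite amounts", {
  cfg <- tiny_config()
  dpx <- 3
  grad <- dpx * cfg$pixel_pitch / (2 * cfg$delta_z)
  c2 <- grad * (cfg$pupil_diameter / 2) / 2 * 1e6
  ph <- wfpi:::phase_from_coeffs(c(0, 0, c2, rep(0, 63)), cfg)
  illum <- make_illumination(cfg)
  pair <- propagate(ph, illum, cfg)
  # centroid displacement along x equals -/+ 1.5 px
  m0 <- unclass(as.matrix(illum))
  xs <- col(m0) - 1
  c0 <- sum(xs * m0) / sum(m0)
  c1 <- sum(xs * unclass(as.matrix(pair$i1))) / sum(pair$i1)
  c2c <- sum(xs * unclass(as.matrix(pair$i2))) / sum(pair$i2)
  expect_equal(c1 - c0, -dpx / 2, tolerance = 0.05)
  expect_equal(c2c - c0, +dpx / 2, tolerance = 0.05)
})

test_that("defocus changes the pupil-image radius by the paraxial amount", {
  cfg <- sim_config(grid = 256L, pupil_diameter = 7e-3, seed = 1)
  S <- 4
  ph <- phase_from_refraction(S, 0, 0, cfg)
  pair <- propagate(ph, NULL, cfg)
  area_r <- function(img) {
    m <- unclass(as.matrix(img))
    sqrt(sum(m > 0.5 * max(m)) / pi)
  }
  r0 <- area_r(make_illumination(cfg))
  dr <- cfg$delta_z * S * (cfg$pupil_diameter / 2) / cfg$pixel_pitch
  # one plane shrinks, the other grows by delta_z * S * r
  ratio <- (area_r(pair$i2) - area_r(pair$i1)) / 2
  expect_equal(abs(ratio), dr, tolerance = 0.05 * dr + 0.5)
  expect_error(propagate(phase_from_refraction(60, 0, 0, cfg), NULL, cfg),
               "reduce delta_z")
})

test_that("photon and read noise follow their first two moments", {
  img <- matrix(4, 50, 50)
  expect_identical(add_noise(img, 0, 0, seed = 1), img)
  scale <- 200
  draws <- vapply(1:400, function(s) add_noise(img, scale, 0, seed = s)[1, 1],
                  numeric(1))
  expect_equal(mean(draws), 4, tolerance = 0.05)
  expect_equal(stats::var(draws), 4 / scale, tolerance = 0.25 * 4 / scale)
  withr <- add_noise(img, 0, 0.3, seed = 2)
  expect_equal(mean(withr), 4, tolerance = 0.05)
  expect_error(add_noise(img, -1), ">= 0")
  # determinism
  expect_identical(add_noise(img, 100, 0.1, seed = 9),
                   add_noise(img, 100, 0.1, seed = 9))
})
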
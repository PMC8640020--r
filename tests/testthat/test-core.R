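test_that("line profiles of a constant image are linear ramps along rows", {
  img <- intensity_image(matrix(1, 8, 10), 1e-5)
  prof <- line_profiles(img, 0)
  full_rows <- Filter(function(p) p$intercept >= 0 && p$intercept <= 7, prof)
  expect_length(full_rows, 8L)
  for (p in full_rows) {
    expect_identical(p$major, "x")
    expect_equal(p$samples, 1:10, tolerance = 1e-12)
  }
})

test_that("a single bright pixel produces one unit-step profile", {
  m <- matrix(0, 8, 10)
  m[3, 6] <- 1                              # y = 2, x = 5 (0-based)
  prof <- line_profiles(intensity_image(m, 1e-5), 0)
  for (p in prof) {
    if (p$intercept == 2) {
      expect_equal(p$samples, c(rep(0, 5), rep(1, 5)))
    } else {
      expect_equal(max(abs(p$samples)), 0)
    }
  }
})

test_that("diagonal profiles match direct summation along the line", {
  m <- matrix(1:16, 4, 4)
  prof <- line_profiles(intensity_image(m, 1e-5), pi / 4)
  diagp <- Filter(function(p) p$intercept == 0, prof)[[1]]
  oracle <- cumsum(vapply(0:3, function(i) m[i + 1, i + 1], numeric(1)))
  expect_equal(diagp$samples, oracle, tolerance = 1e-12)
})

test_that("profiles are always non-decreasing on random non-negative images", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rexp(30 * 40), 30, 40)
    ang <- runif(1, -pi / 2 + 0.01, pi / 2)
    for (p in line_profiles(intensity_image(m, 1e-5), ang))
      expect_gte(min(diff(p$samples)), -1e-12)
  }
})

test_that("profile displacement recovers identity and integer shifts", {
  T0 <- c(0, 0, 0, 1, 3, 6, 3, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  f <- cumsum(T0)
  expect_equal(unname(profile_displacement(f, f)[T0 > 0]), rep(0, 5))
  g <- cumsum(c(rep(0, 3), T0[1:13]))       # shifted by +3
  expect_equal(unname(profile_displacement(f, g)[T0 > 0]), rep(3, 5),
               tolerance = 1e-10)
})

test_that("profile displacement matches the hand inverse-CDF example", {
  f <- cumsum(c(0, 1, 1, 0))
  g <- cumsum(c(0, 0, 1, 1))
  d <- profile_displacement(f, g)
  expect_equal(d[2:3], c(1, 1), tolerance = 1e-12)
  expect_true(all(is.na(d[c(1, 4)])))
})

test_that("displacement rejects bad input and flags zero flux", {
  expect_error(profile_displacement(c(0, 2, 1), c(0, 1, 2)), "non-decreasing")
  expect_true(all(is.na(profile_displacement(rep(0, 5), rep(0, 5)))))
  expect_error(profile_displacement(1:4, 1:5), "parameterization")
})

test_that("identical images give an exactly null gradient field", {
  set.seed(7)
  m <- matrix(rexp(64 * 64), 64, 64)
  g <- recover_gradients(m, m, k = 8)
  expect_gt(sum(g$mask), 1000)
  expect_lt(max(abs(g$grad_h[g$mask])), 1e-9)
  expect_lt(max(abs(g$grad_v[g$mask])), 1e-9)
})

test_that("recover_gradients validates its inputs", {
  m <- matrix(1, 16, 16)
  expect_error(recover_gradients(m, matrix(1, 16, 8)), "dimensions")
  expect_error(recover_gradients(m, m, k = 1), ">= 2")
  expect_error(recover_gradients(m - 2, m, k = 4), "non-negative")
})

test_that("C++ kernel agrees with the R reference path at angle zero", {
  cfg <- tiny_config(grid = 96L, pupil = 3e-3)
  ph <- phase_from_refraction(0.75, 0, 0, cfg)
  pair <- propagate(ph, NULL, cfg)
  m1 <- unclass(as.matrix(pair$i1)); m2 <- unclass(as.matrix(pair$i2))
  acc <- wfpi:::.match_kernel(m1, m2, 0, 1e-6, 0)
  dk <- acc$Bc / pmax(acc$Scc, 1e-12)
  # R reference: per-row cumulative profiles + displacement matcher
  p1 <- line_profiles(m1, 0); p2 <- line_profiles(m2, 0)
  ok_rows <- 30:66
  errs <- c()
  for (i in seq_along(p1)) {
    b <- p1[[i]]$intercept
    if (!(b %in% ok_rows)) next
    dr <- profile_displacement(p1[[i]]$samples, p2[[i]]$samples)
    sel <- which(!is.na(dr))
    sel <- sel[sel > 20 & sel < 76]
    errs <- c(errs, dk[b + 1, sel] - dr[sel])
  }
  expect_lt(sqrt(mean(errs^2, na.rm = TRUE)), 0.05)
})

test_that("recovered uniform displacement is linear in the injected tilt", {
  cfg <- tiny_config()
  pup <- wfpi:::config_pupil(cfg)
  gg <- wfpi:::pupil_grid(cfg$grid, cfg$grid, pup$center, pup$radius_px)
  # tilt coefficient (um) giving a relative plane-to-plane shift of d px:
  # gradient = 2*c2/R_m * 1e-6 m/m; d = 2*dz*grad/s
  tilts_px <- c(0.2, 1, 3, 8)
  meas <- vapply(tilts_px, function(dpx) {
    grad <- dpx * cfg$pixel_pitch / (2 * cfg$delta_z)
    c2 <- grad * (cfg$pupil_diameter / 2) / 2 * 1e6
    ph <- wfpi:::phase_from_coeffs(c(0, 0, c2, rep(0, 63)), cfg)
    pair <- propagate(ph, NULL, cfg)
    g <- recover_gradients(pair$i1, pair$i2, k = 16)
    sel <- gg$rho < 0.7 & g$mask
    mean(g$grad_h[sel])
  }, numeric(1))
  fit <- stats::lm(meas ~ tilts_px)
  expect_rel_equal(coef(fit)[2], 1, 0.05)        # unit gain within 5%
  expect_lt(max(abs(fit$residuals / meas)), 0.05)
  # vertical component stays small
})

test_that("gradient recovery is approximately equivariant under 90-degree rotation", {
  cfg <- tiny_config(seed = 3)
  ph <- phase_from_refraction(0.5, 1, 30, cfg)
  pair <- propagate(ph, NULL, cfg)
  m1 <- unclass(as.matrix(pair$i1)); m2 <- unclass(as.matrix(pair$i2))
  g <- recover_gradients(m1, m2, k = 16)
  gr <- recover_gradients(rot90ccw(m1), rot90ccw(m2), k = 16)
  pup <- wfpi:::config_pupil(cfg)
  gg <- wfpi:::pupil_grid(cfg$grid, cfg$grid, pup$center, pup$radius_px)
  sel <- gg$rho < 0.8
  selr <- rot90ccw(sel)
  ok <- selr & gr$mask & rot90ccw(g$mask)
  # this grid rotation maps the gradient vector (h, v) to (v, -h)
  e1 <- gr$grad_h[ok] - rot90ccw(g$grad_v)[ok]
  e2 <- gr$grad_v[ok] + rot90ccw(g$grad_h)[ok]
  ref <- sqrt(mean(c(g$grad_h[g$mask & sel]^2, g$grad_v[g$mask & sel]^2)))
  expect_lt(sqrt(mean(c(e1^2, e2^2))), 0.05 * ref + 0.01)
})

test_that("precision saturates beyond about 120 angles", {
  cfg <- tiny_config(seed = 9)
  ph <- phase_from_refraction(2, 0, 0, cfg)
  pair <- propagate(ph, NULL, cfg)
  gr <- wfpi:::grad_centered(ph$values * 1e-6)
  fac <- 2 * cfg$delta_z / cfg$pixel_pitch^2
  pup <- wfpi:::config_pupil(cfg)
  gg <- wfpi:::pupil_grid(cfg$grid, cfg$grid, pup$center, pup$radius_px)
  rmse <- vapply(c(120, 240), function(k) {
    g <- recover_gradients(pair$i1, pair$i2, k = k)
    sel <- gg$rho < 0.8 & g$mask
    sqrt(mean((g$grad_h[sel] - fac * gr$gx[sel])^2))
  }, numeric(1))
  expect_lt(abs(rmse[1] - rmse[2]) / rmse[2], 0.05)
})

test_that("metric scaling applies s^2 / (2 dz) and validates parameters", {
  ones <- matrix(1, 8, 8)
  mask <- matrix(TRUE, 8, 8)
  g <- gradient_field(ones, 0 * ones, mask, units = "pixels")
  sp <- scale_params(9e-6, 13.33e-3 / 2)
  gm <- scale_gradients(g, sp)
  expect_equal(gm$units, "metres")
  expect_equal(gm$grad_h[1, 1], (9e-6)^2 / 13.33e-3, tolerance = 1e-12)
  expect_equal(max(abs(gm$grad_v[mask])), 0)
  # doubling delta_z halves the metric gradient
  gm2 <- scale_gradients(g, scale_params(9e-6, 13.33e-3))
  expect_equal(gm2$grad_h[2, 2], gm$grad_h[2, 2] / 2, tolerance = 1e-12)
  expect_error(scale_params(9e-6, -1), "delta_z")
  expect_error(scale_gradients(gm, sp), "already")
})
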
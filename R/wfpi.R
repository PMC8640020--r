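#' Detect the pupil support from intensity images
#'
#' Thresholds at 5% of the robust maximum (99.9th percentile) of the mean of
#' the two images, keeps the largest connected component and fills holes.
#'
#' @param i1,i2 intensity images.
#' @param threshold relative threshold (fraction of the robust maximum).
#' @return logical pupil mask.
#' @export
detect_pupil <- function(i1, i2 = NULL, threshold = 0.05) {
  m <- unclass(as.matrix(i1))
  if (!is.null(i2)) m <- (m + unclass(as.matrix(i2))) / 2
  thr <- threshold * stats::quantile(m, 0.999, names = FALSE)
  bw <- m > thr
  if (!any(bw)) stop("pupil not found: no pixels above the intensity threshold")
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(tab)
  comp <- EBImage::imageData(lab) == keep
  filled <- EBImage::fillHull(EBImage::Image(comp * 1))
  matrix(EBImage::imageData(filled) > 0, nrow(m), ncol(m))
}

# erode a mask by r pixels (Euclidean, via distance transform)
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  mask & (d > r)
}

#' Fit a wavefront phase map to a defocused intensity-image pair
#'
#' The estimator runs the full chain: pupil detection, directional
#' cumulative-profile matching over `k` angles ([recover_gradients()]),
#' model-based refinement of the smooth field component (the current
#' estimate is re-propagated synthetically and the coefficient-space
#' mismatch between the data and model measurements is iterated to zero,
#' cancelling the matcher's geometry-dependent gain),
#' metric scaling ([scale_gradients()]), Fourier least-squares integration
#' over the pupil ([integrate_gradients()]), and the standard analysis:
#' largest inscribed circular pupil, piston/tip/tilt removal, 66-term OSA
#' Zernike fit, band RMS, sphero-cylindrical refraction and the difference
#' map between the measured phase and its Zernike representation.
#'
#' @param i1,i2 [intensity_image()]s at planes `-delta_z` and `+delta_z`
#'   (bias-subtracted, flat-fielded).
#' @param delta_z half-separation of the planes, metres; defaults to the
#'   plane offsets recorded in the images.
#' @param pixel_size pixel pitch, metres; defaults to the image attribute.
#' @param k number of matching angles.
#' @param refine number of model-based refinement passes (0 = raw
#'   single-pass measurement; default 5).
#' @param pupil `"auto"` for intensity-threshold detection, or a logical mask.
#' @param n_terms Zernike terms for the analysis fit.
#' @param rim_guard guard band in pixels subtracted from the inscribed-circle
#'   radius before the Zernike fit, excluding rim-matching artefacts.
#' @param eps_rel per-line relative flux threshold of the matcher.
#' @return object of class `"wfpi"`; see Details.
#' @details The returned object contains `phase` (the integrated
#'   [phase_map()], micrometres, piston removed), `gradients` (metric
#'   [gradient_field()]), `analysis` (see [analyze_eye()]), `coeffs`,
#'   `refraction`, `circle`, and the call parameters. Methods: `print`,
#'   `summary`, `coef` (Zernike micrometres), `fitted` (66-term surface),
#'   `residuals` (difference map), `plot`, `predict` (evaluate the fitted
#'   surface), `simulate` (regenerate an intensity pair from the fitted
#'   phase).
#' @export
wfpi <- function(i1, i2, delta_z = NULL, pixel_size = NULL, k = 120L,
                 refine = 5L, pupil = "auto", n_terms = 66L, rim_guard = 2,
                 eps_rel = 1e-6) {
  if (is.null(pixel_size)) pixel_size <- attr(i1, "pixel_size")
  if (is.null(delta_z)) {
    off <- c(attr(i1, "plane_offset"), attr(i2, "plane_offset"))
    if (!is.null(off) && length(off) == 2L && all(is.finite(off)) && any(off != 0))
      delta_z <- (off[2] - off[1]) / 2
  }
  if (is.null(pixel_size) || is.null(delta_z))
    stop("pixel_size and delta_z are required (pass them or use intensity_image metadata)")
  m1 <- unclass(as.matrix(i1)); m2 <- unclass(as.matrix(i2))
  if (!all(dim(m1) == dim(m2))) stop("intensity images must share dimensions")
  mask_pupil <- if (identical(pupil, "auto")) detect_pupil(m1, m2) else {
    if (!is.logical(pupil) || !all(dim(pupil) == dim(m1)))
      stop("pupil must be \"auto\" or a logical mask matching the images")
    pupil
  }

  # --- raw measurement -------------------------------------------------------
  nr <- nrow(m1); nc <- ncol(m1)
  meas0 <- recover_gradients(m1, m2, k = k, eps_rel = eps_rel)
  gmask <- meas0$mask & mask_pupil
  d0h <- meas0$grad_h; d0h[!gmask] <- 0
  d0v <- meas0$grad_v; d0v[!gmask] <- 0
  # robust bound on plausible displacements: within a band of about half
  # the rim displacement the per-line transport readings are dominated by
  # the sliding of the pupil boundary along the chords and are not valid
  # displacement-field samples
  mag <- sqrt(d0h^2 + d0v^2)
  cap <- 1.5 * stats::quantile(mag[gmask], 0.95, names = FALSE) + 0.5
  clamp <- function(m) pmin(pmax(m, -cap), cap)
  guard_px <- ceiling(cap / 2) + 2
  core <- erode_mask(gmask, guard_px)
  if (sum(core) < 16L) stop("pupil too small after the rim guard band")

  # --- model-based refinement in Zernike-coefficient space -------------------
  # The matcher has a mild geometry-dependent gain on smooth fields. The
  # low-order part of the displacement field is therefore parameterized by
  # Zernike gradients and corrected by a damped fixed-point iteration
  # against the measurement of a synthetically re-propagated image pair: at
  # the fixed point the matcher sees data and model identically, so its
  # bias cancels. The high-frequency residual from the raw measurement is
  # kept as-is and re-attached at the end.
  nt_fit <- min(n_terms, max(6L, floor(sum(core) / 30)))
  if (refine > 0L && sum(core) >= 16L * 6L) {
    circ0 <- largest_inscribed_circle(mask_pupil)
    g0 <- pupil_grid(nr, nc, circ0$center, circ0$radius)
    Gx <- vector("list", nt_fit); Gy <- vector("list", nt_fit)
    for (j in seq_len(nt_fit - 1L)) {
      Z <- matrix(zernike_eval(j, g0$rho, g0$theta), nr, nc)
      gr <- grad_centered(Z)
      Gx[[j + 1L]] <- gr$gx; Gy[[j + 1L]] <- gr$gy
    }
    idx <- which(core)
    if (length(idx) > 6000L)
      idx <- idx[unique(round(seq(1L, length(idx), length.out = 6000L)))]
    D <- rbind(do.call(cbind, lapply(2:nt_fit, function(j) Gx[[j]][idx])),
               do.call(cbind, lapply(2:nt_fit, function(j) Gy[[j]][idx])))
    qrD <- qr(D)
    fit_field <- function(fh, fv) qr.coef(qrD, c(fh[idx], fv[idx]))
    eval_field <- function(cf) {
      fx <- matrix(0, nr, nc); fy <- matrix(0, nr, nc)
      for (j in 2:nt_fit) if (cf[j - 1L] != 0) {
        fx <- fx + cf[j - 1L] * Gx[[j]]; fy <- fy + cf[j - 1L] * Gy[[j]]
      }
      fx[!support] <- 0; fy[!support] <- 0
      # keep the polynomial extrapolation band within the physical bound
      list(fx = clamp(fx), fy = clamp(fy))
    }
    # polynomial gradients blow up far outside the pupil circle: restrict
    # the model field to the flux support (pupil dilated by a few pixels)
    support <- !erode_mask(!mask_pupil, guard_px + 4)
    ch <- fit_field(d0h, d0v)
    E <- eval_field(ch)
    Rh <- clamp(d0h - E$fx); Rv <- clamp(d0v - E$fy)
    Rh[!core] <- 0; Rv[!core] <- 0
    rl <- 1.5 * stats::quantile(sqrt(Rh^2 + Rv^2)[core], 0.99, names = FALSE) + 0.1
    Rh <- pmin(pmax(Rh, -rl), rl); Rv <- pmin(pmax(Rv, -rl), rl)
    eta <- c(0.9, 0.7, rep(0.5, max(0L, refine)))
    for (pass in seq_len(refine)) {
      E <- eval_field(ch)
      # mid-plane flux template from the data under the current field,
      # then the model pair; both carry the same splat smoothing
      tmpl <- (splat_shift(m1, +E$fx / 2, +E$fy / 2) +
               splat_shift(m2, -E$fx / 2, -E$fy / 2)) / 2
      s1 <- splat_shift(tmpl, -E$fx / 2, -E$fy / 2)
      s2 <- splat_shift(tmpl, +E$fx / 2, +E$fy / 2)
      meas_m <- recover_gradients(s1, s2, k = k, eps_rel = eps_rel)
      ok <- gmask & meas_m$mask
      rh <- matrix(0, nr, nc); rv <- rh
      rh[ok] <- d0h[ok] - meas_m$grad_h[ok]
      rv[ok] <- d0v[ok] - meas_m$grad_v[ok]
      ch <- ch + eta[pass] * fit_field(rh, rv)
    }
    E <- eval_field(ch)
    dh <- E$fx + Rh; dv <- E$fy + Rv
  } else {
    dh <- clamp(d0h); dv <- clamp(d0v)
  }
  gpix <- gradient_field(dh, dv, core, units = "pixels")
  sp <- scale_params(pixel_size, delta_z)
  gmet <- scale_gradients(gpix, sp)
  phase <- integrate_gradients(gmet, mask = gmet$mask, pixel_pitch = pixel_size)
  analysis <- analyze_eye(phase, n_terms = n_terms, rim_guard = rim_guard)
  structure(list(phase = phase, gradients = gmet, analysis = analysis,
                 coeffs = analysis$coeffs, refraction = analysis$refraction,
                 circle = analysis$circle, pupil_mask = mask_pupil,
                 params = list(pixel_size = pixel_size, delta_z = delta_z,
                               k = k, refine = refine, n_terms = n_terms,
                               rim_guard = rim_guard)),
            class = "wfpi")
}

#' Reconstruct a phase map from an intensity pair
#'
#' Convenience wrapper around [wfpi()] returning only the integrated
#' [phase_map()].
#'
#' @inheritParams wfpi
#' @param ... passed to [wfpi()].
#' @return a [phase_map()] in micrometres.
#' @export
reconstruct <- function(i1, i2, ...) wfpi(i1, i2, ...)$phase

#' Analyze a phase map the way an aberrometer reports an eye
#'
#' Crops the map to the largest circle inscribed in its pupil mask (minus an
#' optional guard band), removes piston and tip/tilt, fits the first
#' `n_terms` OSA Zernike polynomials, and reports the fitted surface, the
#' difference map with its RMS, band RMS values, the sphero-cylindrical
#' refraction, and the circular pupil diameter used.
#'
#' @param phase a [phase_map()] in micrometres.
#' @param n_terms number of Zernike terms (default 66).
#' @param rim_guard guard band in pixels subtracted from the inscribed
#'   radius.
#' @return list of class `"wfpi_analysis"`: `phase` (cropped, piston/tip/tilt
#'   removed), `fit` ([phase_map()] of the Zernike surface), `difference`
#'   ([phase_map()]), `difference_rms` (um), `coeffs`, `bands` (low, medium,
#'   high, total RMS in um), `refraction`, `circle`, `pupil_diameter_mm`,
#'   `total_rms`, `pv`.
#' @export
analyze_eye <- function(phase, n_terms = 66L, rim_guard = 0) {
  stopifnot(inherits(phase, "phase_map"))
  circ <- largest_inscribed_circle(phase$mask)
  circ$radius <- circ$radius - rim_guard
  if (circ$radius <= 0) stop("pupil too small after rim guard")
  g <- pupil_grid(nrow(phase$values), ncol(phase$values), circ$center, circ$radius)
  keep <- g$disk & phase$mask
  vals <- phase$values; vals[!keep] <- NA_real_
  cropped <- remove_ptt(phase_map(vals, keep, phase$pixel_pitch))
  coeffs <- fit_zernike(cropped, circ$center, circ$radius, n_terms)
  fitmap <- zernike_reconstruct(coeffs, nrow(vals), ncol(vals), phase$pixel_pitch)
  diffv <- cropped$values - fitmap$values
  diffmask <- cropped$mask & fitmap$mask
  diffv[!diffmask] <- NA_real_
  difference <- phase_map(diffv, diffmask, phase$pixel_pitch)
  v <- cropped$values[cropped$mask]
  structure(list(
    phase = cropped, fit = fitmap, difference = difference,
    difference_rms = sqrt(mean(diffv[diffmask]^2)),
    coeffs = coeffs,
    bands = c(low = band_rms(coeffs, "low"), medium = band_rms(coeffs, "medium"),
              high = band_rms(coeffs, "high"), total = band_rms(coeffs, "total")),
    refraction = to_sphero_cylinder(coeffs),
    circle = circ,
    pupil_diameter_mm = 2 * circ$radius * phase$pixel_pitch * 1e3,
    total_rms = sqrt(mean(v^2)), pv = max(v) - min(v)),
    class = "wfpi_analysis")
}

#' High-pass filter a phase map
#'
#' Subtracts a mask-aware Gaussian blur (normalized convolution, so the rim
#' is unbiased) from the phase, revealing the high-frequency components.
#'
#' @param phase a [phase_map()].
#' @param sigma Gaussian sigma in pixels (> 0), default 0.5.
#' @return the high-pass filtered [phase_map()] (same mask).
#' @export
highpass <- function(phase, sigma = 0.5) {
  stopifnot(inherits(phase, "phase_map"))
  if (sigma <= 0) stop("sigma must be > 0")
  low <- normalized_blur(ifelse(phase$mask, phase$values, 0), phase$mask, sigma)
  vals <- phase$values - low
  vals[!phase$mask] <- NA_real_
  phase_map(vals, phase$mask, phase$pixel_pitch)
}

#' Comparison metrics between two co-registered phase maps
#'
#' @param a,b [phase_map()]s on the same grid; with `b` missing, `a` is
#'   compared against zero.
#' @return list with `rms` (raw RMS difference over the mask intersection),
#'   `rms_piston_removed`, `pv` (peak-to-valley of the difference) and
#'   `max_abs`.
#' @export
phase_metrics <- function(a, b = NULL) {
  stopifnot(inherits(a, "phase_map"))
  if (is.null(b)) {
    d <- a$values; m <- a$mask
  } else {
    stopifnot(inherits(b, "phase_map"))
    if (!all(dim(a$values) == dim(b$values))) stop("phase maps must be co-registered")
    m <- a$mask & b$mask
    if (!any(m)) stop("empty mask intersection")
    d <- a$values - b$values
  }
  dv <- d[m]
  list(rms = sqrt(mean(dv^2)),
       rms_piston_removed = stats::sd(dv) * sqrt((length(dv) - 1) / length(dv)),
       pv = max(dv) - min(dv),
       max_abs = max(abs(dv)))
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.wfpi <- function(x, ...) {
  a <- x$analysis
  cat("Wavefront phase imaging fit\n")
  cat(sprintf("  pupil (inscribed): %.2f mm; grid %d x %d px @ %.3g um\n",
              a$pupil_diameter_mm, nrow(x$phase$values), ncol(x$phase$values),
              x$phase$pixel_pitch * 1e6))
  cat(sprintf("  refraction: S %+.2f D, C %+.2f D x %.0f deg\n",
              x$refraction$sphere, x$refraction$cylinder, x$refraction$axis))
  cat(sprintf("  RMS (um): total %.3f | low %.3f medium %.3f high %.3f\n",
              a$bands["total"], a$bands["low"], a$bands["medium"], a$bands["high"]))
  cat(sprintf("  beyond %d Zernike terms: %.4f um RMS\n",
              length(x$coeffs), a$difference_rms))
  invisible(x)
}

#' @export
summary.wfpi <- function(object, ...) {
  a <- object$analysis
  out <- list(refraction = object$refraction, bands = a$bands,
              total_rms = a$total_rms, pv = a$pv,
              difference_rms = a$difference_rms,
              pupil_diameter_mm = a$pupil_diameter_mm,
              grad_residual_rms = attr(object$phase, "grad_residual_rms"),
              params = object$params)
  class(out) <- "summary.wfpi"
  out
}

#' @export
print.summary.wfpi <- function(x, ...) {
  cat("Wavefront phase imaging fit summary\n")
  cat(sprintf("  pupil %.2f mm, k = %d angles, %d refinement pass(es)\n",
              x$pupil_diameter_mm, x$params$k, x$params$refine))
  print(x$refraction)
  cat(sprintf("  phase RMS %.3f um, P-V %.3f um\n", x$total_rms, x$pv))
  cat(sprintf("  band RMS (um): low %.3f, medium %.3f, high %.3f, total %.3f\n",
              x$bands["low"], x$bands["medium"], x$bands["high"], x$bands["total"]))
  cat(sprintf("  difference vs %s-term fit: %.4f um RMS\n",
              format(x$params$n_terms), x$difference_rms))
  cat(sprintf("  gradient integration residual (relative): %.3g\n",
              x$grad_residual_rms))
  invisible(x)
}

#' @export
coef.wfpi <- function(object, ...) object$coeffs

#' @export
fitted.wfpi <- function(object, ...) object$analysis$fit

#' @export
residuals.wfpi <- function(object, ...) object$analysis$difference

#' Evaluate the fitted Zernike surface
#'
#' @param object a `"wfpi"` fit.
#' @param rho,theta optional polar coordinates (rho normalized to the fitted
#'   circle); by default the fitted surface map is returned.
#' @param ... unused.
#' @return a [phase_map()] or, when `rho`/`theta` are given, a numeric vector
#'   of micrometres.
#' @export
predict.wfpi <- function(object, rho = NULL, theta = NULL, ...) {
  if (is.null(rho)) return(object$analysis$fit)
  A <- zernike_basis(rho, theta, length(object$coeffs))
  drop(A %*% as.numeric(object$coeffs))
}

#' Regenerate intensity images from a fitted phase map
#'
#' Runs the forward model on the reconstructed wavefront, producing `nsim`
#' intensity pairs (with the fit's acquisition geometry), optionally with
#' photon/read noise.
#'
#' @param object a `"wfpi"` fit.
#' @param nsim number of pairs.
#' @param seed integer seed.
#' @param noise,photon_scale,read_sigma noise settings, see [add_noise()].
#' @param ... unused.
#' @return list of `nsim` lists with elements `i1`, `i2`.
#' @export
simulate.wfpi <- function(object, nsim = 1, seed = 1L, noise = FALSE,
                          photon_scale = 5e3, read_sigma = 0, ...) {
  ph <- object$phase
  grid <- nrow(ph$values)
  cfg <- sim_config(grid = grid,
                    pupil_diameter = object$analysis$pupil_diameter_mm * 1e-3,
                    pixel_pitch = ph$pixel_pitch,
                    delta_z = object$params$delta_z, seed = seed)
  illum <- matrix(0, grid, grid)
  illum[ph$mask] <- 1
  pair <- propagate(ph, intensity_image(illum, ph$pixel_pitch), cfg)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    if (noise) {
      out[[i]] <- list(i1 = add_noise(pair$i1, photon_scale, read_sigma, seed + 2L * i),
                       i2 = add_noise(pair$i2, photon_scale, read_sigma, seed + 2L * i + 1L))
    } else out[[i]] <- pair
  }
  out
}

#' Plot a wavefront fit
#'
#' Panels: reconstructed phase, 66-term Zernike fit, their difference, and
#' the high-pass filtered phase.
#'
#' @param x a `"wfpi"` fit.
#' @param sigma high-pass sigma in pixels.
#' @param ... passed to [graphics::image()].
#' @export
plot.wfpi <- function(x, sigma = 0.5, ...) {
  a <- x$analysis
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  panels <- list("WFPI phase (um)" = a$phase,
                 "Zernike fit" = a$fit,
                 "Difference" = a$difference,
                 "High-pass" = highpass(a$phase, sigma))
  cols <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)
  for (nm in names(panels)) {
    v <- panels[[nm]]$values
    graphics::image(t(v[nrow(v):1, ]), axes = FALSE, col = cols, main = nm,
                    useRaster = TRUE, ...)
  }
  invisible(x)
}
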
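# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Geometry and acquisition defaults mirror the bench configuration the
#' package emulates: planes separated by `2 delta_z = 13.33` mm and pupil
#' diameters of a few millimetres sampled by order-10-micrometre pixels.
#'
#' @param grid grid side length in pixels.
#' @param pupil_diameter pupil diameter in metres.
#' @param pixel_pitch pixel pitch in the pupil plane, metres; by default the
#'   pupil spans 78% of the grid.
#' @param delta_z half-separation of the two capture planes, metres
#'   (default `13.33e-3 / 2`).
#' @param texture_contrast RMS contrast of an optional multiplicative
#'   illumination texture (default 0: uniform disk; see
#'   [make_illumination()]).
#' @param rim_width raised-cosine rim width of the illumination disk, pixels.
#' @param noise `"none"` or `"photon+read"`.
#' @param photon_scale expected counts per unit intensity for photon noise.
#' @param read_sigma read-noise standard deviation (intensity units).
#' @param seed integer seed driving every random element.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(grid = 256L, pupil_diameter = 7e-3, pixel_pitch = NULL,
                       delta_z = 13.33e-3 / 2, texture_contrast = 0,
                       rim_width = 2, noise = c("none", "photon+read"),
                       photon_scale = 5e3, read_sigma = 0, seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(pixel_pitch)) pixel_pitch <- pupil_diameter / (0.78 * grid)
  if (pupil_diameter / pixel_pitch > grid - 4)
    stop("pupil does not fit in the grid")
  if (delta_z <= 0) stop("delta_z must be > 0")
  structure(list(grid = as.integer(grid), pupil_diameter = pupil_diameter,
                 pixel_pitch = pixel_pitch, delta_z = delta_z,
                 texture_contrast = texture_contrast, rim_width = rim_width,
                 noise = noise, photon_scale = photon_scale,
                 read_sigma = read_sigma, seed = as.integer(seed)),
            class = "sim_config")
}

# pupil geometry helpers for a config: centre and radius in pixels
config_pupil <- function(config) {
  ctr <- (config$grid - 1) / 2
  list(center = c(ctr, ctr),
       radius_px = config$pupil_diameter / 2 / config$pixel_pitch)
}

# phase map on the full grid from OSA coefficients (um), with the mask
# extended `extend_px` beyond the pupil rim by polynomial continuation so
# that gradients exist under the illumination rolloff.
phase_from_coeffs <- function(coeffs_um, config, extend_px = 4) {
  pup <- config_pupil(config)
  g <- pupil_grid(config$grid, config$grid, pup$center, pup$radius_px)
  ext <- g$rho <= 1 + extend_px / pup$radius_px
  vals <- matrix(NA_real_, config$grid, config$grid)
  act <- which(coeffs_um != 0)
  vv <- numeric(sum(ext))
  for (j in act)
    vv <- vv + coeffs_um[j] * zernike_eval(j - 1L, g$rho[ext], g$theta[ext])
  vals[ext] <- vv
  out <- phase_map(vals, ext, config$pixel_pitch)
  attr(out, "pupil") <- list(center = pup$center, radius_px = pup$radius_px,
                             radius = config$pupil_diameter / 2)
  attr(out, "coeffs_um") <- coeffs_um
  out
}

#' Second-order phase map from a sphero-cylindrical refraction
#'
#' Builds the exact second-order wavefront whose power-vector inversion (see
#' [to_sphero_cylinder()]) returns the requested refraction:
#' `M = S + C/2`, `J0 = -(C/2) cos(2 axis)`, `J45 = -(C/2) sin(2 axis)`;
#' `c4 = -M r^2 / (4 sqrt 3)`, `c5 = -J0 r^2 / (2 sqrt 6)`,
#' `c3 = -J45 r^2 / (2 sqrt 6)`.
#'
#' @param S sphere, diopters.
#' @param C cylinder, diopters (either sign convention; the axis is the
#'   cylinder axis of `C` as given).
#' @param axis cylinder axis, degrees.
#' @param config a [sim_config()].
#' @return a [phase_map()] (micrometres) carrying a `pupil` attribute.
#' @export
phase_from_refraction <- function(S, C = 0, axis = 0, config = sim_config()) {
  r <- config$pupil_diameter / 2
  th <- axis * pi / 180
  M <- S + C / 2
  J0 <- -(C / 2) * cos(2 * th)
  J45 <- -(C / 2) * sin(2 * th)
  cf <- numeric(66)
  cf[5] <- -M * r^2 / (4 * sqrt(3)) * 1e6     # c4, um
  cf[6] <- -J0 * r^2 / (2 * sqrt(6)) * 1e6    # c5
  cf[4] <- -J45 * r^2 / (2 * sqrt(6)) * 1e6   # c3
  phase_from_coeffs(cf, config)
}

#' Random deformable-mirror style Zernike phase map
#'
#' Random coefficients for OSA terms j = 3..65 (piston and tip/tilt
#' excluded), mildly weighted down with radial order (`sd = 1 / (n + 1)`),
#' then rescaled so the peak-to-valley over the pupil equals `amplitude_pv`
#' exactly. Deterministic for a given seed.
#'
#' @param amplitude_pv target peak-to-valley amplitude, micrometres (> 0).
#' @param seed integer seed.
#' @param config a [sim_config()].
#' @return a [phase_map()] (micrometres) with attribute `coeffs_um`.
#' @export
random_dm_phase <- function(amplitude_pv, seed = 1L, config = sim_config()) {
  if (amplitude_pv <= 0) stop("amplitude_pv must be > 0")
  cf <- with_seed(seed, {
    n <- osa_index(3:65)$n
    c(0, 0, 0, stats::rnorm(63, sd = 1 / (n + 1)))
  })
  ph <- phase_from_coeffs(cf, config)
  pup <- attr(ph, "pupil")
  g <- pupil_grid(config$grid, config$grid, pup$center, pup$radius_px)
  pv <- diff(range(ph$values[g$disk]))
  cf <- cf * amplitude_pv / pv
  phase_from_coeffs(cf, config)
}

#' Band-limited peak-and-valley phase texture
#'
#' A quasi-periodic random field (white noise filtered by a
#' difference-of-Gaussians band-pass centred near `correlation_length`)
#' rescaled so its peak-to-valley over the pupil falls in the requested
#' range. Emulates fine in-phase peak-and-valley structure riding on top of
#' the low-order ocular aberrations; adding it to a low-order base
#' exercises what a 66-term fit cannot represent.
#'
#' @param amplitude_nm peak-to-valley range in nanometres: a length-2 range
#'   or a single value; `0` yields a flat field.
#' @param correlation_length texture correlation length, metres.
#' @param seed integer seed.
#' @param config a [sim_config()].
#' @return a [phase_map()] in micrometres.
#' @export
pattern_phase <- function(amplitude_nm = c(200, 300),
                          correlation_length = 0.5e-3, seed = 1L,
                          config = sim_config()) {
  if (any(amplitude_nm < 0) || any(amplitude_nm > 1000))
    stop("amplitude range must lie within [0, 1000] nm")
  if (length(amplitude_nm) == 1L) amplitude_nm <- rep(amplitude_nm, 2L)
  pup <- config_pupil(config)
  g <- pupil_grid(config$grid, config$grid, pup$center, pup$radius_px)
  ext <- g$rho <= 1 + 4 / pup$radius_px
  n <- config$grid
  vals <- matrix(0, n, n)
  if (max(amplitude_nm) > 0) {
    sig <- correlation_length / config$pixel_pitch / 2
    noise <- with_seed(seed, matrix(stats::rnorm(n * n), n, n))
    full <- matrix(TRUE, n, n)
    fld <- normalized_blur(noise, full, sig) - normalized_blur(noise, full, 2 * sig)
    target <- with_seed(seed + 1L, stats::runif(1, amplitude_nm[1], amplitude_nm[2]))
    pv <- diff(range(fld[g$disk]))
    vals <- fld * (target / 1000) / pv    # nm target -> um values
  }
  vals[!ext] <- NA_real_
  out <- phase_map(vals, ext, config$pixel_pitch)
  attr(out, "pupil") <- list(center = pup$center, radius_px = pup$radius_px,
                             radius = config$pupil_diameter / 2)
  out
}

#' Pupil illumination map
#'
#' A disk with a raised-cosine rim, optionally multiplied by a seeded
#' band-limited texture emulating the structured intensity that a diffusing
#' retina projects onto the pupil plane (real acquisitions are flat-fielded,
#' so residual structure is sample-induced). The texture mixes two
#' correlation scales (about 1/6 and 1/14 of the pupil radius).
#'
#' @param config a [sim_config()].
#' @param seed seed for the texture (defaults to `config$seed`).
#' @return an [intensity_image()] at the pupil plane.
#' @export
make_illumination <- function(config, seed = config$seed) {
  n <- config$grid
  pup <- config_pupil(config)
  g <- pupil_grid(n, n, pup$center, pup$radius_px)
  r_px <- g$rho * pup$radius_px
  rim <- config$rim_width
  base <- matrix(0, n, n)
  base[r_px <= pup$radius_px] <- 1
  roll <- r_px > pup$radius_px & r_px <= pup$radius_px + rim
  base[roll] <- 0.5 * (1 + cos(pi * (r_px[roll] - pup$radius_px) / rim))
  if (config$texture_contrast > 0) {
    tex <- with_seed(seed, {
      t1 <- normalized_blur(matrix(stats::rnorm(n * n), n, n),
                            matrix(TRUE, n, n), pup$radius_px / 6)
      t2 <- normalized_blur(matrix(stats::rnorm(n * n), n, n),
                            matrix(TRUE, n, n), pup$radius_px / 14)
      t1 / stats::sd(t1) + 0.6 * t2 / stats::sd(t2)
    })
    tex <- 1 + config$texture_contrast * tex / stats::sd(tex)
    base <- base * pmax(tex, 0.05)
  }
  intensity_image(base, config$pixel_pitch, 0)
}

#' Propagate a phase map to the two capture planes
#'
#' Geometric ray transport: each illumination pixel is displaced laterally by
#' `-delta_z * grad W` for the first plane and `+delta_z * grad W` for the
#' second, and deposited by bilinear splatting. Total flux is conserved
#' exactly (an error is raised if any ray would leave the grid, which means
#' the phase is too steep for the chosen plane separation).
#'
#' @param phase a [phase_map()] in micrometres whose mask covers the
#'   illuminated area.
#' @param illumination an [intensity_image()]; defaults to
#'   [make_illumination()] for `config`.
#' @param config a [sim_config()] (supplies `delta_z` and pixel pitch).
#' @return list with intensity images `i1` (plane `-delta_z`) and `i2`
#'   (plane `+delta_z`).
#' @export
propagate <- function(phase, illumination = NULL, config = sim_config()) {
  stopifnot(inherits(phase, "phase_map"))
  if (is.null(illumination)) illumination <- make_illumination(config)
  illum <- unclass(as.matrix(illumination))
  if (!all(dim(illum) == dim(phase$values)))
    stop("illumination and phase grids differ")
  s <- config$pixel_pitch; dz <- config$delta_z
  vals <- phase$values
  # smooth extension past the mask so rim rays carry a defined gradient
  if (any(!phase$mask))
    vals[!phase$mask] <- normalized_blur(vals, phase$mask, 3)[!phase$mask]
  gr <- grad_centered(vals * 1e-6)            # metres OPD per pixel step
  dhx <- dz * gr$gx / s^2                     # half-plane ray shift, px
  dhy <- dz * gr$gy / s^2
  i1 <- splat_shift(illum, -dhx, -dhy)
  i2 <- splat_shift(illum, +dhx, +dhy)
  list(i1 = intensity_image(i1, s, -dz),
       i2 = intensity_image(i2, s, +dz))
}

# forward bilinear splat of img with per-pixel shift (dx, dy)
splat_shift <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  carrying <- img > 0
  x <- matrix(rep(0:(nc - 1), each = nr), nr, nc)[carrying] + dx[carrying]
  y <- matrix(rep(0:(nr - 1), nc), nr, nc)[carrying] + dy[carrying]
  w <- img[carrying]
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1))
    stop("ray displacement exceeds the grid; reduce delta_z or the phase slope")
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  idx <- function(yy, xx) yy + xx * nr + 1L
  ids <- c(idx(y0, x0), idx(y0 + 1, x0), idx(y0, x0 + 1), idx(y0 + 1, x0 + 1))
  wts <- c(w * (1 - fy) * (1 - fx), w * fy * (1 - fx),
           w * (1 - fy) * fx, w * fy * fx)
  out <- numeric(nr * nc)
  acc <- rowsum(wts, group = ids)
  out[as.integer(rownames(acc))] <- acc[, 1]
  matrix(out, nr, nc)
}

#' Inject photon and read noise into an intensity image
#'
#' Photon noise: counts are drawn as `Poisson(values * photon_scale) /
#' photon_scale` (variance = mean / photon_scale). Read noise: additive
#' zero-mean Gaussian with standard deviation `read_sigma`. The result is
#' clamped at zero. `photon_scale = 0` disables photon noise.
#'
#' @param image an [intensity_image()] or matrix.
#' @param photon_scale expected counts per unit intensity (>= 0).
#' @param read_sigma read-noise SD in intensity units (>= 0).
#' @param seed integer seed.
#' @return the noisy image (same class/attributes as the input).
#' @export
add_noise <- function(image, photon_scale = 5e3, read_sigma = 0, seed = 1L) {
  if (photon_scale < 0 || read_sigma < 0) stop("noise parameters must be >= 0")
  vals <- unclass(as.matrix(image))
  out <- with_seed(seed, {
    v <- vals
    if (photon_scale > 0)
      v <- matrix(stats::rpois(length(v), v * photon_scale) / photon_scale,
                  nrow(v), ncol(v))
    if (read_sigma > 0)
      v <- v + matrix(stats::rnorm(length(v), sd = read_sigma), nrow(v), ncol(v))
    pmax(v, 0)
  })
  if (inherits(image, "intensity_image"))
    intensity_image(out, attr(image, "pixel_size"), attr(image, "plane_offset"))
  else out
}
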
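#' OSA single-index to radial order and azimuthal frequency
#'
#' The OSA/ANSI single index is `j = (n (n + 2) + m) / 2` with radial order
#' `n >= 0` and azimuthal frequency `m` in `-n, -n+2, ..., n`. Negative `m`
#' denotes the sine harmonic, non-negative `m` the cosine harmonic.
#'
#' @param j integer vector of OSA indices (>= 0).
#' @return data.frame with columns `j`, `n`, `m`.
#' @export
osa_index <- function(j) {
  j <- as.integer(j)
  if (any(j < 0)) stop("OSA index must be >= 0")
  n <- ceiling((-3 + sqrt(9 + 8 * j)) / 2)
  m <- 2L * j - n * (n + 2L)
  data.frame(j = j, n = as.integer(n), m = as.integer(m))
}

# Radial polynomial R_n^|m|(rho); vectorized in rho, rho may exceed 1
# (polynomial continuation, used when a surface must extend past the pupil).
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  if ((n - m) %% 2L != 0L) return(rep(0, length(rho)))
  s <- 0:((n - m) / 2)
  coef <- (-1)^s * factorial(n - s) /
    (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
  pow <- n - 2 * s
  out <- numeric(length(rho))
  for (i in seq_along(s)) out <- out + coef[i] * rho^pow[i]
  out
}

#' Evaluate a Zernike polynomial at polar coordinates
#'
#' Uses the OSA/ANSI normalization: each polynomial has unit mean square over
#' the unit disk, i.e. `Z_0 = 1`, `Z_4 = sqrt(3) (2 rho^2 - 1)`, etc.
#'
#' @param j OSA index (scalar, 0..).
#' @param rho radial coordinate (>= 0; values > 1 are evaluated by polynomial
#'   continuation).
#' @param theta azimuthal angle in radians.
#' @return numeric vector of polynomial values.
#' @export
zernike_eval <- function(j, rho, theta) {
  nm <- osa_index(j)
  n <- nm$n; m <- nm$m
  norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
  rad <- zernike_radial(n, m, rho)
  ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(-m * theta) else 1
  norm * rad * ang
}

#' Zernike design matrix on pixel samples
#'
#' @param rho,theta polar coordinates of the sample points (rho normalized to
#'   the pupil circle).
#' @param n_terms number of OSA terms (j = 0 .. n_terms - 1).
#' @return matrix `length(rho) x n_terms`.
#' @export
zernike_basis <- function(rho, theta, n_terms = 66L) {
  vapply(seq_len(n_terms) - 1L, function(j) zernike_eval(j, rho, theta),
         numeric(length(rho)))
}

#' Sample a single Zernike polynomial as a phase map
#'
#' @param j OSA index in 0..65.
#' @param size grid side length in pixels (the map is `size x size`).
#' @param center pupil centre `(x, y)` in 0-based pixel coordinates; defaults
#'   to the grid centre.
#' @param radius pupil radius in pixels; defaults to the largest disk fitting
#'   the grid.
#' @param pixel_pitch pixel pitch in metres (metadata only).
#' @return a [phase_map()] holding the polynomial (unit coefficient, so the
#'   values are dimensionless here; scale by a coefficient in micrometres to
#'   get OPD).
#' @export
zernike_surface <- function(j, size, center = NULL, radius = NULL,
                            pixel_pitch = 1e-5) {
  if (length(j) != 1L || j < 0 || j > 65) stop("OSA index j must be in 0..65")
  if (is.null(center)) center <- c((size - 1) / 2, (size - 1) / 2)
  if (is.null(radius)) radius <- (size - 1) / 2
  g <- pupil_grid(size, size, center, radius)
  vals <- matrix(NA_real_, size, size)
  vals[g$disk] <- zernike_eval(j, g$rho[g$disk], g$theta[g$disk])
  phase_map(vals, g$disk, pixel_pitch)
}

# rho/theta grids for a circle on a nrow x ncol grid (0-based pixel coords).
pupil_grid <- function(nr, nc, center, radius) {
  x <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  y <- matrix(rep(0:(nr - 1), nc), nr, nc)
  dx <- (x - center[1]) / radius
  dy <- (y - center[2]) / radius
  rho <- sqrt(dx^2 + dy^2)
  list(rho = rho, theta = atan2(dy, dx), disk = rho <= 1)
}

#' Least-squares Zernike decomposition of a phase map
#'
#' Ordinary least squares on the pixel samples inside the given circle,
#' following common aberrometry practice (no quadrature weighting).
#'
#' @param phase a [phase_map()] in micrometres.
#' @param center circle centre `(x, y)`, 0-based pixels; see
#'   [largest_inscribed_circle()].
#' @param radius circle radius in pixels.
#' @param n_terms number of OSA terms to fit (default 66).
#' @return numeric vector of class `"zernike_coeffs"` of length `n_terms`
#'   (micrometres), with attributes `pupil_center` (px), `pupil_radius_px`,
#'   `pupil_radius` (metres), and `fit_rms` (RMS of the fit residual, um).
#' @export
fit_zernike <- function(phase, center, radius, n_terms = 66L) {
  stopifnot(inherits(phase, "phase_map"))
  if (radius <= 0) stop("radius must be > 0")
  g <- pupil_grid(nrow(phase$values), ncol(phase$values), center, radius)
  sel <- g$disk & phase$mask
  npx <- sum(sel)
  if (npx < 4L * n_terms)
    stop(sprintf("circle too small for a %d-term fit (%d px inside)", n_terms, npx))
  A <- zernike_basis(g$rho[sel], g$theta[sel], n_terms)
  qr_A <- qr(A)
  if (qr_A$rank < n_terms)
    stop("ill-conditioned Zernike design: circle too small or mask too sparse")
  z <- phase$values[sel]
  cf <- qr.coef(qr_A, z)
  res <- z - drop(A %*% cf)
  structure(as.numeric(cf),
            pupil_center = center,
            pupil_radius_px = radius,
            pupil_radius = radius * phase$pixel_pitch,
            fit_rms = sqrt(mean(res^2)),
            class = "zernike_coeffs")
}

#' @export
print.zernike_coeffs <- function(x, ...) {
  cat(sprintf("<zernike_coeffs> %d OSA terms, pupil radius %.3f mm\n",
              length(x), attr(x, "pupil_radius") * 1e3))
  cat(sprintf("  defocus c4 = %+.4g um; total RMS (j>=3) %.4g um; fit residual %.4g um\n",
              x[5], band_rms(x, "total"), attr(x, "fit_rms")))
  invisible(x)
}

#' Reconstruct the fitted Zernike surface on a grid
#'
#' @param coeffs a `"zernike_coeffs"` vector from [fit_zernike()].
#' @param nr,nc output grid dimensions in pixels.
#' @param pixel_pitch pixel pitch in metres.
#' @return a [phase_map()] (micrometres) on the fitting circle.
#' @export
zernike_reconstruct <- function(coeffs, nr, nc, pixel_pitch) {
  center <- attr(coeffs, "pupil_center")
  radius <- attr(coeffs, "pupil_radius_px")
  g <- pupil_grid(nr, nc, center, radius)
  vals <- matrix(NA_real_, nr, nc)
  A <- zernike_basis(g$rho[g$disk], g$theta[g$disk], length(coeffs))
  vals[g$disk] <- drop(A %*% as.numeric(coeffs))
  phase_map(vals, g$disk, pixel_pitch)
}

#' RMS of a Zernike coefficient band
#'
#' Band definitions follow the usual ocular-aberrometry split of the first 66
#' OSA terms: low order is j 3..5, medium j 6..14, high j 15..65; `total`
#' covers j 3..65 (piston and tip/tilt never contribute).
#'
#' @param coeffs numeric coefficient vector (OSA indexing from j = 0).
#' @param band one of `"low"`, `"medium"`, `"high"`, `"total"`.
#' @return RMS in the units of `coeffs` (micrometres).
#' @export
band_rms <- function(coeffs, band = c("total", "low", "medium", "high")) {
  band <- match.arg(band)
  jmax <- length(coeffs) - 1L
  idx <- switch(band,
                low = 3:5, medium = 6:14,
                high = 15:min(65L, jmax), total = 3:min(65L, jmax))
  idx <- idx[idx <= jmax]
  sqrt(sum(coeffs[idx + 1L]^2))
}

#' Sphero-cylindrical refraction from second-order Zernike coefficients
#'
#' Power-vector conversion from the second-order coefficients:
#' `M = -4 sqrt(3) c4 / r^2`, `J0 = -2 sqrt(6) c5 / r^2`,
#' `J45 = -2 sqrt(6) c3 / r^2` (coefficients in metres, pupil radius `r` in
#' metres, powers in diopters). The cylinder is reported in minus-cylinder
#' convention, `C = -2 sqrt(J0^2 + J45^2)`, with axis
#' `0.5 atan2(J45, J0)` mapped to `[0, 180)` degrees. The sphere is reported
#' as `M` itself: half the cylinder is deliberately not folded into the
#' sphere, so that spherical and cylindrical errors remain separable.
#'
#' @param coeffs a `"zernike_coeffs"` vector (micrometres) carrying a
#'   `pupil_radius` attribute in metres, or a plain numeric vector if
#'   `pupil_radius` is given.
#' @param pupil_radius pupil radius in metres (overrides the attribute).
#' @return list of class `"sphero_cylinder"` with elements `M`, `J0`, `J45`
#'   (D), `sphere` (D, equal to `M`), `cylinder` (D, <= 0), `axis` (degrees in
#'   `[0, 180)`), `pupil_diameter_mm`.
#' @export
to_sphero_cylinder <- function(coeffs, pupil_radius = attr(coeffs, "pupil_radius")) {
  if (is.null(pupil_radius) || pupil_radius <= 0)
    stop("pupil_radius (metres) must be > 0")
  c_m <- as.numeric(coeffs) * 1e-6           # um -> m
  r2 <- pupil_radius^2
  M <- -4 * sqrt(3) * c_m[5] / r2
  J0 <- -2 * sqrt(6) * c_m[6] / r2
  J45 <- -2 * sqrt(6) * c_m[4] / r2
  cyl <- -2 * sqrt(J0^2 + J45^2)
  axis <- (0.5 * atan2(J45, J0) * 180 / pi) %% 180
  structure(list(M = M, J0 = J0, J45 = J45, sphere = M,
                 cylinder = cyl, axis = axis,
                 pupil_diameter_mm = 2 * pupil_radius * 1e3),
            class = "sphero_cylinder")
}

#' @export
print.sphero_cylinder <- function(x, ...) {
  cat(sprintf("<sphero_cylinder> S %+0.2f D, C %+0.2f D x %0.1f deg (M %+0.2f, J0 %+0.3f, J45 %+0.3f; pupil %.2f mm)\n",
              x$sphere, x$cylinder, x$axis, x$M, x$J0, x$J45, x$pupil_diameter_mm))
  invisible(x)
}

#' Convert a refraction to plus-cylinder prescription form
#'
#' Builds the plus-cylinder prescription from the power vector: the
#' prescription sphere is `M + C_minus / 2`, the cylinder `-C_minus` and the
#' axis rotates by 90 degrees. Useful when comparing against trial lenses
#' specified with positive cylinder power. (The `sphere` element of
#' [to_sphero_cylinder()] output is the spherical equivalent `M` itself;
#' prescription transposition requires the half-cylinder arithmetic.)
#'
#' @param sc a `"sphero_cylinder"` list.
#' @return list with `sphere`, `cylinder` (>= 0), `axis`.
#' @export
as_plus_cylinder <- function(sc) {
  list(sphere = sc$M + sc$cylinder / 2,
       cylinder = -sc$cylinder,
       axis = (sc$axis + 90) %% 180)
}

#' Largest circle inscribed in a binary mask
#'
#' The centre is the interior point with maximal Euclidean distance to the
#' mask complement (computed by distance transform) and the radius is that
#' distance. Ties are broken by the first occurrence in row-major order.
#'
#' @param mask logical matrix (the pupil support).
#' @return list with `center` (`(x, y)`, 0-based pixels) and `radius` (px).
#' @export
largest_inscribed_circle <- function(mask) {
  if (!any(mask)) stop("empty mask")
  dt <- EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean")
  d <- EBImage::imageData(dt)
  # EBImage images are indexed [x, y]; our masks are [row, col] = [y, x].
  best <- max(d)
  idx <- which(d == best)
  # row-major order in the [row, col] frame: order by (row, col) of the mask
  rr <- (idx - 1L) %% nrow(d)       # x index in EBImage frame
  cc <- (idx - 1L) %/% nrow(d)      # y index
  # But mask was passed as [row(y), col(x)]: EBImage treats dim1 as x.
  # dim1 of `mask` is the row (y) axis, so rr is y and cc is x here.
  ord <- order(rr, cc)
  i <- idx[ord[1L]]
  y <- (i - 1L) %% nrow(d)
  x <- (i - 1L) %/% nrow(d)
  list(center = c(x, y), radius = as.numeric(best) - 0.5)
}

#' Bilinear resampling of a phase map
#'
#' Resamples to a new grid size with bilinear interpolation. The mask is
#' propagated conservatively: an output pixel is valid only if all four
#' contributing input pixels are valid.
#'
#' @param phase a [phase_map()].
#' @param dim_out integer `(nrow, ncol)` of the output grid.
#' @return the resampled [phase_map()] (pixel pitch rescaled accordingly).
#' @export
resample_phase <- function(phase, dim_out) {
  stopifnot(inherits(phase, "phase_map"))
  dim_out <- as.integer(dim_out)
  if (length(dim_out) == 1L) dim_out <- c(dim_out, dim_out)
  if (any(dim_out < 2L)) stop("degenerate target shape")
  nr <- nrow(phase$values); nc <- ncol(phase$values)
  # map output pixel centres onto input pixel coordinates (align corners)
  ry <- seq(0, nr - 1, length.out = dim_out[1])
  rx <- seq(0, nc - 1, length.out = dim_out[2])
  y0 <- pmin(floor(ry), nr - 2); fy <- ry - y0
  x0 <- pmin(floor(rx), nc - 2); fx <- rx - x0
  V <- phase$values; V0 <- V; V0[!phase$mask] <- 0
  M <- phase$mask * 1
  iy <- y0 + 1L; ix <- x0 + 1L
  bl <- function(A) {
    a <- A[iy, ix, drop = FALSE]; b <- A[iy + 1L, ix, drop = FALSE]
    c_ <- A[iy, ix + 1L, drop = FALSE]; d <- A[iy + 1L, ix + 1L, drop = FALSE]
    wy <- matrix(fy, dim_out[1], dim_out[2])
    wx <- matrix(fx, dim_out[1], dim_out[2], byrow = TRUE)
    a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) + c_ * (1 - wy) * wx + d * wy * wx
  }
  vals <- bl(V0)
  wm <- bl(M)
  mask_out <- wm > 1 - 1e-9          # all contributors valid
  vals[!mask_out] <- NA_real_
  pitch <- phase$pixel_pitch * (nr - 1) / (dim_out[1] - 1)
  phase_map(vals, mask_out, pitch)
}
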
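#' Intensity image captured near the conjugated pupil plane
#'
#' Wraps a non-negative numeric matrix together with the acquisition geometry:
#' the pixel pitch in the pupil plane and the signed axial offset of the
#' capture plane relative to the conjugated pupil plane.
#'
#' The grid is row-major with the origin at the top-left corner; `x` is the
#' column index and `y` the row index, both 0-based, with pixel centres at
#' integer coordinates.
#'
#' @param values numeric matrix, all entries finite and >= 0, at least 2 x 2.
#' @param pixel_size pixel pitch in metres (> 0).
#' @param plane_offset signed axial offset of the capture plane in metres
#'   (negative for the plane before the pupil conjugate, positive after).
#' @return An object of class `"intensity_image"`: the matrix with attributes
#'   `pixel_size` and `plane_offset`.
#' @export
intensity_image <- function(values, pixel_size, plane_offset = 0) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 2L || ncol(values) < 2L)
    stop("intensity image must be a numeric matrix of at least 2 x 2")
  if (anyNA(values) || any(!is.finite(values)))
    stop("intensity image must be finite")
  if (any(values < 0))
    stop("intensity image must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (metres)")
  structure(values,
            pixel_size = as.numeric(pixel_size),
            plane_offset = as.numeric(plane_offset),
            class = c("intensity_image", "matrix", "array"))
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, pixel %.4g um, plane offset %+.4g mm\n",
              nrow(x), ncol(x), attr(x, "pixel_size") * 1e6,
              attr(x, "plane_offset") * 1e3))
  cat(sprintf("  flux total %.4g, range [%.4g, %.4g]\n",
              sum(x), min(x), max(x)))
  invisible(x)
}

#' Acquisition scale parameters
#'
#' @param s pixel pitch in the pupil plane, metres (> 0).
#' @param delta_z half-separation between the two capture planes, metres (> 0);
#'   the planes sit at -delta_z and +delta_z so their distance is `2 * delta_z`.
#' @param magnification optical magnification between sensor and pupil plane
#'   (> 0). Used only for bookkeeping/conversions, see [pupil_pixel_size()].
#' @return list of class `"scale_params"`.
#' @export
scale_params <- function(s, delta_z, magnification = 1) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0) stop("s must be > 0")
  if (!is.numeric(delta_z) || length(delta_z) != 1L || delta_z <= 0)
    stop("delta_z must be > 0")
  if (!is.numeric(magnification) || magnification <= 0)
    stop("magnification must be > 0")
  structure(list(s = s, delta_z = delta_z, magnification = magnification),
            class = "scale_params")
}

#' Pixel pitch in the pupil plane from sensor pixel size and magnification
#'
#' A sensor pixel of size `sensor_pixel` observed through an optical system
#' with the given magnification samples the pupil plane with pitch
#' `sensor_pixel / magnification`.
#'
#' @param sensor_pixel sensor pixel size, metres.
#' @param magnification optical magnification (> 0).
#' @return pixel pitch in the pupil plane, metres.
#' @export
pupil_pixel_size <- function(sensor_pixel, magnification) {
  stopifnot(sensor_pixel > 0, magnification > 0)
  sensor_pixel / magnification
}

#' Phase gradient field
#'
#' Per-pixel horizontal and vertical wavefront gradients with a validity mask.
#' Units are either `"pixels"` (raw displacement between the two planes, in
#' pixels of lateral shift) or `"metres"` (optical path difference per pixel
#' step, after [scale_gradients()]).
#'
#' @param grad_h,grad_v numeric matrices of equal size.
#' @param mask logical matrix; where `FALSE` the gradients are undefined.
#' @param units `"pixels"` or `"metres"`.
#' @return list of class `"gradient_field"`.
#' @export
gradient_field <- function(grad_h, grad_v, mask, units = c("pixels", "metres")) {
  units <- match.arg(units)
  if (!all(dim(grad_h) == dim(grad_v)) || !all(dim(grad_h) == dim(mask)))
    stop("grad_h, grad_v and mask must share dimensions")
  mask <- mask & is.finite(grad_h) & is.finite(grad_v)
  grad_h[!mask] <- NA_real_
  grad_v[!mask] <- NA_real_
  structure(list(grad_h = grad_h, grad_v = grad_v,
                 mask = mask, units = units),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> %d x %d px (%s), %d valid px\n",
              nrow(x$grad_h), ncol(x$grad_h), x$units, sum(x$mask)))
  if (any(x$mask))
    cat(sprintf("  |grad| RMS: h %.4g, v %.4g\n",
                sqrt(mean(x$grad_h[x$mask]^2)), sqrt(mean(x$grad_v[x$mask]^2))))
  invisible(x)
}

#' Wavefront phase map
#'
#' Integrated wavefront as optical path difference in micrometres on a pixel
#' grid, defined inside a pupil mask and `NA` outside.
#'
#' @param values numeric matrix, micrometres of optical path difference.
#' @param mask logical matrix, the pupil support.
#' @param pixel_pitch pixel pitch in the pupil plane, metres.
#' @return list of class `"phase_map"`.
#' @export
phase_map <- function(values, mask = NULL, pixel_pitch) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- is.finite(values)
  if (!all(dim(values) == dim(mask))) stop("values and mask dimensions differ")
  if (any(!is.finite(values[mask]))) stop("phase must be finite inside mask")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask,
                 pixel_pitch = as.numeric(pixel_pitch)),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<phase_map> %d x %d px @ %.4g um/px, %d px in pupil\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch * 1e6, sum(x$mask)))
  if (length(v))
    cat(sprintf("  OPD um: RMS %.4g, P-V %.4g, mean %.4g\n",
                sqrt(mean(v^2)), max(v) - min(v), mean(v)))
  invisible(x)
}

#' Remove the piston (mean) term of a phase map
#'
#' @param phase a [phase_map()].
#' @return the phase map with zero mean over the mask.
#' @export
remove_piston <- function(phase) {
  stopifnot(inherits(phase, "phase_map"))
  phase$values <- phase$values - mean(phase$values[phase$mask])
  phase
}

#' Remove piston, tip and tilt from a phase map
#'
#' Subtracts the least-squares plane `a + b x + c y` over the mask.
#'
#' @param phase a [phase_map()].
#' @return the detrended phase map.
#' @export
remove_ptt <- function(phase) {
  stopifnot(inherits(phase, "phase_map"))
  idx <- which(phase$mask, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  z <- phase$values[phase$mask]
  fit <- stats::lm.fit(cbind(1, x, y), z)
  phase$values[phase$mask] <- fit$residuals
  phase
}
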
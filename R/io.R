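#' Read an intensity image from a TIFF file
#'
#' Accepts single-channel 8/16-bit integer or 32-bit float TIFFs. Integer
#' data are rescaled by `tiff::readTIFF` to 0..1; values are used as-is
#' (arbitrary flux units).
#'
#' @param path TIFF file path.
#' @param pixel_size pixel pitch in metres.
#' @param plane_offset signed plane offset in metres.
#' @return an [intensity_image()].
#' @export
read_intensity_tiff <- function(path, pixel_size, plane_offset = 0) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  intensity_image(m, pixel_size, plane_offset)
}

#' Write an intensity image to a 32-bit float TIFF
#'
#' @param image an [intensity_image()] or matrix.
#' @param path output path.
#' @export
write_intensity_tiff <- function(image, path) {
  m <- unclass(as.matrix(image))
  tiff::writeTIFF(m / max(m, 1e-30), path, bits.per.sample = 32L)
  invisible(path)
}

# TIFF float storage is defined on [0, 1]: store an affine-normalized page
# plus the offset/scale in the sidecar, and the mask as a second page
norm01 <- function(vals, mask) {
  v <- vals[mask]
  off <- min(v); sc <- max(max(v) - off, 1e-30)
  out <- (vals - off) / sc
  out[!mask] <- 0
  list(page = out, offset = off, scale = sc)
}

#' Write a phase map as a two-page float TIFF plus JSON sidecar
#'
#' Page 1 holds the affine-normalized phase, page 2 the pupil mask; the
#' sidecar (`<path>.json`) records the offset/scale back to micrometres of
#' optical path, the pixel pitch, piston status and summary statistics.
#'
#' @param phase a [phase_map()].
#' @param path output TIFF path.
#' @export
write_phase_tiff <- function(phase, path) {
  stopifnot(inherits(phase, "phase_map"))
  nz <- norm01(phase$values, phase$mask)
  tiff::writeTIFF(list(nz$page, phase$mask * 1), path,
                  bits.per.sample = 32L, reduce = FALSE)
  v <- phase$values[phase$mask]
  side <- list(pixel_pitch_m = phase$pixel_pitch,
               units = "micrometres OPD",
               offset_um = nz$offset, scale_um = nz$scale,
               piston_removed = abs(mean(v)) < 1e-9,
               rms_um = sqrt(mean(v^2)), pv_um = max(v) - min(v),
               n_valid = sum(phase$mask))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phase map written by [write_phase_tiff()]
#'
#' @param path TIFF path (expects the JSON sidecar alongside).
#' @return a [phase_map()].
#' @export
read_phase_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mask <- pages[[2]] > 0.5
  vals <- pages[[1]] * side$scale_um + side$offset_um
  vals[!mask] <- NA_real_
  phase_map(vals, mask, side$pixel_pitch_m)
}

#' Write a gradient field as float TIFFs plus a mask TIFF
#'
#' Writes `<stem>_h.tif`, `<stem>_v.tif` (32-bit float, affine-normalized
#' with offsets/scales in `<stem>.json`) and `<stem>_mask.tif`.
#'
#' @param g a [gradient_field()].
#' @param stem output path stem.
#' @export
write_gradient_tiffs <- function(g, stem) {
  stopifnot(inherits(g, "gradient_field"))
  nh <- norm01(g$grad_h, g$mask)
  nv <- norm01(g$grad_v, g$mask)
  tiff::writeTIFF(nh$page, paste0(stem, "_h.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(nv$page, paste0(stem, "_v.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(g$mask * 1, paste0(stem, "_mask.tif"), bits.per.sample = 8L)
  jsonlite::write_json(list(units = g$units,
                            h = list(offset = nh$offset, scale = nh$scale),
                            v = list(offset = nv$offset, scale = nv$scale)),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Write Zernike coefficients as JSON or CSV
#'
#' JSON records one object per term (`j`, `n`, `m`, `value_um`) plus the
#' pupil geometry; CSV holds the same table.
#'
#' @param coeffs a `"zernike_coeffs"` vector.
#' @param path output path ending in `.json` or `.csv`.
#' @export
write_zernike <- function(coeffs, path) {
  nm <- osa_index(seq_along(coeffs) - 1L)
  tab <- data.frame(j = nm$j, n = nm$n, m = nm$m, value_um = as.numeric(coeffs))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(pupil_radius_m = attr(coeffs, "pupil_radius"),
                              terms = tab),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a sphero-cylindrical refraction report as JSON
#'
#' @param sc a `"sphero_cylinder"` list.
#' @param path output `.json` path.
#' @export
write_refraction <- function(sc, path) {
  jsonlite::write_json(unclass(sc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
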
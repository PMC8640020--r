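# Fourier-domain least-squares solver for z with centered differences:
# minimizes ||Dx z - p||^2 + ||Dy z - q||^2 on the mirror-extended grid,
# which imposes natural (reflective) boundary behaviour. The centered
# difference operator has spectral response i sin(w), so the least-squares
# solution in frequency space is
#   z_hat = -i (sin(wx) p_hat + sin(wy) q_hat) / (sin^2 wx + sin^2 wy).
fc_solve <- function(p, q) {
  nr <- nrow(p); nc <- ncol(p)
  # mirror extension: p (d/dx) is odd in x, even in y; q (d/dy) the reverse
  P <- cbind(p, -p[, nc:1, drop = FALSE])
  P <- rbind(P, P[nr:1, , drop = FALSE])
  Q <- cbind(q, q[, nc:1, drop = FALSE])
  Q <- rbind(Q, -Q[nr:1, , drop = FALSE])
  NR <- 2L * nr; NC <- 2L * nc
  wy <- 2 * pi * (0:(NR - 1)) / NR
  wx <- 2 * pi * (0:(NC - 1)) / NC
  sy <- matrix(sin(wy), NR, NC)
  sx <- matrix(sin(wx), NR, NC, byrow = TRUE)
  denom <- sx^2 + sy^2
  Ph <- stats::fft(P); Qh <- stats::fft(Q)
  zh <- -1i * (sx * Ph + sy * Qh) / denom
  zh[denom < 1e-14] <- 0
  z <- Re(stats::fft(zh, inverse = TRUE)) / (NR * NC)
  z[seq_len(nr), seq_len(nc), drop = FALSE]
}

# centered differences of the even mirror extension, evaluated on the 2N
# torus and cropped: exactly consistent with fc_solve's spectral operator,
# so solve-then-differentiate is a non-expansive projection (keeps the
# mask-extension iteration stable)
grad_mirror <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  Z <- cbind(z, z[, nc:1, drop = FALSE])
  Z <- rbind(Z, Z[nr:1, , drop = FALSE])
  NR <- 2L * nr; NC <- 2L * nc
  right <- Z[, c(2:NC, 1), drop = FALSE]; left <- Z[, c(NC, 1:(NC - 1)), drop = FALSE]
  down <- Z[c(2:NR, 1), , drop = FALSE]; up <- Z[c(NR, 1:(NR - 1)), , drop = FALSE]
  list(gx = ((right - left) / 2)[seq_len(nr), seq_len(nc)],
       gy = ((down - up) / 2)[seq_len(nr), seq_len(nc)])
}

# centered differences matching fc_solve's operator (one-sided at borders)
grad_centered <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  gx <- z; gy <- z
  gx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / 2
  gx[, 1] <- z[, 2] - z[, 1]; gx[, nc] <- z[, nc] - z[, nc - 1]
  gy[2:(nr - 1), ] <- (z[3:nr, ] - z[1:(nr - 2), ]) / 2
  gy[1, ] <- z[2, ] - z[1, ]; gy[nr, ] <- z[nr, ] - z[nr - 1, ]
  list(gx = gx, gy = gy)
}

#' Integrate a gradient field into a phase map
#'
#' Least-squares integration by a Fourier-domain solve on the bounding box
#' with iterative mask-constraint extension: gradients outside the pupil mask
#' are unknown and are replaced at each iteration by the current estimate's
#' own gradients, so the solution inside the mask is driven by the measured
#' data only. Iteration stops after `max_iter` rounds or when the estimate
#' changes by less than `tol` (relative RMS) between rounds. The piston
#' (mean over the mask) is removed; tip/tilt are retained.
#'
#' @param g a [gradient_field()] in metric units (metres of optical path per
#'   pixel step, from [scale_gradients()]).
#' @param mask optional pupil mask (logical matrix, subset of `g$mask`);
#'   defaults to `g$mask`.
#' @param pixel_pitch pixel pitch in metres for the output map.
#' @param max_iter maximum number of extension iterations.
#' @param tol relative-change stopping tolerance.
#' @return a [phase_map()] in micrometres with attribute
#'   `grad_residual_rms`: the RMS mismatch between the reconstructed and the
#'   measured gradients inside the mask, relative to the measured gradient
#'   RMS.
#' @export
integrate_gradients <- function(g, mask = NULL, pixel_pitch = NULL,
                                max_iter = 50L, tol = 1e-6) {
  stopifnot(inherits(g, "gradient_field"))
  if (g$units != "metres")
    stop("gradient field must be in metric units; see scale_gradients()")
  if (is.null(mask)) mask <- g$mask
  if (any(mask & !g$mask)) stop("mask must be a subset of the field's validity mask")
  if (sum(mask) < 16L) stop("mask too small to integrate (< 16 px)")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  if (max(lab) > 1L) stop("mask is disconnected")
  if (is.null(pixel_pitch))
    pixel_pitch <- 1e-5
  p <- g$grad_h; q <- g$grad_v
  p[!mask] <- 0; q[!mask] <- 0
  gmeas <- sqrt(mean(c(g$grad_h[mask]^2, g$grad_v[mask]^2)))
  inres <- function(z) {
    gr <- grad_mirror(z)
    sqrt(mean(c((gr$gx[mask] - g$grad_h[mask])^2,
                (gr$gy[mask] - g$grad_v[mask])^2)))
  }
  z <- fc_solve(p, q)
  best <- z; best_res <- inres(z); z_prev <- z
  for (it in seq_len(max_iter)) {
    gr <- grad_mirror(z)
    p_ext <- gr$gx; q_ext <- gr$gy
    p_ext[mask] <- g$grad_h[mask]
    q_ext[mask] <- g$grad_v[mask]
    z <- fc_solve(p_ext, q_ext)
    res <- inres(z)
    if (res < best_res) { best <- z; best_res <- res }
    delta <- sqrt(mean((z[mask] - z_prev[mask])^2))
    scale <- sqrt(mean(z[mask]^2)) + 1e-30
    if (delta / scale < tol) break
    z_prev <- z
  }
  z <- best
  resid <- best_res
  vals <- matrix(NA_real_, nrow(z), ncol(z))
  vals[mask] <- (z[mask] - mean(z[mask])) * 1e6   # metres -> um, piston off
  out <- phase_map(vals, mask, pixel_pitch)
  attr(out, "grad_residual_rms") <- resid / max(gmeas, 1e-30)
  out
}

#' RMS of the discrete curl of a gradient field
#'
#' A measured gradient field is integrable only if its curl vanishes; this
#' diagnostic reports the RMS of `d(grad_h)/dy - d(grad_v)/dx` (centered
#' differences) over the interior of the mask (eroded by one pixel so that
#' both differences are defined).
#'
#' @param g a [gradient_field()].
#' @param mask optional mask (defaults to the field's).
#' @return scalar RMS curl in grid units.
#' @export
curl_residual <- function(g, mask = NULL) {
  stopifnot(inherits(g, "gradient_field"))
  if (is.null(mask)) mask <- g$mask
  nr <- nrow(mask); nc <- ncol(mask)
  interior <- mask
  interior[c(1, nr), ] <- FALSE; interior[, c(1, nc)] <- FALSE
  sh <- function(m, dy, dx) {
    out <- matrix(FALSE, nr, nc)
    ys <- (1 + max(0, dy)):(nr + min(0, dy)); xs <- (1 + max(0, dx)):(nc + min(0, dx))
    out[ys - dy, xs - dx] <- m[ys, xs]
    out
  }
  interior <- interior & sh(mask, 1, 0) & sh(mask, -1, 0) &
    sh(mask, 0, 1) & sh(mask, 0, -1)
  if (!any(interior)) stop("mask has no interior")
  gh <- g$grad_h; gv <- g$grad_v
  gh[!g$mask] <- 0; gv[!g$mask] <- 0
  dgh_dy <- (rbind(gh[-1, ], gh[nr, ]) - rbind(gh[1, ], gh[-nr, ])) / 2
  dgv_dx <- (cbind(gv[, -1], gv[, nc]) - cbind(gv[, 1], gv[, -nc])) / 2
  curl <- dgh_dy - dgv_dx
  sqrt(mean(curl[interior]^2))
}
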
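#' Angle grid for directional profile matching
#'
#' `k` discrete angles uniformly covering `(-pi/2, pi/2]` with spacing
#' `pi / k`.
#'
#' @param k positive integer number of angles (>= 2).
#' @return numeric vector of angles in radians, strictly increasing.
#' @export
angle_grid <- function(k) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  -pi / 2 + (seq_len(k)) * pi / k
}

#' Directional cumulative line profiles of an image
#'
#' For one angle, builds the family of parallel lines covering the grid (one
#' line per unit intercept along the minor axis, parameterized along the
#' major axis: `|tan(angle)| <= 1` steps in x, steeper lines step in y) and
#' returns the running cumulative sum of image values sampled bilinearly at
#' unit steps along each line. Samples falling outside the grid contribute
#' zero flux, so every profile is non-decreasing.
#'
#' @param image an [intensity_image()] or non-negative matrix.
#' @param angle angle in radians, in `(-pi/2, pi/2]`.
#' @return list of profiles; each has `intercept`, `major` (`"x"` or `"y"`),
#'   `positions` (0-based major-axis sample coordinates) and `samples`
#'   (cumulative flux).
#' @export
line_profiles <- function(image, angle) {
  img <- unclass(as.matrix(image))
  if (nrow(img) < 2L || ncol(img) < 2L || any(img < 0) || any(!is.finite(img)))
    stop("image must be a finite non-negative matrix, at least 2 x 2")
  if (angle <= -pi / 2 || angle > pi / 2) stop("angle must lie in (-pi/2, pi/2]")
  ta <- tan(angle)
  xmajor <- abs(ta) <= 1 + 1e-12
  slope <- if (xmajor) ta else 1 / ta
  nmaj <- if (xmajor) ncol(img) else nrow(img)
  nmin <- if (xmajor) nrow(img) else ncol(img)
  off_end <- slope * (nmaj - 1)
  b_range <- seq.int(floor(-max(0, off_end)), ceiling((nmin - 1) - min(0, off_end)))
  i <- 0:(nmaj - 1)
  lapply(b_range, function(b) {
    pos <- b + slope * i
    inside <- pos >= 0 & pos <= nmin - 1
    p0 <- pmin(floor(pos), nmin - 2)
    w <- pos - p0
    v <- numeric(nmaj)
    if (any(inside)) {
      ii <- i[inside]; pp <- p0[inside]; ww <- w[inside]
      v[inside] <- if (xmajor)
        img[cbind(pp + 1L, ii + 1L)] * (1 - ww) + img[cbind(pp + 2L, ii + 1L)] * ww
      else
        img[cbind(ii + 1L, pp + 1L)] * (1 - ww) + img[cbind(ii + 1L, pp + 2L)] * ww
    }
    list(intercept = b, major = if (xmajor) "x" else "y",
         positions = i, samples = cumsum(v))
  })
}

#' Displacement between two cumulative profiles
#'
#' One-dimensional transport matching: both profiles are normalized to a
#' common total flux (the second is scaled to the first), then for every
#' sample of `f` carrying local flux above a threshold the matching position
#' on `g` is found by monotone linear inversion and the displacement
#' `g^{-1}(f(x)) - x` is reported. Samples whose local flux is below
#' `eps_rel` times the total are returned as `NA` (low confidence); where the
#' inverse falls on a flat (zero-flux) interval of `g` its midpoint is used.
#'
#' @param f,g non-decreasing numeric vectors (cumulative flux at unit steps).
#' @param eps_rel relative flux threshold for a sample to be considered valid.
#' @return numeric vector of displacements in major-axis pixels (`NA` where
#'   invalid). A profile with zero total flux yields all-`NA`.
#' @export
profile_displacement <- function(f, g, eps_rel = 1e-6) {
  if (length(f) != length(g)) stop("profiles must share their parameterization")
  if (any(diff(f) < -1e-12 * max(abs(f), 1)) || any(diff(g) < -1e-12 * max(abs(g), 1)))
    stop("profiles must be non-decreasing")
  n <- length(f)
  fs <- diff(c(0, f)); gs <- diff(c(0, g))
  Tf <- f[n]; Tg <- g[n]
  out <- rep(NA_real_, n)
  if (Tf <= 0 || Tg <= 0) return(out)
  G <- cumsum(gs) * (Tf / Tg)
  eps <- eps_rel * Tf
  for (i in seq_len(n)) {
    if (fs[i] <= eps) next
    L <- f[i] - fs[i] / 2
    j <- which(G >= L)[1]
    if (is.na(j)) j <- n
    Gj <- G[j]; Gjm1 <- if (j > 1) G[j - 1] else 0
    denom <- Gj - Gjm1
    u <- if (denom > 0) (j - 1.5) + min(max((L - Gjm1) / denom, 0), 1) else (j - 1)
    out[i] <- u - (i - 1)
  }
  out
}

#' Recover the phase-gradient field from a pair of intensity images
#'
#' Runs the directional cumulative-profile matching over a uniform angle
#' grid. Along each line the matched displacement measures the transport of
#' flux along that line, i.e. the projection of the local lateral
#' displacement field onto the line direction. Per pixel, the projection
#' samples from all angles (cos- and sin-weighted, splat bilinearly) are
#' combined by weighted least squares into the horizontal and vertical
#' components. The result is the lateral displacement of plane-2 flux
#' relative to plane-1 flux in pixels, i.e. the wavefront gradient times
#' `2 delta_z / s` (see [scale_gradients()]).
#'
#' @param i1,i2 intensity images (plane at `-delta_z` and `+delta_z`), same
#'   dimensions, bias-subtracted / flat-fielded by the caller.
#' @param k number of discrete angles (>= 2), or pass `angles` directly.
#' @param angles optional explicit angle vector in `(-pi/2, pi/2]`.
#' @param eps_rel relative per-sample flux threshold (fraction of a line's
#'   total flux) below which displacement samples are discarded.
#' @param min_coverage minimum accumulated angular weight (relative to the
#'   median over covered pixels) for a pixel to be considered valid.
#' @return a [gradient_field()] in pixel units.
#' @export
recover_gradients <- function(i1, i2, k = 120L, angles = NULL,
                              eps_rel = 1e-6, min_coverage = 0.05) {
  m1 <- unclass(as.matrix(i1)); m2 <- unclass(as.matrix(i2))
  if (!all(dim(m1) == dim(m2))) stop("intensity images must share dimensions")
  if (any(m1 < 0) || any(m2 < 0)) stop("intensity images must be non-negative")
  if (is.null(angles)) angles <- angle_grid(k)
  if (length(angles) < 2L) stop("k must be >= 2")
  acc <- .match_kernel(m1, m2, as.numeric(angles), eps_rel, 0)
  det <- acc$Scc * acc$Sss - acc$Scs^2
  cov <- acc$Scc + acc$Sss
  thr <- min_coverage * stats::median(cov[cov > 0])
  # well-determined pixels: enough angular weight and a genuinely
  # two-directional normal matrix
  mask <- cov > thr & det > 0.05 * (cov / 2)^2
  gh <- (acc$Bc * acc$Sss - acc$Bs * acc$Scs) / det
  gv <- (acc$Scc * acc$Bs - acc$Scs * acc$Bc) / det
  gh[!mask] <- NA_real_; gv[!mask] <- NA_real_
  gradient_field(gh, gv, mask, units = "pixels")
}

#' Convert a pixel-unit gradient field to physical units
#'
#' Multiplies both components by `s^2 / (2 delta_z)`, turning the
#' displacement in pixels into optical path difference in metres per pixel
#' step.
#'
#' @param g a [gradient_field()] in pixel units.
#' @param params a [scale_params()] (pixel size `s` and half-separation
#'   `delta_z`, both metres).
#' @return the scaled [gradient_field()] with `units = "metres"`.
#' @export
scale_gradients <- function(g, params) {
  stopifnot(inherits(g, "gradient_field"))
  if (!inherits(params, "scale_params"))
    params <- do.call(scale_params, as.list(params))
  if (g$units != "pixels") stop("gradient field is already in metric units")
  fac <- params$s^2 / (2 * params$delta_z)
  gradient_field(g$grad_h * fac, g$grad_v * fac, g$mask, units = "metres")
}

# ---- internal helpers shared by the pipeline --------------------------------

# pull-back bilinear warp: out(y, x) = img(y + ey, x + ex); zero outside
bilinear_warp <- function(img, ex, ey) {
  nr <- nrow(img); nc <- ncol(img)
  x <- matrix(rep(0:(nc - 1), each = nr), nr, nc) + ex
  y <- matrix(rep(0:(nr - 1), nc), nr, nc) + ey
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= 0 & x0 <= nc - 2 & y0 >= 0 & y0 <= nr - 2
  # clamp indices for safe lookup, zero the outside afterwards
  x0c <- pmin(pmax(x0, 0), nc - 2); y0c <- pmin(pmax(y0, 0), nr - 2)
  i00 <- cbind(as.vector(y0c) + 1L, as.vector(x0c) + 1L)
  v <- img[i00] * (1 - fy) * (1 - fx) +
    img[i00 + rep(c(1L, 0L), each = nr * nc)] * fy * (1 - fx) +
    img[i00 + rep(c(0L, 1L), each = nr * nc)] * (1 - fy) * fx +
    img[i00 + rep(c(1L, 1L), each = nr * nc)] * fy * fx
  v <- matrix(v, nr, nc)
  v[!inside] <- 0
  v
}

# separable Gaussian blur with mask-aware normalization:
# blur(values * mask) / blur(mask); outside pixels get the normalized
# extension (useful for extrapolating smooth fields past a pupil rim).
normalized_blur <- function(values, mask, sigma) {
  v <- values; v[!mask] <- 0
  kr <- max(1L, ceiling(4 * sigma))
  kx <- stats::dnorm(-kr:kr, sd = sigma); kx <- kx / sum(kx)
  conv1 <- function(m, along_rows) {
    # pad by zeros; stats::filter handles NA-free numeric
    if (along_rows) {
      apply(m, 2, function(col) {
        padded <- c(rep(0, kr), col, rep(0, kr))
        stats::filter(padded, kx, sides = 2)[(kr + 1):(kr + length(col))]
      })
    } else {
      t(apply(m, 1, function(row) {
        padded <- c(rep(0, kr), row, rep(0, kr))
        stats::filter(padded, kx, sides = 2)[(kr + 1):(kr + length(row))]
      }))
    }
  }
  num <- conv1(conv1(v, TRUE), FALSE)
  den <- conv1(conv1(mask * 1, TRUE), FALSE)
  out <- num / pmax(den, 1e-12)
  out[den < 1e-12] <- 0
  out
}
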
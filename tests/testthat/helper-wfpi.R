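# small simulation geometry used across the unit tests: 128 px grid,
# 4 mm pupil (about 100 px across), bench plane separation
tiny_config <- function(grid = 128L, pupil = 4e-3, seed = 1L, ...) {
  sim_config(grid = grid, pupil_diameter = pupil, seed = seed, ...)
}

# brute-force Euclidean distance of every TRUE pixel to the mask complement
brute_distance_max <- function(mask) {
  inside <- which(mask, arr.ind = TRUE)
  outside <- which(!mask, arr.ind = TRUE)
  best <- -Inf; at <- NULL
  for (i in seq_len(nrow(inside))) {
    d2 <- (outside[, 1] - inside[i, 1])^2 + (outside[, 2] - inside[i, 2])^2
    d <- sqrt(min(d2))
    if (d > best) { best <- d; at <- inside[i, ] }
  }
  list(center = c(at[2] - 1L, at[1] - 1L), radius = best)
}

# counter-clockwise 90-degree rotation of a square matrix
rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y), tol * max(abs(y), 1e-12))
}
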
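# Test phantoms.  `small_phantom()` is numerically equivalent to the default
# 256x192 @ 1.4 mm scene at half resolution (2.8 mm spacing, same field of
# view); `tiny_phantom()` additionally shrinks the anatomy for cheap unit
# tests that only need a moving scene, not the published geometry.

small_phantom <- function(seed = 1L, motion_mode = "free_breathing",
                          n_frames = 45L, heart_rate = 75, ...) {
  generate_series(phantom_config(
    n_frames = n_frames, matrix = c(96L, 128L), spacing = c(2.8, 2.8),
    seed = seed, motion_mode = motion_mode, heart_rate = heart_rate, ...))
}

tiny_geometry <- list(lv_offset = c(6, 3), r_endo = 8, r_epi = 16, r_circ = 18,
                      rv_offset = 30, rv_semi = c(12, 9),
                      liver_offset = c(-6, 22), liver_semi = c(18, 10))

tiny_phantom <- function(seed = 1L, motion_mode = "free_breathing",
                         n_frames = 20L, ...) {
  generate_series(phantom_config(
    n_frames = n_frames, matrix = c(72L, 96L), spacing = c(2.8, 2.8),
    seed = seed, motion_mode = motion_mode, geometry = tiny_geometry, ...))
}

# brute-force even-odd point-in-polygon (crossing number), independent of the
# compiled rasterizer
pip_oracle <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- !inside
    j <- i
  }
  inside
}

rasterize_oracle <- function(contour, shape) {
  m <- matrix(0L, shape[1], shape[2])
  for (r in seq_len(shape[1]))
    for (c in seq_len(shape[2]))
      if (pip_oracle(c - 1, r - 1, contour[, 1], contour[, 2])) m[r, c] <- 1L
  m
}

# random star-shaped (simple) polygon around a centre
random_polygon <- function(n = 8L, cx = 10, cy = 10, rmax = 8) {
  th <- sort(runif(n, 0, 2 * pi))
  rr <- runif(n, 1, rmax)
  cbind(cx + rr * cos(th), cy + rr * sin(th))
}

random_segmentation_set <- function(n_frames = 3L) {
  frames <- lapply(seq_len(n_frames), function(i) {
    ctr <- c(runif(1, 20, 30), runif(1, 20, 30))
    th0 <- runif(1, 0, 2 * pi)
    rays <- t(vapply(th0 + c(0, 2, 4) * pi / 3, function(th)
      ctr + 12 * c(cos(th), sin(th)), numeric(2)))
    ang <- seq(0, 2 * pi, length.out = 25)[-25]
    segmentation_frame(sprintf("frame%04d", i), ctr, rays,
                       endo = cbind(ctr[1] + 5 * cos(ang), ctr[2] + 5 * sin(ang)),
                       epi = cbind(ctr[1] + 10 * cos(ang), ctr[2] + 10 * sin(ang)))
  })
  segmentation_set(frames, rv_peak = sample(n_frames, 1),
                   lv_peak = sample(n_frames, 1),
                   slice_level = sample(0:2, 1),
                   rv_insertion = sample(c("anterior", "posterior"), 1))
}

# 1-pixel 4-neighbourhood erosion: strips the soft-edge boundary pixels of a
# rasterized mask before intensity comparisons
erode1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, ], 0); dn <- rbind(0, m[-nr, ])
  lf <- cbind(m[, -1], 0); rt <- cbind(0, m[, -nc])
  out <- (m == 1) & (up == 1) & (dn == 1) & (lf == 1) & (rt == 1)
  matrix(as.integer(out), nr, nc)
}
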
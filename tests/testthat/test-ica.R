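mk_series <- function(arr, dt = 0.8, spacing = c(2.8, 2.8)) {
  perfusion_series(arr, times = (seq_len(dim(arr)[3]) - 1) * dt,
                   spacing = spacing, n_pd = 0L)
}

# decomposition object with prescribed mixing curves (for labelling tests)
mk_decomposition <- function(mixing, times, shape = c(8, 8), spacing = c(2.8, 2.8)) {
  k <- ncol(mixing)
  comps <- lapply(seq_len(k), function(i) {
    m <- matrix(0, shape[1], shape[2]); m[i %% shape[1] + 1, ] <- 1; m
  })
  structure(list(components = comps, mixing = mixing,
                 mean_image = matrix(0, shape[1], shape[2]),
                 times = times, spacing = spacing, shape = shape,
                 mode_used = "deflation", converged = TRUE),
            class = "ica_decomposition")
}

test_that("ICA recovers a known 3-source mixture", {
  set.seed(31)
  shape <- c(24, 30)
  pat <- list(matrix(0, 24, 30), matrix(0, 24, 30), matrix(0, 24, 30))
  pat[[1]][4:10, 5:12] <- 1
  pat[[2]][14:20, 8:16] <- 1
  pat[[3]][6:18, 20:27] <- 1
  tt <- (0:39) * 0.8
  curves <- cbind(enhancement_curve(list(onset = 4, amplitude = 10, alpha = 2.5,
                                         beta = 1.5, baseline = 0), tt),
                  enhancement_curve(list(onset = 10, amplitude = 8, alpha = 3,
                                         beta = 3, baseline = 0), tt),
                  5 * sin(2 * pi * tt / 4.8))
  S <- t(vapply(pat, as.vector, numeric(24 * 30)))
  X <- curves %*% S + matrix(rnorm(40 * 720, sd = 0.05), 40)
  arr <- array(t(X), dim = c(24, 30, 40))
  dec <- ica_decompose(mk_series(arr), n_components = 3, seed = 11)
  # every generating curve is recovered by some mixing curve up to sign
  cors <- abs(cor(dec$mixing, curves))
  best <- apply(cors, 2, max)
  expect_true(all(best > 0.95))
  expect_length(unique(apply(cors, 2, which.max)), 3L)   # distinct components
})

test_that("full-rank decomposition reconstructs noise-free input", {
  set.seed(12)
  arr <- array(0, dim = c(10, 12, 8))
  base <- matrix(runif(120, 50, 100), 10, 12)
  for (t in 1:8) arr[, , t] <- base + t * matrix(runif(120), 10, 12)
  s <- mk_series(arr)
  dec <- ica_decompose(s, n_components = 7, seed = 3)
  rec <- ica_reconstruct(dec)
  expect_lt(sqrt(sum((rec - arr)^2)) / sqrt(sum(arr^2)), 1e-6)
})

test_that("decomposition is reproducible from its seed and refuses PD frames", {
  ph <- tiny_phantom(seed = 8, n_frames = 14)
  s <- strip_proton_density(ph$series)
  d1 <- ica_decompose(s, 4, seed = 5)
  d2 <- ica_decompose(s, 4, seed = 5)
  expect_identical(d1$mixing, d2$mixing)
  expect_identical(d1$components, d2$components)
  expect_error(ica_decompose(ph$series, 4), "strip")
  expect_error(ica_decompose(s, 2), ">= 3")
  expect_error(ica_decompose(s, 30), "fewer frames")
})

test_that("mean_frequency matches the zero-crossing oracle", {
  tt <- 0:59
  x <- sin(2 * pi * 0.25 * tt + 0.3)
  sgn <- sign(x - mean(x)); sgn <- sgn[sgn != 0]
  crossings <- sum(diff(sgn) != 0)
  oracle <- crossings / (2 * (max(tt) - min(tt))) * 60
  expect_equal(mean_frequency(x, tt), oracle)
  expect_lt(abs(oracle - 15) / 15, 0.05)              # 0.25 Hz = 15 per min
  expect_equal(mean_frequency(rep(2, 10), 1:10), 0)   # constant -> 0
  expect_equal(mean_frequency(rep(c(1, -1), 30), 0:59), 30)  # Nyquist
  expect_error(mean_frequency(1:3, 1:3), "4 samples")
})

test_that("frequency fallback applies the strict 14 breaths/min threshold", {
  tt <- 0:60
  sin_at <- function(per_min) sin(2 * pi * per_min / 60 * tt + 0.2)
  ramp <- seq(0, 1, length.out = 61)
  m1 <- cbind(sin_at(15), sin_at(8), sin_at(5))
  d1 <- mk_decomposition(m1, tt)
  f1 <- vapply(1:3, function(i) mean_frequency(m1[, i], tt), numeric(1))
  expect_equal(f1[1], 15); expect_gt(f1[1], 14)
  lab <- fallback_motion_label(d1)
  expect_equal(lab$motion_index, 1L)
  expect_equal(lab$method_used, "frequency_fallback")
  # mean frequency of exactly 14 is not above the threshold
  m2 <- cbind(sin_at(14), sin_at(8), ramp)
  expect_equal(mean_frequency(m2[, 1], tt), 14)
  lab2 <- fallback_motion_label(mk_decomposition(m2, tt))
  expect_true(is.na(lab2$motion_index))
  # a single oscillating curve at 20/min among smooth ramps
  m3 <- cbind(ramp, sin_at(20), ramp^2)
  lab3 <- fallback_motion_label(mk_decomposition(m3, tt))
  expect_equal(lab3$motion_index, 2L)
})

test_that("wavelet labelling finds motion on a rest phantom and orders RV/LV", {
  ph <- small_phantom(seed = 5, n_frames = 45)
  s <- strip_proton_density(ph$series)
  dec <- ica_decompose(s, 5, seed = 2)
  lab <- classify_wavelet(dec)
  expect_equal(lab$method_used, "wavelet")
  expect_false(is.na(lab$motion_index))
  # the labelled motion curve oscillates near the breathing rate, the
  # enhancement curves do not
  f <- mean_frequency(dec$mixing[, lab$motion_index], dec$times)
  expect_gt(f, 0.6 * ph$config$breathing_rate)
  # RV/LV labels follow the bolus order
  expect_false(is.na(lab$rv_index))
  expect_false(is.na(lab$lv_index))
  cor_rv <- cor(dec$mixing[, lab$rv_index], ph$truth_curves$rv[-(1:2)])
  cor_lv <- cor(dec$mixing[, lab$lv_index], ph$truth_curves$lv[-(1:2)])
  expect_gt(cor_rv, 0.9)
  expect_gt(cor_lv, 0.9)
  expect_lt(which.max(dec$mixing[, lab$rv_index]),
            which.max(dec$mixing[, lab$lv_index]))
})

test_that("smooth ramps leave the motion component unresolved", {
  tt <- (0:40) * 0.8
  m <- cbind(seq(0, 1, length.out = 41), seq(0, 1, length.out = 41)^2,
             sqrt(seq(0, 1, length.out = 41)))
  lab <- classify_wavelet(mk_decomposition(m, tt))
  expect_true(is.na(lab$motion_index))
  expect_equal(lab$method_used, "none")
})

test_that("label indices follow component permutations", {
  ph <- tiny_phantom(seed = 10, n_frames = 24)
  s <- strip_proton_density(ph$series)
  dec <- ica_decompose(s, 4, seed = 7)
  lab <- classify_wavelet(dec)
  perm <- c(3, 1, 4, 2)
  dec2 <- dec
  dec2$components <- dec$components[perm]
  dec2$mixing <- dec$mixing[, perm]
  lab2 <- classify_wavelet(dec2)
  remap <- function(i) if (is.na(i)) NA_integer_ else which(perm == i)
  expect_equal(lab2$motion_index, remap(lab$motion_index))
  expect_equal(lab2$rv_index, remap(lab$rv_index))
  expect_equal(lab2$lv_index, remap(lab$lv_index))
})

test_that("motion component is identified on at least 9 of 10 phantom seeds", {
  hits <- 0L
  for (seed in 1:10) {
    ph <- small_phantom(seed = seed, n_frames = 45)
    s <- strip_proton_density(ph$series)
    dec <- ica_decompose(s, 5, seed = 1000 + seed)
    lab <- perfmoco:::resolve_motion_index(dec)
    if (!is.na(lab$motion_index)) {
      f <- mean_frequency(dec$mixing[, lab$motion_index], dec$times)
      if (f > 0.6 * ph$config$breathing_rate) hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("segment_rv_lv applies the 30 mm sanity check", {
  blob_dec <- function(dist_mm, spacing = 2) {
    shape <- c(40, 40)
    mk <- function(cx) {
      m <- matrix(0, shape[1], shape[2])
      xs <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1])
      ys <- matrix(rep(seq_len(shape[1]) - 1, shape[2]), shape[1])
      m[(xs - cx)^2 + (ys - 20)^2 < 16] <- 1
      m + matrix(abs(rnorm(prod(shape), sd = .01)), shape[1])
    }
    d <- mk_decomposition(cbind(c(rep(0, 5), rep(1, 5)), c(rep(1, 5), rep(0, 5)),
                                rep(1, 10)),
                          times = 0:9, shape = shape, spacing = rep(spacing, 2))
    d$components[[1]] <- mk(10)
    d$components[[2]] <- mk(10 + dist_mm / spacing)
    d
  }
  lab <- component_labels(3L, 1L, 2L, "wavelet")
  roi25 <- segment_rv_lv(blob_dec(25), lab)
  expect_true(roi25$rejected)
  expect_null(roi25$roi_box)
  expect_lt(roi25$center_distance_mm, 30)
  roi35 <- segment_rv_lv(blob_dec(35), lab)
  expect_false(roi35$rejected)
  expect_gt(roi35$center_distance_mm, 30)
  box <- roi35$roi_box
  both <- which(roi35$rv_mask == 1L | roi35$lv_mask == 1L, arr.ind = TRUE)
  expect_true(all(both[, 1] >= box[1] & both[, 1] <= box[2] &
                    both[, 2] >= box[3] & both[, 2] <= box[4]))
  # identical IC images: distance 0 -> rejected
  d0 <- blob_dec(35)
  d0$components[[2]] <- d0$components[[1]]
  expect_true(segment_rv_lv(d0, lab)$rejected)
  expect_error(segment_rv_lv(d0, component_labels(1L, NA, NA, "wavelet")),
               "resolved")
})

test_that("synthetic references drop only the motion component", {
  ph <- small_phantom(seed = 5, n_frames = 30)
  s <- strip_proton_density(ph$series)
  dec <- ica_decompose(s, 5, seed = 2)
  lab <- perfmoco:::resolve_motion_index(dec)
  # dropping nothing reproduces the reconstruction
  expect_equal(ica_reconstruct(dec, drop = integer(0)), ica_reconstruct(dec))
  refs <- synthetic_references(dec, lab)
  expect_equal(dim(refs$data), dim(s$data))
  # temporal high-frequency energy (per-pixel first differences) shrinks
  hf <- function(a) sum(apply(a, c(1, 2), function(v) sum(diff(v)^2)))
  expect_lt(hf(refs$data), hf(s$data))
  expect_error(synthetic_references(dec, component_labels(NA, 1L, 2L, "none")),
               "fallback")
})

test_that("motion-free series yields references close to the reconstruction", {
  ph <- small_phantom(seed = 2, motion_mode = "none", n_frames = 24)
  s <- strip_proton_density(ph$series)
  dec <- ica_decompose(s, 5, seed = 4)
  lab <- perfmoco:::resolve_motion_index(dec)
  rec <- ica_reconstruct(dec)
  if (!is.na(lab$motion_index)) {
    refs <- synthetic_references(dec, lab)
    # whatever got labelled as motion carries almost no energy
    expect_lt(mean((refs$data - rec)^2), 0.5 * ph$config$noise_sigma^2)
  } else succeed("no motion component on a motion-free series")
})

test_that("the wavelet transform is orthonormal and invertible", {
  lo <- perfmoco:::DB5_LO
  expect_equal(sum(lo), sqrt(2), tolerance = 1e-9)
  expect_equal(sum(lo^2), 1, tolerance = 1e-9)
  set.seed(23)
  for (n in c(16, 64)) {
    x <- rnorm(n)
    w <- perfmoco:::dwt_db5(x)
    expect_equal(perfmoco:::idwt_db5(w), x, tolerance = 1e-10)
    # Parseval: energy preserved
    e <- sum(unlist(w$details)^2) + sum(w$approx^2)
    expect_equal(e, sum(x^2), tolerance = 1e-10)
  }
  expect_error(perfmoco:::dwt_db5(rnorm(20)), "power-of-two")
})

test_that("decompositions export as PNG components and a mixing table", {
  ph <- tiny_phantom(seed = 12, n_frames = 12)
  dec <- ica_decompose(strip_proton_density(ph$series), 3, seed = 1)
  dir <- withr::local_tempdir()
  export_decomposition(dec, dir)
  expect_length(list.files(dir, pattern = "component0[1-3]\\.png"), 3L)
  tab <- read.csv(file.path(dir, "mixing.csv"))
  expect_equal(names(tab), c("frame", "time", "IC1", "IC2", "IC3"))
  expect_equal(tab$IC2, dec$mixing[, 2], tolerance = 1e-12)
})
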
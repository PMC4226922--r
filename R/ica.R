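#' ICA decomposition of a perfusion series
#'
#' Runs a fixed-point (FastICA-style, tanh contrast) independent component
#' analysis on the image series.  Frames are the observed mixtures and the
#' independent components are spatial feature images; the mixing matrix holds
#' one weight curve per component over the frames.  The series is
#' reconstructed as `mean_image + mixing %*% components` up to the truncated
#' PCA subspace (exactly, for `n_components = n_frames - 1` on noise-free
#' input).
#'
#' Deflation mode is attempted first; if it does not converge or does not
#' yield a usable separation (no motion component identifiable by the
#' wavelet/frequency labelling), the symmetric mode is run with at most 400
#' iterations and its result is used regardless of convergence.  Component
#' signs are normalized so each mixing curve's peak is positive.
#'
#' @param series a [perfusion_series] with the proton-density frames already
#'   stripped.
#' @param n_components number of components (>= 3, < number of frames);
#'   default 5.
#' @param mode `"auto"` (deflation, then symmetric as fallback),
#'   `"deflation"` or `"symmetric"`.
#' @param seed RNG seed for the random orthogonal initialization; the
#'   decomposition is reproducible from it.
#' @param tol fixed-point convergence tolerance.
#' @return an object of class `ica_decomposition`: `components` (list of
#'   feature images), `mixing` (frames x components), `mean_image`, `times`,
#'   `spacing`, `mode_used`, `converged`.
#' @export
ica_decompose <- function(series, n_components = 5L,
                          mode = c("auto", "deflation", "symmetric"),
                          seed = 1L, tol = 1e-4) {
  mode <- match.arg(mode)
  if (series$n_pd > 0L)
    stop("strip the proton-density frames before running ICA (strip_proton_density)")
  nf <- n_frames(series)
  k <- as.integer(n_components)
  if (k < 3L) stop("n_components must be >= 3")
  if (k >= nf) stop("fewer frames than components")
  X <- series_matrix(series)
  mean_image <- colMeans(X)
  Xc <- sweep(X, 2L, mean_image)

  run <- function(which_mode) {
    old <- get0(".Random.seed", envir = .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
    set.seed(seed)
    fastica_core(Xc, k, which_mode, tol = tol,
                 max_iter = if (which_mode == "symmetric") 400L else 200L)
  }
  build <- function(res, used) {
    A <- res$A; S <- res$S
    for (i in seq_len(k)) {                 # mixing-curve peak positive
      if (max(A[, i]) < -min(A[, i])) {
        A[, i] <- -A[, i]; S[i, ] <- -S[i, ]
      }
    }
    d <- dim(series$data)
    comps <- lapply(seq_len(k), function(i) matrix(S[i, ], d[1], d[2]))
    structure(list(components = comps, mixing = A,
                   mean_image = matrix(mean_image, d[1], d[2]),
                   times = series$times, spacing = series$spacing,
                   shape = d[1:2], mode_used = used,
                   converged = res$converged),
              class = "ica_decomposition")
  }

  if (mode == "deflation") return(build(run("deflation"), "deflation"))
  if (mode == "symmetric") return(build(run("symmetric"), "symmetric"))
  defl <- build(run("deflation"), "deflation")
  usable <- defl$converged &&
    !is.na(resolve_motion_index(defl)$motion_index)
  if (usable) return(defl)
  build(run("symmetric"), "symmetric")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components over %d frames (%s mode%s)\n",
              length(x$components), nrow(x$mixing), x$mode_used,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

# fixed-point ICA on PCA-whitened data; X is frames x pixels, row-centred by
# the caller in the image-mean sense
fastica_core <- function(Xc, k, mode, tol = 1e-4, max_iter = 200L) {
  p <- ncol(Xc)
  C <- Xc %*% t(Xc) / p
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(k)], .Machine$double.eps)
  K <- diag(1 / sqrt(ev), k) %*% t(eg$vectors[, seq_len(k), drop = FALSE])
  Z <- K %*% Xc                                   # k x p, unit covariance
  converged <- TRUE
  if (mode == "deflation") {
    W <- matrix(0, k, k)
    for (i in seq_len(k)) {
      w <- rnorm(k); w <- w / sqrt(sum(w^2))
      ok <- FALSE
      for (it in seq_len(max_iter)) {
        wz <- drop(w %*% Z)
        g <- tanh(wz)
        w1 <- Z %*% g / p - mean(1 - g^2) * w
        if (i > 1) {
          proj <- W[seq_len(i - 1), , drop = FALSE]
          w1 <- w1 - t(proj) %*% (proj %*% w1)
        }
        w1 <- drop(w1) / sqrt(sum(w1^2))
        if (abs(abs(sum(w1 * w)) - 1) < tol) { w <- w1; ok <- TRUE; break }
        w <- w1
      }
      if (!ok) converged <- FALSE
      W[i, ] <- w
    }
  } else {
    W <- matrix(rnorm(k * k), k, k)
    sym_decor <- function(M) {
      s <- svd(M)
      s$u %*% t(s$v)
    }
    W <- sym_decor(W)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      U <- W %*% Z
      G <- tanh(U)
      W1 <- G %*% t(Z) / p - diag(rowMeans(1 - G^2), k) %*% W
      W1 <- sym_decor(W1)
      delta <- max(abs(abs(rowSums(W1 * W)) - 1))
      W <- W1
      if (delta < tol) { ok <- TRUE; break }
    }
    converged <- ok
  }
  S <- W %*% Z
  # least-squares mixing so mean + A S reconstructs the PCA subspace exactly
  A <- Xc %*% t(S) %*% solve(S %*% t(S))
  list(A = A, S = S, converged = converged)
}

#' Export a decomposition as component images and a mixing-curve table
#'
#' Writes each feature image as a gray PNG (intensities windowed to its own
#' range) and the mixing matrix as a CSV with one row per frame (`frame`,
#' `time`, one `IC<k>` column per component).
#'
#' @param decomposition an `ica_decomposition`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
export_decomposition <- function(decomposition, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(decomposition$components)) {
    img <- decomposition$components[[i]]
    rng <- range(img)
    den <- if (diff(rng) > 0) diff(rng) else 1
    png::writePNG((img - rng[1]) / den,
                  file.path(dir, sprintf("component%02d.png", i)))
  }
  tab <- data.frame(frame = seq_along(decomposition$times),
                    time = decomposition$times)
  for (i in seq_len(ncol(decomposition$mixing)))
    tab[[sprintf("IC%d", i)]] <- decomposition$mixing[, i]
  write.csv(tab, file.path(dir, "mixing.csv"), row.names = FALSE)
  invisible(dir)
}

#' Reconstruct (or partially reconstruct) the series from a decomposition
#'
#' @param decomposition an `ica_decomposition`.
#' @param drop integer vector of component indices to leave out (empty =
#'   full reconstruction).
#' @return numeric 3D array `[rows, cols, frames]`.
#' @export
ica_reconstruct <- function(decomposition, drop = integer(0)) {
  keep <- setdiff(seq_along(decomposition$components), drop)
  d <- c(decomposition$shape, nrow(decomposition$mixing))
  S <- t(vapply(decomposition$components, as.vector,
                numeric(prod(decomposition$shape))))
  X <- decomposition$mixing[, keep, drop = FALSE] %*% S[keep, , drop = FALSE]
  X <- sweep(X, 2L, as.vector(decomposition$mean_image), `+`)
  array(t(X), dim = d)
}

#' Mean frequency of a mixing curve
#'
#' Zero-crossing estimate: the mean-subtracted curve's sign changes are
#' counted and converted to cycles per minute,
#' `crossings / (2 * (t_last - t_first)) * 60`.  Exact zeros are skipped
#' when counting sign changes.  A constant curve has frequency 0.
#'
#' @param curve numeric vector (>= 4 samples).
#' @param times acquisition times in seconds, strictly increasing.
#' @return frequency in cycles (breaths) per minute.
#' @export
mean_frequency <- function(curve, times) {
  if (length(curve) < 4L) stop("need at least 4 samples")
  if (length(times) != length(curve) || any(diff(times) <= 0))
    stop("times must be increasing and match the curve length")
  x <- curve - mean(curve)
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0)
  crossings <- sum(diff(s) != 0)
  crossings / (2 * (times[length(times)] - times[1])) * 60
}

# wavelet energy split of one mixing curve: energy in the `fine_levels`
# finest detail levels vs everything else (mean removed first)
wavelet_energy_split <- function(curve, fine_levels = 2L) {
  x <- curve - mean(curve)
  p <- pad_pow2(x)
  w <- dwt_db5(p$x)
  e <- vapply(w$details, function(d) sum(d^2), numeric(1))
  fine <- sum(e[seq_len(min(fine_levels, length(e)))])
  low <- sum(e) - fine + sum(w$approx^2)
  list(fine = fine, low = low, w = w, n = p$n)
}

coarse_reconstruction <- function(curve, fine_levels = 2L) {
  sp <- wavelet_energy_split(curve, fine_levels)
  w <- sp$w
  for (lev in seq_len(min(fine_levels, length(w$details))))
    w$details[[lev]] <- 0 * w$details[[lev]]
  idwt_db5(w)[seq_len(sp$n)] + mean(curve)
}

#' Component labels
#'
#' @param motion_index,rv_index,lv_index component indices (`NA` =
#'   unresolved).
#' @param method_used `"wavelet"`, `"frequency_fallback"` or `"none"`.
#' @export
component_labels <- function(motion_index = NA_integer_, rv_index = NA_integer_,
                             lv_index = NA_integer_, method_used = "none") {
  res <- c(motion_index, rv_index, lv_index)
  if (anyDuplicated(res[!is.na(res)]))
    stop("resolved component labels must be distinct")
  structure(list(motion_index = as.integer(motion_index),
                 rv_index = as.integer(rv_index),
                 lv_index = as.integer(lv_index),
                 method_used = method_used),
            class = "component_labels")
}

#' Wavelet labelling of the IC mixing curves
#'
#' Each mixing curve is decomposed with the Daubechies wavelet of five
#' vanishing moments.  Breathing motion appears as fine-scale oscillation
#' (one cycle over roughly six frames at rest), so the motion component is
#' the curve with the largest energy in the two finest detail levels,
#' accepted only when that fine-scale energy exceeds the remaining
#' (low-frequency) energy by the dominance margin.  RV and LV enhancement
#' components are then taken as the two non-motion curves with the largest
#' coarse-scale reconstruction peaks, ordered by peak time (the RV peak
#' precedes the LV peak).  Unresolved labels are reported as `NA`; that is a
#' valid outcome handled by the frequency fallback.
#'
#' @param decomposition an `ica_decomposition`.
#' @param fine_levels number of finest detail levels counted as "fine"
#'   (default 2; at ~6 frames per breathing cycle the oscillation falls in
#'   the two finest levels).
#' @param dominance dominance margin: motion requires
#'   `fine > (1 + dominance) * low` (default 0.5).
#' @return a [component_labels] with `method_used = "wavelet"` when motion
#'   was resolved.
#' @export
classify_wavelet <- function(decomposition, fine_levels = 2L, dominance = 0.5) {
  A <- decomposition$mixing
  k <- ncol(A)
  splits <- lapply(seq_len(k), function(i)
    wavelet_energy_split(A[, i], fine_levels))
  fine <- vapply(splits, `[[`, numeric(1), "fine")
  low <- vapply(splits, `[[`, numeric(1), "low")
  candidates <- which(fine > (1 + dominance) * low)
  motion <- if (length(candidates) > 0)
    candidates[which.max((fine / low)[candidates])] else NA_integer_

  rvlv <- label_rv_lv(decomposition, motion, fine_levels)
  component_labels(motion, rvlv[1], rvlv[2],
                   method_used = if (is.na(motion)) "none" else "wavelet")
}

label_rv_lv <- function(decomposition, motion_index, fine_levels = 2L) {
  A <- decomposition$mixing
  cand <- setdiff(seq_len(ncol(A)), motion_index)
  if (length(cand) < 2L) return(c(NA_integer_, NA_integer_))
  coarse <- lapply(cand, function(i) coarse_reconstruction(A[, i], fine_levels))
  peaks <- vapply(coarse, max, numeric(1))
  top <- cand[order(peaks, decreasing = TRUE)[1:2]]
  tpk <- vapply(top, function(i)
    which.max(coarse_reconstruction(A[, i], fine_levels)), integer(1))
  if (tpk[1] == tpk[2]) return(c(NA_integer_, NA_integer_))
  c(top[order(tpk)][1], top[order(tpk)][2])
}

resolve_motion_index <- function(decomposition, fine_levels = 2L,
                                 dominance = 0.5, threshold_per_min = 14) {
  lab <- classify_wavelet(decomposition, fine_levels, dominance)
  if (is.na(lab$motion_index))
    lab <- fallback_motion_label(decomposition, threshold_per_min)
  lab
}

#' Frequency-based fallback labelling of the motion component
#'
#' In stress studies the heart rate rises while the breathing rate does not
#' increase proportionally, so a breathing cycle stretches over more frames
#' and the wavelet labelling can fail.  As a fallback, the component whose
#' mixing curve has the highest mean frequency is labelled motion when that
#' frequency lies strictly above the threshold (14 breaths per minute by
#' default).  A tie at the maximum frequency is reported unresolved.
#'
#' @param decomposition an `ica_decomposition`.
#' @param threshold_per_min rejection threshold in breaths per minute.
#' @return a [component_labels] with `method_used = "frequency_fallback"`
#'   when motion was resolved.
#' @export
fallback_motion_label <- function(decomposition, threshold_per_min = 14) {
  A <- decomposition$mixing
  freqs <- vapply(seq_len(ncol(A)), function(i)
    mean_frequency(A[, i], decomposition$times), numeric(1))
  best <- which(freqs == max(freqs))
  rvlv <- label_rv_lv(decomposition, if (length(best) == 1L) best else NA_integer_)
  if (length(best) != 1L || freqs[best] <= threshold_per_min)
    return(component_labels(NA_integer_, rvlv[1], rvlv[2], "none"))
  component_labels(best, rvlv[1], rvlv[2], "frequency_fallback")
}

otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(findInterval(values,
        seq(rng[1], rng[2], length.out = n_bins + 1L), all.inside = TRUE), 1L),
        n_bins), nbins = n_bins)
  w <- cumsum(h)
  centers <- seq(rng[1], rng[2], length.out = n_bins + 1L)[-1] - diff(rng) / (2 * n_bins)
  m <- cumsum(h * centers)
  total_m <- m[n_bins]; total_w <- w[n_bins]
  between <- (total_m * w - m * total_w)^2 /
    pmax(w * (total_w - w), .Machine$double.eps)
  centers[which.max(between[-n_bins])]
}

largest_component <- function(mask) {
  lab <- cpp_label_components(mask)
  if (max(lab) == 0L) return(mask * 0L)
  sizes <- tabulate(lab[lab > 0L])
  matrix(as.integer(lab == which.max(sizes)), nrow(mask), ncol(mask))
}

#' Segment the RV and LV cavities from their IC images
#'
#' Each labelled IC image is thresholded (Otsu on its positive part) and
#' reduced to its largest connected component.  The segmentation is rejected
#' when the distance between the geometric centres of the two masks is below
#' the threshold (30 mm by default: an adult heart is about 90 mm across in
#' the short-axis view, so closer centres indicate a failed segmentation), or
#' when a mask comes out empty.  On acceptance a region of interest box
#' covering both masks, dilated by `margin_px`, is returned; motion
#' compensation can then be restricted to that region.
#'
#' @param decomposition an `ica_decomposition`.
#' @param labels a [component_labels] with `rv_index` and `lv_index`
#'   resolved.
#' @param threshold_mm rejection distance between mask centres (mm).
#' @param margin_px ROI dilation margin in pixels.
#' @return `list(rv_mask, lv_mask, roi_box, rejected, center_distance_mm,
#'   reason)`; `roi_box = c(row0, row1, col0, col1)` (1-based, inclusive) is
#'   `NULL` when rejected.
#' @export
segment_rv_lv <- function(decomposition, labels, threshold_mm = 30,
                          margin_px = 10L) {
  if (is.na(labels$rv_index) || is.na(labels$lv_index))
    stop("rv_index and lv_index must be resolved")
  sp <- decomposition$spacing
  one_mask <- function(img) {
    pos <- img[img > 0]
    if (length(pos) < 2L) return(matrix(0L, nrow(img), ncol(img)))
    thr <- otsu_threshold(pos)
    largest_component(matrix(as.integer(img >= thr), nrow(img), ncol(img)))
  }
  rv <- one_mask(decomposition$components[[labels$rv_index]])
  lv <- one_mask(decomposition$components[[labels$lv_index]])
  rejected <- FALSE; reason <- NA_character_; dist_mm <- NA_real_
  if (!any(rv == 1L) || !any(lv == 1L)) {
    rejected <- TRUE; reason <- "empty mask after thresholding"
  } else {
    c_rv <- colMeans(which(rv == 1L, arr.ind = TRUE) - 1L) * sp
    c_lv <- colMeans(which(lv == 1L, arr.ind = TRUE) - 1L) * sp
    dist_mm <- sqrt(sum((c_rv - c_lv)^2))
    if (dist_mm < threshold_mm) {
      rejected <- TRUE
      reason <- sprintf("RV/LV centre distance %.1f mm below %.0f mm",
                        dist_mm, threshold_mm)
    }
  }
  roi_box <- NULL
  if (!rejected) {
    idx <- which(rv == 1L | lv == 1L, arr.ind = TRUE)
    roi_box <- c(max(min(idx[, 1]) - margin_px, 1L),
                 min(max(idx[, 1]) + margin_px, nrow(rv)),
                 max(min(idx[, 2]) - margin_px, 1L),
                 min(max(idx[, 2]) + margin_px, ncol(rv)))
  }
  list(rv_mask = rv, lv_mask = lv, roi_box = roi_box, rejected = rejected,
       center_distance_mm = dist_mm, reason = reason)
}

#' Synthetic motion-free reference series
#'
#' Recombines all independent components except the one labelled as motion:
#' `reference[t] = mean_image + sum_{i != motion} mixing[t, i] * IC_i`.  The
#' result keeps the intensity profile of the original series (so SSD is a
#' valid similarity measure against it) but is, ideally, free of motion.
#'
#' @param decomposition an `ica_decomposition`.
#' @param labels a [component_labels] with `motion_index` resolved.
#' @return a [perfusion_series] of reference frames.
#' @export
synthetic_references <- function(decomposition, labels) {
  if (is.na(labels$motion_index))
    stop("motion component not identified; run the frequency fallback ",
         "(fallback_motion_label) or treat the series as failed")
  arr <- ica_reconstruct(decomposition, drop = labels$motion_index)
  perfusion_series(arr, times = decomposition$times,
                   spacing = decomposition$spacing, n_pd = 0L)
}
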
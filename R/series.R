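#' 2D+t perfusion series
#'
#' The central image container: an ordered stack of single-slice frames
#' acquired over the first pass of a contrast bolus, together with the
#' acquisition time of each frame and the in-plane pixel spacing.
#'
#' Frames are stored as a single 3D array `data[row, col, frame]` in arbitrary
#' intensity units; acquisition times are seconds from the start of the
#' series and must be strictly increasing.  The first `n_pd` frames are
#' proton-density weighted calibration images that are excluded from any
#' motion analysis.  Pixel coordinates are 0-based `(row, col)` indices;
#' physical position in mm is `index * spacing`.
#'
#' @param data numeric 3D array `[rows, cols, frames]` (or a list of equal
#'   shaped matrices).
#' @param times numeric vector of acquisition times in seconds, one per
#'   frame, strictly increasing, non-negative.
#' @param spacing numeric length-2, pixel spacing in mm `(row, col)`; both
#'   positive.
#' @param n_pd number of leading proton-density frames (default 2; use 0 for
#'   a series that has already been stripped).
#' @param patient_id,study,slice_level optional labels; `study` is one of
#'   `"rest"`/`"stress"`, `slice_level` one of `"apical"`, `"mid"`, `"basal"`.
#' @param bit8 logical; `TRUE` marks an 8-bit (PNG-derived) series whose
#'   intensities were windowed per-series and must not be compared across
#'   series.
#' @return an object of class `perfusion_series`.
#' @export
perfusion_series <- function(data, times, spacing = c(1.4, 1.4), n_pd = 2L,
                             patient_id = NA_character_, study = NA_character_,
                             slice_level = NA_character_, bit8 = FALSE) {
  if (is.list(data)) {
    shp <- dim(data[[1]])
    if (!all(vapply(data, function(m) identical(dim(m), shp), logical(1))))
      stop("all frames must share the same shape")
    data <- array(unlist(data), dim = c(shp, length(data)))
  }
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array [rows, cols, frames]")
  nf <- dim(data)[3]
  if (nf < 3L) stop("a perfusion series needs at least 3 frames")
  if (length(times) != nf) stop("'times' must have one entry per frame")
  if (any(!is.finite(times)) || any(times < 0)) stop("times must be finite and non-negative")
  if (any(diff(times) <= 0)) stop("acquisition times must be strictly increasing")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("pixel spacing must be positive")
  n_pd <- as.integer(n_pd)
  if (n_pd < 0L || n_pd >= nf) stop("'n_pd' must be in [0, n_frames)")
  structure(list(data = data, times = as.numeric(times),
                 spacing = as.numeric(spacing), n_pd = n_pd,
                 patient_id = patient_id, study = study,
                 slice_level = slice_level, bit8 = isTRUE(bit8)),
            class = "perfusion_series")
}

#' @export
print.perfusion_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<perfusion_series> %d frames of %dx%d px (%.3g x %.3g mm)\n",
              d[3], d[1], d[2], x$spacing[1], x$spacing[2]))
  cat(sprintf("  times %.2f..%.2f s, %d PD frame(s)%s\n",
              x$times[1], x$times[d[3]], x$n_pd,
              if (x$bit8) ", 8-bit (non-quantitative)" else ""))
  invisible(x)
}

#' @rdname perfusion_series
#' @param series a `perfusion_series`.
#' @export
n_frames <- function(series) dim(series$data)[3]

#' @rdname perfusion_series
#' @param i frame index (1-based).
#' @export
frame_matrix <- function(series, i) series$data[, , i]

#' Drop the leading proton-density frames
#'
#' Perfusion protocols acquire proton-density weighted calibration images at
#' the start of the series (by convention the first two frames).  These have
#' a different contrast and take no part in motion analysis.  The input is
#' not modified; a series already flagged as stripped (`n_pd == 0`) is
#' returned unchanged.
#'
#' @param series a [perfusion_series].
#' @param n number of frames to strip; defaults to the series' `n_pd` flag.
#' @return a `perfusion_series` without the leading PD frames (`n_pd = 0`).
#' @export
strip_proton_density <- function(series, n = NULL) {
  if (is.null(n)) n <- series$n_pd
  n <- as.integer(n)
  if (n == 0L) return(series)
  nf <- n_frames(series)
  if (n >= nf) stop("cannot strip all frames")
  keep <- seq.int(n + 1L, nf)
  out <- series
  out$data <- series$data[, , keep, drop = FALSE]
  out$times <- series$times[keep]
  out$n_pd <- 0L
  out
}

# frames x pixels matrix view (column-major pixel order)
series_matrix <- function(series) {
  d <- dim(series$data)
  t(matrix(series$data, nrow = d[1] * d[2], ncol = d[3]))
}

series_with_data <- function(series, data, times = series$times) {
  out <- series
  out$data <- data
  out$times <- times
  out
}
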
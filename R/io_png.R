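#' Read a perfusion series from 8-bit PNG frames plus a sidecar file
#'
#' The PNG dialect stores each frame as a single-channel 8-bit gray PNG and a
#' JSON sidecar with the pixel spacing, per-frame acquisition times and the
#' series labels.  Because the 16-bit to 8-bit mapping is chosen per series,
#' 8-bit series are flagged non-quantitative (`bit8 = TRUE`).
#'
#' @param files character vector of PNG paths, in the order given by the
#'   sidecar `files` entry if present, otherwise taken as already ordered.
#' @param metadata_path path to the JSON sidecar (fields: `spacing`, `times`,
#'   optionally `n_pd`, `patient_id`, `study`, `slice_level`, `files`).
#' @param strict if `TRUE`, RGB input is an error; otherwise it is converted
#'   to gray by luminance with a warning.
#' @return a [perfusion_series] with intensities in 0..255.
#' @export
load_png_series <- function(files, metadata_path, strict = FALSE) {
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  if (is.null(meta$spacing) || is.null(meta$times))
    stop("sidecar must provide 'spacing' and 'times'")
  if (!is.null(meta$files)) {
    idx <- match(meta$files, basename(files))
    if (anyNA(idx)) stop("sidecar 'files' entries missing from the file list")
    files <- files[idx]
  }
  if (length(files) != length(meta$times))
    stop("number of PNG files does not match sidecar 'times'")
  frames <- lapply(files, function(f) {
    px <- png::readPNG(f)
    if (length(dim(px)) == 3L) {
      if (strict) stop("RGB PNG not allowed in strict mode: ", f)
      warning("RGB PNG converted to gray by luminance: ", basename(f))
      px <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
    }
    round(px * 255)
  })
  shp <- dim(frames[[1]])
  if (!all(vapply(frames, function(m) identical(dim(m), shp), logical(1))))
    stop("PNG frames have mismatched shapes")
  perfusion_series(frames, times = meta$times, spacing = meta$spacing,
                   n_pd = if (is.null(meta$n_pd)) 2L else meta$n_pd,
                   patient_id = meta$patient_id %||% NA_character_,
                   study = meta$study %||% NA_character_,
                   slice_level = meta$slice_level %||% NA_character_,
                   bit8 = TRUE)
}

#' Write a perfusion series as 8-bit PNG frames plus a JSON sidecar
#'
#' Intensities are linearly windowed to 0..255 over the series-wide range
#' (identity if already in range), mirroring the per-series manual windowing
#' of the source data.  Returns the written file paths invisibly.
#'
#' @param series a [perfusion_series].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the frames.
#' @export
write_png_series <- function(series, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- range(series$data)
  scale01 <- if (rng[1] >= 0 && rng[2] <= 255) function(m) m / 255 else
    function(m) (m - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  nf <- n_frames(series)
  files <- sprintf("%s%04d.png", prefix, seq_len(nf))
  for (i in seq_len(nf))
    png::writePNG(pmin(pmax(scale01(series$data[, , i]), 0), 1),
                  file.path(dir, files[i]))
  meta <- list(spacing = series$spacing, times = series$times,
               n_pd = series$n_pd, patient_id = series$patient_id,
               study = series$study, slice_level = series$slice_level,
               files = files)
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, c(files, "series.json")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
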
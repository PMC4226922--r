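# Minimal single-frame MR DICOM codec (explicit VR little endian).  Covers
# exactly the elements a perfusion frame needs: acquisition/trigger time,
# pixel spacing, geometry and 16-bit unsigned pixel data.  Not a general
# DICOM implementation.

DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_pad <- function(raw_val, pad = as.raw(0x20)) {
  if (length(raw_val) %% 2L == 1L) c(raw_val, pad) else raw_val
}

dcm_element <- function(group, element, vr, value_raw) {
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"), value_raw)
  } else {
    c(head, writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dcm_str <- function(group, element, vr, s, pad = as.raw(0x20))
  dcm_element(group, element, vr, dcm_pad(charToRaw(s), pad))

dcm_us <- function(group, element, v)
  dcm_element(group, element, "US", writeBin(as.integer(v), raw(), size = 2,
                                             endian = "little"))

# seconds from midnight -> TM "HHMMSS.FFFFFF"
dcm_format_tm <- function(t) {
  h <- floor(t / 3600); t <- t - 3600 * h
  m <- floor(t / 60); s <- t - 60 * m
  sprintf("%02d%02d%09.6f", h, m, s)
}

dcm_parse_tm <- function(s) {
  s <- trimws(s)
  if (!grepl("^[0-9]{6}(\\.[0-9]+)?$", s)) return(NA_real_)
  3600 * as.numeric(substr(s, 1, 2)) + 60 * as.numeric(substr(s, 3, 4)) +
    as.numeric(substr(s, 5, nchar(s)))
}

#' Write a perfusion series as single-frame DICOM files
#'
#' Emits one minimal MR object per frame (explicit VR little endian) with the
#' acquisition time, trigger time, pixel spacing and 16-bit unsigned pixel
#' data.  Intensities are rounded to integers; values outside 0..65535 are
#' clamped with a warning.
#'
#' @param series a [perfusion_series].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the written paths, invisibly.
#' @export
write_dicom_series <- function(series, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$data)
  nf <- d[3]
  files <- file.path(dir, sprintf("%s%04d.dcm", prefix, seq_len(nf)))
  pid <- if (is.na(series$patient_id)) "ANON" else as.character(series$patient_id)
  desc <- paste(ifelse(is.na(series$study), "NA", series$study),
                ifelse(is.na(series$slice_level), "NA", series$slice_level),
                series$n_pd, sep = "|")
  for (i in seq_len(nf)) {
    px <- round(series$data[, , i])
    if (any(px < 0 | px > 65535)) {
      warning("pixel values clamped to 0..65535 for 16-bit DICOM storage")
      px <- pmin(pmax(px, 0), 65535)
    }
    # DICOM stores pixels row by row
    pxv <- as.integer(t(px))
    pix_raw <- writeBin(pxv, raw(), size = 2, endian = "little")
    meta_body <- c(
      dcm_str(0x0002, 0x0010, "UI", DCM_TS_EXPLICIT_LE, pad = as.raw(0x00)))
    meta <- c(
      dcm_element(0x0002, 0x0000, "UL",
                  writeBin(length(meta_body), raw(), size = 4, endian = "little")),
      meta_body)
    body <- c(
      dcm_str(0x0008, 0x0032, "TM", dcm_format_tm(series$times[i])),
      dcm_str(0x0008, 0x0060, "CS", "MR"),
      dcm_str(0x0008, 0x103E, "LO", desc),
      dcm_str(0x0010, 0x0020, "LO", pid),
      dcm_str(0x0018, 0x1060, "DS", sprintf("%.6f", series$times[i] * 1000)),
      dcm_str(0x0020, 0x0013, "IS", as.character(i)),
      dcm_us(0x0028, 0x0002, 1L),
      dcm_us(0x0028, 0x0010, d[1]),
      dcm_us(0x0028, 0x0011, d[2]),
      dcm_str(0x0028, 0x0030, "DS",
              sprintf("%.6f\\%.6f", series$spacing[1], series$spacing[2])),
      dcm_us(0x0028, 0x0100, 16L),
      dcm_us(0x0028, 0x0101, 16L),
      dcm_us(0x0028, 0x0102, 15L),
      dcm_us(0x0028, 0x0103, 0L),
      dcm_element(0x7FE0, 0x0010, "OW", pix_raw))
    con <- file(files[i], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(files)
}

# parse one DICOM file into a list of tag -> value (raw + decoded where known)
read_dicom_file <- function(path) {
  buf <- readBin(path, raw(), n = file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  els <- list()
  u16 <- function(p) readBin(buf[p:(p + 1L)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(p) readBin(buf[p:(p + 3L)], "integer", size = 4,
                             endian = "little")
  n <- length(buf)
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or corrupt DICOM not supported: ", path)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); pos <- pos + 12L
    } else {
      len <- u16(pos + 6L); pos <- pos + 8L
    }
    if (len < 0 || pos + len - 1L > n) stop("truncated DICOM element in ", path)
    val <- if (len > 0) buf[pos:(pos + len - 1L)] else raw(0)
    els[[sprintf("%04X,%04X", group, element)]] <- list(vr = vr, raw = val)
    pos <- pos + len
  }
  els
}

dcm_get_str <- function(els, tag) {
  e <- els[[tag]]
  if (is.null(e)) return(NA_character_)
  trimws(rawToChar(e$raw))
}

dcm_get_us <- function(els, tag) {
  e <- els[[tag]]
  if (is.null(e)) return(NA_integer_)
  readBin(e$raw, "integer", size = 2, endian = "little", signed = FALSE)
}

#' Read a directory of single-frame DICOM files as a perfusion series
#'
#' Frames are ordered by acquisition time regardless of file names.  The
#' acquisition-time tag (0008,0032) takes priority; if absent, the trigger
#' time (0018,1060) is used.  A file providing neither is a format error.
#'
#' @param dir directory containing the `.dcm` files of one slice series.
#' @param n_pd number of leading proton-density frames.  The DICOM format
#'   carries no per-frame tag for this; by convention the first two frames.
#'   `NULL` (default) uses the count stored in the series description by
#'   [write_dicom_series()], falling back to 2.
#' @return a [perfusion_series].
#' @export
load_dicom_series <- function(dir, n_pd = NULL) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L) stop("no DICOM files found in ", dir)
  frames <- vector("list", length(files))
  times <- numeric(length(files))
  spacing <- NULL; labels <- NULL; pid <- NA_character_
  for (i in seq_along(files)) {
    els <- read_dicom_file(files[i])
    t_acq <- dcm_parse_tm(dcm_get_str(els, "0008,0032"))
    if (is.na(t_acq)) {
      tt <- suppressWarnings(as.numeric(dcm_get_str(els, "0018,1060")))
      t_acq <- if (is.na(tt)) NA_real_ else tt / 1000
    }
    if (is.na(t_acq))
      stop("no usable acquisition or trigger time tag in ", basename(files[i]))
    times[i] <- t_acq
    rows <- dcm_get_us(els, "0028,0010"); cols <- dcm_get_us(els, "0028,0011")
    if (is.na(rows) || is.na(cols)) stop("missing Rows/Columns in ", basename(files[i]))
    sp <- dcm_get_str(els, "0028,0030")
    sp <- if (is.na(sp)) c(1, 1) else as.numeric(strsplit(sp, "\\\\")[[1]])
    if (is.null(spacing)) spacing <- sp
    pix <- els[["7FE0,0010"]]
    if (is.null(pix)) stop("missing pixel data in ", basename(files[i]))
    v <- readBin(pix$raw, "integer", n = rows * cols, size = 2,
                 endian = "little", signed = FALSE)
    frames[[i]] <- matrix(as.double(v), nrow = rows, ncol = cols, byrow = TRUE)
    if (is.null(labels)) {
      labels <- strsplit(dcm_get_str(els, "0008,103E"), "|", fixed = TRUE)[[1]]
      pid <- dcm_get_str(els, "0010,0020")
    }
  }
  ord <- order(times)
  if (anyDuplicated(times)) stop("ambiguous (duplicated) acquisition times in ", dir)
  frames <- frames[ord]
  times <- times[ord] - min(times)
  if (is.null(n_pd)) {
    stored <- if (length(labels) == 3L)
      suppressWarnings(as.integer(labels[3])) else NA_integer_
    n_pd <- if (!is.na(stored)) stored else 2L
  }
  study <- if (length(labels) >= 1L && labels[1] != "NA") labels[1] else NA_character_
  slice <- if (length(labels) >= 2L && labels[2] != "NA") labels[2] else NA_character_
  perfusion_series(frames, times = times, spacing = spacing, n_pd = n_pd,
                   patient_id = pid, study = study, slice_level = slice)
}
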
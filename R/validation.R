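#' Mean-intensity time curve over masks
#'
#' `value[t]` is the mean intensity of frame `t` over `masks[[t]]` (a single
#' mask is recycled over all frames).  An empty mask yields `NA` for that
#' frame; downstream scoring resolves the missing value (a fully empty
#' transformed section scores a Pearson coefficient of exactly 0).
#'
#' @param series a [perfusion_series].
#' @param masks one 0/1 matrix, or a list with one mask per frame.
#' @return numeric vector, one value per frame.
#' @export
intensity_curve <- function(series, masks) {
  nf <- n_frames(series)
  if (is.matrix(masks)) masks <- rep(list(masks), nf)
  if (length(masks) != nf) stop("need one mask per frame (or a single mask)")
  vapply(seq_len(nf), function(t) {
    m <- masks[[t]] != 0
    if (!any(m)) return(NA_real_)
    mean(series$data[, , t][m])
  }, numeric(1))
}

#' Normalized mean squared error between curves
#'
#' `sum((curve - gt)^2) / sum((gt - mean(gt))^2)`: squared error normalized
#' by the ground-truth variance sum, so a constant curve at the ground-truth
#' mean scores exactly 1.  Lower is better; equality scores 0.
#'
#' @param curve,gt_curve equal-length numeric vectors (length >= 2).
#' @return NMSE (>= 0), or `NA` when the ground truth is constant.
#' @export
nmse <- function(curve, gt_curve) {
  if (length(curve) != length(gt_curve) || length(curve) < 2L)
    stop("curves must have equal length >= 2")
  ss <- sum((gt_curve - mean(gt_curve))^2)
  if (ss == 0) {
    warning("constant ground-truth curve: NMSE undefined")
    return(NA_real_)
  }
  sum((curve - gt_curve)^2) / ss
}

#' Pearson correlation between curves
#'
#' Signed Pearson coefficient.  A curve from an empty transformed mask
#' (all `NA`) scores exactly 0 to mark the failed motion compensation; a
#' zero-variance input also scores 0 with a warning.
#'
#' @param curve,gt_curve equal-length numeric vectors (length >= 2).
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(curve, gt_curve) {
  if (length(curve) != length(gt_curve) || length(curve) < 2L)
    stop("curves must have equal length >= 2")
  if (all(is.na(curve))) return(0)
  ok <- !is.na(curve) & !is.na(gt_curve)
  if (sd(curve[ok]) == 0 || sd(gt_curve[ok]) == 0) {
    warning("zero-variance curve: correlation set to 0")
    return(0)
  }
  cor(curve[ok], gt_curve[ok])
}

#' Build the three per-section time-intensity curve families
#'
#' For each myocardial section the validation compares three curves:
#' `K_gt`, evaluated with each frame's own segmentation masks on the original
#' series (the ground truth); `K_org`, evaluated with the unaltered key-frame
#' (LV-peak) section masks on the original series (the unregistered
#' baseline); and `K_reg`, evaluated on the motion-compensated series with
#' the key-frame masks adjusted by the key frame's transform.
#'
#' @param series the original [perfusion_series] (PD frames stripped, frame
#'   count matching `segset`).
#' @param registered_series the motion-compensated series (`NULL` to skip
#'   `K_reg`).
#' @param segset a [segmentation_set] covering every frame, with the LV peak
#'   marked.
#' @param transforms per-frame list of `transform_field`s used for the
#'   compensation (`NULL` means identity; only the key frame's entry is
#'   used).
#' @param n_sections number of myocardial sections (default 12).
#' @return `list(K_gt, K_org, K_reg, section_ids, key_frame_index)`; each
#'   `K_*` is a `frames x sections` matrix (`K_reg` `NULL` when not
#'   computed).
#' @export
build_curves <- function(series, registered_series = NULL, segset,
                         transforms = NULL, n_sections = 12L) {
  nf <- n_frames(series)
  if (length(segset$frames) != nf)
    stop("segmentation must cover all frames (", length(segset$frames),
         " vs ", nf, ")")
  key <- segset$lv_peak
  if (is.na(key)) stop("missing LV-peak index in the segmentation set")
  shape <- dim(series$data)[1:2]

  per_frame <- lapply(segset$frames, function(fr)
    section_masks(fr, shape, n_sections)$sections)
  key_masks <- per_frame[[key]]

  K_gt <- vapply(seq_len(n_sections), function(s)
    intensity_curve(series, lapply(per_frame, `[[`, s)), numeric(nf))
  K_org <- vapply(seq_len(n_sections), function(s)
    intensity_curve(series, key_masks[[s]]), numeric(nf))

  K_reg <- NULL
  if (!is.null(registered_series)) {
    adj_masks <- if (is.null(transforms)) key_masks else
      lapply(key_masks, function(m) apply_transform(transforms[[key]], m, "mask"))
    K_reg <- vapply(seq_len(n_sections), function(s)
      intensity_curve(registered_series, adj_masks[[s]]), numeric(nf))
  }
  list(K_gt = K_gt, K_org = K_org, K_reg = K_reg,
       section_ids = seq_len(n_sections), key_frame_index = key)
}

#' Score a curve set into a tidy table
#'
#' One data point per myocardial section, measure and phase; the statistical
#' unit of the validation is (patient, slice, study, section).
#'
#' @param curves output of [build_curves()].
#' @param patient,slice,study labels attached to every row.
#' @param method name used for the registered phase (e.g. `"ICA-SP"`).
#' @return data.frame with columns patient, slice, study, section, measure
#'   (`NMSE`/`R2`), phase (`unregistered`/`method`), value.
#' @export
score_curves <- function(curves, patient = "phantom", slice = "mid",
                         study = "rest", method = "method") {
  rows <- list()
  for (s in curves$section_ids) {
    gt <- curves$K_gt[, s]
    add <- function(phase, measure, value)
      rows[[length(rows) + 1L]] <<- data.frame(
        patient = patient, slice = slice, study = study, section = s,
        measure = measure, phase = phase, value = value,
        stringsAsFactors = FALSE)
    add("unregistered", "NMSE", nmse(curves$K_org[, s], gt))
    add("unregistered", "R2", pearson_cc(curves$K_org[, s], gt))
    if (!is.null(curves$K_reg)) {
      reg <- curves$K_reg[, s]
      add(method, "NMSE", if (all(is.na(reg))) NA_real_ else nmse(reg, gt))
      add(method, "R2", pearson_cc(reg, gt))
    }
  }
  do.call(rbind, rows)
}

#' Summary statistics of a score table
#'
#' Mean, variation (sample standard deviation), median, min and max per
#' measure and phase, optionally split by study (`all` / `rest` / `stress`).
#' Series listed in `exclude` are dropped first (the convention used to
#' report a method ignoring its failed series).
#'
#' @param score_table data.frame as produced by [score_curves()] (rows from
#'   several series may be concatenated).
#' @param split_study also produce per-study blocks.
#' @param exclude optional data.frame with columns patient, slice, study
#'   identifying series to drop.
#' @return data.frame with columns study, measure, phase, mean, variation,
#'   median, min, max, n.
#' @export
summarize_scores <- function(score_table, split_study = TRUE, exclude = NULL) {
  if (nrow(score_table) == 0L) stop("empty score table")
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    key <- function(d) paste(d$patient, d$slice, d$study, sep = "\r")
    score_table <- score_table[!(key(score_table) %in% key(exclude)), ,
                               drop = FALSE]
  }
  blocks <- list(all = score_table)
  if (split_study)
    for (st in intersect(c("rest", "stress"), unique(score_table$study)))
      blocks[[st]] <- score_table[score_table$study == st, , drop = FALSE]
  out <- list()
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    for (ms in unique(b$measure))
      for (ph in unique(b$phase)) {
        v <- b$value[b$measure == ms & b$phase == ph]
        v <- v[!is.na(v)]
        if (length(v) == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          study = bn, measure = ms, phase = ph,
          mean = mean(v), variation = sd(v), median = median(v),
          min = min(v), max = max(v), n = length(v),
          stringsAsFactors = FALSE)
      }
  }
  res <- do.call(rbind, out)
  res$variation[is.na(res$variation)] <- 0
  res
}
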
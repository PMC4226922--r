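#' Select the same-breathing-phase subset for QUASI-P
#'
#' A global reference frame is chosen from the last third of the series
#' (late, past the fast enhancement phase) as the frame with the best summed
#' NGF similarity to its five temporal neighbours.  The NGF cost of every
#' frame against the reference, as a function of time, oscillates with the
#' breathing; frames at (non-strict) local minima of that curve within a
#' 3-frame window belong to the reference's breathing phase.  To give the
#' measure a capture range wider than the edge width, the similarity is
#' evaluated on a coarse pyramid level (two 2x block-mean reductions) with a
#' raised noise parameter (3x the median gradient magnitude) — the same logic
#' that motivates multi-resolution registration.
#'
#' The slow contrast-enhancement trend is removed with a running median
#' (window 7).  Breathing is considered present when the detrended curve's
#' robust spread exceeds 4% of the reference's self-similarity contrast
#' (`median(costs) - costs[ref]`, the measure's own noise scale); interior
#' local minima whose dip reaches at least a quarter of the deepest detrended
#' dip then join the subset — roughly one frame per breathing cycle even when
#' the cycle amplitude drifts — as do the series endpoints (one-sided minima
#' in the lowest cost quartile).  Without a detectable oscillation — a motion-free
#' series — the subset deliberately degenerates to the reference and at most
#' the endpoints, the documented failure mode of the method; no maximum
#' temporal gap is imposed.  A series of identical frames ties everywhere and
#' keeps every frame.
#'
#' @param series a [perfusion_series] (PD frames are stripped first; indices
#'   refer to the stripped series).  Needs >= 6 frames.
#' @param eta NGF noise parameter for the full-resolution cost curve returned
#'   alongside (`"auto"` by default); the coarse selection always uses its
#'   own auto estimate.
#' @return `list(reference_index, subset_indices, costs)`; `costs` is the
#'   coarse-level NGF cost of every frame against the reference.
#' @export
select_subset <- function(series, eta = "auto") {
  if (series$n_pd > 0L) series <- strip_proton_density(series)
  nf <- n_frames(series)
  if (nf < 6L) stop("subset selection needs at least 6 frames")
  coarse <- function(m) cpp_downsample2(cpp_downsample2(m))

  frames <- lapply(seq_len(nf), function(i) coarse(frame_matrix(series, i)))
  sim_eta <- 3 * ngf_auto_eta(frames[[nf]])

  last_third <- seq.int(max(floor(2 * nf / 3), 1L) + 1L, nf)
  neigh_cost <- vapply(last_third, function(i) {
    nb <- setdiff(seq.int(max(1L, i - 3L), min(nf, i + 3L)), i)
    nb <- head(nb, 5L)
    mean(vapply(nb, function(j)
      ngf_cost(frames[[j]], frames[[i]], eta = sim_eta,
               want_grad = FALSE)$cost, numeric(1)))
  }, numeric(1))
  ref <- last_third[which.min(neigh_cost)]

  costs <- vapply(seq_len(nf), function(j)
    ngf_cost(frames[[j]], frames[[ref]], eta = sim_eta,
             want_grad = FALSE)$cost, numeric(1))

  if (diff(range(costs)) == 0) {              # all frames tie: one phase
    return(list(reference_index = ref, subset_indices = seq_len(nf),
                costs = costs))
  }
  trend <- stats::runmed(costs, 7)
  resid <- costs - trend
  dmin <- min(resid[-ref], 0)
  # breathing makes the detrended cost oscillate well above the curve's
  # jitter; the reference's self-similarity contrast (median cost minus the
  # reference's own cost) provides the absolute scale.  Without a detectable
  # oscillation the subset degenerates to the reference and at most the
  # endpoints — the method's documented failure mode on motion-free input.
  floor_gap <- max(median(costs) - costs[ref], .Machine$double.eps)
  oscillating <- mad(resid[-ref]) / floor_gap >= 0.04
  subset <- ref
  if (oscillating) {
    for (i in seq.int(2L, nf - 1L)) {
      if (i == ref) next
      if (costs[i] <= costs[i - 1L] && costs[i] <= costs[i + 1L] &&
          resid[i] <= 0.25 * dmin)
        subset <- c(subset, i)
    }
  }
  q25 <- quantile(costs, 0.25)
  ep_ok <- function(i, nb) costs[i] <= costs[nb] && costs[i] <= q25 &&
    (!oscillating || resid[i] <= 0.25 * dmin)
  if (ep_ok(1L, 2L)) subset <- c(subset, 1L)
  if (ep_ok(nf, nf - 1L)) subset <- c(subset, nf)
  subset <- sort(unique(subset))
  if (length(subset) < 2L)
    stop("degenerate breathing-phase subset (fewer than 2 frames)")
  list(reference_index = ref, subset_indices = subset, costs = costs)
}

#' Interpolate synthetic reference frames in time
#'
#' Per-pixel linear interpolation between the temporally adjacent registered
#' subset frames; times outside the subset span are clamped to the nearest
#' subset frame.  A time equal to a subset time reproduces that frame
#' exactly.
#'
#' @param registered_subset the registered subset frames in subset order: a
#'   [perfusion_series] or a 3D array `[rows, cols, subset]` (the subset may
#'   be as small as 2 frames).
#' @param subset_times acquisition times of the subset frames (sorted).
#' @param all_times times at which references are required.
#' @param spacing pixel spacing for the result (taken from the series input
#'   when available).
#' @return a [perfusion_series] of reference frames at `all_times`.
#' @export
interpolate_references <- function(registered_subset, subset_times, all_times,
                                   spacing = c(1.4, 1.4)) {
  if (inherits(registered_subset, "perfusion_series")) {
    spacing <- registered_subset$spacing
    registered_subset <- registered_subset$data
  }
  d <- dim(registered_subset)
  ns <- d[3]
  if (ns == 0L) stop("empty subset")
  if (length(subset_times) != ns) stop("subset_times must match the subset")
  if (ns > 1L && any(diff(subset_times) <= 0)) stop("subset must be sorted by time")
  out <- array(0, dim = c(d[1], d[2], length(all_times)))
  for (k in seq_along(all_times)) {
    if (ns == 1L) { out[, , k] <- registered_subset[, , 1L]; next }
    t <- min(max(all_times[k], subset_times[1]), subset_times[ns])
    hi <- findInterval(t, subset_times, rightmost.closed = TRUE) + 1L
    hi <- min(max(hi, 2L), ns)
    lo <- hi - 1L
    w <- (t - subset_times[lo]) / (subset_times[hi] - subset_times[lo])
    out[, , k] <- (1 - w) * registered_subset[, , lo] +
      w * registered_subset[, , hi]
  }
  tt <- all_times
  if (any(diff(tt) <= 0)) tt <- seq_along(all_times)   # defensive
  perfusion_series(out, times = tt, spacing = spacing, n_pd = 0L)
}

#' QUASI-P motion compensation
#'
#' Three steps: (1) find a global reference and the subset of frames in its
#' breathing phase ([select_subset()]); (2) register the subset frames to the
#' reference by optimizing NGF; (3) interpolate synthetic references in time
#' from the registered subset and register every remaining frame to its
#' reference by optimizing SSD.  Subset frames keep their step-2 alignment.
#' Registration uses knot spacing 5 at full scale, kappa 0.1, 3 levels and
#' gradient descent (start step 0.01, epsilon 0.01), one pass.
#'
#' A degenerate subset does not abort a batch: the failure is reported in the
#' result (`failed = TRUE` with the reason).
#'
#' @param series a [perfusion_series]; leading PD frames are stripped
#'   automatically.
#' @param config list of options: `reg` (a [reg_config()]), `eta` (`"auto"`).
#'   See [default_config()].
#' @return a `moco_result` (see [run_icasp()]) with `subset_indices` and
#'   `reference_index` added.
#' @export
run_quasip <- function(series, config = NULL) {
  cfg <- modifyList(default_config()$quasip, config %||% list())
  if (series$n_pd > 0L) series <- strip_proton_density(series)
  nf <- n_frames(series)
  shape <- dim(series$data)[1:2]
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  fail <- function(reason) {
    note("FAILED: %s", reason)
    structure(list(registered_series = series,
                   transforms = lapply(seq_len(nf), function(i)
                     transform_identity(shape)),
                   labels = NULL, roi = NULL, passes_used = 0L,
                   method = "QUASI-P", failed = TRUE, reason = reason,
                   log = log_lines,
                   subset_indices = integer(0), reference_index = NA_integer_),
              class = "moco_result")
  }

  sel <- tryCatch(select_subset(series, eta = cfg$eta), error = identity)
  if (inherits(sel, "error")) return(fail(conditionMessage(sel)))
  note("reference frame %d, subset of %d frames: %s", sel$reference_index,
       length(sel$subset_indices), paste(sel$subset_indices, collapse = " "))

  ref_img <- frame_matrix(series, sel$reference_index)
  cfg_ngf <- cfg$reg; cfg_ngf$measure <- "ngf"; cfg_ngf$eta <- cfg$eta
  cfg_ssd <- cfg$reg; cfg_ssd$measure <- "ssd"

  transforms <- lapply(seq_len(nf), function(i) transform_identity(shape))
  reg_data <- series$data
  for (i in sel$subset_indices) {
    if (i == sel$reference_index) next
    tf <- register(frame_matrix(series, i), ref_img, cfg_ngf)
    transforms[[i]] <- tf
    reg_data[, , i] <- apply_transform(tf, frame_matrix(series, i))
  }
  note("step 2: registered %d subset frames to the reference with NGF",
       length(sel$subset_indices) - 1L)

  refs <- interpolate_references(reg_data[, , sel$subset_indices, drop = FALSE],
                                 series$times[sel$subset_indices],
                                 series$times, spacing = series$spacing)

  rest <- setdiff(seq_len(nf), sel$subset_indices)
  for (i in rest) {
    tf <- register(frame_matrix(series, i), frame_matrix(refs, i), cfg_ssd)
    transforms[[i]] <- tf
    reg_data[, , i] <- apply_transform(tf, frame_matrix(series, i))
  }
  note("step 3: registered %d remaining frames to interpolated references with SSD",
       length(rest))

  structure(list(registered_series = series_with_data(series, reg_data),
                 transforms = transforms, labels = NULL, roi = NULL,
                 passes_used = 1L, method = "QUASI-P", failed = FALSE,
                 reason = NA_character_, log = log_lines,
                 subset_indices = sel$subset_indices,
                 reference_index = sel$reference_index),
            class = "moco_result")
}
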
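#' Shipped pipeline defaults
#'
#' All published parameter settings in one structured configuration: ICA-SP
#' registers with SSD, curvature weight 10, knot spacing 16 at working scale
#' 0.5, 3 multi-resolution levels, a quasi-Newton optimizer (<= 300
#' iterations, 1e-3 tolerances) and at most 5 passes; QUASI-P registers with
#' curvature weight 0.1, knot spacing 5 at full scale, 3 levels, gradient
#' descent (start step 0.01, epsilon 0.01), one pass.  The ROI sanity check
#' rejects RV/LV centre distances below 30 mm and the frequency fallback
#' threshold is 14 breaths per minute.
#'
#' @return nested list with entries `phantom`, `icasp`, `quasip`,
#'   `validation`, `experiment`.
#' @export
default_config <- function() {
  list(
    phantom = list(),                      # overrides for phantom_config()
    icasp = list(
      reg = reg_config(measure = "ssd", kappa = 10, knot_spacing = 16,
                       scale = 0.5, levels = 3L, optimizer = "quasi_newton",
                       max_iter = 300L, f_tol = 1e-3, x_tol = 1e-3),
      n_components = 5L, max_passes = 5L, min_update_px = 0.5,
      roi_threshold_mm = 30, roi_margin_px = 10L, use_roi = TRUE,
      freq_threshold = 14, seed = 1L),
    quasip = list(
      reg = reg_config(measure = "ssd", kappa = 0.1, knot_spacing = 5,
                       scale = 1, levels = 3L, optimizer = "gradient_descent",
                       start_step = 0.01, epsilon = 0.01),
      eta = "auto"),
    validation = list(n_sections = 12L),
    experiment = list(stress_heart_rate = 120, studies = c("rest", "stress")))
}

#' Read / write a configuration file
#'
#' Configurations are JSON files with one section per module; missing entries
#' fall back to [default_config()].
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  modifyList(default_config(), user)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Drop the leading PD frames from a segmentation set
#'
#' Companion to [strip_proton_density()]: removes the first `n_pd` frames
#' and shifts the RV/LV peak indices so the set matches a stripped series.
#'
#' @param segset a [segmentation_set] covering all frames.
#' @param n_pd number of leading proton-density frames to drop.
#' @return a [segmentation_set] for the stripped series.
#' @export
seg_strip_pd <- function(segset, n_pd) {
  if (n_pd == 0L) return(segset)
  shift <- function(i) if (is.na(i)) i else i - n_pd
  segmentation_set(segset$frames[-seq_len(n_pd)],
                   rv_peak = shift(segset$rv_peak),
                   lv_peak = shift(segset$lv_peak),
                   slice_level = segset$slice_level,
                   rv_insertion = segset$rv_insertion)
}

# run one method on one phantom and score it
score_phantom_run <- function(ph, method, cfg, patient, study) {
  stripped <- strip_proton_density(ph$series)
  segs <- seg_strip_pd(ph$truth_segmentation, ph$series$n_pd)
  res <- switch(method,
    "ICA-SP" = tryCatch(run_icasp(ph$series, cfg$icasp), error = identity),
    "QUASI-P" = run_quasip(ph$series, cfg$quasip),
    stop("unknown method ", method))
  if (inherits(res, "error") || isTRUE(res$failed)) {
    reason <- if (inherits(res, "error")) conditionMessage(res) else res$reason
    return(list(result = NULL, failed = TRUE, reason = reason,
                scores = score_curves(
                  build_curves(stripped, NULL, segs, NULL,
                               cfg$validation$n_sections),
                  patient = patient, study = study, method = method)))
  }
  curves <- build_curves(stripped, res$registered_series, segs,
                         res$transforms, cfg$validation$n_sections)
  list(result = res, failed = FALSE, reason = NA_character_,
       scores = score_curves(curves, patient = patient, study = study,
                             method = method))
}

#' Run an in-silico motion-compensation experiment
#'
#' `free_breathing`: for every seed, moving phantoms are generated for the
#' configured studies (rest, and stress with a raised heart rate), both
#' pipelines are run, and the section scores are summarized per method with
#' `unregistered` as the baseline.  `no_motion`: a single motion-free phantom
#' per seed, both pipelines, summarized the same way — the unregistered rows
#' are identically NMSE 0 / correlation 1 because the key-frame masks equal
#' the per-frame ground-truth masks.  Pipeline failures are recorded per
#' series (and the affected method additionally summarized with failed series
#' excluded, the `*` convention) but never abort the batch.
#'
#' @param experiment `"free_breathing"` or `"no_motion"`.
#' @param config nested configuration (see [default_config()]); entries under
#'   `$phantom` override [phantom_config()] arguments.
#' @param seeds integer vector, one phantom per seed.
#' @param methods pipelines to run.
#' @return list of class `perfmoco_experiment`: `scores`, `summary`,
#'   `summary_excluding_failures`, `failures`, `provenance`.
#' @export
run_experiment <- function(experiment = c("free_breathing", "no_motion"),
                           config = NULL, seeds = 1L,
                           methods = c("ICA-SP", "QUASI-P")) {
  experiment <- match.arg(experiment)
  cfg <- modifyList(default_config(), config %||% list())
  studies <- if (experiment == "no_motion") "rest" else cfg$experiment$studies

  all_scores <- list()
  failures <- list()
  for (seed in seeds) {
    for (study in studies) {
      ph_args <- modifyList(
        list(seed = seed,
             motion_mode = if (experiment == "no_motion") "none"
                           else "free_breathing"),
        cfg$phantom)
      if (study == "stress")
        ph_args$heart_rate <- cfg$experiment$stress_heart_rate
      ph <- generate_series(do.call(phantom_config, ph_args))
      patient <- sprintf("phantom%03d", seed)
      base <- NULL
      for (method in methods) {
        run <- score_phantom_run(ph, method, cfg, patient, study)
        if (run$failed)
          failures[[length(failures) + 1L]] <- data.frame(
            patient = patient, slice = "mid", study = study, method = method,
            reason = run$reason, stringsAsFactors = FALSE)
        sc <- run$scores
        if (is.null(base)) {
          base <- sc[sc$phase == "unregistered", , drop = FALSE]
          all_scores[[length(all_scores) + 1L]] <- base
        }
        all_scores[[length(all_scores) + 1L]] <-
          sc[sc$phase != "unregistered", , drop = FALSE]
      }
    }
  }
  scores <- do.call(rbind, all_scores)
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(patient = character(0), slice = character(0),
               study = character(0), method = character(0),
               reason = character(0))
  summary <- summarize_scores(scores)
  sum_excl <- NULL
  if (nrow(failures) > 0L)
    sum_excl <- summarize_scores(scores, exclude = failures)
  structure(list(experiment = experiment, scores = scores, summary = summary,
                 summary_excluding_failures = sum_excl, failures = failures,
                 provenance = list(seeds = seeds, methods = methods,
                                   config = cfg,
                                   package = "perfmoco",
                                   version = as.character(
                                     utils::packageVersion("perfmoco")),
                                   r_version = R.version.string)),
            class = "perfmoco_experiment")
}

#' @export
print.perfmoco_experiment <- function(x, ...) {
  cat(sprintf("<perfmoco_experiment:%s> %d score rows, %d failure(s)\n",
              x$experiment, nrow(x$scores), nrow(x$failures)))
  s <- x$summary[x$summary$study == "all", ]
  for (ms in unique(s$measure)) {
    cat(sprintf("  %s:\n", ms))
    b <- s[s$measure == ms, ]
    for (i in seq_len(nrow(b)))
      cat(sprintf("    %-14s mean %.2f  sd %.2f  median %.2f  min %.2f  max %.2f\n",
                  b$phase[i], b$mean[i], b$variation[i], b$median[i],
                  b$min[i], b$max[i]))
  }
  invisible(x)
}
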
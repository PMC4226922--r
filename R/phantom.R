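#' Configuration of the synthetic perfusion phantom
#'
#' The phantom emulates an ECG-triggered free-breathing first-pass perfusion
#' acquisition: 60 frames (the first two proton-density weighted), a
#' 256x192 matrix at 1.4 mm pixel spacing, sequential RV -> LV -> myocardial
#' contrast enhancement, and quasi-periodic breathing translation of the
#' heart inside a static chest.  At a resting heart rate of 75 beats/min and
#' a breathing rate of 12 breaths/min one breathing cycle covers roughly six
#' frames; raising `heart_rate` while keeping `breathing_rate` emulates a
#' stress study, stretching the cycle over more frames.
#'
#' @param n_frames total frames (default 60).
#' @param n_pd_frames leading proton-density frames (default 2).
#' @param matrix image shape `(rows, cols)` (default `c(192, 256)`).
#' @param spacing pixel spacing in mm (scalar or `(row, col)`).
#' @param heart_rate beats per minute; frames are triggered once per beat.
#' @param breathing_rate breaths per minute.
#' @param motion_amplitude head-foot breathing amplitude of the heart in mm
#'   (default 6, calibrated so the unregistered section scores of the default
#'   free-breathing phantom match the published unregistered level of the
#'   real free-breathing series; within the reported range of respiratory
#'   cardiac excursion).
#' @param motion_mode `"free_breathing"` (quasi-periodic, drifting amplitude
#'   and period), `"shallow"` (30% amplitude) or `"none"`.
#' @param enhancement per-compartment gamma-variate bolus parameters; see
#'   [enhancement_curve()].  Defaults give RV onset < LV onset < myocardial
#'   onset.
#' @param noise_sigma additive Gaussian noise standard deviation (intensity
#'   units; tissue intensities are on a 0..255-ish scale).
#' @param seed integer RNG seed; the whole phantom is reproducible from it.
#' @param geometry anatomy dimensions in mm; override only for reduced test
#'   scenes.  `deform_amp` adds an optional small radial pulsation of the
#'   myocardial radii (fraction, default 0).
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_frames = 60L, n_pd_frames = 2L,
                           matrix = c(192L, 256L), spacing = c(1.4, 1.4),
                           heart_rate = 75, breathing_rate = 12,
                           motion_amplitude = 6,
                           motion_mode = c("free_breathing", "shallow", "none"),
                           enhancement = NULL, noise_sigma = 4, seed = 1L,
                           geometry = NULL) {
  motion_mode <- match.arg(motion_mode)
  if (heart_rate <= 0 || breathing_rate <= 0) stop("rates must be positive")
  if (motion_amplitude < 0) stop("motion_amplitude must be >= 0")
  if (n_pd_frames >= n_frames) stop("n_pd_frames must be < n_frames")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  dflt_enh <- list(
    rv  = list(onset = 6, amplitude = 180, alpha = 2.5, beta = 1.5, baseline = 50),
    lv  = list(onset = 10, amplitude = 160, alpha = 2.5, beta = 1.8, baseline = 50),
    myo = list(onset = 14, amplitude = 40, alpha = 3.0, beta = 4.0, baseline = 65))
  enhancement <- modifyList(dflt_enh, enhancement %||% list())
  dflt_geom <- list(lv_offset = c(10, 5),      # LV centre offset from image centre (x, y) mm
                    r_endo = 11, r_epi = 23, r_circ = 26,
                    rv_offset = 42,            # RV centre distance from LV centre, -x direction
                    rv_semi = c(16, 12),       # RV ellipse semi-axes (x, y) mm
                    liver_offset = c(-8, 30),  # sub-diaphragmatic mass, moves with breathing
                    liver_semi = c(26, 15),
                    body_frac = c(0.45, 0.42), # chest ellipse semi-axes as FOV fraction
                    deform_amp = 0)
  geometry <- modifyList(dflt_geom, geometry %||% list())
  structure(list(n_frames = as.integer(n_frames),
                 n_pd_frames = as.integer(n_pd_frames),
                 matrix = as.integer(matrix), spacing = as.numeric(spacing),
                 heart_rate = heart_rate, breathing_rate = breathing_rate,
                 motion_amplitude = motion_amplitude, motion_mode = motion_mode,
                 enhancement = enhancement, noise_sigma = noise_sigma,
                 seed = as.integer(seed), geometry = geometry),
            class = "phantom_config")
}

#' Gamma-variate contrast enhancement curve
#'
#' The standard first-pass bolus model: intensity is a baseline plus an
#' amplitude-normalized gamma variate,
#' `A * ((t - t0) / (alpha * beta))^alpha * exp(alpha - (t - t0) / beta)`
#' for `t > t0` and the baseline before the onset.  The curve peaks at
#' `t0 + alpha * beta` with value `baseline + A`.
#'
#' @param params list with `onset` (s), `amplitude`, `alpha`, `beta` (shape
#'   parameters, both positive), `baseline`.
#' @param times numeric vector of increasing times (s).
#' @return intensity vector of `length(times)`.
#' @export
enhancement_curve <- function(params, times) {
  if (any(diff(times) <= 0)) stop("times must be increasing")
  a <- params$alpha; b <- params$beta
  if (is.null(a) || is.null(b) || a <= 0 || b <= 0)
    stop("gamma-variate shape parameters must be positive")
  base <- params$baseline %||% 0
  d <- times - params$onset
  y <- rep(base, length(times))
  up <- d > 0
  y[up] <- base + params$amplitude * (d[up] / (a * b))^a * exp(a - d[up] / b)
  y
}

# smooth random modulation: cubic interpolation through seeded knot noise
smooth_noise <- function(times, n_knots = 5L) {
  kt <- seq(min(times), max(times), length.out = max(n_knots, 2L))
  kv <- rnorm(length(kt))
  stats::spline(kt, kv, xout = times)$y
}

#' Quasi-periodic breathing trajectory
#'
#' Head-foot dominant displacement of the heart: a sinusoid whose amplitude
#' and period drift smoothly over the series (seeded), with a smaller
#' phase-shifted in-plane transverse component (35% of the main amplitude).
#' `motion_mode = "none"` returns zeros; `"shallow"` scales the amplitude to
#' 30%.
#'
#' @param config a [phantom_config] (rates, amplitude, mode, seed).
#' @param times acquisition times in seconds.
#' @return `n x 2` matrix of displacements in mm, columns `(dy, dx)` =
#'   (head-foot/row, transverse/column).
#' @export
breathing_trajectory <- function(config, times) {
  n <- length(times)
  if (config$motion_mode == "none" || config$motion_amplitude == 0)
    return(matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx"))))
  amp <- config$motion_amplitude *
    if (config$motion_mode == "shallow") 0.3 else 1
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(config$seed + 7919L)
  f0 <- config$breathing_rate / 60                      # Hz
  f_t <- f0 * (1 + 0.08 * smooth_noise(times))          # drifting rate
  a_t <- amp * (1 + 0.15 * smooth_noise(times))         # drifting amplitude
  phi0 <- runif(1, 0, 2 * pi)
  dt <- diff(c(times[1], times))
  phase <- 2 * pi * cumsum(f_t * dt) + phi0
  dy <- a_t * sin(phase)
  dx <- 0.35 * a_t * sin(phase + 1.1)
  cbind(dy = dy, dx = dx)
}

# soft-edged ellipse membership in [0, 1]; all lengths in mm
ellipse_alpha <- function(gx, gy, cx, cy, a, b, edge) {
  q <- sqrt(((gx - cx) / a)^2 + ((gy - cy) / b)^2)
  pmin(pmax((1 - q) * min(a, b) / edge + 0.5, 0), 1)
}

circle_polygon <- function(cx, cy, r, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Generate a synthetic perfusion series with ground truth
#'
#' Renders an ellipse-based scene (static chest, RV cavity, LV cavity,
#' myocardial ring) whose compartment intensities follow the configured
#' gamma-variate enhancement curves and whose heart translates along the
#' breathing trajectory.  The first `n_pd_frames` are rendered with a
#' proton-density-like flat bright contrast and no bolus.  Gaussian noise is
#' added everywhere.  The result is bit-reproducible from `config$seed`.
#'
#' Alongside the series the generator returns the exact per-frame
#' segmentation (contours track the motion), the true motion-correcting
#' transforms (a windowed rigid translation: warping frame `t` by its truth
#' transform reproduces the motion-free render up to noise), and the true
#' per-compartment enhancement curves.
#'
#' @param config a [phantom_config].
#' @return `list(series, truth_segmentation, truth_transforms, truth_curves,
#'   trajectory_mm, config)` of class `phantom_result`.
#' @export
generate_series <- function(config) {
  g <- config$geometry
  nr <- config$matrix[1]; nc <- config$matrix[2]
  sp <- config$spacing
  fov <- c(nc * sp[2], nr * sp[1])                       # (x, y) mm
  ctr <- fov / 2
  lv_c <- ctr + g$lv_offset                              # (x, y) mm
  rv_c <- lv_c - c(g$rv_offset, 0)
  edge <- 1.5 * mean(sp)

  dt <- 60 / config$heart_rate
  times <- (seq_len(config$n_frames) - 1L) * dt
  traj <- breathing_trajectory(config, times)            # mm (dy, dx)
  max_d <- max(abs(traj), 0)

  # windowed-translation truth transform geometry (everything that moves —
  # heart and the sub-diaphragmatic mass — must sit inside radius r1)
  r1 <- max(g$rv_offset + g$rv_semi[1], g$r_circ,
            sqrt(sum(g$liver_offset^2)) + max(g$liver_semi)) + max_d + 4
  r2 <- r1 + 12
  body_a <- g$body_frac[1] * fov[1]; body_b <- g$body_frac[2] * fov[2]
  # the heart (and its truth-transform blend zone) must stay inside the chest
  bq <- sqrt(((lv_c[1] - ctr[1]) / body_a)^2 + ((lv_c[2] - ctr[2]) / body_b)^2)
  clearance <- (1 - bq) * min(body_a, body_b)
  if (r2 > clearance)
    stop("anatomy exceeds the matrix: heart + motion range does not fit the chest")

  px <- (seq_len(nc) - 1L) * sp[2]                       # x of pixel centres, mm
  py <- (seq_len(nr) - 1L) * sp[1]
  gx <- matrix(px, nr, nc, byrow = TRUE)
  gy <- matrix(py, nr, nc)

  int_base <- c(air = 5, body = 60, liver = 90)
  pd_int <- c(rv = 150, lv = 150, myo = 145, liver = 140)
  enh <- config$enhancement
  curves <- list(times = times,
                 rv = enhancement_curve(enh$rv, times),
                 lv = enhancement_curve(enh$lv, times),
                 myo = enhancement_curve(enh$myo, times))

  body_alpha <- ellipse_alpha(gx, gy, ctr[1], ctr[2], body_a, body_b, edge)
  background <- int_base["air"] + (int_base["body"] - int_base["air"]) * body_alpha

  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(config$seed)

  render <- function(d_mm, i_rv, i_lv, i_myo, i_liver, r_scale = 1) {
    lv <- lv_c + c(d_mm[2], d_mm[1])                     # traj is (dy, dx)
    rv <- rv_c + c(d_mm[2], d_mm[1])
    li <- lv_c + g$liver_offset + c(d_mm[2], d_mm[1])
    img <- background
    a <- ellipse_alpha(gx, gy, li[1], li[2], g$liver_semi[1], g$liver_semi[2], edge)
    img <- img * (1 - a) + i_liver * a
    a <- ellipse_alpha(gx, gy, rv[1], rv[2], g$rv_semi[1], g$rv_semi[2], edge)
    img <- img * (1 - a) + i_rv * a
    a <- ellipse_alpha(gx, gy, lv[1], lv[2], g$r_epi * r_scale, g$r_epi * r_scale, edge)
    img <- img * (1 - a) + i_myo * a
    a <- ellipse_alpha(gx, gy, lv[1], lv[2], g$r_endo * r_scale, g$r_endo * r_scale, edge)
    img <- img * (1 - a) + i_lv * a
    img
  }

  frames <- array(0, dim = c(nr, nc, config$n_frames))
  seg_frames <- vector("list", config$n_frames)
  transforms <- vector("list", config$n_frames)
  npd <- config$n_pd_frames
  for (t in seq_len(config$n_frames)) {
    d <- traj[t, ]
    r_scale <- 1 + g$deform_amp * sin(2 * pi * times[t] / 3)
    img <- if (t <= npd)
      render(d, pd_int["rv"], pd_int["lv"], pd_int["myo"], pd_int["liver"])
    else
      render(d, curves$rv[t], curves$lv[t], curves$myo[t], int_base["liver"],
             r_scale)
    frames[, , t] <- img + rnorm(nr * nc, sd = config$noise_sigma)

    lv_t <- lv_c + c(d[2], d[1])
    theta0 <- atan2(rv_c[2] - lv_c[2], rv_c[1] - lv_c[1])
    rays_mm <- t(vapply(theta0 + c(0, 2, 4) * pi / 3, function(th)
      lv_t + g$r_circ * c(cos(th), sin(th)), numeric(2)))
    to_px <- function(m) {
      m <- rbind(m)
      cbind(m[, 1] / sp[2], m[, 2] / sp[1])
    }
    seg_frames[[t]] <- segmentation_frame(
      image_ref = sprintf("frame%04d", t),
      star_center = to_px(lv_t),
      star_rays = to_px(rays_mm),
      endo = to_px(circle_polygon(lv_t[1], lv_t[2], g$r_endo * r_scale)),
      epi = to_px(circle_polygon(lv_t[1], lv_t[2], g$r_epi * r_scale)))
    transforms[[t]] <- transform_window_translation(
      d_px = c(d[1] / sp[1], d[2] / sp[2]),
      center_px = c(lv_c[2] / sp[1], lv_c[1] / sp[2]),
      r1_px = r1 / mean(sp), r2_px = r2 / mean(sp),
      domain = c(nr, nc))
  }

  series <- perfusion_series(frames, times = times, spacing = sp, n_pd = npd,
                             patient_id = sprintf("phantom%03d", config$seed),
                             study = if (config$heart_rate > 95) "stress" else "rest",
                             slice_level = "mid")
  segset <- segmentation_set(seg_frames,
                             rv_peak = which.max(curves$rv),
                             lv_peak = which.max(curves$lv),
                             slice_level = 1L)
  structure(list(series = series, truth_segmentation = segset,
                 truth_transforms = transforms, truth_curves = curves,
                 trajectory_mm = traj, config = config),
            class = "phantom_result")
}
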
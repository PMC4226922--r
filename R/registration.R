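#' Transform fields
#'
#' A `transform_field` maps coordinates of the target (registered) image to
#' coordinates of the source image: applying it to an image is the pull-back
#' `out(x) = img(x + u(x))`; applying it to points maps them forward,
#' `p -> p + u(p)`.  Displacements `u` are expressed in full-resolution
#' pixels, `(row, col)` order, 0-based coordinates.
#'
#' Three parameterizations exist: a cubic B-spline free-form deformation on a
#' uniform knot grid (`transform_bspline`; zero coefficients give the
#' identity), a dense per-pixel field (`transform_dense`, used for composed
#' multi-pass transforms), and a windowed rigid translation
#' (`transform_window_translation`, the phantom's ground truth: constant
#' displacement inside radius `r1`, smoothstep falloff to zero at `r2`).
#'
#' B-spline transforms computed on a cropped and/or downscaled working region
#' carry `origin` (full-res offset of the crop) and `scale` (working pixels
#' per full-res pixel); outside the crop the displacement is zero.
#'
#' @param cy,cx coefficient grids (displacement in working pixels).
#' @param h knot spacing in working pixels.
#' @param domain full-resolution `(rows, cols)` of the region covered.
#' @param scale working pixels per full-resolution pixel (1 or 0.5 typically).
#' @param origin full-resolution `(row, col)` offset of the covered region.
#' @return an object of class `transform_field`.
#' @export
transform_bspline <- function(cy, cx, h, domain, scale = 1, origin = c(0L, 0L)) {
  structure(list(type = "bspline", cy = cy, cx = cx, h = h,
                 domain = as.integer(domain), scale = scale,
                 origin = as.numeric(origin)),
            class = "transform_field")
}

#' @rdname transform_bspline
#' @param uy,ux dense displacement fields (full-resolution pixels).
#' @export
transform_dense <- function(uy, ux) {
  structure(list(type = "dense", uy = uy, ux = ux,
                 domain = dim(uy), scale = 1, origin = c(0, 0)),
            class = "transform_field")
}

#' @rdname transform_bspline
#' @param d_px displacement `(dy, dx)` in pixels.
#' @param center_px window centre `(row, col)`.
#' @param r1_px,r2_px inner (full displacement) and outer (zero) radii, px.
#' @export
transform_window_translation <- function(d_px, center_px, r1_px, r2_px, domain) {
  structure(list(type = "window_translation", d_px = as.numeric(d_px),
                 center_px = as.numeric(center_px), r1_px = r1_px,
                 r2_px = r2_px, domain = as.integer(domain),
                 scale = 1, origin = c(0, 0)),
            class = "transform_field")
}

#' @rdname transform_bspline
#' @export
transform_identity <- function(domain)
  transform_dense(matrix(0, domain[1], domain[2]), matrix(0, domain[1], domain[2]))

#' @export
print.transform_field <- function(x, ...) {
  cat(sprintf("<transform_field:%s> domain %dx%d", x$type, x$domain[1], x$domain[2]))
  if (x$type == "bspline")
    cat(sprintf(", knots %dx%d (h = %g working px, scale %g)",
                nrow(x$cy), ncol(x$cy), x$h, x$scale))
  cat("\n")
  invisible(x)
}

#' Evaluate the displacement of a transform
#'
#' @param transform a `transform_field`.
#' @param points optional `n x 2` matrix of full-resolution `(row, col)`
#'   coordinates; by default the displacement is evaluated on the full pixel
#'   grid of `shape`.
#' @param shape `(rows, cols)` of the grid evaluation (defaults to the
#'   transform's domain).
#' @return for grid evaluation `list(uy, ux)` matrices; for `points` an
#'   `n x 2` matrix of `(dy, dx)` displacements in pixels.
#' @export
eval_displacement <- function(transform, points = NULL, shape = NULL) {
  tf <- transform
  grid_mode <- is.null(points)
  if (grid_mode) {
    if (is.null(shape)) shape <- tf$domain
    pts_r <- rep(seq_len(shape[1]) - 1, times = shape[2])
    pts_c <- rep(seq_len(shape[2]) - 1, each = shape[1])
  } else {
    points <- rbind(points)
    pts_r <- points[, 1]; pts_c <- points[, 2]
  }
  n <- length(pts_r)
  if (tf$type == "dense") {
    uy <- cpp_interp2_bilinear(tf$uy, pts_r, pts_c)
    ux <- cpp_interp2_bilinear(tf$ux, pts_r, pts_c)
    out <- which(pts_r < 0 | pts_r > tf$domain[1] - 1 |
                   pts_c < 0 | pts_c > tf$domain[2] - 1)
    uy[out] <- 0; ux[out] <- 0
  } else if (tf$type == "window_translation") {
    r <- sqrt((pts_r - tf$center_px[1])^2 + (pts_c - tf$center_px[2])^2)
    s <- pmin(pmax((r - tf$r1_px) / (tf$r2_px - tf$r1_px), 0), 1)
    w <- 1 - (3 * s^2 - 2 * s^3)
    uy <- tf$d_px[1] * w; ux <- tf$d_px[2] * w
  } else {
    lr <- (pts_r - tf$origin[1]) * tf$scale
    lc <- (pts_c - tf$origin[2]) * tf$scale
    d <- cpp_eval_bspline_disp(tf$cy, tf$cx, tf$h, lr, lc)
    uy <- d$uy / tf$scale; ux <- d$ux / tf$scale
    wlim <- (tf$domain - 1) * tf$scale
    out <- which(lr < 0 | lr > wlim[1] | lc < 0 | lc > wlim[2])
    uy[out] <- 0; ux[out] <- 0
  }
  if (grid_mode)
    list(uy = matrix(uy, shape[1], shape[2]), ux = matrix(ux, shape[1], shape[2]))
  else cbind(dy = uy, dx = ux)
}

#' Apply a transform to an image, mask or point set
#'
#' Images are resampled with cubic interpolation (constant border extension),
#' masks with nearest-neighbour lookup (samples leaving the domain become 0;
#' a transformed mask that contains no pixel is flagged with
#' `attr(, "empty") = TRUE`), and points are mapped forward `p -> p + u(p)`.
#'
#' @param transform a `transform_field`.
#' @param x a numeric matrix (image), an integer/logical matrix passed with
#'   `type = "mask"`, or an `n x 2` matrix of `(row, col)` points with
#'   `type = "points"`.
#' @param type one of `"image"`, `"mask"`, `"points"`.
#' @return the transformed object of the same kind.
#' @export
apply_transform <- function(transform, x, type = c("image", "mask", "points")) {
  type <- match.arg(type)
  if (type == "points") {
    d <- eval_displacement(transform, points = x)
    return(rbind(x) + d)
  }
  u <- eval_displacement(transform, shape = dim(x))
  if (type == "image") return(cpp_warp_image(x, u$uy, u$ux))
  m <- cpp_warp_mask(matrix(as.integer(x), nrow(x), ncol(x)), u$uy, u$ux)
  if (!any(m != 0L)) attr(m, "empty") <- TRUE
  m
}

#' Compose two transforms
#'
#' Returns a dense transform equivalent to applying `first` and then `second`
#' (pull-back order): `u(x) = u2(x) + u1(x + u2(x))`.
#'
#' @param first,second `transform_field`s sharing the full-resolution domain.
#' @param shape evaluation grid, defaults to `second$domain`.
#' @export
compose_transforms <- function(first, second, shape = NULL) {
  if (is.null(shape)) shape <- second$domain
  u2 <- eval_displacement(second, shape = shape)
  pr <- rep(seq_len(shape[1]) - 1, times = shape[2]) + as.vector(u2$uy)
  pc <- rep(seq_len(shape[2]) - 1, each = shape[1]) + as.vector(u2$ux)
  d1 <- eval_displacement(first, points = cbind(pr, pc))
  transform_dense(u2$uy + matrix(d1[, 1], shape[1], shape[2]),
                  u2$ux + matrix(d1[, 2], shape[1], shape[2]))
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) if (is.null(m)) NULL else as.matrix(m)
  switch(o$type,
    bspline = transform_bspline(as_mat(o$cy), as_mat(o$cx), o$h, o$domain,
                                o$scale, o$origin),
    dense = transform_dense(as_mat(o$uy), as_mat(o$ux)),
    window_translation = transform_window_translation(o$d_px, o$center_px,
                                                      o$r1_px, o$r2_px, o$domain),
    stop("unknown transform type: ", o$type))
}

#' Serialize a transform to structured text (JSON)
#'
#' @param transform a `transform_field`.
#' @param path file path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Registration configuration
#'
#' Defaults follow the published parameterization of the two pipelines: the
#' ICA-SP stage uses SSD with curvature weight `kappa = 10`, knot spacing 16
#' at working scale 0.5, 3 multi-resolution levels and a limited-memory
#' quasi-Newton optimizer (at most 300 iterations, 1e-3 relative
#' objective-function tolerance, 1e-3 absolute x-tolerance); the QUASI-P
#' stages use `kappa = 0.1`, knot spacing 5 at full scale, 3 levels and
#' adaptive-step gradient descent (start step 0.01 px, stopping epsilon
#' 0.01 px).
#'
#' @param measure `"ssd"` or `"ngf"`.
#' @param kappa curvature regularization weight (>= 0).
#' @param knot_spacing B-spline knot spacing in working pixels.
#' @param scale working scale applied to the images before registration
#'   (1, 0.5 or 0.25).
#' @param levels multi-resolution levels (>= 1).
#' @param optimizer `"quasi_newton"` or `"gradient_descent"`.
#' @param max_iter,f_tol,x_tol quasi-Newton breaking conditions.
#' @param start_step,epsilon gradient-descent step control (pixels).
#' @param eta NGF noise parameter; `"auto"` estimates it per level as the
#'   median gradient magnitude of the reference.
#' @export
reg_config <- function(measure = c("ssd", "ngf"), kappa = 10, knot_spacing = 16,
                       scale = 0.5, levels = 3L,
                       optimizer = c("quasi_newton", "gradient_descent"),
                       max_iter = 300L, f_tol = 1e-3, x_tol = 1e-3,
                       start_step = 0.01, epsilon = 0.01, eta = "auto") {
  measure <- match.arg(measure)
  optimizer <- match.arg(optimizer)
  if (kappa < 0) stop("kappa must be >= 0")
  if (levels < 1L) stop("levels must be >= 1")
  if (!scale %in% c(1, 0.5, 0.25)) stop("scale must be 1, 0.5 or 0.25")
  list(measure = measure, kappa = kappa, knot_spacing = knot_spacing,
       scale = scale, levels = as.integer(levels), optimizer = optimizer,
       max_iter = as.integer(max_iter), f_tol = f_tol, x_tol = x_tol,
       start_step = start_step, epsilon = epsilon, eta = eta)
}

ngf_auto_eta <- function(img) {
  gy <- (rbind(img[-1, , drop = FALSE], img[nrow(img), ]) -
           rbind(img[1, ], img[-nrow(img), , drop = FALSE])) / 2
  gx <- (cbind(img[, -1, drop = FALSE], img[, ncol(img)]) -
           cbind(img[, 1], img[, -ncol(img), drop = FALSE])) / 2
  e <- median(sqrt(gy^2 + gx^2))
  if (e <= 0) e <- 1e-3 * max(abs(img), 1e-12)
  e
}

measure_code <- function(measure) if (measure == "ngf") 1L else 0L

#' Similarity and penalty costs with coefficient gradients
#'
#' `ssd_cost` is half the mean squared intensity difference between the
#' warped moving image and the reference; `ngf_cost` is the normalized
#' gradient field misalignment `mean(1 - <n(M), n(R)>^2)` with
#' `n(I) = grad(I) / sqrt(|grad(I)|^2 + eta^2)`, insensitive to monotone
#' intensity rescaling; `curvature_penalty` is the discrete second-derivative
#' (bending) energy of the displacement, zero for any affine field.
#' Gradients are with respect to the B-spline coefficients of `transform`.
#'
#' @param moving,reference equally shaped numeric matrices.
#' @param transform a B-spline `transform_field`; `NULL` means identity with
#'   knot spacing `h`.
#' @param h knot spacing used to build the identity transform.
#' @param kappa curvature weight added to the returned cost (0 = measure
#'   only).
#' @param want_grad return coefficient gradients `gcy`, `gcx`.
#' @return `list(cost, gcy, gcx)` (gradients only when requested).
#' @export
ssd_cost <- function(moving, reference, transform = NULL, h = 16, kappa = 0,
                     want_grad = TRUE) {
  measure_cost(moving, reference, transform, h, kappa, "ssd", 0, want_grad)
}

#' @rdname ssd_cost
#' @param eta NGF noise parameter (`"auto"` = median gradient magnitude of
#'   the reference).
#' @export
ngf_cost <- function(moving, reference, eta = "auto", transform = NULL, h = 16,
                     kappa = 0, want_grad = FALSE) {
  if (identical(eta, "auto")) eta <- ngf_auto_eta(reference)
  if (eta <= 0) stop("eta must be positive")
  measure_cost(moving, reference, transform, h, kappa, "ngf", eta, want_grad)
}

measure_cost <- function(moving, reference, transform, h, kappa, measure, eta,
                         want_grad) {
  if (!identical(dim(moving), dim(reference))) stop("image shape mismatch")
  if (is.null(transform)) {
    ngy <- cpp_bspline_grid_dim(nrow(moving), h)
    ngx <- cpp_bspline_grid_dim(ncol(moving), h)
    transform <- transform_bspline(matrix(0, ngy, ngx), matrix(0, ngy, ngx),
                                   h, dim(moving))
  }
  if (transform$type != "bspline")
    stop("cost gradients require a B-spline transform")
  out <- cpp_reg_cost_grad(transform$cy, transform$cx, moving, reference,
                           transform$h, 1, kappa, measure_code(measure), eta,
                           want_grad)
  if (!is.finite(out$cost)) stop("non-finite registration cost")
  out
}

#' @rdname ssd_cost
#' @export
curvature_penalty <- function(transform, want_grad = TRUE) {
  if (transform$type != "bspline")
    stop("curvature penalty is defined for B-spline transforms")
  wshape <- ceiling(transform$domain * transform$scale)
  cpp_curv_cost_grad(transform$cy, transform$cx, transform$h,
                     wshape[1], wshape[2], want_grad)
}

# adaptive-step gradient descent: steps along -g/|g|_inf so `step` is the
# maximum coefficient change in pixels; grows moderately on success, halves
# on failure, stops when step < epsilon or max_iter is reached.  The gradient
# is evaluated once per accepted position and reused across step halvings.
optim_gradient_descent <- function(par, fn, gr, start_step, epsilon, max_iter) {
  f <- fn(par)
  g <- gr(par)
  step <- start_step
  it <- 0L
  while (it < max_iter) {
    gmax <- max(abs(g))
    if (gmax == 0) break
    trial <- par - step * g / gmax
    ft <- fn(trial)
    if (ft < f) {
      par <- trial; f <- ft
      g <- gr(par)
      step <- min(step * 2, 4)
    } else {
      step <- step / 2
      if (step < epsilon) break
    }
    it <- it + 1L
  }
  list(par = par, value = f, iterations = it)
}

#' Non-linear B-spline registration
#'
#' Registers `moving` to `reference` by minimizing
#' `measure + kappa * curvature` over the coefficients of a cubic B-spline
#' free-form deformation, coarse-to-fine over `config$levels` resolution
#' levels (a single coefficient grid is optimized throughout; coarse levels
#' see block-averaged images).  Images are pre-scaled by `config$scale` and
#' jointly normalized to the reference intensity range so the published
#' `kappa` weights are meaningful.  Deterministic given its inputs.
#'
#' @param moving,reference equally shaped numeric matrices.
#' @param config a [reg_config()].
#' @return a B-spline `transform_field` mapping reference coordinates into
#'   `moving` (apply it to `moving` to align it with `reference`), with
#'   attributes `initial_cost` and `final_cost` (identity and final
#'   objective value at the finest level; the final value never exceeds the
#'   identity's — a candidate costing more than the identity is discarded).
#' @export
register <- function(moving, reference, config = reg_config()) {
  if (!identical(dim(moving), dim(reference))) stop("image shape mismatch")
  full_shape <- dim(moving)
  rng <- range(reference)
  den <- if (diff(rng) > 0) diff(rng) else 1
  mov <- (moving - rng[1]) / den
  ref <- (reference - rng[1]) / den

  # curvature weights are calibrated against the [0,1]-normalized SSD scale
  # (~1e-2); the NGF misalignment measure is O(1) per pixel, about 100x
  # larger, so the same weight would under-regularize by that factor
  kappa <- config$kappa * if (config$measure == "ngf") 100 else 1

  n_half <- round(log2(1 / config$scale))
  for (k in seq_len(n_half)) {
    mov <- cpp_downsample2(mov); ref <- cpp_downsample2(ref)
  }
  wshape <- dim(mov)
  h <- config$knot_spacing
  ngy <- cpp_bspline_grid_dim(wshape[1], h)
  ngx <- cpp_bspline_grid_dim(wshape[2], h)
  npar <- ngy * ngx

  pyr_m <- list(mov); pyr_r <- list(ref)
  for (lev in seq_len(config$levels - 1L)) {
    pyr_m[[lev + 1L]] <- cpp_downsample2(pyr_m[[lev]])
    pyr_r[[lev + 1L]] <- cpp_downsample2(pyr_r[[lev]])
  }

  par <- numeric(2L * npar)
  split_par <- function(p)
    list(cy = matrix(p[seq_len(npar)], ngy, ngx),
         cx = matrix(p[npar + seq_len(npar)], ngy, ngx))
  eta_fine <- 0

  for (lev in seq.int(config$levels, 1L)) {
    fac <- 2^(lev - 1L)
    m <- pyr_m[[lev]]; r <- pyr_r[[lev]]
    eta <- 0
    if (config$measure == "ngf") {
      # registration needs eta well above the noise-gradient scale: warping
      # smooths the noise, and with a small eta that systematic change in the
      # flat-region gradient statistics swamps the alignment signal
      eta <- if (identical(config$eta, "auto")) 4 * ngf_auto_eta(r)
             else config$eta / den
    }
    cache <- new.env(parent = emptyenv())
    evalfg <- function(p, grad) {
      key <- if (grad) "g" else "f"
      hit <- !is.null(cache$par) && identical(cache$par, p)
      if (hit && !is.null(cache[[key]])) return(cache[[key]])
      cf <- split_par(p)
      out <- cpp_reg_cost_grad(cf$cy, cf$cx, m, r, h, fac, kappa,
                               measure_code(config$measure), eta, grad)
      if (!is.finite(out$cost))
        stop("non-finite registration cost at level ", lev)
      if (!hit) cache$g <- NULL
      cache$par <- p
      cache$f <- out$cost
      if (grad) cache$g <- c(out$gcy, out$gcx)
      cache[[key]]
    }
    fn <- function(p) evalfg(p, FALSE)
    gr <- function(p) evalfg(p, TRUE)
    if (lev == 1L) eta_fine <- eta
    if (config$optimizer == "quasi_newton") {
      # scale the objective to ~1 at the level start so L-BFGS-B's factr
      # criterion (which compares against max(|f|, 1)) realizes the intended
      # relative objective-function tolerance
      f0 <- max(fn(par), .Machine$double.xmin)
      res <- optim(par, function(p) fn(p) / f0, function(p) gr(p) / f0,
                   method = "L-BFGS-B",
                   control = list(maxit = config$max_iter,
                                  factr = config$f_tol / .Machine$double.eps,
                                  pgtol = 0))
      cand <- res$par; cval <- res$value * f0
    } else {
      res <- optim_gradient_descent(par, fn, gr, config$start_step,
                                    config$epsilon, config$max_iter)
      cand <- res$par; cval <- res$value
    }
    # per-level descent contract: never accept a cost increase
    if (cval <= fn(par)) par <- cand
  }

  # global descent contract at the finest level: a "registration" that costs
  # more than the identity is discarded
  cost_fine <- function(p) {
    cf <- split_par(p)
    cpp_reg_cost_grad(cf$cy, cf$cx, pyr_m[[1]], pyr_r[[1]], h, 1, kappa,
                      measure_code(config$measure), eta_fine, FALSE)$cost
  }
  init_cost <- cost_fine(numeric(2L * npar))
  final_cost <- cost_fine(par)
  if (final_cost > init_cost) {
    par <- numeric(2L * npar)
    final_cost <- init_cost
  }

  cf <- split_par(par)
  out <- transform_bspline(cf$cy, cf$cx, h, full_shape, scale = config$scale)
  attr(out, "initial_cost") <- init_cost
  attr(out, "final_cost") <- final_cost
  out
}
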
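fd_gradient <- function(fun, par, eps = 1e-5) {
  vapply(seq_along(par), function(i) {
    p1 <- par; p1[i] <- p1[i] + eps
    p2 <- par; p2[i] <- p2[i] - eps
    (fun(p1) - fun(p2)) / (2 * eps)
  }, numeric(1))
}

make_tf <- function(shape, h, sd = 0) {
  ngy <- perfmoco:::cpp_bspline_grid_dim(shape[1], h)
  ngx <- perfmoco:::cpp_bspline_grid_dim(shape[2], h)
  transform_bspline(matrix(rnorm(ngy * ngx, sd = sd), ngy, ngx),
                    matrix(rnorm(ngy * ngx, sd = sd), ngy, ngx), h, shape)
}

test_that("ssd_cost closed forms", {
  img <- matrix(runif(20 * 24), 20, 24)
  expect_equal(ssd_cost(img, img, want_grad = FALSE)$cost, 0)
  # constant offset c: cost = c^2 / 2
  expect_equal(ssd_cost(img + 3, img, want_grad = FALSE)$cost, 9 / 2,
               tolerance = 1e-12)
  expect_error(ssd_cost(img, img[1:10, ]), "mismatch")
})

test_that("SSD and curvature gradients match central finite differences", {
  set.seed(21)
  for (k in 1:20) {
    shape <- c(sample(12:32, 1), sample(12:32, 1))
    h <- sample(4:8, 1)
    mov <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    ref <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    tf <- make_tf(shape, h, sd = 0.4)
    kappa <- runif(1, 0, 2)
    out <- perfmoco:::cpp_reg_cost_grad(tf$cy, tf$cx, mov, ref, h, 1, kappa,
                                        0L, 0, TRUE)
    par <- c(tf$cy, tf$cx)
    np <- length(tf$cy)
    fun <- function(p)
      perfmoco:::cpp_reg_cost_grad(matrix(p[1:np], nrow(tf$cy)),
                                   matrix(p[np + 1:np], nrow(tf$cy)),
                                   mov, ref, h, 1, kappa, 0L, 0, FALSE)$cost
    num <- fd_gradient(fun, par)
    expect_lt(max(abs(num - c(out$gcy, out$gcx))) / max(abs(num)), 1e-4)
  }
})

test_that("curvature penalty is zero for affine displacements", {
  shape <- c(24, 30)
  tf <- make_tf(shape, 6)
  expect_equal(curvature_penalty(tf, want_grad = FALSE)$cost, 0)
  # pure translation: constant coefficients
  tf$cy[] <- 2.5; tf$cx[] <- -1.25
  expect_equal(curvature_penalty(tf, want_grad = FALSE)$cost, 0, tolerance = 1e-20)
  # affine ramp in the coefficients gives an affine displacement field
  tf$cy <- outer(seq_len(nrow(tf$cy)), seq_len(ncol(tf$cy)),
                 function(i, j) 0.3 * i - 0.1 * j)
  tf$cx <- outer(seq_len(nrow(tf$cx)), seq_len(ncol(tf$cx)),
                 function(i, j) 0.05 * i + 0.2 * j)
  expect_lt(curvature_penalty(tf, want_grad = FALSE)$cost, 1e-18)
})

test_that("curvature penalty matches a brute-force bending energy", {
  set.seed(5)
  shape <- c(18, 22)
  tf <- make_tf(shape, 5, sd = 0.8)
  u <- eval_displacement(tf, shape = shape)
  bend <- function(f) {
    nr <- nrow(f); nc <- ncol(f)
    dyy <- f[-c(1, 2), ] - 2 * f[-c(1, nr), ] + f[-c(nr - 1, nr), ]
    dxx <- f[, -c(1, 2)] - 2 * f[, -c(1, nc)] + f[, -c(nc - 1, nc)]
    dxy <- (f[-c(1, 2), -c(1, 2)] - f[-c(1, 2), -c(nc - 1, nc)] -
              f[-c(nr - 1, nr), -c(1, 2)] + f[-c(nr - 1, nr), -c(nc - 1, nc)]) / 4
    sum(dyy^2) + sum(dxx^2) + 2 * sum(dxy^2)
  }
  expected <- (bend(u$uy) + bend(u$ux)) / prod(shape)
  expect_equal(curvature_penalty(tf, want_grad = FALSE)$cost, expected,
               tolerance = 1e-6)
})

test_that("NGF cost behaves as an intensity-robust alignment measure", {
  set.seed(3)
  img <- matrix(0, 32, 32)
  img[10:22, 10:22] <- 5
  img <- perfmoco:::cpp_downsample2(img)  # smooth edges a little
  self <- ngf_cost(img, img, eta = 0.1)$cost
  # global intensity scaling changes the cost by < 1%
  scaled <- ngf_cost(2 * img, img, eta = 0.1)$cost
  expect_lt(abs(scaled - self) / self, 0.01)
  # misaligned gradients cost strictly more
  rot <- t(img)[, rev(seq_len(ncol(img)))]   # 90 degree rotation
  shifted <- img[c(4:16, 1:3), ]
  expect_gt(ngf_cost(shifted, img, eta = 0.1)$cost, self)
  expect_error(ngf_cost(img, img, eta = -1), "positive")
})

test_that("register recovers identity and known translations", {
  ph <- small_phantom(seed = 3, motion_mode = "none", n_frames = 8)
  img <- ph$series$data[, , 6]
  rc <- reg_config(measure = "ssd", kappa = 10, knot_spacing = 16, scale = 1,
                   levels = 3)
  # moving == reference -> stays at identity
  tf0 <- register(img, img, rc)
  u0 <- eval_displacement(tf0, shape = dim(img))
  expect_lt(max(abs(c(u0$uy, u0$ux))), 0.1)
  # known 3 px translation
  shift <- transform_dense(matrix(3, nrow(img), ncol(img)),
                           matrix(0, nrow(img), ncol(img)))
  mov <- apply_transform(shift, img)
  tf <- register(mov, img, rc)
  u <- eval_displacement(tf, shape = dim(img))
  centre <- u$uy[25:75, 30:100]
  expect_lt(abs(mean(centre) + 3), 0.5)
  # descent contract
  expect_lte(attr(tf, "final_cost"), attr(tf, "initial_cost"))
})

test_that("translation-recovery bias stays below 0.5 px over 10 noisy frames", {
  rc <- reg_config(measure = "ssd", kappa = 10, knot_spacing = 16, scale = 1,
                   levels = 3)
  errs <- vapply(1:10, function(seed) {
    ph <- tiny_phantom(seed = seed, motion_mode = "none", n_frames = 6)
    img <- ph$series$data[, , 5]
    shift <- transform_dense(matrix(2, nrow(img), ncol(img)),
                             matrix(0, nrow(img), ncol(img)))
    mov <- apply_transform(shift, img)
    tf <- register(mov, img, rc)
    u <- eval_displacement(tf, shape = dim(img))
    mean(u$uy[20:55, 25:75]) + 2
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.5)
})

test_that("gradient-descent registration honours the descent contract", {
  ph <- tiny_phantom(seed = 9, motion_mode = "none", n_frames = 6)
  a <- ph$series$data[, , 4]; b <- ph$series$data[, , 6]
  rc <- reg_config(measure = "ssd", kappa = 0.1, knot_spacing = 5, scale = 1,
                   levels = 3, optimizer = "gradient_descent")
  tf <- register(a, b, rc)
  expect_lte(attr(tf, "final_cost"), attr(tf, "initial_cost"))
})

test_that("apply_transform handles images, masks and points", {
  img <- matrix(rnorm(30 * 40), 30, 40)
  id <- transform_identity(c(30, 40))
  expect_equal(apply_transform(id, img), img, tolerance = 1e-12)
  # translation moves points forward
  tr <- transform_dense(matrix(0, 30, 40), matrix(5, 30, 40))
  p <- apply_transform(tr, cbind(10, 7), type = "points")
  expect_equal(as.numeric(p), c(10, 12))
  # mask pushed outside the domain comes back empty and flagged
  mask <- matrix(0L, 30, 40); mask[2:4, 2:4] <- 1L
  big <- transform_dense(matrix(200, 30, 40), matrix(0, 30, 40))
  out <- apply_transform(big, mask, type = "mask")
  expect_true(isTRUE(attr(out, "empty")))
  expect_equal(sum(out), 0)
})

test_that("transforms compose in application order", {
  set.seed(8)
  img <- apply_transform(transform_identity(c(24, 24)),
                         matrix(cumsum(rnorm(24 * 24)), 24, 24))
  t1 <- transform_dense(matrix(2, 24, 24), matrix(0, 24, 24))
  t2 <- transform_dense(matrix(0, 24, 24), matrix(3, 24, 24))
  once <- apply_transform(t2, apply_transform(t1, img))
  comp <- apply_transform(compose_transforms(t1, t2), img)
  # interiors agree (borders differ by clamping order)
  expect_equal(comp[5:20, 5:18], once[5:20, 5:18], tolerance = 1e-8)
})

test_that("transform serialization round trips", {
  set.seed(2)
  tf <- make_tf(c(20, 24), 6, sd = 0.5)
  tf$scale <- 0.5; tf$origin <- c(3, 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(tf, path)
  tf2 <- read_transform(path)
  expect_equal(tf2$cy, tf$cy, tolerance = 1e-12)
  expect_equal(tf2$scale, tf$scale)
  expect_equal(tf2$origin, tf$origin)
  u1 <- eval_displacement(tf, shape = c(20, 24))
  u2 <- eval_displacement(tf2, shape = c(20, 24))
  expect_equal(u1, u2, tolerance = 1e-12)
})
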
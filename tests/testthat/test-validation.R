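test_that("intensity_curve averages over masks frame by frame", {
  arr <- array(7, dim = c(6, 6, 4))
  s <- perfusion_series(arr, times = 0:3, n_pd = 0L)
  mask <- matrix(0L, 6, 6); mask[2:4, 2:4] <- 1L
  expect_equal(intensity_curve(s, mask), rep(7, 4))
  # single-pixel mask returns that pixel's trajectory
  arr2 <- arr; arr2[3, 3, ] <- 1:4
  s2 <- perfusion_series(arr2, times = 0:3, n_pd = 0L)
  single <- matrix(0L, 6, 6); single[3, 3] <- 1L
  expect_equal(intensity_curve(s2, single), 1:4 + 0)
  # empty mask -> NA at that frame
  masks <- c(rep(list(mask), 3), list(matrix(0L, 6, 6)))
  expect_equal(is.na(intensity_curve(s, masks)), c(FALSE, FALSE, FALSE, TRUE))
  expect_error(intensity_curve(s, masks[1:2]), "one mask per frame")
})

test_that("phantom truth masks reproduce the myocardial enhancement curve", {
  ph <- small_phantom(seed = 13, n_frames = 25)
  s <- strip_proton_density(ph$series)
  segs <- perfmoco:::seg_strip_pd(ph$truth_segmentation, 2)
  shape <- dim(s$data)[1:2]
  masks <- lapply(segs$frames, function(fr) erode1(myocardium_mask(fr, shape)))
  curve <- intensity_curve(s, masks)
  truth <- ph$truth_curves$myo[-(1:2)]
  n <- sum(masks[[1]])
  expect_lt(max(abs(curve - truth)), 4 * ph$config$noise_sigma / sqrt(n) + 0.5)
})

test_that("nmse matches its closed forms and a brute-force evaluation", {
  set.seed(17)
  gt <- rnorm(20, 10, 3)
  expect_equal(nmse(gt, gt), 0)
  # curve = gt + c
  cc <- 1.7
  expect_equal(nmse(gt + cc, gt), 20 * cc^2 / sum((gt - mean(gt))^2),
               tolerance = 1e-12)
  # constant curve at the ground-truth mean scores exactly 1
  expect_equal(nmse(rep(mean(gt), 20), gt), 1, tolerance = 1e-12)
  # brute force on random pairs
  for (k in 1:50) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(nmse(a, b), sum((a - b)^2) / sum((b - mean(b))^2),
                 tolerance = 1e-12)
  }
  expect_warning(expect_true(is.na(nmse(gt, rep(1, 20)))), "constant")
  expect_error(nmse(1:3, 1:4), "equal length")
})

test_that("pearson_cc matches cor and implements the empty-mask rule", {
  set.seed(18)
  gt <- rnorm(30)
  expect_equal(pearson_cc(2 * gt + 1, gt), 1)
  expect_equal(pearson_cc(-gt, gt), -1)
  for (k in 1:50) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(pearson_cc(a, b), cor(a, b), tolerance = 1e-12)
  }
  # an empty transformed mask scores exactly 0
  expect_identical(pearson_cc(rep(NA_real_, 30), gt), 0)
  expect_warning(expect_identical(pearson_cc(rep(1, 30), gt), 0), "zero-variance")
})

test_that("build_curves identities: motion-free and identity transforms", {
  ph <- small_phantom(seed = 3, motion_mode = "none", n_frames = 20)
  s <- strip_proton_density(ph$series)
  segs <- perfmoco:::seg_strip_pd(ph$truth_segmentation, 2)
  shape <- dim(s$data)[1:2]
  id <- lapply(seq_len(n_frames(s)), function(i) transform_identity(shape))
  cur <- build_curves(s, s, segs, id)
  # no motion: per-frame masks equal the key-frame masks -> K_org == K_gt
  expect_equal(cur$K_org, cur$K_gt, tolerance = 1e-12)
  # identity transforms on the same series -> K_reg == K_org
  expect_equal(cur$K_reg, cur$K_org, tolerance = 1e-12)
  expect_equal(cur$key_frame_index, segs$lv_peak)
  segs_na <- segs; segs_na$lv_peak <- NA_integer_
  expect_error(build_curves(s, NULL, segs_na), "LV-peak")
})

test_that("truth transforms act as a perfect registration", {
  for (seed in c(2, 9)) {
    ph <- small_phantom(seed = seed, n_frames = 30)
    s <- strip_proton_density(ph$series)
    segs <- perfmoco:::seg_strip_pd(ph$truth_segmentation, 2)
    tfs <- ph$truth_transforms[-(1:2)]
    regdata <- s$data
    for (t in seq_len(n_frames(s)))
      regdata[, , t] <- apply_transform(tfs[[t]], s$data[, , t])
    reg <- perfmoco:::series_with_data(s, regdata)
    cur <- build_curves(s, reg, segs, tfs)
    sc <- score_curves(cur, method = "truth")
    m <- function(ph_, ms) mean(sc$value[sc$phase == ph_ & sc$measure == ms],
                                na.rm = TRUE)
    # perfect-registration limit: at least as good as unregistered
    expect_gte(m("truth", "R2"), m("unregistered", "R2"))
    expect_lte(m("truth", "NMSE"), m("unregistered", "NMSE"))
    # and close to the ground truth itself
    expect_gt(m("truth", "R2"), 0.97)
    expect_lt(m("truth", "NMSE"), 0.12)
  }
})

test_that("summarize_scores matches a brute-force recomputation", {
  one <- data.frame(patient = "p", slice = "mid", study = "rest", section = 1,
                    measure = "NMSE", phase = "unregistered", value = 3.5)
  s1 <- summarize_scores(one, split_study = FALSE)
  expect_equal(unlist(s1[1, c("mean", "variation", "median", "min", "max")]),
               c(mean = 3.5, variation = 0, median = 3.5, min = 3.5, max = 3.5))
  two <- rbind(one, transform(one, section = 2, value = 0))
  s2 <- summarize_scores(two, split_study = FALSE)
  expect_equal(s2$mean, 1.75)
  expect_equal(s2$median, 1.75)
  set.seed(19)
  for (k in 1:200) {
    n <- sample(3:12, 1)
    tab <- data.frame(patient = "p", slice = "mid",
                      study = sample(c("rest", "stress"), n, replace = TRUE),
                      section = seq_len(n), measure = "R2",
                      phase = "unregistered", value = rnorm(n))
    sm <- summarize_scores(tab)
    all_row <- sm[sm$study == "all", ]
    expect_equal(all_row$mean, mean(tab$value), tolerance = 1e-12)
    expect_equal(all_row$variation, sd(tab$value), tolerance = 1e-12)
    expect_equal(all_row$median, median(tab$value), tolerance = 1e-12)
    expect_equal(all_row$min, min(tab$value))
    expect_equal(all_row$max, max(tab$value))
    for (st in c("rest", "stress")) {
      v <- tab$value[tab$study == st]
      if (length(v) == 0) next
      row <- sm[sm$study == st, ]
      expect_equal(row$mean, mean(v), tolerance = 1e-12)
    }
  }
})

test_that("summarize_scores can exclude failed series", {
  tab <- rbind(
    data.frame(patient = "a", slice = "mid", study = "rest", section = 1:3,
               measure = "NMSE", phase = "QUASI-P", value = c(1, 2, 3)),
    data.frame(patient = "b", slice = "mid", study = "rest", section = 1:3,
               measure = "NMSE", phase = "QUASI-P", value = c(10, 10, 10)))
  excl <- data.frame(patient = "b", slice = "mid", study = "rest")
  sm <- summarize_scores(tab, split_study = FALSE, exclude = excl)
  expect_equal(sm$mean, 2)
  expect_equal(sm$n, 3L)
})
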
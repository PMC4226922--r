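test_that("segmentation XML round trip is the identity", {
  set.seed(42)
  for (k in 1:5) {
    s <- random_segmentation_set(n_frames = sample(1:4, 1))
    path <- withr::local_tempfile(fileext = ".xml")
    write_segmentation(s, path)
    s2 <- read_segmentation(path)
    expect_equal(s2, s, tolerance = 1e-12)
  }
  # empty frame list still yields a valid file
  s0 <- segmentation_set(list(), slice_level = 0L)
  path <- withr::local_tempfile(fileext = ".xml")
  write_segmentation(s0, path)
  expect_length(read_segmentation(path)$frames, 0L)
})

test_that("segmentation parsing reports schema violations with a path", {
  s <- random_segmentation_set(2L)
  path <- withr::local_tempfile(fileext = ".xml")
  write_segmentation(s, path)
  doc <- xml2::read_xml(path)
  xml2::xml_remove(xml2::xml_find_first(doc, "//frame[2]/star"))
  bad <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc, bad)
  expect_error(read_segmentation(bad), "star")
  expect_error(read_segmentation(bad, validate = FALSE), "frame\\[2\\]")
})

test_that("peak-enhancement frame indices survive the round trip", {
  s <- random_segmentation_set(4L)
  s$lv_peak <- 3L; s$rv_peak <- 2L
  path <- withr::local_tempfile(fileext = ".xml")
  write_segmentation(s, path)
  s2 <- read_segmentation(path)
  expect_identical(s2$lv_peak, 3L)
  expect_identical(s2$rv_peak, 2L)
})

test_that("non-finite coordinates are refused on write", {
  s <- random_segmentation_set(1L)
  s$frames[[1]]$endo[2, 1] <- NaN
  expect_error(write_segmentation(s, withr::local_tempfile(fileext = ".xml")),
               "non-finite")
})

test_that("circumcircle matches the closed form", {
  cc <- circumcircle(c(0, 1), c(1, 0), c(0, -1))
  expect_equal(cc$center, c(0, 0), tolerance = 1e-12)
  expect_equal(cc$radius, 1, tolerance = 1e-12)
  # equilateral triangle: centre = centroid
  p <- rbind(c(0, 0), c(2, 0), c(1, sqrt(3)))
  cc <- circumcircle(p[1, ], p[2, ], p[3, ])
  expect_equal(cc$center, colMeans(p), tolerance = 1e-9)
  # |center - p_i| = radius for random triples
  set.seed(7)
  for (k in 1:20) {
    q <- matrix(runif(6, -10, 10), 3, 2)
    cc <- circumcircle(q[1, ], q[2, ], q[3, ])
    d <- sqrt(rowSums(sweep(q, 2, cc$center)^2))
    expect_lt(max(abs(d - cc$radius)) / cc$radius, 1e-9)
  }
  expect_error(circumcircle(c(0, 0), c(1, 1), c(2, 2)), "collinear")
})

test_that("rasterize_contour matches the point-in-polygon oracle", {
  # axis-aligned 10x10 square covers exactly 100 pixel centres
  sq <- rbind(c(2.5, 2.5), c(12.5, 2.5), c(12.5, 12.5), c(2.5, 12.5))
  m <- rasterize_contour(sq, c(32, 32))
  expect_equal(sum(m), 100)
  # triangle vs brute force
  tri <- rbind(c(0, 0), c(0, 4), c(4, 0))
  expect_equal(rasterize_contour(tri, c(8, 8)), rasterize_oracle(tri, c(8, 8)))
  # property: 100 random star-shaped polygons, every pixel agrees
  set.seed(11)
  for (k in 1:100) {
    poly <- random_polygon(n = sample(4:12, 1))
    shape <- c(22, 22)
    expect_identical(rasterize_contour(poly, shape),
                     rasterize_oracle(poly, shape))
  }
})

test_that("degenerate contours are handled", {
  expect_error(rasterize_contour(rbind(c(0, 0), c(1, 1)), c(8, 8)), "3 points")
  expect_warning(m <- rasterize_contour(rbind(c(0, 0), c(2, 2), c(4, 4)), c(8, 8)),
                 "degenerate")
  expect_equal(sum(m), 0)
})

test_that("myocardium_mask is the ring between the contours", {
  ang <- seq(0, 2 * pi, length.out = 73)[-73]
  ctr <- c(16, 16)
  fr <- segmentation_frame("f", ctr,
                           rbind(ctr + c(12, 0), ctr + c(-6, 10.39), ctr + c(-6, -10.39)),
                           endo = cbind(ctr[1] + 6 * cos(ang), ctr[2] + 6 * sin(ang)),
                           epi = cbind(ctr[1] + 10 * cos(ang), ctr[2] + 10 * sin(ang)))
  m <- myocardium_mask(fr, c(32, 32))
  expect_equal(sum(m), pi * (100 - 36), tolerance = 0.05)
  # identical contours -> empty ring
  fr2 <- fr; fr2$endo <- fr2$epi
  expect_equal(sum(myocardium_mask(fr2, c(32, 32))), 0)
  # non-nested contours warn but still return the set difference
  fr3 <- fr; fr3$endo <- sweep(fr$endo, 2, c(8, 0), `+`)
  expect_warning(myocardium_mask(fr3, c(32, 32)), "nested")
})

test_that("section division partitions the myocardium", {
  ph <- tiny_phantom(seed = 2, motion_mode = "none", n_frames = 5)
  fr <- ph$truth_segmentation$frames[[3]]
  shape <- dim(ph$series$data)[1:2]
  sm <- section_masks(fr, shape)                 # default: 12 sections
  expect_length(sm$sections, 12L)
  expect_equal(sm$angular_increment, 30)
  u <- Reduce(`+`, sm$sections)
  expect_true(all(u <= 1L))                      # pairwise disjoint
  expect_equal(u, sm$myocardium_mask)            # union = myocardium
  sm6 <- section_masks(fr, shape, n_sections = 6)
  expect_length(sm6$sections, 6L)
  expect_equal(Reduce(`+`, sm6$sections), sm6$myocardium_mask)
  # empty myocardium errors
  fr0 <- fr; fr0$endo <- fr0$epi
  expect_error(section_masks(fr0, shape), "empty")
})

test_that("section labels rotate with the RV insertion ray", {
  # rotating contours and RV_ip by 30 deg clockwise about LV_c permutes the
  # section labels by one position (up to rasterization boundary pixels)
  ph <- tiny_phantom(seed = 3, motion_mode = "none", n_frames = 5)
  fr <- ph$truth_segmentation$frames[[2]]
  shape <- dim(ph$series$data)[1:2]
  ctr <- fr$star_center
  rot <- function(p, th) {
    p <- sweep(rbind(p), 2, ctr)
    sweep(cbind(p[, 1] * cos(th) - p[, 2] * sin(th),
                p[, 1] * sin(th) + p[, 2] * cos(th)), 2, ctr, `+`)
  }
  th <- pi / 6                                   # clockwise in y-down coords
  fr2 <- fr
  fr2$star_rays <- rot(fr$star_rays, th)
  fr2$endo <- rot(fr$endo, th)
  fr2$epi <- rot(fr$epi, th)
  s1 <- section_masks(fr, shape)
  s2 <- section_masks(fr2, shape)
  myo_n <- sum(s1$myocardium_mask)
  for (k in 1:12) {
    # the angular origin advanced by one increment: new section k = old k+1
    diff_px <- sum(abs(s2$sections[[k]] - s1$sections[[(k %% 12) + 1]]))
    expect_lt(diff_px / myo_n, 0.02)
  }
})

test_that("masks export as 0/255 PNG", {
  m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, path)
  back <- png::readPNG(path)
  expect_equal(matrix(as.integer(back > 0.5), 8, 8), m)
})
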
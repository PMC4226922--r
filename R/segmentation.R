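#' Segmentation of one perfusion frame
#'
#' Holds the manual segmentation of a single frame: the closed endocardial
#' and epicardial contours, and the "star" — the left-ventricle centre point
#' `LV_c` plus three points on the epicardial circumcircle, the first of
#' which is co-located with the RV insertion point `RV_ip`.  The ray
#' `LV_c -> RV_ip` anchors the angular origin of the myocardial section
#' division.
#'
#' All coordinates are 0-based pixel positions given as `(x = column,
#' y = row)`; contour matrices have columns `x`, `y`.  Contours are closed
#' implicitly (last point connects back to the first).
#'
#' @param image_ref file name of the segmented frame.
#' @param star_center numeric length-2 `(x, y)`: the LV centre.
#' @param star_rays 3x2 matrix of circumcircle points, first row = `RV_ip`.
#' @param endo,epi Nx2 contour matrices (N >= 3).
#' @return an object of class `segmentation_frame`.
#' @export
segmentation_frame <- function(image_ref, star_center, star_rays, endo, epi) {
  star_rays <- as.matrix(star_rays)
  endo <- as.matrix(endo); epi <- as.matrix(epi)
  if (length(star_center) != 2L) stop("star_center must be an (x, y) pair")
  if (!identical(dim(star_rays), c(3L, 2L))) stop("star needs exactly 3 ray points")
  if (nrow(endo) < 3L || nrow(epi) < 3L) stop("contours need at least 3 points")
  pts <- rbind(star_center, star_rays, endo, epi)
  if (any(!is.finite(pts))) stop("non-finite coordinate in segmentation frame")
  structure(list(image_ref = as.character(image_ref),
                 star_center = as.numeric(star_center),
                 star_rays = unname(star_rays),
                 endo = unname(endo), epi = unname(epi)),
            class = "segmentation_frame")
}

#' Segmentation set for one slice series
#'
#' @param frames list of [segmentation_frame] objects, one per time step.
#' @param rv_peak,lv_peak 1-based indices of the RV / LV peak-enhancement
#'   frames (`NA` when not marked).
#' @param slice_level 0 = apical, 1 = middle, 2 = basal.
#' @param rv_insertion which of the two RV insertion points the first star
#'   ray passes through (`"anterior"` or `"posterior"`), consistent over the
#'   series.
#' @return an object of class `segmentation_set`.
#' @export
segmentation_set <- function(frames, rv_peak = NA_integer_, lv_peak = NA_integer_,
                             slice_level = 1L, rv_insertion = "anterior") {
  nf <- length(frames)
  for (idx in c(rv_peak, lv_peak))
    if (!is.na(idx) && (idx < 1L || idx > max(nf, 1L)))
      stop("peak frame index out of range")
  structure(list(frames = frames,
                 rv_peak = as.integer(rv_peak), lv_peak = as.integer(lv_peak),
                 slice_level = as.integer(slice_level),
                 rv_insertion = match.arg(rv_insertion, c("anterior", "posterior"))),
            class = "segmentation_set")
}

#' @export
print.segmentation_set <- function(x, ...) {
  cat(sprintf("<segmentation_set> %d frames, slice level %d, RV peak %s, LV peak %s\n",
              length(x$frames), x$slice_level, x$rv_peak, x$lv_peak))
  invisible(x)
}

xml_points <- function(node, mat) {
  for (i in seq_len(nrow(mat)))
    xml2::xml_add_child(node, "point", x = format(mat[i, 1], digits = 17),
                        y = format(mat[i, 2], digits = 17))
}

#' Write a segmentation set as XML
#'
#' The dialect uses `workset/description/frame/star/section` elements with
#' `point` children carrying `x`,`y` attributes; the validating schema ships
#' with the package (`system.file("extdata", "segmentation.xsd", package =
#' "perfmoco")`).  `read_segmentation(write_segmentation(s))` is the
#' identity.
#'
#' @param set a [segmentation_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(set, path) {
  if (!inherits(set, "segmentation_set")) stop("'set' must be a segmentation_set")
  doc <- xml2::xml_new_root("workset")
  desc <- xml2::xml_add_child(doc, "description")
  if (!is.na(set$rv_peak))
    xml2::xml_add_child(desc, "RVpeak", value = as.character(set$rv_peak))
  if (!is.na(set$lv_peak))
    xml2::xml_add_child(desc, "LVpeak", value = as.character(set$lv_peak))
  xml2::xml_add_child(desc, "RVinsertion", value = set$rv_insertion)
  xml2::xml_add_child(desc, "slice", value = as.character(set$slice_level))
  for (fr in set$frames) {
    if (any(!is.finite(c(fr$star_center, fr$star_rays, fr$endo, fr$epi))))
      stop("non-finite coordinate; refusing to write segmentation")
    fn <- xml2::xml_add_child(doc, "frame", image = fr$image_ref)
    star <- xml2::xml_add_child(fn, "star")
    xml2::xml_add_child(star, "center",
                        x = format(fr$star_center[1], digits = 17),
                        y = format(fr$star_center[2], digits = 17))
    xml_points(star, fr$star_rays)
    endo <- xml2::xml_add_child(fn, "section", role = "endocardium")
    xml_points(endo, fr$endo)
    epi <- xml2::xml_add_child(fn, "section", role = "epicardium")
    xml_points(epi, fr$epi)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

seg_parse_points <- function(node, path) {
  pts <- xml2::xml_find_all(node, "./point")
  if (length(pts) == 0L) stop("no points under ", path)
  cbind(as.numeric(xml2::xml_attr(pts, "x")),
        as.numeric(xml2::xml_attr(pts, "y")))
}

#' Read a segmentation set from XML
#'
#' Validates against the shipped schema first; a schema violation is reported
#' with the offending element path.
#'
#' @param path XML file path.
#' @param validate run XSD validation (default `TRUE`).
#' @return a [segmentation_set].
#' @export
read_segmentation <- function(path, validate = TRUE) {
  doc <- xml2::read_xml(path)
  if (validate) {
    xsd_path <- system.file("extdata", "segmentation.xsd", package = "perfmoco")
    if (nzchar(xsd_path)) {
      ok <- xml2::xml_validate(doc, xml2::read_xml(xsd_path))
      if (!ok) stop("segmentation schema violation at ",
                    paste(attr(ok, "errors"), collapse = "; "))
    }
  }
  desc <- xml2::xml_find_first(doc, "./description")
  get_val <- function(el) {
    n <- xml2::xml_find_first(desc, paste0("./", el))
    if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_attr(n, "value")
  }
  frames_xml <- xml2::xml_find_all(doc, "./frame")
  frames <- vector("list", length(frames_xml))
  for (i in seq_along(frames_xml)) {
    fn <- frames_xml[[i]]
    fpath <- sprintf("frame[%d]", i)
    star <- xml2::xml_find_first(fn, "./star")
    if (inherits(star, "xml_missing")) stop("missing star at ", fpath)
    ctr <- xml2::xml_find_first(star, "./center")
    if (inherits(ctr, "xml_missing")) stop("missing star center at ", fpath, "/star")
    rays <- seg_parse_points(star, paste0(fpath, "/star"))
    if (nrow(rays) != 3L) stop("star must have 3 ray points at ", fpath, "/star")
    secs <- xml2::xml_find_all(fn, "./section")
    roles <- xml2::xml_attr(secs, "role")
    endo_i <- which(roles == "endocardium"); epi_i <- which(roles == "epicardium")
    if (length(endo_i) != 1L || length(epi_i) != 1L)
      stop("frame must carry one endocardium and one epicardium section at ", fpath)
    frames[[i]] <- segmentation_frame(
      image_ref = xml2::xml_attr(fn, "image"),
      star_center = c(as.numeric(xml2::xml_attr(ctr, "x")),
                      as.numeric(xml2::xml_attr(ctr, "y"))),
      star_rays = rays,
      endo = seg_parse_points(secs[[endo_i]], paste0(fpath, "/section[endocardium]")),
      epi = seg_parse_points(secs[[epi_i]], paste0(fpath, "/section[epicardium]")))
  }
  segmentation_set(frames,
                   rv_peak = as.integer(get_val("RVpeak")),
                   lv_peak = as.integer(get_val("LVpeak")),
                   slice_level = as.integer(get_val("slice")),
                   rv_insertion = get_val("RVinsertion"))
}

#' Circumcircle of three points
#'
#' The three star rays mark points on the epicardial circumcircle; this
#' recovers its centre and radius in closed form.
#'
#' @param p1,p2,p3 numeric `(x, y)` pairs, not collinear.
#' @return `list(center = c(x, y), radius)` with `|center - p_i| = radius`.
#' @export
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  scale <- max(abs(c(ax, ay, bx, by, cx, cy, 1)))
  if (abs(d) < 1e-12 * scale^2) stop("circumcircle: points are collinear")
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ux - ax)^2 + (uy - ay)^2))
}

#' Rasterize a closed contour to a binary mask
#'
#' Even-odd polygon fill: a pixel belongs to the mask iff its centre lies
#' inside the polygon (crossing-number rule).  Pixel centres sit at integer
#' 0-based `(row, col)` positions.
#'
#' @param contour Nx2 matrix of `(x, y)` vertices, N >= 3.
#' @param grid_shape integer `(rows, cols)`.
#' @return integer 0/1 matrix of the requested shape.
#' @export
rasterize_contour <- function(contour, grid_shape) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3L) stop("a contour needs at least 3 points")
  # drop an explicit closing point
  n <- nrow(contour)
  if (all(contour[1, ] == contour[n, ]) && n > 3L) contour <- contour[-n, , drop = FALSE]
  area2 <- sum(contour[, 1] * c(contour[-1, 2], contour[1, 2]) -
                 c(contour[-1, 1], contour[1, 1]) * contour[, 2])
  if (abs(area2) < 1e-9) {
    warning("degenerate (collinear) contour rasterizes to an empty mask")
    return(matrix(0L, grid_shape[1], grid_shape[2]))
  }
  cpp_rasterize_polygon(contour[, 1], contour[, 2],
                        as.integer(grid_shape[1]), as.integer(grid_shape[2]))
}

#' Myocardium mask from the two contours
#'
#' Epicardial fill minus endocardial fill.  When the contours do not nest a
#' warning is raised and the set difference is returned regardless.
#'
#' @param frame a [segmentation_frame].
#' @param grid_shape integer `(rows, cols)`.
#' @return integer 0/1 matrix.
#' @export
myocardium_mask <- function(frame, grid_shape) {
  epi <- rasterize_contour(frame$epi, grid_shape)
  endo <- rasterize_contour(frame$endo, grid_shape)
  if (any(endo == 1L & epi == 0L))
    warning("endocardial contour is not nested inside the epicardial contour")
  out <- epi
  out[endo == 1L] <- 0L
  out
}

#' Write a binary mask as a 0/255 gray PNG
#'
#' @param mask 0/1 integer (or logical) matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Divide the myocardium into angular sections
#'
#' Rotates the ray `LV_c -> RV_ip` clockwise in image coordinates (y down)
#' with equal angular increments of `360 / n_sections` degrees, assigning
#' each myocardial pixel to exactly one half-open angular sector; with the
#' default `n_sections = 12` the increment is 30 degrees.  Boundary pixels on
#' a sector ray go to the lower-angle sector so the sections always form a
#' partition of the myocardium mask.
#'
#' @param frame a [segmentation_frame].
#' @param grid_shape integer `(rows, cols)`.
#' @param n_sections number of sections (default 12).
#' @return `list(myocardium_mask, sections, n_sections, angular_increment)`;
#'   `sections` is a list of disjoint 0/1 masks whose union equals
#'   `myocardium_mask`.
#' @export
section_masks <- function(frame, grid_shape, n_sections = 12L) {
  n_sections <- as.integer(n_sections)
  if (n_sections < 1L) stop("n_sections must be >= 1")
  myo <- myocardium_mask(frame, grid_shape)
  if (!any(myo == 1L)) stop("empty myocardium mask; cannot build sections")
  cx <- frame$star_center[1]; cy <- frame$star_center[2]
  rv <- frame$star_rays[1, ]
  theta0 <- atan2(rv[2] - cy, rv[1] - cx)
  idx <- which(myo == 1L, arr.ind = TRUE)
  px <- idx[, 2] - 1; py <- idx[, 1] - 1          # 0-based pixel centres
  # y grows downward, so increasing atan2 angle is the visual clockwise sense
  rel <- (atan2(py - cy, px - cx) - theta0) %% (2 * pi)
  inc <- 2 * pi / n_sections
  k <- pmin(floor(rel / inc), n_sections - 1L)
  sections <- lapply(seq_len(n_sections) - 1L, function(s) {
    m <- matrix(0L, grid_shape[1], grid_shape[2])
    sel <- idx[k == s, , drop = FALSE]
    m[sel] <- 1L
    m
  })
  list(myocardium_mask = myo, sections = sections, n_sections = n_sections,
       angular_increment = 360 / n_sections)
}
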
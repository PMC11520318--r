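#' Preprocess a raw frame to a contrast-enhanced grayscale image
#'
#' Converts RGB to luminance if needed and rescales intensities to span
#' [0, 1] by percentile clipping (1st-99th), the usual contrast
#' enhancement before edge detection.
#'
#' @param frame numeric matrix (grayscale) or 3-d array (RGB), or a
#'   `cyto_frame`.
#' @return numeric matrix in [0, 1].
#' @export
preprocess <- function(frame) {
  img <- if (inherits(frame, "cyto_frame")) frame$image else frame
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  if (!is.matrix(img)) stopf("frame must be a 2-d or 3-d numeric array")
  q <- stats::quantile(img, c(0.01, 0.99), names = FALSE)
  if (q[2] - q[1] <= .Machine$double.eps * max(1, abs(q[2])))
    stopf("constant image: zero dynamic range")
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}

# Sobel gradient magnitude (EBImage::filter2 handles the convolution)
gradient_magnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(img, kx)
  gy <- EBImage::filter2(img, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Segment the cell outline in a preprocessed frame
#'
#' Gradient-magnitude edge detection with hysteresis thresholds set from a
#' robust noise estimate, followed by closing of the edge ring, filling of
#' the enclosed contour, and connected-component labelling. Components
#' below `min_area` pixels are discarded, as are components touching the
#' left or right frame edge (cells partially outside the capture window).
#'
#' @param image preprocessed grayscale matrix (see [preprocess()]).
#' @param min_area minimum component area in pixels.
#' @param hi_k,lo_k hysteresis thresholds as multiples of the robust
#'   noise-gradient estimate (median absolute deviation of the gradient
#'   magnitude); the high threshold is floored at 25% of the maximum
#'   gradient so that noise-free images still threshold sensibly.
#' @return list with `mask` (logical matrix, largest accepted component),
#'   `labels` (integer matrix of all accepted components), `count`
#'   (number of accepted components). `count = 0` and an all-`FALSE` mask
#'   signal "no cell in frame".
#' @export
segment_cell <- function(image, min_area = 20, hi_k = 6, lo_k = 2.5) {
  g <- gradient_magnitude(image)
  noise <- stats::mad(g)
  hi <- max(hi_k * noise, 0.25 * max(g))
  lo <- (lo_k / hi_k) * hi
  strong <- g >= hi
  weak <- g >= lo
  lab_w <- EBImage::bwlabel(weak)
  keep <- setdiff(unique(lab_w[strong]), 0)
  edges <- matrix(lab_w %in% keep, nrow(image), ncol(image))
  brush <- EBImage::makeBrush(3, "box")
  closed <- EBImage::erode(EBImage::fillHull(EBImage::dilate(edges, brush)),
                           brush) > 0
  # the hysteresis ring straddles the true perimeter; refine the filled
  # region to the half-contrast level, the unbiased boundary for a
  # symmetrically blurred dark object on a light background
  if (any(closed) && !all(closed)) {
    bg <- stats::median(image[!closed])
    fg <- stats::median(image[closed])
    if (fg < bg) closed <- closed & (image <= (bg + fg) / 2)
  }
  lab <- EBImage::bwlabel(closed)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    touching <- unique(c(lab[, 1], lab[, ncol(lab)]))
    drop <- which(areas < min_area)
    drop <- union(drop, setdiff(touching, 0))
    lab[lab %in% drop] <- 0L
  }
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (!length(ids))
    return(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                labels = lab, count = 0L))
  areas <- vapply(ids, function(i) sum(lab == i), integer(1))
  list(mask = lab == ids[which.max(areas)], labels = lab,
       count = length(ids))
}

#' Moment-based ellipse fit of a binary mask
#'
#' Computes the centroid and normalized second-order central moments of
#' the mask pixels (with the 1/12 per-pixel correction for the finite
#' pixel footprint); the eigenvalues of the 2x2 moment matrix give the
#' axis lengths as `4 * sqrt(lambda)`, the convention under which a solid
#' disk returns its diameter. The orientation is the angle of the
#' principal eigenvector from the image x (flow) axis.
#'
#' @param mask logical or 0/1 matrix (rows = y, cols = x).
#' @return list with `major_px`, `minor_px`, `orientation_rad`,
#'   `centroid_x_px`, `centroid_y_px`, `area_px` (centroids in pixel units
#'   with pixel centres at integer - 0.5).
#' @export
fit_ellipse_moments <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) < 2) stopf("degenerate mask: fewer than 2 pixels")
  ys <- idx[, 1] - 0.5
  xs <- idx[, 2] - 0.5
  mx <- mean(xs); my <- mean(ys)
  dx <- xs - mx; dy <- ys - my
  m20 <- mean(dx^2) + 1 / 12
  m02 <- mean(dy^2) + 1 / 12
  m11 <- mean(dx * dy)
  tr <- m20 + m02
  det_ <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  l1 <- tr / 2 + det_
  l2 <- tr / 2 - det_
  list(major_px = 4 * sqrt(l1), minor_px = 4 * sqrt(max(l2, 0)),
       orientation_rad = 0.5 * atan2(2 * m11, m20 - m02),
       centroid_x_px = mx, centroid_y_px = my, area_px = nrow(idx))
}

#' Optical deformability (OD)
#'
#' The ratio of the major to the minor axis of the moment-fit ellipse;
#' 1 for solid spheres, larger for deformed cells.
#'
#' @param major,minor axis lengths (any common unit).
#' @return OD, dimensionless, always >= 1 (axes are sorted).
#' @export
optical_deformability <- function(major, minor) {
  if (any(minor <= 0)) stopf("minor axis must be positive")
  pmax(major, minor) / pmin(major, minor)
}

#' Optical diameter referenced to calibration beads
#'
#' The area-equivalent diameter `sqrt(major * minor) * pixel_scale`,
#' rescaled so that the calibration-bead median equals the known bead
#' size. Bead referencing makes the result insensitive to the axis-mean
#' convention chosen.
#'
#' @param major,minor axis lengths in pixels.
#' @param calib an [optical_calibration()] result.
#' @return diameter(s) in um.
#' @export
optical_diameter <- function(major, minor, calib) {
  if (is.null(calib$pixel_scale_um) || is.null(calib$od_scale))
    stopf("missing optical calibration")
  sqrt(major * minor) * calib$pixel_scale_um * calib$od_scale
}

#' Pixel-scale calibration from bead measurements
#'
#' With beads of known diameter, the pixel scale is
#' `bead_diameter_um / median(bead mean-axis in px)`.
#'
#' @param bead_measurements data frame with columns `major_px`, `minor_px`
#'   (bead rows only).
#' @param bead_diameter_um known bead diameter.
#' @param min_beads minimum number of bead measurements required.
#' @return pixel scale in um per pixel.
#' @export
calibrate_pixels <- function(bead_measurements, bead_diameter_um = 10,
                             min_beads = 10) {
  if (nrow(bead_measurements) < min_beads)
    stopf("need at least %d bead measurements, got %d", min_beads,
          nrow(bead_measurements))
  mean_axis <- (bead_measurements$major_px + bead_measurements$minor_px) / 2
  bead_diameter_um / stats::median(mean_axis)
}

#' Full optical calibration from bead measurements
#'
#' Combines the pixel-scale calibration with the bead-median rescaling of
#' the area-equivalent optical diameter, so beads read exactly
#' `bead_diameter_um`.
#'
#' @inheritParams calibrate_pixels
#' @return list with `pixel_scale_um`, `od_scale`, `n_beads`.
#' @export
optical_calibration <- function(bead_measurements, bead_diameter_um = 10,
                                min_beads = 10) {
  px <- calibrate_pixels(bead_measurements, bead_diameter_um, min_beads)
  geo <- sqrt(bead_measurements$major_px * bead_measurements$minor_px) * px
  list(pixel_scale_um = px,
       od_scale = bead_diameter_um / stats::median(geo),
       n_beads = nrow(bead_measurements))
}

#' Measure all objects in a frame stack
#'
#' Runs [preprocess()], [segment_cell()] and [fit_ellipse_moments()] over
#' every frame and every accepted component, producing the per-object
#' optical table. Frames without any accepted component are skipped (and
#' counted in the attribute `n_empty_frames`).
#'
#' @param stack a `frame_stack` (see [render_run_frames()] /
#'   [read_frames()]).
#' @param pixel_scale_um microns per pixel used for `y_um`; defaults to
#'   the stack's own scale. `y_um` is the centroid offset from the channel
#'   midline (image vertical centre).
#' @param min_area minimum component area in pixels.
#' @return a `data.frame` of class `optical_measurements`: `frame_index`,
#'   `timestamp_s`, `object_id`, `centroid_x_px`, `centroid_y_px`,
#'   `major_px`, `minor_px`, `orientation_rad`, `od`, `y_um`,
#'   `n_objects_in_frame`.
#' @export
measure_frames <- function(stack, pixel_scale_um = NULL, min_area = 20) {
  px <- pixel_scale_um %||% stack$pixel_scale_um
  rows <- list()
  n_empty <- 0L
  for (i in seq_along(stack$frames)) {
    fr <- stack$frames[[i]]
    img <- tryCatch(preprocess(fr), error = function(e) NULL)
    if (is.null(img)) { n_empty <- n_empty + 1L; next }
    seg <- segment_cell(img, min_area = min_area)
    if (seg$count == 0L) { n_empty <- n_empty + 1L; next }
    H <- nrow(img)
    ids <- setdiff(unique(as.vector(seg$labels)), 0L)
    for (k in seq_along(ids)) {
      fit <- fit_ellipse_moments(seg$labels == ids[k])
      rows[[length(rows) + 1L]] <- data.frame(
        frame_index = stack$frame_index[i],
        timestamp_s = stack$timestamps[i],
        object_id = k,
        centroid_x_px = fit$centroid_x_px,
        centroid_y_px = fit$centroid_y_px,
        major_px = fit$major_px, minor_px = fit$minor_px,
        orientation_rad = fit$orientation_rad,
        od = optical_deformability(fit$major_px, fit$minor_px),
        y_um = (fit$centroid_y_px - H / 2) * px,
        n_objects_in_frame = seg$count)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame_index = integer(0), timestamp_s = numeric(0),
               object_id = integer(0), centroid_x_px = numeric(0),
               centroid_y_px = numeric(0), major_px = numeric(0),
               minor_px = numeric(0), orientation_rad = numeric(0),
               od = numeric(0), y_um = numeric(0),
               n_objects_in_frame = integer(0))
  attr(out, "n_empty_frames") <- n_empty
  class(out) <- c("optical_measurements", "data.frame")
  out
}
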
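test_that("preprocessing rescales to [0,1] and rejects constant images", {
  p <- data.frame(x_um = 0, y_um = 0, diameter_um = 10, deform_opt = 1,
                  tail_skew = 0, velocity_m_s = 0.1)
  fr <- render_frame(p, geom0, acq0)
  rgb <- array(rep(fr$image, 3), c(dim(fr$image), 3))
  g <- preprocess(rgb)
  expect_true(is.matrix(g))
  expect_equal(range(g), c(0, 1), tolerance = 1e-6)
  # idempotent up to rescaling
  expect_equal(preprocess(g), g, tolerance = 0.05)
  expect_error(preprocess(matrix(0.5, 20, 20)), "constant image")
})

test_that("segmentation finds one accurate component at SNR 10", {
  m <- measure_single(diameter_um = 12, deform = 1.16, noise = 0.1,
                      velocity = 0.144, seed = 5)
  expect_equal(m$seg$count, 1L)
  iou <- sum(m$seg$mask & m$frame$mask) / sum(m$seg$mask | m$frame$mask)
  expect_gt(iou, 0.95)
})

test_that("blank frames signal no cell; two cells are counted", {
  blank <- render_frame(NULL, geom0, acq0, noise_sd = 0.05, seed = 2)
  seg <- segment_cell(preprocess(blank))
  expect_equal(seg$count, 0L)
  expect_true(all(!seg$mask))
  p2 <- data.frame(x_um = c(-8, 8), y_um = c(-6, 6), diameter_um = 10,
                   deform_opt = 1, tail_skew = 0, velocity_m_s = 0.1)
  fr2 <- render_frame(p2, geom0, acq0, noise_sd = 0.05, seed = 2)
  expect_equal(segment_cell(preprocess(fr2))$count, 2L)
})

test_that("components touching the lateral frame edges are excluded", {
  p <- data.frame(x_um = geom0$roi_width_um / 2 - 1, y_um = 0,
                  diameter_um = 10, deform_opt = 1, tail_skew = 0,
                  velocity_m_s = 0.1)
  fr <- render_frame(p, geom0, acq0)
  expect_equal(segment_cell(preprocess(fr))$count, 0L)
})

test_that("moment fit returns a disk's diameter", {
  mask <- analytic_mask(128, 128, 64, 64, 50)
  fit <- fit_ellipse_moments(mask)
  expect_equal(fit$major_px, 100, tolerance = 0.005)
  expect_equal(fit$minor_px, 100, tolerance = 0.005)
  expect_equal(fit$major_px / fit$minor_px, 1, tolerance = 0.005)
  expect_equal(fit$centroid_x_px, 64, tolerance = 0.05)
})

test_that("moment fit recovers rotated ellipse axes within 1%", {
  W <- H <- 160
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - 80
  ys <- matrix(rep(seq_len(H) - 0.5, W), H, W) - 80
  for (ang in c(0, 30, 77) * pi / 180) {
    xr <- xs * cos(ang) + ys * sin(ang)
    yr <- -xs * sin(ang) + ys * cos(ang)
    mask <- (xr / 60)^2 + (yr / 40)^2 <= 1
    fit <- fit_ellipse_moments(mask)
    expect_equal(fit$major_px, 120, tolerance = 0.01)
    expect_equal(fit$minor_px, 80, tolerance = 0.01)
    expect_equal(fit$major_px / fit$minor_px, 1.5, tolerance = 0.01)
    ref <- pca_axes_oracle(mask)
    expect_equal(fit$major_px, unname(ref["major"]), tolerance = 0.01)
  }
  expect_error(fit_ellipse_moments(matrix(c(1, rep(0, 8)), 3, 3)),
               "degenerate")
})

test_that("moment fit agrees with the pixel-cloud covariance oracle on random blobs", {
  for (s in 1:50) {
    mask <- random_blob(s)
    if (sum(mask) < 200) next
    fit <- fit_ellipse_moments(mask)
    ref <- pca_axes_oracle(mask)
    expect_equal(fit$major_px, unname(ref["major"]), tolerance = 0.01)
    expect_equal(fit$minor_px, unname(ref["minor"]), tolerance = 0.01)
  }
})

test_that("optical deformability is the sorted axis ratio", {
  expect_equal(optical_deformability(120, 80), 1.5)
  expect_equal(optical_deformability(80, 120), 1.5)   # axes sorted, OD >= 1
  expect_error(optical_deformability(10, 0), "positive")
  m <- measure_single(diameter_um = 10, deform = 1)
  expect_equal(optical_deformability(m$fit$major_px, m$fit$minor_px), 1,
               tolerance = 0.05)
})

test_that("optical diameter is the bead-referenced geometric mean of axes", {
  calib <- list(pixel_scale_um = 0.63, od_scale = 1)
  expect_equal(optical_diameter(22, 18, calib), sqrt(396) * 0.63,
               tolerance = 1e-12)
  expect_error(optical_diameter(22, 18, list()), "calibration")
})

test_that("pixel calibration: 10 um beads at 15.87 px give 0.63 um per px", {
  beads <- data.frame(major_px = rep(15.873, 12), minor_px = rep(15.873, 12))
  expect_equal(calibrate_pixels(beads), 0.63, tolerance = 1e-3)
  beads2 <- data.frame(major_px = rep(20, 12), minor_px = rep(20, 12))
  expect_equal(calibrate_pixels(beads2), 0.5)
  expect_error(calibrate_pixels(beads[1:5, ]), "at least 10")
})

test_that("pixel scale round-trips through rendered bead frames within 2%", {
  cfg <- cohort_config(n_cells = 0, n_beads = 25, flow_ul_min = 5,
                       event_rate_hz = 5, image_noise_sd = 0.03, seed = 19)
  co <- sample_cohort(cfg, geom0)
  st <- render_run_frames(co, geom0, acq0, noise_sd = 0.03, seed = 19)
  om <- measure_frames(st)
  expect_gt(nrow(om), 10)
  expect_equal(calibrate_pixels(om), acq0$pixel_scale_um, tolerance = 0.02)
})

test_that("tear-drop tails strictly inflate the measured OD", {
  od <- vapply(c(0, 0.15, 0.3), function(s)
    measure_single(diameter_um = 16, deform = 1.16, skew = s)$fit$major_px /
      measure_single(diameter_um = 16, deform = 1.16, skew = s)$fit$minor_px,
    numeric(1))
  expect_true(all(diff(od) > 0))
})

test_that("sub-micron motion blur changes OD by less than 3%", {
  # 0.9 um blur on a 12 um cell: velocity 0.45 m/s for a 2 us pulse
  sharp <- measure_single(diameter_um = 12, deform = 1.16, blur = FALSE)
  blurred <- measure_single(diameter_um = 12, deform = 1.16, velocity = 0.45,
                            blur = TRUE)
  od_s <- sharp$fit$major_px / sharp$fit$minor_px
  od_b <- blurred$fit$major_px / blurred$fit$minor_px
  expect_lt(abs(od_b - od_s) / od_s, 0.03)
})

test_that("cohort mean OD tracks the generator truth within 2% (no tails)", {
  cfg <- cohort_config(n_cells = 80, n_beads = 0, deform_mean = 1.16,
                       deform_sd = 0.02, wall_deform_gain = 0,
                       wall_skew_gain = 0, image_noise_sd = 0.05,
                       flow_ul_min = 5, event_rate_hz = 5, seed = 23)
  co <- sample_cohort(cfg, geom0)
  st <- render_run_frames(co, geom0, acq0, noise_sd = 0.05, seed = 23)
  om <- measure_frames(st)
  expect_gt(nrow(om), 50)
  expect_lt(abs(mean(om$od) / 1.16 - 1), 0.02)
})
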
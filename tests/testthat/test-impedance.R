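test_that("well-separated noise-free beads are all detected with exact transit times", {
  cfg <- cohort_config(n_cells = 0, n_beads = 50, bead_diameter_cv = 0,
                       flow_ul_min = 5, event_rate_hz = 5, seed = 3)
  co <- sample_cohort(cfg, geom0)
  tr <- synthesize_trace(co, geom0, acq0, noise_sd = 0)
  ev <- detect_events(tr, geom0, acq0, min_prominence = 0.2)
  expect_equal(nrow(ev), 50)
  ix <- match_events_to_truth(ev, co)
  expect_true(!anyNA(ix))
  dt_true <- geom0$d1_um * 1e-6 / co$velocity_m_s[ix]
  expect_lt(max(abs(ev$dt1_s - dt_true)) * acq0$sample_rate_hz, 1)
  # noise-free amplitude matches the injected volume-law amplitude to 1%
  expect_lt(max(abs(ev$dI1 / (co$diameter_um[ix] / 10)^3 - 1)), 0.01)
})

test_that("pure noise at the 5-sigma prominence threshold yields no events", {
  acq_long <- acquisition_settings()
  tr <- synthesize_trace(NULL, geom0, acq_long, noise_sd = 0.05,
                         duration_s = 1e6 / acq_long$sample_rate_hz, seed = 17)
  ev <- detect_events(tr, geom0, acq_long)   # default: 5x estimated noise SD
  expect_equal(nrow(ev), 0)
})

test_that("velocity follows d1 / dt1", {
  expect_equal(estimate_velocity(400e-6, geom0), 0.1)
  expect_equal(estimate_velocity(277.8e-6, geom0), 0.144, tolerance = 1e-4)
  expect_error(estimate_velocity(-1e-4, geom0), "positive")
})

test_that("velocity recovery on noisy traces has sub-2% median error at SNR 20", {
  cfg <- cohort_config(n_cells = 0, n_beads = 120, bead_diameter_cv = 0,
                       flow_ul_min = 5, event_rate_hz = 8, trace_snr = 20,
                       seed = 14)
  co <- sample_cohort(cfg, geom0)
  tr <- synthesize_trace(co, geom0, acq0, noise_sd = 1 / 20, seed = 14)
  ev <- detect_events(tr, geom0, acq0)
  expect_gt(nrow(ev), 100)
  ix <- match_events_to_truth(ev, co)
  rel <- abs(ev$velocity_m_s - co$velocity_m_s[ix]) / co$velocity_m_s[ix]
  expect_lt(median(rel, na.rm = TRUE), 0.02)
})

test_that("trigger prediction adds d2/velocity past the configuration-1 midpoint", {
  ev <- data.frame(t_extremum1_s = 0, t_extremum2_s = 4e-4,
                   velocity_m_s = 0.1)
  expect_equal(predict_trigger(ev, geom0), 2e-4 + 3.5e-3)  # dt2 = 3.5 ms
  expect_equal(predict_trigger(ev, geom0, latency_s = 1e-4),
               2e-4 + 3.5e-3 + 1e-4)
  ev$velocity_m_s <- -1
  expect_error(predict_trigger(ev, geom0), "non-positive")
})

test_that("electrical diameter is the bead-referenced cube root", {
  calib <- list(dI1_bead_median = 0.8, ed_raw_bead_median = 1,
                bead_diameter_um = 10)
  expect_equal(electrical_diameter(0.8, calib), 10)
  expect_equal(electrical_diameter(0.8 * 1.728, calib), 12)
  expect_error(electrical_diameter(1, list()), "calibration")
})

test_that("electrical deformability is bead-normalised", {
  calib <- list(ed_raw_bead_median = 0.8)
  expect_equal(electrical_deformability(0.928, 1, calib), 1.16)
  expect_error(electrical_deformability(1, 0, calib), "zero")
  # bead events map to median ED = 1 by construction
  cfg <- cohort_config(n_cells = 0, n_beads = 40, flow_ul_min = 5,
                       event_rate_hz = 5, trace_snr = 50, seed = 21)
  co <- sample_cohort(cfg, geom0)
  tr <- synthesize_trace(co, geom0, acq0, noise_sd = 1 / 50, seed = 21)
  ev <- detect_events(tr, geom0, acq0)
  cal <- bead_calibration(ev, rep(TRUE, nrow(ev)))
  ed <- electrical_deformability(ev$dI1, ev$dI2, cal)
  expect_equal(median(ed), 1)
  expect_lt(sd(ed), 0.05)
})

test_that("ED of rigid spheres is size-invariant across 5-20 um", {
  p <- data.frame(id = 1:6, kind = "bead",
                  diameter_um = c(5, 8, 11, 14, 17, 20),
                  deform_true = 1, deform_opt = 1, tail_skew = 0,
                  y_um = 0, z_um = 0, velocity_m_s = 0.1,
                  t_entry_s = seq(0.02, by = 0.02, length.out = 6),
                  group = "bead", flow_ul_min = 5, seed = 1L)
  tr <- synthesize_trace(p, geom0, acq0, noise_sd = 0)
  ev <- detect_events(tr, geom0, acq0, min_prominence = 0.05)
  expect_equal(nrow(ev), 6)
  expect_lt(max(abs(ev$ed_raw - 1)), 1e-3)
})

test_that("deformability recovery: simulated cells read back their group mean", {
  cfg <- cohort_config(n_cells = 150, n_beads = 40, deform_mean = 1.16,
                       deform_sd = 0.011, flow_ul_min = 5, event_rate_hz = 8,
                       trace_snr = 30, seed = 31)
  co <- sample_cohort(cfg, geom0)
  tr <- synthesize_trace(co, geom0, acq0, noise_sd = 1 / 30, seed = 31)
  ev <- detect_events(tr, geom0, acq0)
  ix <- match_events_to_truth(ev, co)
  is_bead <- !is.na(ix) & co$kind[ix] == "bead"
  cal <- bead_calibration(ev, is_bead)
  ed <- electrical_deformability(ev$dI1, ev$dI2, cal)[!is.na(ix) &
                                                        co$kind[ix] == "cell"]
  se <- sd(ed) / sqrt(length(ed))
  expect_lt(abs(mean(ed) - 1.16), 2 * se + 0.005)
  # electrical diameter recovers truth within 1% noise-aside
  d_el <- electrical_diameter(ev$dI1, cal)
  cells <- !is.na(ix) & co$kind[ix] == "cell"
  expect_lt(median(abs(d_el[cells] / co$diameter_um[ix][cells] - 1)), 0.02)
})

test_that("event tables round-trip through CSV", {
  ev <- data.frame(event_id = 1:2, t_extremum1_s = c(0.1, 0.2),
                   t_extremum2_s = c(0.1004, 0.2004), dt1_s = 4e-4,
                   velocity_m_s = 0.1, dI1 = c(1, 1.7), dI2 = c(1, 1.5),
                   ed_raw = c(1, 1.133), t_trigger_s = c(0.104, 0.204))
  f <- tempfile(fileext = ".csv")
  write_events(ev, f)
  expect_equal(read_events(f)$dI1, ev$dI1)
  unlink(f)
})
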
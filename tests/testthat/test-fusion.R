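# minimal hand-built tables for the pairing logic
ecal0 <- list(dI1_bead_median = 1, ed_raw_bead_median = 1,
              bead_diameter_um = 10)
ocal0 <- list(pixel_scale_um = 0.63, od_scale = 1)

mk_events <- function(t_trigger, dI1 = 1, dI2 = 1) {
  n <- length(t_trigger)
  data.frame(event_id = seq_len(n), t_extremum1_s = t_trigger - 4e-3,
             t_extremum2_s = t_trigger - 3.6e-3, dt1_s = 4e-4,
             velocity_m_s = 0.1, dI1 = rep_len(dI1, n),
             dI2 = rep_len(dI2, n), ed_raw = rep_len(dI1 / dI2, n),
             t_trigger_s = t_trigger)
}
mk_optics <- function(frame_index, x_px = 27, y_um = 0, n_obj = 1) {
  n <- length(frame_index)
  data.frame(frame_index = frame_index, timestamp_s = frame_index / 100,
             object_id = 1, centroid_x_px = rep_len(x_px, n),
             centroid_y_px = 31.5, major_px = 19, minor_px = 16,
             orientation_rad = 0, od = 19 / 16,
             y_um = rep_len(y_um, n), n_objects_in_frame = rep_len(n_obj, n))
}

test_that("events map to the frame floor(t_trigger * frame_rate)", {
  ev <- mk_events(0.1234)
  op <- mk_optics(12)
  cc <- match_events_to_frames(ev, op, acq0, ecal0, ocal0, frame_width_px = 54)
  expect_equal(cc$frame_index, 12)
  expect_false(cc$coincident)
  expect_equal(cc$ed, 1)
  expect_equal(cc$od, 19 / 16)
})

test_that("events sharing a frame are both flagged coincident", {
  ev <- mk_events(c(0.121, 0.128))
  op <- mk_optics(c(12, 12), x_px = c(20, 34), n_obj = 2)
  cc <- match_events_to_frames(ev, op, acq0, ecal0, ocal0, frame_width_px = 54)
  expect_equal(nrow(cc), 2)
  expect_true(all(cc$coincident))
})

test_that("disjoint clocks are an error", {
  expect_error(match_events_to_frames(mk_events(0.12), mk_optics(900), acq0,
                                      ecal0, ocal0, frame_width_px = 54),
               "disjoint")
})

test_that("pairing is invariant under input row permutation", {
  set.seed(4)
  ev <- mk_events(sort(runif(20, 0, 5)))
  op <- mk_optics(floor(ev$t_trigger_s * 100))
  base <- match_events_to_frames(ev, op, acq0, ecal0, ocal0, frame_width_px = 54)
  perm <- match_events_to_frames(ev[sample(20), ], op[sample(20), ], acq0,
                                 ecal0, ocal0, frame_width_px = 54)
  key <- function(x) x[order(x$event_id), c("event_id", "frame_index", "od")]
  expect_equal(key(base), key(perm), ignore_attr = TRUE)
})

test_that("coincidence rate reproduces the frame-count arithmetic", {
  op <- mk_optics(1:2844, n_obj = c(rep(2, 53), rep(1, 2791)))
  cr <- coincidence_rate(op)
  expect_equal(cr$percent, 1.9)
  expect_equal(cr$n_multi, 53L)
  op1 <- mk_optics(1:100, n_obj = 1)
  expect_equal(coincidence_rate(op1)$percent, 0)
  expect_error(coincidence_rate(op1[0, ]), "zero frames")
})

test_that("observed coincidence matches the Poisson prediction at lambda = 0.2", {
  set.seed(7)
  k <- rpois(20000, 0.2)
  occupied <- k >= 1
  op <- mk_optics(seq_len(sum(occupied)), n_obj = k[occupied])
  cr <- coincidence_rate(op)
  lam <- 0.2
  p_pred <- (1 - exp(-lam) - lam * exp(-lam)) / (1 - exp(-lam))
  se <- sqrt(p_pred * (1 - p_pred) / sum(occupied))
  expect_lt(abs(cr$percent / 100 - p_pred), 3 * se + 5e-4)
})

test_that("coincidence fraction grows with the event rate", {
  set.seed(8)
  rates <- vapply(c(0.05, 0.1, 0.2, 0.4), function(lam) {
    k <- rpois(30000, lam)
    k1 <- k[k >= 1]
    coincidence_rate(mk_optics(seq_along(k1), n_obj = k1))$percent
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("poisson pmf is exact and normalised", {
  expect_equal(poisson_pmf(0, 0), 1)
  expect_equal(poisson_pmf(0.2, 2), 0.2^2 * exp(-0.2) / 2)
  expect_equal(poisson_pmf(0.2, 2), 0.01637, tolerance = 1e-3)
  expect_lt(abs(sum(poisson_pmf(2, 0:50)) - 1), 1e-12)
  expect_error(poisson_pmf(-1, 0), "non-negative")
  expect_error(poisson_pmf(1, 1.5), "integer")
})

test_that("blur displacement is velocity times pulse duration", {
  expect_equal(blur_length(0.144, 2e-6)$displacement_um, 0.288)
  expect_equal(blur_length(3 * 0.144, 2e-6)$displacement_um, 0.864)
  b <- blur_length(3 * 0.144, 2e-6, diameter_um = 12)
  expect_equal(b$percent_of_diameter, 7.2)
  expect_error(blur_length(-1, 1e-6), "non-negative")
})

test_that("the y gate keeps the midline band and reports retention per group", {
  cc <- data.frame(event_id = 1:4, y_um = c(0, 6.3, 7.0, -10), ed = 1,
                   od = 1.2, gate_pass = NA, coincident = FALSE)
  g <- apply_y_gate(cc, 6.3)
  expect_equal(g$table$event_id, 1:2)   # 6.3 inclusive, 7.0 rejected
  expect_equal(g$report$summary, "2/4 (50%)")
  # gating alters membership only, never the measured values
  expect_equal(g$table$od, cc$od[g$all$gate_pass])
  expect_equal(g$all$ed, cc$ed)
})

test_that("retention report formats the printed counts", {
  set.seed(10)
  mk_group <- function(n, n_in, grp) data.frame(
    y_um = c(runif(n_in, -6.3, 6.3),
             runif(n - n_in, 6.35, 17) * sample(c(-1, 1), n - n_in, TRUE)),
    ed = 1, od = 1.2, group = grp)
  cc <- rbind(mk_group(1430, 672, "untreated"), mk_group(1095, 465, "latB"))
  rep <- apply_y_gate(cc, 6.3)$report
  expect_equal(rep$summary[rep$group == "untreated"], "672/1430 (47%)")
  expect_equal(rep$summary[rep$group == "latB"], "465/1095 (42%)")
})

test_that("simulated pairing recovers ground-truth event-frame pairs", {
  cfg <- cohort_config(n_cells = 60, n_beads = 20, flow_ul_min = 5,
                       event_rate_hz = 5, trace_snr = 30,
                       image_noise_sd = 0.03, seed = 33)
  res <- run_pipeline(list(cohort = cfg))
  cc <- res$correlated[!res$correlated$coincident, ]
  opt_truth <- match_optics_to_truth(res$optics, render_run_frames(
    res$cohort, geom0, acq0, noise_sd = cfg$image_noise_sd, seed = cfg$seed))
  agree <- cc$truth_id == opt_truth[cc$optics_row]
  expect_gt(mean(agree, na.rm = TRUE), 0.98)
})
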
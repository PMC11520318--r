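#' Match detected events to simulated ground truth
#'
#' Pairs each detected event with the nearest ground-truth particle by
#' configuration-1 arrival time (the first extremum sits at the first
#' electrode-pair centre, i.e. at `t_entry_s`). Used for recovery tests and
#' for labelling bead events inside simulated pipelines; real data needs an
#' external bead label instead.
#'
#' @param events an `impedance_events` table.
#' @param cohort a `particle_truth` table.
#' @param tol_s maximum |time difference| accepted (s).
#' @return integer vector: for each event, the matching cohort row index
#'   (`NA` if none within `tol_s`).
#' @export
match_events_to_truth <- function(events, cohort, tol_s = 2e-3) {
  vapply(events$t_extremum1_s, function(t) {
    i <- which.min(abs(cohort$t_entry_s - t))
    if (abs(cohort$t_entry_s[i] - t) <= tol_s) i else NA_integer_
  }, integer(1))
}

#' Match optical measurements to simulated ground truth
#'
#' Pairs each measured object with the rendered particle on the same frame
#' whose position along the flow is nearest to the observed centroid.
#'
#' @param optics an `optical_measurements` table.
#' @param stack the `frame_stack` that produced it (must carry `truth`).
#' @return integer vector of cohort particle `id`s (`NA` if unmatched).
#' @export
match_optics_to_truth <- function(optics, stack) {
  if (is.null(stack$truth)) stopf("frame stack carries no ground truth")
  px <- stack$pixel_scale_um
  W_px <- ncol(stack$frames[[1]]$image)
  ids <- rep(NA_integer_, nrow(optics))
  for (r in seq_len(nrow(optics))) {
    k <- match(optics$frame_index[r], stack$frame_index)
    if (is.na(k)) next
    tr <- stack$truth[[k]]
    x_obs <- (optics$centroid_x_px[r] - W_px / 2) * px
    j <- which.min(abs(tr$x_um - x_obs))
    if (abs(tr$x_um[j] - x_obs) <= tr$diameter_um[j]) ids[r] <- tr$id[j]
  }
  ids
}

#' Run the full simulate-measure-correlate pipeline on one cohort
#'
#' Executes every stage in order on a single simulated acquisition run:
#' draw the cohort, synthesize the two-channel impedance trace, render the
#' impedance-triggered frames, detect events, measure the frames,
#' calibrate both chains on the bead events, correlate events with frames,
#' apply the lateral position gate and summarise per group. When
#' `out_dir` is given, every table is written as CSV along with a
#' retention-report JSON and a YAML run manifest.
#'
#' @param config list with elements `cohort` (a [cohort_config()]),
#'   optional `geom`, `acq`, `gate_halfwidth_um` (default 6.3),
#'   `exclude_coincident` (default TRUE), `out_dir`.
#' @return a `pipeline_result` list: `cohort`, `events`, `optics`,
#'   `correlated` (with `group`/`kind` truth labels attached),
#'   `gated` (the [apply_y_gate()] result), `summary` (per-group
#'   [group_summary()] of gated, non-coincident rows), `coincidence`
#'   ([coincidence_rate()]), `calibration`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- config$cohort
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_beads == 0) stopf("calibration impossible: cohort has zero beads")
  geom <- config$geom %||% channel_geometry()
  acq <- config$acq %||% acquisition_settings()
  gate <- config$gate_halfwidth_um %||% 6.3
  excl <- config$exclude_coincident %||% TRUE

  cohort <- sample_cohort(cfg, geom)
  noise_sd <- if (is.finite(cfg$trace_snr)) 1 / cfg$trace_snr else 0
  trace <- synthesize_trace(cohort, geom, acq, noise_sd = noise_sd,
                            seed = cfg$seed)
  events <- detect_events(trace, geom, acq)
  if (!nrow(events)) stopf("no impedance events detected")
  stack <- render_run_frames(cohort, geom, acq, noise_sd = cfg$image_noise_sd,
                             seed = cfg$seed)
  optics <- measure_frames(stack)
  if (!nrow(optics)) stopf("no optical measurements")

  truth_ix <- match_events_to_truth(events, cohort)
  is_bead_ev <- !is.na(truth_ix) & cohort$kind[truth_ix] == "bead"
  if (!any(is_bead_ev)) stopf("calibration impossible: no bead events detected")
  ecal <- bead_calibration(events, is_bead_ev, cfg$bead_diameter_um)

  opt_ids <- match_optics_to_truth(optics, stack)
  is_bead_opt <- !is.na(opt_ids) &
    cohort$kind[match(opt_ids, cohort$id)] == "bead"
  ocal <- optical_calibration(optics[is_bead_opt, , drop = FALSE],
                              cfg$bead_diameter_um)
  # re-express lateral positions with the bead-calibrated pixel scale
  optics$y_um <- optics$y_um / stack$pixel_scale_um * ocal$pixel_scale_um

  correlated <- match_events_to_frames(events, optics, acq, ecal, ocal,
                                       frame_width_px =
                                         ncol(stack$frames[[1]]$image))
  ev_truth <- truth_ix[match(correlated$event_id, events$event_id)]
  correlated$kind <- ifelse(is.na(ev_truth), NA, cohort$kind[ev_truth])
  correlated$group <- ifelse(is.na(ev_truth), NA, cohort$group[ev_truth])
  correlated$truth_id <- ifelse(is.na(ev_truth), NA, cohort$id[ev_truth])

  gated <- apply_y_gate(correlated, gate)
  stat_rows <- gated$table
  if (excl) stat_rows <- stat_rows[!stat_rows$coincident, , drop = FALSE]
  summary <- group_summary(stat_rows)
  coinc <- coincidence_rate(optics)

  manifest <- list(
    package_version = as.character(utils::packageVersion("deformacyte")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "")],
    geometry = unclass(geom), acquisition = unclass(acq),
    gate_halfwidth_um = gate,
    counts = list(particles = nrow(cohort), events = nrow(events),
                  optical_objects = nrow(optics),
                  correlated = nrow(correlated),
                  gated = nrow(gated$table),
                  empty_frames = attr(optics, "n_empty_frames"),
                  unmatched_events = attr(correlated, "n_unmatched_events")))

  res <- list(cohort = cohort, trace = trace, events = events,
              optics = optics, correlated = correlated, gated = gated,
              summary = summary, coincidence = coinc,
              calibration = list(electrical = ecal, optical = ocal),
              manifest = manifest)
  class(res) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(x, f) utils::write.csv(x, file.path(config$out_dir, f),
                                          row.names = FALSE)
    wp(cohort, "particles.csv")
    wp(events, "events.csv")
    wp(optics, "optics.csv")
    wp(gated$all, "correlated.csv")
    wp(summary, "summary.csv")
    jsonlite::write_json(list(retention = gated$report,
                              coincidence = coinc),
                         file.path(config$out_dir, "retention.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  res
}

#' Run a multi-cohort study and correlate the modalities
#'
#' Runs [run_pipeline()] over several cohorts (e.g. three flow rates, or a
#' dose series), collects gated non-coincident group means of ED and OD
#' per run, and fits the between-modality line OD ~ ED over the group
#' means — the standard check that the electrical readout tracks the
#' optical one (slope near 1 through the bead point at (1, 1)).
#'
#' @param cohort_configs list of [cohort_config()] objects.
#' @param ... further `config` entries passed to each [run_pipeline()]
#'   call (`geom`, `acq`, `gate_halfwidth_um`, ...).
#' @return list with `runs` (pipeline results), `group_means` (one row per
#'   run x group), `modality_fit` (a [linear_fit()] of od_mean on
#'   ed_mean).
#' @export
run_study <- function(cohort_configs, ...) {
  extra <- list(...)
  runs <- lapply(cohort_configs, function(cfg)
    run_pipeline(c(list(cohort = cfg), extra)))
  gm <- do.call(rbind, lapply(seq_along(runs), function(i) {
    s <- runs[[i]]$summary
    s$run <- i
    s$flow_ul_min <- cohort_configs[[i]]$flow_ul_min
    s$concentration <- attr(cohort_configs[[i]], "concentration") %||% NA_real_
    s
  }))
  fit <- if (nrow(gm) >= 3)
    linear_fit(gm$ed_mean, gm$od_mean) else NULL
  list(runs = runs, group_means = gm, modality_fit = fit)
}

#' Audit pipeline tables against their invariants
#'
#' Schema and invariant checks over the three stage tables: required
#' columns present, transit times and amplitudes positive, trigger after
#' the second extremum, major >= minor > 0, OD >= 1, ED > 0, lateral
#' positions inside the channel, and gate flags consistent with `y_um`.
#' Diagnostics are always returned, never thrown.
#'
#' @param events,optics,correlated stage tables (any may be `NULL` to
#'   skip).
#' @param gate_halfwidth_um gate used when checking `gate_pass`
#'   consistency.
#' @param width_um channel width for the position sanity check.
#' @return data frame with columns `table`, `rule`, `n_violations`; zero
#'   rows when everything checks out.
#' @export
validate_tables <- function(events = NULL, optics = NULL, correlated = NULL,
                            gate_halfwidth_um = 6.3, width_um = 40) {
  bad <- list()
  note <- function(tbl, rule, n) {
    if (n > 0) bad[[length(bad) + 1L]] <<-
        data.frame(table = tbl, rule = rule, n_violations = as.integer(n))
  }
  need <- function(tbl, df, cols) {
    miss <- setdiff(cols, names(df))
    note(tbl, paste("missing columns:", paste(miss, collapse = ",")),
         length(miss))
    length(miss) == 0
  }
  if (!is.null(events) &&
      need("events", events, c("dt1_s", "velocity_m_s", "dI1", "dI2",
                               "t_extremum2_s", "t_trigger_s"))) {
    note("events", "dt1_s <= 0", sum(events$dt1_s <= 0))
    note("events", "dI1 <= 0", sum(events$dI1 <= 0))
    note("events", "dI2 <= 0", sum(events$dI2 <= 0))
    note("events", "t_trigger_s <= t_extremum2_s",
         sum(events$t_trigger_s <= events$t_extremum2_s))
  }
  if (!is.null(optics) &&
      need("optics", optics, c("major_px", "minor_px", "od", "y_um"))) {
    note("optics", "minor_px <= 0", sum(optics$minor_px <= 0))
    note("optics", "major_px < minor_px",
         sum(optics$major_px < optics$minor_px))
    note("optics", "od < 1", sum(optics$od < 1))
    note("optics", "|y_um| > channel half-width",
         sum(abs(optics$y_um) > width_um / 2))
  }
  if (!is.null(correlated) &&
      need("correlated", correlated, c("ed", "od", "y_um", "gate_pass"))) {
    note("correlated", "ed <= 0", sum(correlated$ed <= 0))
    note("correlated", "od < 1", sum(correlated$od < 1))
    gp <- correlated$gate_pass
    expect <- abs(correlated$y_um) <= gate_halfwidth_um
    note("correlated", "gate_pass inconsistent with y_um",
         sum(!is.na(gp) & gp != expect))
  }
  if (!length(bad))
    return(data.frame(table = character(0), rule = character(0),
                      n_violations = integer(0)))
  do.call(rbind, bad)
}
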
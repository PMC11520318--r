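#' Configuration of a synthetic particle cohort
#'
#' One cohort is a single acquisition run: a mixture of cells from one
#' treatment group and rigid 10 um calibration beads, at one flow rate.
#'
#' Deformability is the dimensionless long-axis / short-axis ratio; rigid
#' spheres have deformability 1. Cells carry two shape truths: `deform_true`,
#' the shear elongation along the flow axis that the impedance ratio probes,
#' and an optical shape that is additionally amplified near the channel
#' walls, where unbalanced shear distorts cells into tear-drops. The wall
#' effect inflates the optically measured long axis but leaves the impedance
#' ratio essentially untouched, which is exactly the artefact the lateral
#' position gate removes.
#'
#' @param n_cells,n_beads particle counts.
#' @param group treatment label for the cells (beads are labelled "bead").
#' @param flow_ul_min flow rate of the run (ul/min).
#' @param deform_mean,deform_sd population mean and SD of the cell
#'   deformability at this group x flow rate (dimensionless, >= 1).
#' @param cell_diameter_mean_um,cell_diameter_sd_um cell size distribution.
#' @param bead_diameter_um,bead_diameter_cv calibration bead size (um) and
#'   coefficient of variation.
#' @param wall_deform_gain quadratic coefficient (kappa) of the optical
#'   deformability increase with normalised lateral offset `(2|y|/width)^2`.
#' @param wall_skew_gain quadratic coefficient of the tear-drop asymmetry
#'   `tail_skew` with the same normalised offset.
#' @param focusing_sd_um SD of the truncated-normal lateral (y) position
#'   spread produced by the partial viscoelastic focusing.
#' @param z_sd_um SD of the height (z) position spread.
#' @param event_rate_hz mean particle arrival rate (Poisson process, 1/s).
#' @param trace_snr amplitude signal-to-noise ratio of the impedance trace,
#'   defined against the bead amplitude; `Inf` disables trace noise.
#' @param image_noise_sd Gaussian pixel noise SD as a fraction of the image
#'   contrast; 0 disables image noise.
#' @param seed integer seed recorded in all outputs.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_cells = 500, n_beads = 100,
                          group = "untreated", flow_ul_min = 10,
                          deform_mean = 1.16, deform_sd = 0.06,
                          cell_diameter_mean_um = 12, cell_diameter_sd_um = 1,
                          bead_diameter_um = 10, bead_diameter_cv = 0.01,
                          wall_deform_gain = 0.5, wall_skew_gain = 0.3,
                          focusing_sd_um = 7, z_sd_um = 5,
                          event_rate_hz = 10,
                          trace_snr = 20, image_noise_sd = 0.05,
                          seed = 1L) {
  if (deform_mean < 1) stopf("deform_mean must be >= 1")
  if (deform_sd < 0 || wall_deform_gain < 0 || wall_skew_gain < 0)
    stopf("spread and wall-gain parameters must be non-negative")
  assert_pos(focusing_sd_um, "focusing_sd_um")
  assert_pos(event_rate_hz, "event_rate_hz")
  if (n_cells < 0 || n_beads < 0) stopf("particle counts must be non-negative")
  structure(as.list(environment()), class = "cohort_config")
}

#' Draw a ground-truth particle cohort
#'
#' Samples one synthetic run: arrival times from a Poisson process at
#' `event_rate_hz`, lateral positions from a truncated normal (partial
#' focusing), sizes and deformabilities per group, and per-particle
#' velocities from the laminar duct profile at each particle's (y, z).
#'
#' Cells: `deform_true = deform_mean * noise` (truncated at 1), the flow-axis
#' elongation probed electrically; `deform_opt = deform_true *
#' (1 + wall_deform_gain * (2|y|/width)^2)` is the rendered optical axis
#' ratio and `tail_skew = wall_skew_gain * (2|y|/width)^2` the rendered
#' tear-drop asymmetry. Beads: deformability exactly 1, no skew.
#'
#' @param config a [cohort_config()].
#' @param geom a [channel_geometry()].
#' @return a `data.frame` of class `particle_truth`, sorted by `t_entry_s`,
#'   one row per particle with columns `id, kind, diameter_um, deform_true,
#'   deform_opt, tail_skew, y_um, z_um, velocity_m_s, t_entry_s, group,
#'   flow_ul_min, seed`.
#' @export
sample_cohort <- function(config, geom = channel_geometry()) {
  stopifnot(inherits(config, "cohort_config"), inherits(geom, "channel_geometry"))
  cfg <- config
  dmax <- max(cfg$cell_diameter_mean_um + 4 * cfg$cell_diameter_sd_um,
              cfg$bead_diameter_um)
  if (dmax >= geom$height_um)
    stopf("particle diameter (%g um) exceeds channel height (%g um)",
          dmax, geom$height_um)
  set.seed(derive_seed(cfg$seed, "cohort"))
  n <- cfg$n_cells + cfg$n_beads
  if (n == 0L) stopf("empty cohort")
  kind <- sample(rep(c("cell", "bead"), c(cfg$n_cells, cfg$n_beads)))

  diameter <- ifelse(
    kind == "bead",
    rtrunc_norm(n, cfg$bead_diameter_um,
                cfg$bead_diameter_um * cfg$bead_diameter_cv,
                0.5 * cfg$bead_diameter_um, 1.5 * cfg$bead_diameter_um),
    rtrunc_norm(n, cfg$cell_diameter_mean_um, cfg$cell_diameter_sd_um,
                max(2, cfg$cell_diameter_mean_um - 4 * cfg$cell_diameter_sd_um),
                cfg$cell_diameter_mean_um + 4 * cfg$cell_diameter_sd_um))

  ylim <- geom$width_um / 2 - diameter / 2
  zlim <- geom$height_um / 2 - diameter / 2
  y <- rtrunc_norm(n, 0, cfg$focusing_sd_um, -ylim, ylim)
  z <- rtrunc_norm(n, 0, cfg$z_sd_um, -zlim, zlim)

  rel_noise <- if (cfg$deform_mean > 1) cfg$deform_sd / cfg$deform_mean else 0
  deform_true <- pmax(1, cfg$deform_mean * (1 + stats::rnorm(n, 0, rel_noise)))
  deform_true[kind == "bead"] <- 1
  u2 <- (2 * abs(y) / geom$width_um)^2
  deform_opt <- deform_true * (1 + cfg$wall_deform_gain * u2)
  tail_skew <- cfg$wall_skew_gain * u2
  deform_opt[kind == "bead"] <- 1
  tail_skew[kind == "bead"] <- 0

  velocity <- velocity_profile(y, z, cfg$flow_ul_min, geom)
  t_entry <- cumsum(stats::rexp(n, cfg$event_rate_hz))

  out <- data.frame(
    id = seq_len(n), kind = kind, diameter_um = diameter,
    deform_true = deform_true, deform_opt = deform_opt, tail_skew = tail_skew,
    y_um = y, z_um = z, velocity_m_s = velocity, t_entry_s = t_entry,
    group = ifelse(kind == "bead", "bead", cfg$group),
    flow_ul_min = cfg$flow_ul_min, seed = cfg$seed,
    stringsAsFactors = FALSE)
  out <- out[order(out$t_entry_s), ]
  rownames(out) <- NULL
  class(out) <- c("particle_truth", "data.frame")
  out
}

#' Generate cohorts along a dose-response curve
#'
#' Builds one cohort configuration per concentration x replicate, with the
#' group mean deformability following the three-parameter Hill curve
#' [hill_curve()]. Used to emulate graded fixation (e.g. glutaraldehyde)
#' experiments where stiffening drives deformability from the untreated
#' plateau `y_max` down towards the rigid-bead floor `y_min`.
#'
#' @param concentrations non-negative dose levels (% v/v); include 0 as the
#'   untreated anchor.
#' @param hill_params list or vector with `y_max`, `y_min`, `ec50`.
#' @param n_reps replicates per concentration.
#' @param seed master seed; replicate seeds are derived from it.
#' @param ... further arguments passed to [cohort_config()] (e.g. `n_cells`,
#'   `flow_ul_min`, `deform_sd`).
#' @return a list of [cohort_config()] objects with attributes
#'   `concentration` and `replicate` set on each element.
#' @export
simulate_dose_response <- function(concentrations, hill_params, n_reps = 3,
                                   seed = 1L, ...) {
  hp <- as.list(hill_params)
  if (any(concentrations < 0)) stopf("concentrations must be >= 0")
  if (hp$ec50 <= 0) stopf("ec50 must be positive")
  cfgs <- list()
  for (i in seq_along(concentrations)) {
    cc <- concentrations[i]
    mu <- hill_curve(cc, hp$y_max, hp$y_min, hp$ec50)
    for (r in seq_len(n_reps)) {
      cfg <- cohort_config(group = sprintf("dose_%g", cc),
                           deform_mean = max(1, mu),
                           seed = derive_seed(seed, sprintf("dose%g_rep%d", cc, r)),
                           ...)
      attr(cfg, "concentration") <- cc
      attr(cfg, "replicate") <- r
      cfgs[[length(cfgs) + 1L]] <- cfg
    }
  }
  cfgs
}
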
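# strict local extrema of x above a threshold, thinned so that within
# `min_sep` samples only the largest survives
local_maxima <- function(x, thr, min_sep) {
  n <- length(x)
  if (n < 3) return(integer(0))
  core <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                  x[2:(n - 1)] > thr) + 1L
  if (length(core) < 2 || min_sep <= 1) return(core)
  keep <- logical(length(core))
  ord <- order(x[core], decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(core[i] - taken) >= min_sep)) {
      keep[i] <- TRUE
      taken <- c(taken, core[i])
    }
  }
  sort(core[keep])
}

# 3-point parabolic refinement around sample index i of series x;
# returns sub-sample offset (in samples) and refined extremum value
parabolic_refine <- function(x, i) {
  if (i <= 1L || i >= length(x)) return(c(0, x[i]))
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (denom == 0) return(c(0, x[i]))
  d <- 0.5 * (x[i - 1] - x[i + 1]) / denom
  d <- max(min(d, 0.5), -0.5)
  c(d, x[i] - 0.25 * (x[i - 1] - x[i + 1]) * d)
}

# Gaussian smoothing for detection only (positions/amplitudes are refined
# on the raw trace afterwards)
smooth_gauss <- function(x, sigma_samples) {
  m <- ceiling(3 * sigma_samples)
  k <- exp(-((-m):m)^2 / (2 * sigma_samples^2))
  k <- k / sum(k)
  stats::filter(c(rep(x[1], m), x, rep(x[length(x)], m)), k,
                sides = 2)[(m + 1):(m + length(x))]
}

# iterated least-squares parabola vertex around index i0, window halfwidth w;
# averages the noise over the crest instead of trusting 3 samples
refine_extremum_ls <- function(x, i0, w) {
  n <- length(x)
  i <- i0
  frac <- 0
  for (iter in 1:3) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    u <- (lo:hi) - i
    y <- x[lo:hi]
    S <- vapply(0:4, function(p) sum(as.numeric(u)^p), numeric(1))
    M <- matrix(c(S[1], S[2], S[3],
                  S[2], S[3], S[4],
                  S[3], S[4], S[5]), 3, 3)
    rhs <- c(sum(y), sum(y * u), sum(y * u^2))
    co <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(co) || co[3] >= 0) {        # not a maximum: 3-point fallback
      r <- parabolic_refine(x, i)
      return(c(i + r[1], r[2]))
    }
    v <- -co[2] / (2 * co[3])
    v <- max(min(v, w), -w)
    i_new <- i + as.integer(round(v))
    frac <- v - round(v)
    if (i_new == i) { frac <- v; break }
    i <- i_new
  }
  lo <- max(1L, i - w); hi <- min(n, i + w)
  u <- (lo:hi) - i
  y <- x[lo:hi]
  S <- vapply(0:4, function(p) sum(as.numeric(u)^p), numeric(1))
  M <- matrix(c(S[1], S[2], S[3], S[2], S[3], S[4], S[3], S[4], S[5]), 3, 3)
  co <- tryCatch(solve(M, c(sum(y), sum(y * u), sum(y * u^2))),
                 error = function(e) NULL)
  if (is.null(co) || co[3] >= 0) {
    r <- parabolic_refine(x, i)
    return(c(i + r[1], r[2]))
  }
  v <- max(min(-co[2] / (2 * co[3]), w), -w)
  c(i + v, co[1] + co[2] * v + co[3] * v^2)
}

# matched bi-Gaussian template amplitude by linear least squares:
# A = sum(x m) / sum(m^2) with m(t) = g(t - t1) - g(t - t1 - dt1),
# optionally maximised over integer shifts (for the downstream channel,
# whose exact timing carries the velocity-estimate error)
template_ls_amp <- function(x, fs, t1_s, dt1_s, sigma_s, shift_samples = 0L) {
  n <- length(x)
  lo <- floor((t1_s - 2.5 * sigma_s) * fs) + 1L
  hi <- ceiling((t1_s + dt1_s + 2.5 * sigma_s) * fs) + 1L
  pad <- max(abs(shift_samples))
  if (lo - pad < 1L || hi + pad > n) return(NA_real_)
  tt <- (seq.int(lo, hi) - 1L) / fs
  best <- NA_real_
  for (s in shift_samples) {
    t0 <- t1_s + s / fs
    m <- exp(-(tt - t0)^2 / (2 * sigma_s^2)) -
      exp(-(tt - t0 - dt1_s)^2 / (2 * sigma_s^2))
    a <- sum(x[(lo:hi) + s] * m) / sum(m^2)
    if (is.na(best) || a > best) best <- a
  }
  best
}

#' Detect impedance events on a two-channel differential trace
#'
#' Runs peak-valley detection on the configuration-1 channel: candidate
#' positive peaks and negative valleys above `min_prominence` are paired
#' greedily in time — each peak with the next valley of comparable
#' magnitude (ratio within 0.5-2) arriving within the transit time of the
#' slowest plausible particle (0.01 m/s over `d1_um`). Candidates come from
#' a lightly smoothed copy of the trace so that noise cannot split a
#' crest; positions are then refined to sub-sample precision on the raw
#' trace by an iterated least-squares parabola over the crest, and the
#' transit time `dt1` is the refined peak-to-valley separation. The
#' amplitude `dI1` is the least-squares amplitude of the matched
#' bi-Gaussian template — the half peak-to-valley excursion of the ideal
#' signature, insensitive to baseline offset and near-optimal under white
#' noise.
#'
#' The configuration-2 amplitude `dI2` is read from the second channel by
#' the same matched template placed at the delay predicted by the event's
#' own velocity, scanning a few samples of shift to absorb the propagated
#' timing error. Unpaired extrema and events clipped by the trace edges
#' are dropped.
#'
#' @param trace an `impedance_trace` (see [synthesize_trace()]).
#' @param geom a [channel_geometry()].
#' @param acq an [acquisition_settings()]; defaults to the trace's sample
#'   rate.
#' @param min_prominence detection threshold in trace units; default 5x the
#'   robust noise SD estimated from first differences of channel 1.
#' @return a `data.frame` of class `impedance_events`: `event_id`,
#'   `t_extremum1_s`, `t_extremum2_s`, `dt1_s`, `velocity_m_s`, `dI1`,
#'   `dI2`, `ed_raw` (= dI1/dI2, bead-unnormalised), `t_trigger_s`.
#' @export
detect_events <- function(trace, geom = channel_geometry(), acq = NULL,
                          min_prominence = NULL) {
  stopifnot(inherits(trace, "impedance_trace"))
  x <- trace$ch1
  if (!length(x)) stopf("empty trace")
  if (any(!is.finite(x))) stopf("trace contains non-finite samples")
  fs <- trace$sample_rate_hz
  if (is.null(min_prominence)) {
    noise_sd <- stats::mad(diff(x)) / sqrt(2)
    min_prominence <- max(5 * noise_sd, 1e-12)
  }
  max_dt1 <- geom$d1_um * 1e-6 / 0.01          # slowest plausible particle
  max_gap <- round(max_dt1 * fs)
  # detect on a lightly smoothed copy (sigma 3 samples): noise wiggles must
  # not split a Gaussian crest; positions/amplitudes are refined on the raw
  # trace below. The smoothed peak keeps >= ~50% of the raw height at the
  # narrowest admissible Gaussian, hence the 0.5 factor on the threshold.
  xs <- smooth_gauss(x, 3)
  thr_s <- 0.5 * min_prominence
  min_sep <- 4L
  peaks <- local_maxima(xs, thr_s, min_sep)
  valleys <- local_maxima(-xs, thr_s, min_sep)
  edge <- 5L
  peaks <- peaks[peaks > edge & peaks < length(x) - edge]
  valleys <- valleys[valleys > edge & valleys < length(x) - edge]

  sig_frac <- geom$electrode_halfwidth_um / geom$d1_um  # sigma = frac * dt1
  events <- list()
  vi <- 1L
  used_v <- logical(length(valleys))
  for (pk in peaks) {
    while (vi <= length(valleys) && valleys[vi] <= pk) vi <- vi + 1L
    cand <- vi
    matched <- NA_integer_
    while (cand <= length(valleys) && valleys[cand] - pk <= max_gap) {
      if (!used_v[cand]) {
        ratio <- -xs[valleys[cand]] / xs[pk]
        if (ratio >= 0.5 && ratio <= 2) { matched <- cand; break }
      }
      cand <- cand + 1L
    }
    if (is.na(matched)) next
    used_v[matched] <- TRUE
    vl <- valleys[matched]
    # refine on the raw trace with a window matched to the Gaussian width
    sig0 <- max(2L, round(sig_frac * (vl - pk)))
    w <- max(2L, round(0.8 * sig0))
    rp <- refine_extremum_ls(x, pk, w)
    rv <- refine_extremum_ls(-x, vl, w)
    t1 <- (rp[1] - 1) / fs
    t2 <- (rv[1] - 1) / fs
    dt1 <- t2 - t1
    if (dt1 <= 0) next
    v <- geom$d1_um * 1e-6 / dt1
    sigma_s <- geom$electrode_halfwidth_um * 1e-6 / v
    dI1 <- template_ls_amp(x, fs, t1, dt1, sigma_s)
    if (is.na(dI1) || dI1 <= 0) next
    # matched window downstream: scan shifts to absorb the timing error
    # that the velocity estimate propagates into the predicted delay
    shift_max <- max(3L, ceiling(sigma_s * fs))
    dI2 <- template_ls_amp(trace$ch2, fs, t1 + geom$d12_um * 1e-6 / v, dt1,
                           sigma_s, shift_samples = -shift_max:shift_max)
    if (is.na(dI2) || dI2 <= 0) next
    events[[length(events) + 1L]] <- data.frame(
      t_extremum1_s = t1, t_extremum2_s = t2, dt1_s = dt1,
      velocity_m_s = v, dI1 = dI1, dI2 = dI2, ed_raw = dI1 / dI2)
  }
  if (!length(events)) {
    out <- data.frame(event_id = integer(0), t_extremum1_s = numeric(0),
                      t_extremum2_s = numeric(0), dt1_s = numeric(0),
                      velocity_m_s = numeric(0), dI1 = numeric(0),
                      dI2 = numeric(0), ed_raw = numeric(0),
                      t_trigger_s = numeric(0))
    class(out) <- c("impedance_events", "data.frame")
    return(out)
  }
  out <- do.call(rbind, events)
  out <- cbind(event_id = seq_len(nrow(out)), out)
  out$t_trigger_s <- predict_trigger(out, geom)
  class(out) <- c("impedance_events", "data.frame")
  out
}

#' Velocity from an impedance event
#'
#' The transit velocity is the electrode spacing over the peak-to-valley
#' transit time, `d1_um / dt1`.
#'
#' @param event an `impedance_events` row (or whole table), or a numeric
#'   vector of transit times in seconds.
#' @param geom a [channel_geometry()].
#' @return velocity in m/s.
#' @export
estimate_velocity <- function(event, geom = channel_geometry()) {
  dt1 <- if (is.numeric(event)) event else event$dt1_s
  if (any(dt1 <= 0)) stopf("transit time must be positive")
  geom$d1_um * 1e-6 / dt1
}

#' Predict the illumination trigger time for events
#'
#' A particle crosses the configuration-1 midpoint at the mean of its peak
#' and valley times; it reaches the optical window centre `d2_um`
#' downstream after `d2_um / velocity`. The LED should fire then, plus any
#' fixed system latency.
#'
#' @param events an `impedance_events` table.
#' @param geom a [channel_geometry()] (supplies `d2_um`).
#' @param latency_s fixed trigger latency to add (s).
#' @return trigger times in seconds (vector).
#' @export
predict_trigger <- function(events, geom = channel_geometry(), latency_s = 0) {
  if (any(events$velocity_m_s <= 0)) stopf("non-positive velocity")
  t_mid <- (events$t_extremum1_s + events$t_extremum2_s) / 2
  t_mid + geom$d2_um * 1e-6 / events$velocity_m_s + latency_s
}

#' Bead calibration statistics for the electrical chain
#'
#' Computes the reference medians over rigid calibration-bead events: the
#' configuration-1 amplitude median (anchors the electrical diameter at the
#' known 10 um bead size through the cube-root volume law) and the raw
#' amplitude-ratio median (anchors electrical deformability at 1 for rigid
#' spheres). Medians are used for outlier robustness.
#'
#' @param events an `impedance_events` table.
#' @param is_bead logical vector marking bead events (from a beads-only
#'   calibration run, or from ground truth in simulation).
#' @param bead_diameter_um known bead diameter.
#' @return list with `dI1_bead_median`, `ed_raw_bead_median`,
#'   `bead_diameter_um`, `n_beads`.
#' @export
bead_calibration <- function(events, is_bead, bead_diameter_um = 10) {
  if (sum(is_bead) < 1) stopf("calibration impossible: no bead events")
  list(dI1_bead_median = stats::median(events$dI1[is_bead]),
       ed_raw_bead_median = stats::median(events$ed_raw[is_bead]),
       bead_diameter_um = bead_diameter_um,
       n_beads = sum(is_bead))
}

#' Electrical diameter from the configuration-1 amplitude
#'
#' The low-frequency impedance amplitude scales with particle volume, so
#' the diameter is the cube root of the amplitude referenced to the
#' calibration beads: `d = bead_diameter * (dI1 / dI1_bead_median)^(1/3)`.
#'
#' @param dI1 configuration-1 amplitude(s).
#' @param calib a [bead_calibration()] result.
#' @return diameter(s) in um.
#' @export
electrical_diameter <- function(dI1, calib) {
  if (is.null(calib$dI1_bead_median)) stopf("missing bead calibration")
  calib$bead_diameter_um * (dI1 / calib$dI1_bead_median)^(1 / 3)
}

#' Electrical deformability (ED)
#'
#' The ratio of the two configuration amplitudes, probing the cell shape
#' along two orthogonal projections, normalised against the rigid
#' calibration beads so that spheres read exactly 1:
#' `ED = (dI1/dI2) / median_beads(dI1/dI2)`.
#'
#' @param dI1,dI2 amplitudes from configurations 1 and 2.
#' @param calib a [bead_calibration()] result.
#' @return ED value(s), dimensionless.
#' @export
electrical_deformability <- function(dI1, dI2, calib) {
  if (any(dI2 == 0)) stopf("zero configuration-2 amplitude")
  if (is.null(calib$ed_raw_bead_median)) stopf("missing bead calibration")
  (dI1 / dI2) / calib$ed_raw_bead_median
}

#' Write / read an impedance event table
#'
#' CSV with one row per event; column names carry units
#' (`*_s` seconds, amplitudes in trace units).
#'
#' @param events an `impedance_events` table.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("impedance_events", "data.frame")
  out
}
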
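#' Synthesize a two-channel differential impedance trace
#'
#' Each particle transiting an electrode configuration produces an
#' anti-symmetric double Gaussian on that configuration's differential
#' channel: a positive Gaussian as it crosses the first electrode pair and
#' a mirrored negative one at the second pair, separated by the transit
#' time `dt1 = d1_um / velocity`. The Gaussian width is
#' `electrode_halfwidth_um / velocity`.
#'
#' Amplitudes follow the low-frequency (insulating-particle) volume law:
#' the configuration-1 amplitude `A1` scales with `diameter^3`, normalised
#' so a 10 um bead has amplitude `amp_scale`. Configuration 2 probes the
#' orthogonal projection of the deformed cell, encoded here through an
#' identity shape-factor link: `A2 = A1 / deform_true`, so the amplitude
#' ratio `A1/A2` equals the true axis ratio, is 1 for rigid spheres, and is
#' strictly increasing and trivially invertible in the true deformability.
#' This link is a modelling convenience for ground-truth recovery, not a
#' dielectric model of the cell interior.
#'
#' Particles may overlap in time; contributions add, so coincidences are
#' representable. White Gaussian noise at `noise_sd` is added per channel.
#'
#' @param particles a `particle_truth` data frame (see [sample_cohort()]);
#'   may be empty.
#' @param geom a [channel_geometry()].
#' @param acq an [acquisition_settings()].
#' @param noise_sd additive Gaussian noise SD (same units as amplitudes).
#' @param amp_scale amplitude of a 10 um bead on channel 1.
#' @param duration_s trace length; defaults to the last entry time plus a
#'   clearance margin.
#' @param seed seed for the noise stream.
#' @return an `impedance_trace`: list with numeric vectors `ch1`, `ch2`,
#'   plus `sample_rate_hz`, `amp_scale`, `noise_sd`, `seed`.
#' @export
synthesize_trace <- function(particles, geom = channel_geometry(),
                             acq = acquisition_settings(), noise_sd = 0,
                             amp_scale = 1, duration_s = NULL, seed = 1L) {
  stopifnot(inherits(geom, "channel_geometry"),
            inherits(acq, "acquisition_settings"))
  fs <- acq$sample_rate_hz
  n_p <- if (is.null(particles)) 0L else nrow(particles)
  if (n_p > 0) {
    sigma_s <- geom$electrode_halfwidth_um * 1e-6 / particles$velocity_m_s
    # the central +-2 sigma lobe of each Gaussian must span >= 8 samples
    if (any(fs * 4 * sigma_s < 8))
      stopf("sample rate too low: need >= 8 samples per Gaussian width, got %.1f",
            min(fs * 4 * sigma_s))
  }
  if (is.null(duration_s)) {
    tail_s <- if (n_p > 0)
      max((geom$d12_um + geom$d1_um) * 1e-6 / particles$velocity_m_s +
            6 * geom$electrode_halfwidth_um * 1e-6 / particles$velocity_m_s)
    else 0.01
    duration_s <- (if (n_p > 0) max(particles$t_entry_s) else 0) + tail_s + 2e-3
  }
  n <- ceiling(duration_s * fs)
  ch1 <- numeric(n)
  ch2 <- numeric(n)
  tvec_add <- function(ch, t0, dt1, sigma, amp) {
    # add amp * [g(t - t0) - g(t - t0 - dt1)] touching only a local window
    lo <- max(1L, floor((t0 - 5 * sigma) * fs) + 1L)
    hi <- min(n, ceiling((t0 + dt1 + 5 * sigma) * fs) + 1L)
    if (lo > n || hi < 1L) return(ch)
    tt <- (seq.int(lo, hi) - 1L) / fs
    ch[lo:hi] <- ch[lo:hi] + amp * (exp(-(tt - t0)^2 / (2 * sigma^2)) -
                                    exp(-(tt - t0 - dt1)^2 / (2 * sigma^2)))
    ch
  }
  for (i in seq_len(n_p)) {
    p <- particles[i, ]
    v <- p$velocity_m_s
    dt1 <- geom$d1_um * 1e-6 / v
    sigma <- geom$electrode_halfwidth_um * 1e-6 / v
    a1 <- amp_scale * (p$diameter_um / 10)^3
    a2 <- a1 / p$deform_true
    ch1 <- tvec_add(ch1, p$t_entry_s, dt1, sigma, a1)
    ch2 <- tvec_add(ch2, p$t_entry_s + geom$d12_um * 1e-6 / v, dt1, sigma, a2)
  }
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "trace-noise"))
    ch1 <- ch1 + stats::rnorm(n, 0, noise_sd)
    ch2 <- ch2 + stats::rnorm(n, 0, noise_sd)
  }
  structure(list(ch1 = ch1, ch2 = ch2, sample_rate_hz = fs,
                 amp_scale = amp_scale, noise_sd = noise_sd, seed = seed),
            class = "impedance_trace")
}

#' Write / read a two-channel impedance trace
#'
#' CSV format: two columns `ch1,ch2`, one row per sample, with the sample
#' rate and seed in a JSON sidecar `<path>.json`. Binary format: float32
#' little-endian, channel 1 block then channel 2 block, same sidecar.
#'
#' @param trace an `impedance_trace`.
#' @param path output path.
#' @param format `"csv"` or `"bin"`.
#' @return `path`, invisibly (`write_trace`); an `impedance_trace`
#'   (`read_trace`).
#' @export
write_trace <- function(trace, path, format = c("csv", "bin")) {
  format <- match.arg(format)
  meta <- list(sample_rate_hz = trace$sample_rate_hz, seed = trace$seed,
               n_samples = length(trace$ch1), format = format,
               amp_scale = trace$amp_scale, noise_sd = trace$noise_sd)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  if (format == "csv") {
    utils::write.csv(data.frame(ch1 = trace$ch1, ch2 = trace$ch2),
                     path, row.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(trace$ch1), con, size = 4, endian = "little")
    writeBin(as.numeric(trace$ch2), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(meta$format, "bin")) {
    con <- file(path, "rb")
    on.exit(close(con))
    x <- readBin(con, "numeric", n = 2 * meta$n_samples, size = 4,
                 endian = "little")
    ch1 <- x[seq_len(meta$n_samples)]
    ch2 <- x[meta$n_samples + seq_len(meta$n_samples)]
  } else {
    df <- utils::read.csv(path)
    ch1 <- df$ch1; ch2 <- df$ch2
  }
  structure(list(ch1 = ch1, ch2 = ch2, sample_rate_hz = meta$sample_rate_hz,
                 amp_scale = meta$amp_scale %||% 1,
                 noise_sd = meta$noise_sd %||% NA_real_, seed = meta$seed),
            class = "impedance_trace")
}
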
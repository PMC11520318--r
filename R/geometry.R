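#' Microfluidic channel and electrode geometry
#'
#' Describes the sensing/imaging channel: a rectangular duct of
#' `width_um` (y, the image vertical axis) by `height_um` (z, the optical
#' axis), with two differential electrode configurations followed by an
#' optical image-capture window downstream.
#'
#' Coordinates: x runs along the flow (image horizontal axis), y across the
#' channel width with the origin on the midline, z across the height with
#' the origin on the midplane. x = 0 at the centre of the first electrode
#' pair of configuration 1.
#'
#' @param width_um channel width along y (um).
#' @param height_um channel height along z (um).
#' @param d1_um centre-to-centre spacing of the configuration-1 electrode
#'   pairs (um); the transit-time baseline.
#' @param d2_um distance from the configuration-1 midpoint to the centre of
#'   the optical window (um). Device-specific; always read from this object,
#'   never hard-coded downstream.
#' @param roi_width_um width of the optical image-capture window along the
#'   flow (um).
#' @param d12_um offset from the first configuration-1 electrode pair to the
#'   first configuration-2 pair (um); fixes where the second double-Gaussian
#'   sits on the configuration-2 channel.
#' @param electrode_halfwidth_um electrode half-width (um); sets the Gaussian
#'   width of a transit signature as `electrode_halfwidth_um / velocity`.
#' @return an object of class `channel_geometry`.
#' @export
channel_geometry <- function(width_um = 40, height_um = 30, d1_um = 40,
                             d2_um = 350, roi_width_um = 34,
                             d12_um = 100, electrode_halfwidth_um = 10) {
  for (nm in c("width_um", "height_um", "d1_um", "d2_um", "roi_width_um",
               "d12_um", "electrode_halfwidth_um"))
    assert_pos(get(nm), nm)
  if (roi_width_um >= d2_um)
    stopf("roi_width_um (%g) must be smaller than d2_um (%g)", roi_width_um, d2_um)
  structure(list(width_um = width_um, height_um = height_um, d1_um = d1_um,
                 d2_um = d2_um, roi_width_um = roi_width_um, d12_um = d12_um,
                 electrode_halfwidth_um = electrode_halfwidth_um),
            class = "channel_geometry")
}

#' Acquisition settings for the impedance and imaging chains
#'
#' @param sample_rate_hz ADC sample rate of the impedance stream (Hz).
#' @param frame_rate_hz free-running camera frame rate (Hz).
#' @param led_pulse_s LED illumination pulse duration (s); sets motion blur
#'   as `velocity * led_pulse_s`.
#' @param pixel_scale_um microns per camera pixel.
#' @param latency_jitter_s standard deviation of the trigger latency (s);
#'   spreads illumination positions around the window centre.
#' @return an object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(sample_rate_hz = 87000, frame_rate_hz = 100,
                                 led_pulse_s = 2e-6, pixel_scale_um = 0.63,
                                 latency_jitter_s = 2e-5) {
  assert_pos(sample_rate_hz, "sample_rate_hz")
  assert_pos(frame_rate_hz, "frame_rate_hz")
  assert_pos(pixel_scale_um, "pixel_scale_um")
  if (led_pulse_s < 0 || latency_jitter_s < 0)
    stopf("led_pulse_s and latency_jitter_s must be non-negative")
  if (sample_rate_hz < 50 * frame_rate_hz)
    stopf("sample_rate_hz must be much larger than frame_rate_hz")
  structure(list(sample_rate_hz = sample_rate_hz, frame_rate_hz = frame_rate_hz,
                 led_pulse_s = led_pulse_s, pixel_scale_um = pixel_scale_um,
                 latency_jitter_s = latency_jitter_s),
            class = "acquisition_settings")
}

# stable cosh(x)/cosh(X) for 0 <= x <= X, avoiding overflow at large X
cosh_ratio <- function(x, X) {
  exp(x - X) * (1 + exp(-2 * x)) / (1 + exp(-2 * X))
}

#' Laminar velocity profile in the rectangular channel
#'
#' Newtonian pressure-driven flow in a rectangular duct, from the classical
#' Fourier-series solution, scaled so the cross-sectional mean equals Q/A
#' for the requested volumetric flow rate. The profile vanishes on all four
#' walls and peaks at the channel centre (0, 0).
#'
#' The suspending medium in a shear deformability cytometer is weakly
#' viscoelastic; the Newtonian profile is used as a realistic stand-in for
#' the velocity magnitudes and their spatial structure, not as a rheological
#' model of the methylcellulose carrier.
#'
#' @param y_um lateral position(s) from the channel midline (um).
#' @param z_um height(s) from the channel midplane (um).
#' @param flow_ul_min volumetric flow rate (ul/min).
#' @param geom a [channel_geometry()].
#' @param n_terms number of odd series terms.
#' @return axial velocity in m/s, vectorised over `y_um`/`z_um`.
#' @export
velocity_profile <- function(y_um, z_um, flow_ul_min, geom, n_terms = 101) {
  stopifnot(inherits(geom, "channel_geometry"))
  assert_pos(flow_ul_min, "flow_ul_min")
  a <- geom$width_um
  b <- geom$height_um
  k <- max(length(y_um), length(z_um))
  y <- rep_len(y_um, k)
  z <- rep_len(z_um, k)
  if (any(abs(y) > a / 2 + 1e-9) || any(abs(z) > b / 2 + 1e-9))
    stopf("position outside the %g x %g um channel", a, b)
  n <- seq(1, 2 * n_terms - 1, by = 2)
  sgn <- rep_len(c(1, -1), length(n))            # (-1)^((n-1)/2) for odd n
  u <- numeric(k)
  for (i in seq_along(n)) {
    ni <- n[i]
    u <- u + sgn[i] / ni^3 * cos(ni * pi * y / a) *
      (1 - cosh_ratio(ni * pi * abs(z) / a, ni * pi * b / (2 * a)))
  }
  mean_u <- sum(2 / (pi * n^4) *
                  (1 - 2 * a / (n * pi * b) * tanh(n * pi * b / (2 * a))))
  q_m3s <- flow_ul_min * 1e-9 / 60
  area_m2 <- a * b * 1e-12
  (q_m3s / area_m2) * u / mean_u
}
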
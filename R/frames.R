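# continuous box blur kernel of width k pixels, sampled on integer taps
box_kernel <- function(k_px) {
  if (k_px <= 0) return(1)
  m <- ceiling((k_px + 1) / 2)
  taps <- -m:m
  w <- pmax(0, pmin(taps + 0.5, k_px / 2) - pmax(taps - 0.5, -k_px / 2))
  w <- w[w > 0]
  w / sum(w)
}

# polar boundary radius of the rendered cell shape at angle theta from the
# flow axis: area-preserving ellipse of axis ratio `deform`, times a
# one-sided C1 tear-drop factor that extends only the downstream side.
# A symmetric (1 + skew*cos(theta)) limacon would leave the total
# flow-axis extent unchanged and can even lower the moment-fit axis ratio
# of an elongated cell; the one-sided tail is what skews the measured
# long axis upward, as the near-wall artefact does.
shape_radius <- function(theta, r0_um, deform, skew) {
  a <- r0_um * sqrt(deform)
  b <- r0_um / sqrt(deform)
  (a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)) *
    (1 + skew * ((1 + cos(theta)) / 2)^2)
}

#' Render one brightfield-like frame of the optical window
#'
#' Draws dark filled cell outlines on a light background, as projected by a
#' short LED pulse onto the camera. The window spans `roi_width_um` along
#' the flow (image x, columns) and the full channel width along y (rows),
#' with the origin at the top-left and pixel centres at integer + 0.5.
#'
#' Cell boundaries follow `r(theta) = r0 * e(theta) * (1 + tail_skew *
#' ((1 + cos(theta))/2)^2)` where `e(theta)` is an area-preserving ellipse
#' stretching the flow axis by `deform_opt` and the second factor is a
#' smooth one-sided tail; `tail_skew > 0` gives the tear-drop shape of
#' cells sheared near a wall and strictly inflates the moment-fit long
#' axis, the artefact the lateral gate removes. Edges are anti-aliased by signed-distance
#' coverage. Motion blur is a 1-D box convolution along the flow of length
#' `velocity * led_pulse_s` per particle, and Gaussian pixel noise is added
#' at `noise_sd` (fraction of the unit contrast).
#'
#' @param particles data frame with columns `x_um` (offset of the particle
#'   centre from the window centre, along flow), `y_um`, `diameter_um`,
#'   `deform_opt`, `tail_skew`, `velocity_m_s`. May have zero rows (blank
#'   frame).
#' @param geom a [channel_geometry()].
#' @param acq an [acquisition_settings()].
#' @param noise_sd Gaussian pixel noise SD in contrast units.
#' @param blur apply the LED-pulse motion blur.
#' @param timestamp frame timestamp (s), stored on the result.
#' @param seed noise seed.
#' @return a `cyto_frame`: list with `image` (numeric matrix, rows = y,
#'   cols = x, background 1, cells dark), `mask` (logical ground-truth
#'   mask before blur/noise), `n_objects`, `timestamp`.
#' @export
render_frame <- function(particles, geom = channel_geometry(),
                         acq = acquisition_settings(), noise_sd = 0,
                         blur = TRUE, timestamp = NA_real_, seed = 1L) {
  px <- acq$pixel_scale_um
  W <- round(geom$roi_width_um / px)
  H <- round(geom$width_um / px)
  xs <- ((seq_len(W) - 0.5) - W / 2) * px   # um from window centre, along flow
  ys <- ((seq_len(H) - 0.5) - H / 2) * px   # um from channel midline
  cover <- matrix(0, H, W)
  mask <- matrix(FALSE, H, W)
  n_p <- if (is.null(particles)) 0L else nrow(particles)
  n_in <- 0L
  for (i in seq_len(n_p)) {
    p <- particles[i, ]
    rmax <- (p$diameter_um / 2) * sqrt(max(p$deform_opt, 1)) *
      (1 + p$tail_skew) + px
    if (abs(p$x_um) - rmax > geom$roi_width_um / 2)
      stopf("particle %d lies fully outside the image window", i)
    ci <- which(abs(xs - p$x_um) <= rmax)
    ri <- which(abs(ys - p$y_um) <= rmax)
    if (!length(ci) || !length(ri)) next
    dx <- outer(rep(1, length(ri)), xs[ci] - p$x_um)
    dy <- outer(ys[ri] - p$y_um, rep(1, length(ci)))
    th <- atan2(dy, dx)
    dist <- sqrt(dx^2 + dy^2) -
      shape_radius(th, p$diameter_um / 2, p$deform_opt, p$tail_skew)
    cov_i <- pmin(pmax(0.5 - dist / px, 0), 1)
    if (blur && acq$led_pulse_s > 0) {
      k <- box_kernel(p$velocity_m_s * acq$led_pulse_s * 1e6 / px)
      if (length(k) > 1)
        cov_i <- t(apply(cov_i, 1, function(row)
          stats::convolve(row, rev(k), type = "open")[
            (length(k) - 1) / 2 + seq_along(row)]))
    }
    cover[ri, ci] <- pmax(cover[ri, ci], cov_i)
    mask[ri, ci] <- mask[ri, ci] | (cov_i >= 0.5)
    n_in <- n_in + as.integer(abs(p$x_um) <= geom$roi_width_um / 2)
  }
  img <- 1 - cover
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "frame-noise"))
    img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    img <- pmin(pmax(img, 0), 1)
  }
  structure(list(image = img, mask = mask, n_objects = n_in,
                 timestamp = timestamp),
            class = "cyto_frame")
}

#' Render the impedance-triggered frame sequence of a run
#'
#' Emulates the trigger chain on ground truth: each particle fires the LED
#' when it is predicted to reach the window centre, offset by a Gaussian
#' trigger-latency error of SD `acq$latency_jitter_s`. Flashes landing in
#' the same camera frame period (free-running at `frame_rate_hz`) expose
#' the same frame, so nearby particles produce multi-object frames
#' (coincidences). All particles inside the window at a flash instant are
#' rendered.
#'
#' @param cohort a `particle_truth` data frame from [sample_cohort()].
#' @param geom,acq geometry and acquisition settings.
#' @param noise_sd pixel noise SD (contrast units).
#' @param seed seed for latency jitter and pixel noise.
#' @return a `frame_stack`: list with `frames` (list of `cyto_frame`),
#'   `frame_index` (0-based camera frame numbers), `timestamps` (flash
#'   times, s), `truth` (per-frame data frames of rendered particles with
#'   their `x_um` offsets), and `pixel_scale_um`.
#' @export
render_run_frames <- function(cohort, geom = channel_geometry(),
                              acq = acquisition_settings(), noise_sd = 0,
                              seed = 1L) {
  stopifnot(nrow(cohort) > 0)
  set.seed(derive_seed(seed, "trigger-latency"))
  x_wc_um <- geom$d1_um / 2 + geom$d2_um   # window centre, from x = 0
  lat <- stats::rnorm(nrow(cohort), 0, acq$latency_jitter_s)
  t_fire <- cohort$t_entry_s + x_wc_um * 1e-6 / cohort$velocity_m_s + lat
  fidx <- floor(t_fire * acq$frame_rate_hz)
  ord <- order(t_fire)
  frames <- list(); truth <- list()
  f_out <- integer(0); ts_out <- numeric(0)
  for (fi in sort(unique(fidx))) {
    firings <- ord[fidx[ord] == fi]
    vis <- NULL
    for (j in firings) {
      t0 <- t_fire[j]
      x_all <- (t0 - cohort$t_entry_s) * cohort$velocity_m_s * 1e6 - x_wc_um
      # strictly inside render_frame's own outside-window bound
      rmax <- cohort$diameter_um / 2 * sqrt(pmax(cohort$deform_opt, 1)) *
        (1 + cohort$tail_skew)
      in_win <- which(abs(x_all) <= geom$roi_width_um / 2 + rmax)
      if (length(in_win)) {
        v <- cohort[in_win, c("id", "y_um", "diameter_um", "deform_opt",
                              "tail_skew", "velocity_m_s", "kind", "group")]
        v$x_um <- x_all[in_win]
        v$t_fire_s <- t0
        vis <- rbind(vis, v)
      }
    }
    if (is.null(vis)) next
    vis <- vis[!duplicated(vis$id), ]   # one drawing per particle per frame
    fr <- render_frame(vis, geom, acq, noise_sd = noise_sd,
                       timestamp = min(vis$t_fire_s),
                       seed = derive_seed(seed, paste0("frame", fi)))
    frames[[length(frames) + 1L]] <- fr
    truth[[length(truth) + 1L]] <- vis
    f_out <- c(f_out, fi)
    ts_out <- c(ts_out, min(vis$t_fire_s))
  }
  structure(list(frames = frames, frame_index = f_out, timestamps = ts_out,
                 truth = truth, pixel_scale_um = acq$pixel_scale_um,
                 seed = seed),
            class = "frame_stack")
}

#' Write / read a frame stack as multi-page TIFF
#'
#' Images are stored as 32-bit float grayscale TIFF pages; frame indices and
#' timestamps go to a sidecar CSV `<path>.meta.csv` (columns `frame_index`,
#' `timestamp_s`). Requires the `tiff` package.
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path.
#' @return `path` invisibly (`write_frames`); a `frame_stack` without
#'   ground truth (`read_frames`).
#' @export
write_frames <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("the 'tiff' package is required for TIFF output")
  tiff::writeTIFF(lapply(stack$frames, `[[`, "image"), path,
                  bits.per.sample = 32L)
  utils::write.csv(data.frame(frame_index = stack$frame_index,
                              timestamp_s = stack$timestamps),
                   paste0(path, ".meta.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_frames
#' @param pixel_scale_um pixel scale to attach on read.
#' @export
read_frames <- function(path, pixel_scale_um = 0.63) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("the 'tiff' package is required for TIFF input")
  imgs <- tiff::readTIFF(path, all = TRUE)
  meta <- utils::read.csv(paste0(path, ".meta.csv"))
  frames <- lapply(seq_along(imgs), function(i)
    structure(list(image = imgs[[i]], mask = NULL, n_objects = NA_integer_,
                   timestamp = meta$timestamp_s[i]), class = "cyto_frame"))
  structure(list(frames = frames, frame_index = meta$frame_index,
                 timestamps = meta$timestamp_s, truth = NULL,
                 pixel_scale_um = pixel_scale_um, seed = NA_integer_),
            class = "frame_stack")
}
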
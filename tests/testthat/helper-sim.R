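# shared fixtures and independent oracles, built in code at test time

geom0 <- channel_geometry()
acq0 <- acquisition_settings()

# render a single centred particle and return frame + segmentation + fit
measure_single <- function(diameter_um = 10, deform = 1, skew = 0,
                           velocity = 0.1, noise = 0, blur = TRUE,
                           y_um = 0, seed = 11) {
  p <- data.frame(x_um = 0, y_um = y_um, diameter_um = diameter_um,
                  deform_opt = deform, tail_skew = skew,
                  velocity_m_s = velocity)
  fr <- render_frame(p, geom0, acq0, noise_sd = noise, blur = blur,
                     seed = seed)
  seg <- segment_cell(preprocess(fr))
  fit <- if (seg$count > 0) fit_ellipse_moments(seg$mask) else NULL
  list(frame = fr, seg = seg, fit = fit)
}

# brute-force pixel-cloud covariance oracle for the ellipse axes:
# eigendecomposition of the sample covariance of mask pixel coordinates
pca_axes_oracle <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  ev <- eigen(stats::cov(idx), symmetric = TRUE, only.values = TRUE)$values
  c(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(max(ev[2], 0)))
}

# rasterised analytic mask of the shape model (independent of render_frame's
# coverage path): pixel centre inside iff its radius is below the boundary
analytic_mask <- function(W, H, cx, cy, r0, deform = 1, skew = 0) {
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - cx
  ys <- matrix(rep(seq_len(H) - 0.5, W), H, W) - cy
  th <- atan2(ys, xs)
  a <- r0 * sqrt(deform); b <- r0 / sqrt(deform)
  rb <- (a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)) *
    (1 + skew * ((1 + cos(th)) / 2)^2)
  sqrt(xs^2 + ys^2) <= rb
}

# random blob: union of 1-3 random ellipses, guaranteed non-degenerate
random_blob <- function(seed, W = 64, H = 64) {
  set.seed(seed)
  m <- matrix(FALSE, H, W)
  for (k in seq_len(sample(1:3, 1))) {
    r0 <- runif(1, 6, 12)
    m <- m | analytic_mask(W, H, runif(1, 24, 40), runif(1, 24, 40),
                           r0, runif(1, 1, 1.8), runif(1, 0, 0.3))
  }
  m
}

# 2-D finite-difference Poiseuille oracle: SOR solve of lap(u) = -1 on the
# duct cross-section, zero on walls; returns max/mean velocity ratio
fd_duct_ratio <- function(width = 40, height = 30, h = 0.5) {
  ny <- round(width / h) + 1
  nz <- round(height / h) + 1
  u <- matrix(0, ny, nz)
  omega <- 2 / (1 + sin(pi / max(ny, nz)))
  ii <- 2:(ny - 1); jj <- 2:(nz - 1)
  parity <- outer(ii, jj, `+`) %% 2
  for (iter in 1:4000) {
    u_old <- u
    for (par in 0:1) {   # red-black SOR, vectorised
      nb <- u[ii - 1, jj] + u[ii + 1, jj] + u[ii, jj - 1] + u[ii, jj + 1]
      upd <- (1 - omega) * u[ii, jj] + omega * 0.25 * (nb + h^2)
      sel <- parity == par
      tmp <- u[ii, jj]; tmp[sel] <- upd[sel]; u[ii, jj] <- tmp
    }
    if (iter %% 50 == 0 && max(abs(u - u_old)) < 1e-10) break
  }
  wy <- c(0.5, rep(1, ny - 2), 0.5)
  wz <- c(0.5, rep(1, nz - 2), 0.5)
  mean_u <- sum(outer(wy, wz) * u) / sum(outer(wy, wz))
  max(u) / mean_u
}
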
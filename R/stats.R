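#' Normal fit of a deformability sample
#'
#' @param values numeric vector, n >= 2.
#' @return list with `mean` and `sd` (n - 1 denominator).
#' @export
normal_fit <- function(values) {
  if (length(values) < 2) stopf("need at least 2 values")
  list(mean = mean(values), sd = stats::sd(values))
}

#' Least-squares linear fit, optionally through the origin
#'
#' R-squared is always computed against the mean model
#' (`1 - SSE / sum((y - mean(y))^2)`), including for through-origin fits,
#' so that the two variants are comparable.
#'
#' @param x,y numeric vectors, n >= 3.
#' @param through_origin force a zero intercept.
#' @return list with `slope`, `intercept`, `r2`.
#' @export
linear_fit <- function(x, y, through_origin = FALSE) {
  if (length(x) < 3 || length(x) != length(y)) stopf("need n >= 3 paired points")
  if (stats::sd(x) == 0) stopf("degenerate x")
  fit <- if (through_origin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  co <- stats::coef(fit)
  slope <- unname(co[length(co)])
  intercept <- if (through_origin) 0 else unname(co[1])
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r2 = if (sst > 0) 1 - sse / sst else NA_real_)
}

#' Three-parameter Hill dose-response curve
#'
#' `y(c) = y_max + (y_min - y_max) * c / (ec50 + c)` with unit Hill slope:
#' the deformability falls from the untreated plateau `y_max` at zero dose
#' to the rigid floor `y_min` at saturation, passing through the midpoint
#' `(y_max + y_min)/2` at `c = ec50`.
#'
#' @param c concentration(s), >= 0.
#' @param y_max zero-dose response.
#' @param y_min saturating response.
#' @param ec50 half-maximal concentration, > 0.
#' @return response value(s).
#' @export
hill_curve <- function(c, y_max, y_min, ec50) {
  if (ec50 <= 0) stopf("ec50 must be positive")
  if (any(c < 0)) stopf("concentrations must be >= 0")
  y_max + (y_min - y_max) * c / (ec50 + c)
}

#' Fit the three-parameter Hill equation to dose-response data
#'
#' Nonlinear least squares (Levenberg-Marquardt) with a multi-start over a
#' log-spaced grid of EC50 initial values spanning the positive
#' concentration range, keeping the best-SSE converged fit. Zero
#' concentrations are handled exactly by the model (`y(0) = y_max`), so
#' the untreated anchor needs no log transform. A percentile bootstrap
#' over observations (resampling within concentration levels) gives the
#' EC50 confidence interval.
#'
#' Unidentifiable data (flat responses) yield `converged = FALSE` with a
#' diagnostic message rather than a spurious estimate.
#'
#' @param concentrations dose levels, >= 0, at least 4 distinct values
#'   including (a value near) zero recommended.
#' @param responses observed responses (same length).
#' @param n_boot bootstrap replicates for the EC50 CI (0 disables).
#' @param seed seed for the bootstrap.
#' @return a `dose_response_fit` list: `y_max`, `y_min`, `ec50`,
#'   `residual_sse`, `converged`, `ci_ec50` (2.5/97.5 percentiles or `NA`),
#'   `diagnostics`.
#' @export
fit_hill <- function(concentrations, responses, n_boot = 200, seed = 1L) {
  cc <- as.numeric(concentrations)
  yy <- as.numeric(responses)
  if (length(cc) != length(yy)) stopf("length mismatch")
  if (length(unique(cc)) < 4) stopf("need >= 4 concentration levels")
  if (any(yy <= 0)) stopf("responses must be positive")
  fail <- function(msg) structure(
    list(y_max = NA_real_, y_min = NA_real_, ec50 = NA_real_,
         residual_sse = NA_real_, converged = FALSE,
         ci_ec50 = c(NA_real_, NA_real_), diagnostics = msg),
    class = "dose_response_fit")
  if (stats::sd(yy) < 1e-12 * max(abs(yy)))
    return(fail("responses are constant: ec50 unidentifiable"))
  means <- tapply(yy, cc, mean)
  if (abs(max(means) - min(means)) < 1e-10 * max(abs(yy)))
    return(fail("no dose effect in level means: ec50 unidentifiable"))

  fit_once <- function(cc, yy) {
    pos <- sort(unique(cc[cc > 0]))
    grid <- exp(seq(log(min(pos) / 3), log(max(pos) * 3), length.out = 9))
    y_max0 <- mean(yy[cc == min(cc)])
    y_min0 <- min(tapply(yy, cc, mean))
    best <- NULL
    for (e0 in grid) {
      f <- tryCatch(
        minpack.lm::nlsLM(
          yy ~ y_max + (y_min - y_max) * cc / (ec50 + cc),
          start = list(y_max = y_max0, y_min = y_min0, ec50 = e0),
          lower = c(y_max = 0, y_min = 0, ec50 = min(pos) * 1e-6),
          upper = c(y_max = Inf, y_min = Inf, ec50 = max(pos) * 1e6),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(f)) next
      sse <- sum(stats::residuals(f)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(par = stats::coef(f), sse = sse)
    }
    best
  }
  best <- fit_once(cc, yy)
  if (is.null(best)) return(fail("nonlinear least squares did not converge"))

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(derive_seed(seed, "hill-boot"))
    idx_by_level <- split(seq_along(cc), cc)
    ec_b <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(idx_by_level, function(ix)
        ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
      fb <- fit_once(cc[idx], yy[idx])
      if (!is.null(fb)) ec_b[b] <- fb$par[["ec50"]]
    }
    if (sum(!is.na(ec_b)) >= max(10, n_boot / 2))
      ci <- unname(stats::quantile(ec_b, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(y_max = unname(best$par[["y_max"]]),
                 y_min = unname(best$par[["y_min"]]),
                 ec50 = unname(best$par[["ec50"]]),
                 residual_sse = best$sse, converged = TRUE,
                 ci_ec50 = ci, diagnostics = "ok"),
            class = "dose_response_fit")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' a two-sided p-value, as used for treated-vs-untreated deformability
#' comparisons.
#'
#' @param a,b numeric samples, each n >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      stopf("zero variance in both groups with equal means")
    return(list(t = Inf * sign(mean(a) - mean(b)), df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Per-group summaries of electrical and optical deformability
#'
#' @param correlated a `correlated_events` table (with optional `group`
#'   column).
#' @return data frame per group: `n`, and `mean`, `sd`, `sem` for `ed`
#'   and `od`.
#' @export
group_summary <- function(correlated) {
  grp <- if (!is.null(correlated$group)) correlated$group else
    rep("all", nrow(correlated))
  do.call(rbind, lapply(unique(grp), function(g) {
    s <- correlated[grp == g, ]
    data.frame(group = g, n = nrow(s),
               ed_mean = mean(s$ed), ed_sd = stats::sd(s$ed),
               ed_sem = stats::sd(s$ed) / sqrt(nrow(s)),
               od_mean = mean(s$od), od_sd = stats::sd(s$od),
               od_sem = stats::sd(s$od) / sqrt(nrow(s)))
  }))
}
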
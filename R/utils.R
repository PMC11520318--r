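# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("'%s' must be a single positive finite number", name)
  invisible(x)
}

#' Derive a per-stage seed from a master seed
#'
#' Fans a single master seed out to reproducible per-stage seeds so that
#' every pipeline stage can be re-run independently with the same stream.
#' The derivation is a fixed integer hash of the stage label; results stay
#' below 2^31 so they are valid R integer seeds.
#'
#' @param seed master seed (single integer).
#' @param stage character stage label, e.g. `"trace"`.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483587)
}

# truncated normal by rejection, vectorised over mean/sd/bounds; bounds are
# never many sigmas inside the bulk in this package, so rejection is cheap
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (all(sd <= 0)) return(pmin(pmax(mean, lower), upper))
  out <- numeric(n)
  need <- seq_len(n)
  for (iter in 1:1000) {
    if (!length(need)) break
    x <- stats::rnorm(length(need), mean[need], sd[need])
    ok <- x >= lower[need] & x <= upper[need]
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  if (length(need))  # pathological bounds: fall back to clamped draws
    out[need] <- pmin(pmax(mean[need], lower[need]), upper[need])
  out
}
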
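#' Trapezoidal area under a sampled curve
#'
#' Total (not incremental) area under the polyline through `(time, value)`,
#' in `value * min` units. This is the integration rule used for all OGTT
#' areas and clamp window averages in the package.
#'
#' @param time numeric vector of sample times (minutes), strictly increasing.
#' @param value numeric vector, same length as `time`.
#' @return Scalar area.
#' @export
trapz <- function(time, value) {
  if (length(time) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(time) != length(value)) stop("time/value length mismatch", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  sum(diff(time) * (utils::head(value, -1L) + utils::tail(value, -1L)) / 2)
}

#' Time-weighted mean of a sampled curve over an interval
#'
#' Trapezoidal integral divided by interval length; samples at the interval
#' bounds are obtained by linear interpolation so the mean is invariant to
#' resampling of a piecewise-linear trace.
#'
#' @param time,value sampled curve.
#' @param t_start,t_end interval bounds (minutes); default full range.
#' @return Scalar mean.
#' @export
time_weighted_mean <- function(time, value, t_start = min(time), t_end = max(time)) {
  if (t_start < min(time) || t_end > max(time)) {
    stop("interval outside sampled range", call. = FALSE)
  }
  keep <- time > t_start & time < t_end
  tt <- c(t_start, time[keep], t_end)
  vv <- c(
    stats::approx(time, value, xout = t_start)$y,
    value[keep],
    stats::approx(time, value, xout = t_end)$y
  )
  trapz(tt, vv) / (t_end - t_start)
}

#' Round half away from zero
#'
#' Table-style rounding (2.45 -> 2.5 at one decimal), unlike [round()]'s
#' round-half-even. Used when reproducing printed table cells.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: linear interpolation of a (time_min, value) curve, anchored at
# the origin (curves are zero before injection / time zero)
interp_curve <- function(curve, xout) {
  t <- curve$time_min
  v <- curve$value
  if (t[1] > 0) { t <- c(0, t); v <- c(0, v) }
  stats::approx(t, v, xout = xout, rule = 2)$y
}

# internal: scalar > 0 check with a caller-facing message
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

# internal: construct a timed-series data.frame
timed_series <- function(time_min, value, unit = "") {
  stopifnot(length(time_min) == length(value))
  structure(
    data.frame(time_min = time_min, value = value),
    unit = unit
  )
}

# internal: derive a per-stream 31-bit seed from a base seed and stream labels
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}

# internal: run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
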
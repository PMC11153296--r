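#' Kinetic parameters of the irreversible FDG two-tissue-compartment model
#'
#' K1 (ml ml^-1 min^-1) delivers tracer from plasma to the free tissue pool,
#' k2 (min^-1) returns it, k3 (min^-1) phosphorylates it irreversibly, and
#' Vb is the fractional blood volume contaminating the tissue signal. The
#' macro-parameter net influx rate is `Ki = K1 * k3 / (k2 + k3)`.
#'
#' @param K1,k2,k3 rate constants, all >= 0.
#' @param Vb blood volume fraction in \[0, 1\].
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3, Vb = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, Vb = Vb)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("kinetic parameters must be finite and non-negative", call. = FALSE)
  }
  if (Vb > 1) stop("Vb must be <= 1", call. = FALSE)
  structure(list(K1 = K1, k2 = k2, k3 = k3, Vb = Vb), class = "kinetic_params")
}

#' Analytic net influx rate of a parameter set
#'
#' @param params a [kinetic_params()].
#' @return `K1 * k3 / (k2 + k3)` (0 when `k2 + k3 == 0`).
#' @export
analytic_ki <- function(params) {
  if (params$k2 + params$k3 == 0) return(0)
  params$K1 * params$k3 / (params$k2 + params$k3)
}

#' Analytic arterial input function (Feng model)
#'
#' Sum-of-exponentials plasma curve with a linear rise,
#' `Cp(t) = (A1 t - A2 - A3) e^(-l1 t) + A2 e^(-l2 t) + A3 e^(-l3 t)`,
#' scaled so that its peak equals `peak_kBq_ml`. All activities are
#' decay-corrected to injection time.
#'
#' @param times_min evaluation times, minutes.
#' @param peak_kBq_ml peak plasma activity, kBq/ml.
#' @param A relative amplitudes `(A1, A2, A3)` (A1 in 1/min).
#' @param lambda decay rates `(l1, l2, l3)`, 1/min.
#' @return data.frame `time_min`, `value` (kBq/ml).
#' @export
feng_input <- function(times_min, peak_kBq_ml = 100,
                       A = c(851.1, 20.8, 21.88),
                       lambda = c(4.134, 0.1191, 0.01043)) {
  shape <- function(t) {
    ifelse(t <= 0, 0,
      (A[1] * t - A[2] - A[3]) * exp(-lambda[1] * t) +
        A[2] * exp(-lambda[2] * t) + A[3] * exp(-lambda[3] * t))
  }
  t_dense <- seq(0, max(times_min, 5), by = 0.01)
  peak0 <- max(shape(t_dense))
  timed_series(times_min, pmax(shape(times_min), 0) * peak_kBq_ml / peak0,
               unit = "kBq/ml")
}

#' Forward-simulate an irreversible 2TCM tissue curve
#'
#' Solves `C_T(t) = K1/(k2+k3) * [k3 + k2 e^(-(k2+k3) t)] (x) Cp(t)
#' + Vb Cb(t)` by exact quadrature of the convolution on a fine internal
#' grid (the blood curve `Cb` is taken equal to the plasma curve `Cp`).
#'
#' @param params a [kinetic_params()].
#' @param input_fn plasma input function, data.frame `time_min`, `value`,
#'   sampled densely enough to interpolate linearly; must cover `times_min`.
#' @param times_min output times, minutes.
#' @param dt internal integration step, minutes.
#' @return data.frame `time_min`, `value` — the tissue time-activity curve.
#' @export
simulate_2tcm <- function(params, input_fn, times_min, dt = 0.05) {
  stopifnot(inherits(params, "kinetic_params"))
  if (max(times_min) > max(input_fn$time_min) + 1e-9) {
    stop("input function does not cover the requested times", call. = FALSE)
  }
  beta <- params$k2 + params$k3
  tg <- seq(0, max(times_min), by = dt)
  cp <- interp_curve(input_fn, tg)
  cum_cp <- cumulative_trapz(tg, cp)
  if (params$K1 == 0) {
    ct <- rep(0, length(tg))
  } else if (beta == 0) {
    ct <- params$K1 * cum_cp
  } else {
    # C_T = K1/beta * (k3 * int Cp + k2 * e^{-beta t} * int e^{beta s} Cp ds)
    # The weighted integral is accumulated in a decayed form to avoid overflow.
    decayed <- exp_weighted_trapz(tg, cp, beta)
    ct <- params$K1 / beta * (params$k3 * cum_cp + params$k2 * decayed)
  }
  ct <- ct + params$Vb * cp
  timed_series(times_min,
               stats::approx(tg, ct, xout = times_min, rule = 2)$y,
               unit = "kBq/ml")
}

# internal: cumulative trapezoid integral along t
cumulative_trapz <- function(t, v) {
  c(0, cumsum(diff(t) * (utils::head(v, -1L) + utils::tail(v, -1L)) / 2))
}

# internal: y(t) = e^{-beta t} * int_0^t e^{beta s} v(s) ds, computed
# recursively so no term ever exceeds the running integral's scale
exp_weighted_trapz <- function(t, v, beta) {
  n <- length(t)
  out <- numeric(n)
  for (i in 2:n) {
    h <- t[i] - t[i - 1]
    d <- exp(-beta * h)
    # trapezoid on [t_{i-1}, t_i] with the e^{beta(s - t_i)} weight applied
    out[i] <- out[i - 1] * d + h * (v[i - 1] * d + v[i]) / 2
  }
  out
}

#' Patlak graphical analysis
#'
#' Regresses `C_T(t)/Cp(t)` on the "normalised time"
#' `int_0^t Cp dtau / Cp(t)` for `t >= t_star`; for an irreversible tracer
#' the late-time relationship is linear with slope Ki (the net influx rate)
#' and intercept the effective distribution volume.
#'
#' @param tac tissue curve, data.frame `time_min`, `value`.
#' @param input_fn plasma input function (dense), data.frame `time_min`, `value`.
#' @param t_star start of the linear phase, minutes (default 10: the end of
#'   the dynamic scan; all whole-body passes are later).
#' @return An object of class `patlak_result`: list with `ki`, `v0`, `r2`,
#'   `t_star`, `n_points`.
#' @export
patlak_fit <- function(tac, input_fn, t_star = 10) {
  keep <- tac$time_min >= t_star
  if (sum(keep) < 2L) stop("need >= 2 samples at t >= t_star", call. = FALSE)
  tt <- tac$time_min[keep]
  cp <- interp_curve(input_fn, tt)
  if (any(cp <= 0)) stop("plasma activity must be positive at fit times", call. = FALSE)
  tg <- seq(0, max(tt), by = 0.05)
  cpg <- interp_curve(input_fn, tg)
  icp <- stats::approx(tg, cumulative_trapz(tg, cpg), xout = tt)$y
  x <- icp / cp
  y <- tac$value[keep] / cp
  ols_line(x, y, t_star)
}

# internal: closed-form OLS with r2, shared by ROI and voxel fits
ols_line <- function(x, y, t_star) {
  n <- length(x)
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("degenerate Patlak abscissa", call. = FALSE)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  v0 <- ybar - slope * xbar
  sst <- sum((y - ybar)^2)
  r2 <- if (sst == 0) 1 else 1 - sum((y - (v0 + slope * x))^2) / sst
  structure(list(ki = slope, v0 = v0, r2 = max(0, min(1, r2)),
                 t_star = t_star, n_points = n),
            class = "patlak_result")
}

#' @export
print.patlak_result <- function(x, ...) {
  cat(sprintf("<patlak ki=%.5g ml/ml/min, v0=%.3g, r2=%.4f, n=%d (t*>=%g min)>\n",
              x$ki, x$v0, x$r2, x$n_points, x$t_star))
  invisible(x)
}

#' Default whole-body PET pass schedule
#'
#' Five static whole-body passes of ten 30-s bed positions each, following
#' the 10-min dynamic scan. Each organ is seen once per pass, at the frame
#' covering its bed position.
#'
#' @param pass_starts start times of the five passes, minutes.
#' @param n_bed number of bed positions per pass.
#' @param bed_s duration of one bed position, seconds.
#' @return data.frame `pass`, `bed`, `start_min`, `end_min`, `mid_min`.
#' @export
pass_schedule <- function(pass_starts = c(12, 30, 50, 70, 90),
                          n_bed = 10, bed_s = 30) {
  bed_min <- bed_s / 60
  out <- expand.grid(bed = seq_len(n_bed), pass = seq_along(pass_starts))
  out$start_min <- pass_starts[out$pass] + (out$bed - 1) * bed_min
  out$end_min <- out$start_min + bed_min
  out$mid_min <- out$start_min + bed_min / 2
  out[, c("pass", "bed", "start_min", "end_min", "mid_min")]
}

#' Sample a continuous TAC on the whole-body pass grid
#'
#' Frame-duration averaging of a densely sampled tissue curve over each
#' 30-s bed-position window of the five passes for one organ.
#'
#' @param tac dense tissue curve, data.frame `time_min`, `value`.
#' @param schedule a [pass_schedule()] (or subset), one row per frame.
#' @param bed bed position of the organ; frames of other beds are ignored.
#' @return data.frame `time_min` (frame midpoints), `value` (frame means).
#' @export
sample_whole_body_passes <- function(tac, schedule, bed = NULL) {
  if (!is.null(bed)) schedule <- schedule[schedule$bed == bed, , drop = FALSE]
  if (nrow(schedule) == 0L) stop("empty pass schedule", call. = FALSE)
  if (min(schedule$start_min) < min(tac$time_min) ||
      max(schedule$end_min) > max(tac$time_min)) {
    stop("pass schedule outside TAC support", call. = FALSE)
  }
  value <- mapply(function(a, b) {
    time_weighted_mean(tac$time_min, tac$value, a, b)
  }, schedule$start_min, schedule$end_min)
  timed_series(schedule$mid_min, value, unit = attr(tac, "unit") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default tissue lumped constants
#'
#' Literature defaults converting FDG flux to glucose flux per tissue;
#' exposed as configuration because published cohort tables do not pin them.
#'
#' @return Named numeric vector of lumped constants.
#' @export
default_lumped_constants <- function() {
  c(brain = 0.81, leg_muscle = 1.16, heart = 1.00, adipose = 1.14,
    sat = 1.14, liver = 1.00, pancreas = 1.00, lean_other = 1.00)
}

#' Convert a net influx rate to a tissue glucose metabolic rate
#'
#' `MRglu = Ki * [glucose] / LC`, reported per 100 ml of tissue:
#' with Ki in min^-1 and glucose in mmol/l (= umol/ml), the result is in
#' umol (100 ml tissue)^-1 min^-1.
#'
#' @param ki net influx rate, ml ml^-1 min^-1 (vectorised).
#' @param plasma_glucose steady-state plasma glucose, mmol/l.
#' @param lc lumped constant (> 0).
#' @return MRglu, umol (100 ml)^-1 min^-1.
#' @export
ki_to_mrglu <- function(ki, plasma_glucose, lc) {
  check_positive(plasma_glucose, "plasma_glucose")
  check_positive(lc, "lc")
  ki * plasma_glucose / lc * 100
}

#' Voxelwise Patlak Ki image
#'
#' Fits the Patlak line in every body voxel of a dynamic image series.
#' Background voxels (time-averaged activity below `background_tol` times
#' the series robust maximum) are masked to `NA`, as are voxels whose fit is
#' non-finite.
#'
#' @param activity_images list of [voxel_image()] frames on one grid.
#' @param frame_times_min frame midpoint times, same length.
#' @param input_fn plasma input function (dense), data.frame `time_min`, `value`.
#' @param t_star start of the Patlak linear phase, minutes.
#' @param background_tol background threshold as a fraction of the robust
#'   (99.9th percentile) maximum mean activity.
#' @return A [voxel_image()] of Ki (ml ml^-1 min^-1) with `NA` outside the body.
#' @export
make_ki_image <- function(activity_images, frame_times_min, input_fn,
                          t_star = 10, background_tol = 0.01) {
  if (length(activity_images) != length(frame_times_min)) {
    stop("one frame time per image is required", call. = FALSE)
  }
  ref <- activity_images[[1]]
  for (img in activity_images[-1]) check_same_grid(ref, img)
  keep <- frame_times_min >= t_star
  if (sum(keep) < 2L) stop("need >= 2 frames at t >= t_star", call. = FALSE)
  tt <- frame_times_min[keep]
  cp <- interp_curve(input_fn, tt)
  if (any(cp <= 0)) stop("plasma activity must be positive at fit times", call. = FALSE)
  tg <- seq(0, max(tt), by = 0.05)
  cpg <- interp_curve(input_fn, tg)
  icp <- stats::approx(tg, cumulative_trapz(tg, cpg), xout = tt)$y
  x <- icp / cp

  nvox <- prod(dim(ref$data))
  ymat <- vapply(which(keep), function(i) as.numeric(activity_images[[i]]$data),
                 numeric(nvox))
  mean_all <- rowMeans(vapply(seq_along(activity_images),
                              function(i) as.numeric(activity_images[[i]]$data),
                              numeric(nvox)))
  bg <- mean_all <= background_tol * stats::quantile(mean_all, 0.999, names = FALSE)

  ymat <- sweep(ymat, 2L, cp, "/")
  xc <- x - mean(x)
  slope <- as.numeric(ymat %*% xc) / sum(xc^2)
  slope[bg | !is.finite(slope)] <- NA_real_
  voxel_image(array(slope, dim = dim(ref$data)), ref$vox_mm)
}
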
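# Unit-peak gamma-variate bump used for OGTT excursions: 0 at t = 0,
# maximum 1 at t = tp; p > 1 delays the onset (late-peaking insulin).
ogtt_bump <- function(t, tp, p = 1) {
  ifelse(t <= 0, 0, (t / tp)^p * exp(p * (1 - t / tp)))
}

# internal: zero-noise OGTT glucose curve for a record on a time grid.
# Pre records (and post records without an AUC effect) anchor the curve to
# the subject's 2-h glucose; post records with an AUC effect anchor it to
# auc_factor times the stored pre-curve AUC (earlier peak, solved amplitude).
ogtt_glucose_curve <- function(rec, times) {
  o <- rec$ogtt
  g0 <- rec$vars[["fasting_glucose"]]
  b <- ogtt_bump(times, o$tp_glucose, o$p_glucose)
  if (!is.null(o$pre_auc_glucose) && abs(o$auc_factor - 1) > 1e-12) {
    target <- o$auc_factor * o$pre_auc_glucose
    span <- max(times) - min(times)
    amp <- (target - g0 * span) / trapz(times, b)
  } else {
    b120 <- ogtt_bump(120, o$tp_glucose, o$p_glucose)
    amp <- (rec$vars[["two_hour_glucose"]] - g0) / b120
  }
  pmax(g0 + amp * b, 0)
}

#' Generate an OGTT sample bundle for one participant
#'
#' Glucose follows a gamma-variate excursion above fasting anchored to the
#' subject's 2-h glucose; after surgery the curve is re-anchored to the
#' configured glucose-AUC increase (default +20%) with an earlier, higher
#' peak. Insulin follows a delayed excursion scaled by the configured
#' insulin response; C-peptide tracks insulin. At zero noise the t = 0
#' samples equal the fasting values exactly and the post/pre trapezoid AUC
#' ratio equals the configured factor exactly.
#'
#' @param participant a `participant_record`.
#' @param seed integer seed (default: derived from the cohort seed).
#' @param noise_cv multiplicative measurement CV applied to samples after
#'   t = 0 (default: the configured `ogtt_cv`).
#' @return data.frame `time_min`, `glucose_mmol_l`, `insulin_pmol_l`,
#'   `c_peptide_nmol_l`.
#' @export
generate_ogtt <- function(participant, seed = NULL,
                          noise_cv = participant$config$noise_params$ogtt_cv) {
  stopifnot(inherits(participant, "participant_record"))
  cfg <- participant$config
  if (is.null(seed)) seed <- cfg$seed
  times <- cfg$ogtt$times_min
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("OGTT schedule must start at 0 and strictly increase", call. = FALSE)
  }
  o <- participant$ogtt
  glucose <- ogtt_glucose_curve(participant, times)
  i0 <- participant$vars[["fasting_insulin"]]
  insulin <- i0 + o$insulin_response * i0 * ogtt_bump(times, o$tp_insulin, o$p_insulin)
  with_seed(derive_seed(seed, "ogtt", participant$id, participant$timepoint), {
    if (noise_cv > 0) {
      late <- times > 0
      glucose[late] <- glucose[late] *
        exp(stats::rnorm(sum(late), 0, noise_cv))
      insulin[late] <- insulin[late] *
        exp(stats::rnorm(sum(late), 0, noise_cv))
    }
  })
  data.frame(
    time_min = times,
    glucose_mmol_l = glucose,
    insulin_pmol_l = insulin,
    c_peptide_nmol_l = 0.3 + 0.004 * insulin
  )
}

#' Generate hyperinsulinaemic-euglycaemic clamp traces
#'
#' Plasma glucose relaxes from fasting to the clamp target (5.6 mmol/l) and
#' insulin rises to the clamp level (700 pmol/l) along a quadratic
#' equilibration ramp that reaches the target exactly at `equil_min`
#' (default 40 min), so the 60-120 min steady-state window is flat at zero
#' noise. The glucose infusion rate ramps up to the subject's true
#' `m_value * LBM` (mg/min). Multiplicative measurement noise is applied
#' per sample.
#'
#' @param participant a `participant_record`.
#' @param seed integer seed.
#' @param noise list overriding the configured CVs: `clamp_glucose_cv`,
#'   `clamp_insulin_cv`, `gir_cv`.
#' @return A [clamp_record()] with the subject's LBM and anthropometrics.
#' @export
generate_clamp_trace <- function(participant, seed = NULL, noise = NULL) {
  stopifnot(inherits(participant, "participant_record"))
  cfg <- participant$config
  if (is.null(seed)) seed <- cfg$seed
  np <- utils::modifyList(cfg$noise_params, noise %||% list())
  cl <- cfg$clamp
  if (cl$duration_min < 120) stop("clamp duration must be >= 120 min", call. = FALSE)
  if (cl$dt_min <= 0) stop("sampling interval must be > 0", call. = FALSE)
  times <- seq(0, cl$duration_min, by = cl$dt_min)
  ramp <- pmax(0, 1 - times / cl$equil_min)^2

  g0 <- participant$vars[["fasting_glucose"]]
  i0 <- participant$vars[["fasting_insulin"]]
  gir_ss <- participant$vars[["m_value"]] * participant$vars[["lbm"]]

  glucose <- cl$glucose_target + (g0 - cl$glucose_target) * ramp
  insulin <- cl$insulin_target + (i0 - cl$insulin_target) * ramp
  gir <- gir_ss * (1 - ramp)

  with_seed(derive_seed(seed, "clamp", participant$id, participant$timepoint), {
    late <- times > 0
    if (np$clamp_glucose_cv > 0) {
      glucose[late] <- glucose[late] * exp(stats::rnorm(sum(late), 0, np$clamp_glucose_cv))
    }
    if (np$clamp_insulin_cv > 0) {
      insulin[late] <- insulin[late] * exp(stats::rnorm(sum(late), 0, np$clamp_insulin_cv))
    }
    if (np$gir_cv > 0) {
      gir[late] <- gir[late] * exp(stats::rnorm(sum(late), 0, np$gir_cv))
    }
  })

  clamp_record(
    glucose = timed_series(times, glucose, "mmol/l"),
    insulin = timed_series(times, insulin, "pmol/l"),
    gir = timed_series(times, pmax(gir, 0), "mg/min"),
    lbm_kg = participant$vars[["lbm"]],
    height_m = participant$height,
    weight_kg = participant$vars[["weight"]],
    window = cl$window
  )
}
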
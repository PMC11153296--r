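#' Simulate an FDG-PET session for one participant
#'
#' Injects 4 MBq of FDG per kg body weight, builds an analytic (Feng-type)
#' plasma input function scaled to the dose, forward-simulates every
#' organ's tissue time-activity curve from its irreversible 2TCM parameter
#' set, samples each organ on the dynamic-scan and whole-body-pass frame
#' grid (frame-duration averaged), and accrues urinary activity into the
#' bladder by first-order clearance. All activities are decay-corrected to
#' injection time. Deterministic given the seed.
#'
#' @param participant a `participant_record` (carries the organ kinetics).
#' @param seed integer seed for the measurement noise.
#' @param noise_cv multiplicative CV applied to sampled TAC frames
#'   (default: configured `tac_cv`).
#' @param dt_out dense TAC output step, minutes.
#' @return List of class `fdg_session`:
#'   `input_fn` (dense plasma curve, kBq/ml),
#'   `tacs` (named list of dense organ curves),
#'   `passes` (named list of frame-sampled organ curves with noise),
#'   `schedule` (the [pass_schedule()] used),
#'   `urine` (cumulative bladder activity, kBq, non-decreasing),
#'   `dose_MBq`, and `truth` (per-organ analytic Ki and the
#'   glucose-equivalent urinary loss rate).
#' @export
generate_fdg_session <- function(participant, seed = NULL,
                                 noise_cv = participant$config$noise_params$tac_cv,
                                 dt_out = 0.25) {
  stopifnot(inherits(participant, "participant_record"))
  cfg <- participant$config
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(participant$kinetics) || !length(participant$kinetics)) {
    stop("participant has no organ kinetics", call. = FALSE)
  }
  weight <- participant$vars[["weight"]]
  dose_MBq <- cfg$pet$dose_mbq_per_kg * weight
  peak <- dose_MBq * 1000 / (weight * 230)

  sched <- pass_schedule(cfg$pet$pass_starts)
  t_end <- max(sched$end_min) + 2
  t_dense <- seq(0, t_end, by = dt_out)
  input_fn <- feng_input(seq(0, t_end, by = 0.05), peak)

  org <- cfg$organ_params
  tacs <- lapply(participant$kinetics, simulate_2tcm,
                 input_fn = input_fn, times_min = t_dense)
  beds <- stats::setNames(org$bed, org$organ)

  # dynamic frames (thorax scan, 0-10 min) then the five whole-body passes
  dyn_times <- seq(0.25, 10, by = 0.5)
  passes <- lapply(names(tacs), function(o) {
    wb <- sample_whole_body_passes(tacs[[o]], sched, bed = beds[[o]])
    if (beds[[o]] == 3L) { # thorax organs are also covered by the dynamic scan
      dyn <- timed_series(dyn_times,
                          stats::approx(tacs[[o]]$time_min, tacs[[o]]$value,
                                        xout = dyn_times)$y)
      wb <- rbind(dyn, wb)
    }
    wb
  })
  names(passes) <- names(tacs)
  with_seed(derive_seed(seed, "fdg", participant$id, participant$timepoint), {
    if (noise_cv > 0) {
      passes <- lapply(passes, function(p) {
        p$value <- p$value * exp(stats::rnorm(nrow(p), 0, noise_cv))
        p
      })
    }
  })

  dose_kbq <- dose_MBq * 1000
  fu <- cfg$pet$urinary_frac
  tau <- cfg$pet$urinary_tau
  urine <- timed_series(t_dense, fu * dose_kbq * (1 - exp(-t_dense / tau)), "kBq")
  t_ss <- mean(cfg$clamp$window)
  urate_ss <- fu * dose_kbq / tau * exp(-t_ss / tau)
  cp_ss <- stats::approx(input_fn$time_min, input_fn$value, xout = t_ss)$y

  structure(
    list(
      input_fn = input_fn, tacs = tacs, passes = passes, schedule = sched,
      urine = urine, dose_MBq = dose_MBq,
      truth = list(
        ki = vapply(participant$kinetics, analytic_ki, numeric(1)),
        urinary_rate_kBq_min = urate_ss,
        plasma_ss_kBq_ml = cp_ss,
        urinary_loss_umol_min = urate_ss / cp_ss * cfg$clamp$glucose_target
      )
    ),
    class = "fdg_session"
  )
}
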
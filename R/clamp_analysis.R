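#' Body surface area
#'
#' Du Bois (default) or Mosteller formula, height in metres, weight in kg.
#'
#' @param height_m height, m.
#' @param weight_kg weight, kg.
#' @param method `"dubois"` or `"mosteller"`.
#' @return BSA in m^2.
#' @export
body_surface_area <- function(height_m, weight_kg, method = c("dubois", "mosteller")) {
  method <- match.arg(method)
  check_positive(height_m, "height_m")
  check_positive(weight_kg, "weight_kg")
  h_cm <- height_m * 100
  switch(method,
    dubois = 0.007184 * weight_kg^0.425 * h_cm^0.725,
    mosteller = sqrt(h_cm * weight_kg / 3600)
  )
}

#' Clamp insulin infusion rate
#'
#' Insulin is infused at 56 mU per m^2 body surface per minute during the
#' hyperinsulinaemic-euglycaemic clamp.
#'
#' @inheritParams body_surface_area
#' @param rate_per_m2 infusion rate per unit BSA, mU m^-2 min^-1.
#' @return Infusion rate in mU/min.
#' @export
insulin_infusion_rate <- function(height_m, weight_kg, rate_per_m2 = 56,
                                  method = "dubois") {
  rate_per_m2 * body_surface_area(height_m, weight_kg, method)
}

#' Build a clamp record
#'
#' Bundles the clamp traces with the anthropometrics needed for M-value
#' normalisation. Traces are data.frames with columns `time_min`, `value`.
#'
#' @param glucose plasma glucose trace, mmol/l.
#' @param insulin plasma insulin trace, pmol/l.
#' @param gir glucose infusion rate trace, mg/min.
#' @param lbm_kg lean body mass, kg.
#' @param height_m,weight_kg anthropometrics.
#' @param window steady-state window `[t_start, t_end]` in minutes.
#' @return An object of class `clamp_record`.
#' @export
clamp_record <- function(glucose, insulin, gir, lbm_kg,
                         height_m = NA_real_, weight_kg = NA_real_,
                         window = c(60, 120)) {
  check_positive(lbm_kg, "lbm_kg")
  if (any(gir$value < 0)) stop("GIR must be non-negative", call. = FALSE)
  for (tr in list(glucose, insulin, gir)) {
    if (min(tr$time_min) > window[1] || max(tr$time_min) < window[2]) {
      stop("traces must cover the steady-state window", call. = FALSE)
    }
  }
  structure(
    list(glucose = glucose, insulin = insulin, gir = gir, lbm_kg = lbm_kg,
         height_m = height_m, weight_kg = weight_kg, window = window),
    class = "clamp_record"
  )
}

#' Steady-state window assessment
#'
#' Returns the nominal steady-state window (default 60-120 min) together
#' with the glucose coefficient of variation inside it, and flags the clamp
#' non-steady when the CV exceeds `cv_tol`.
#'
#' @param record a [clamp_record()].
#' @param cv_tol maximum acceptable glucose CV within the window (default 0.05).
#' @return List with `window`, `cv`, `steady` (logical).
#' @export
steady_state_window <- function(record, cv_tol = 0.05) {
  stopifnot(inherits(record, "clamp_record"))
  w <- record$window
  g <- record$glucose
  keep <- g$time_min >= w[1] & g$time_min <= w[2]
  if (sum(keep) < 2L) stop("too few glucose samples inside the window", call. = FALSE)
  v <- g$value[keep]
  cv <- stats::sd(v) / mean(v)
  list(window = w, cv = cv, steady = cv <= cv_tol)
}

#' Whole-body insulin sensitivity (M value)
#'
#' Time-weighted mean glucose infusion rate over the steady-state window,
#' normalised to lean body mass: mg (kg LBM)^-1 min^-1.
#'
#' @param record a [clamp_record()].
#' @return M value, mg (kg LBM)^-1 min^-1.
#' @export
m_value <- function(record) {
  stopifnot(inherits(record, "clamp_record"))
  w <- record$window
  gir_bar <- time_weighted_mean(record$gir$time_min, record$gir$value, w[1], w[2])
  gir_bar / record$lbm_kg
}

#' Glucose infusion rate in molar units
#'
#' Converts the M value to umol (kg LBM)^-1 min^-1 using the molar mass of
#' glucose (180.16 g/mol; 1 mg = 5.5506 umol).
#'
#' @param record a [clamp_record()], or a numeric M value in
#'   mg (kg LBM)^-1 min^-1.
#' @return GIR in umol (kg LBM)^-1 min^-1.
#' @export
gir_micromol <- function(record) {
  m <- if (inherits(record, "clamp_record")) m_value(record) else record
  m * 1000 / 180.16
}

#' Mean clamp glucose and insulin over the steady-state window
#'
#' @param record a [clamp_record()].
#' @return List with `glucose_mmol_l`, `insulin_pmol_l`.
#' @export
clamp_steady_levels <- function(record) {
  stopifnot(inherits(record, "clamp_record"))
  w <- record$window
  list(
    glucose_mmol_l = time_weighted_mean(record$glucose$time_min,
                                        record$glucose$value, w[1], w[2]),
    insulin_pmol_l = time_weighted_mean(record$insulin$time_min,
                                        record$insulin$value, w[1], w[2])
  )
}
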
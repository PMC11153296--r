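#' Fasting insulin-resistance index (HOMA-IR)
#'
#' HOMA1-IR: fasting glucose times fasting insulin divided by 22.5, with
#' glucose in mmol/l and insulin converted from pmol/l to uU/ml using the
#' standard factor 6.945 (equivalently, `glucose * insulin / 156.2625`).
#'
#' @param fasting_glucose fasting plasma glucose, mmol/l.
#' @param fasting_insulin fasting serum insulin, pmol/l.
#' @return HOMA-IR (unitless). Vectorised.
#' @examples
#' homa_ir(5.6, 67.9) # ~2.4
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin) {
  check_positive(fasting_glucose, "fasting_glucose")
  check_positive(fasting_insulin, "fasting_insulin")
  fasting_glucose * (fasting_insulin / 6.945) / 22.5
}

#' Total area under a sampled curve (trapezoid rule)
#'
#' Total AUC over the sampled interval, not incremental above baseline.
#'
#' @param series data.frame with columns `time_min` and `value`.
#' @return Area in `value * min`.
#' @export
auc_trapezoid <- function(series) {
  trapz(series$time_min, series$value)
}

#' Matsuda composite insulin-sensitivity index
#'
#' `10000 / sqrt(G0 * I0 * Gmean * Imean)` with glucose in mg/dl and insulin
#' in uU/ml; the means are time-weighted (trapezoidal) over the sampled OGTT.
#' Inputs use the package's native units (mmol/l, pmol/l) and are converted
#' internally (mmol/l -> mg/dl: x18.016; pmol/l -> uU/ml: /6.945). The
#' composite-mean variant is a documented convention; published cohort values
#' cannot pin the exact formula.
#'
#' @param ogtt data.frame with columns `time_min`, `glucose_mmol_l`,
#'   `insulin_pmol_l`; first sample must be at time 0.
#' @return Matsuda index (unitless).
#' @export
matsuda_index <- function(ogtt) {
  validate_ogtt(ogtt, min_samples = 3L)
  if (any(ogtt$glucose_mmol_l <= 0) || any(ogtt$insulin_pmol_l <= 0)) {
    stop("glucose and insulin must be positive", call. = FALSE)
  }
  g <- ogtt$glucose_mmol_l * 18.016
  i <- ogtt$insulin_pmol_l / 6.945
  g_mean <- time_weighted_mean(ogtt$time_min, g)
  i_mean <- time_weighted_mean(ogtt$time_min, i)
  10000 / sqrt(g[1] * i[1] * g_mean * i_mean)
}

#' Insulinogenic index (30-min incremental ratio)
#'
#' `(I30 - I0) / (G30 - G0)` with insulin in mU/l and glucose in mmol/l.
#' The early-phase convention requiring a 30 min sample; returns `NA` with a
#' warning when `G30 == G0` (undefined ratio).
#'
#' @inheritParams matsuda_index
#' @return Insulinogenic index (mU/l per mmol/l).
#' @export
insulinogenic_index <- function(ogtt) {
  validate_ogtt(ogtt, min_samples = 2L)
  i0 <- which(ogtt$time_min == 0)
  i30 <- which(ogtt$time_min == 30)
  if (length(i0) != 1L || length(i30) != 1L) {
    stop("samples at 0 and 30 min are required", call. = FALSE)
  }
  dg <- ogtt$glucose_mmol_l[i30] - ogtt$glucose_mmol_l[i0]
  di <- (ogtt$insulin_pmol_l[i30] - ogtt$insulin_pmol_l[i0]) / 6.945
  if (dg == 0) {
    if (di == 0) return(0)
    warning("G30 == G0: insulinogenic index undefined", call. = FALSE)
    return(NA_real_)
  }
  di / dg
}

#' Disposition index
#'
#' Product of the insulinogenic and Matsuda indices (secretion adjusted for
#' sensitivity).
#'
#' @inheritParams matsuda_index
#' @return Disposition index (unitless).
#' @export
disposition_index <- function(ogtt) {
  insulinogenic_index(ogtt) * matsuda_index(ogtt)
}

#' Convert HbA1c from IFCC (mmol/mol) to NGSP (%)
#'
#' NGSP master equation: `% = 0.09148 * mmol/mol + 2.152`.
#'
#' @param hba1c_mmol_mol HbA1c in IFCC units, mmol/mol.
#' @return HbA1c in NGSP percent. Vectorised.
#' @examples
#' hba1c_ifcc_to_ngsp(35.3) # 5.38
#' @export
hba1c_ifcc_to_ngsp <- function(hba1c_mmol_mol) {
  if (any(!is.finite(hba1c_mmol_mol)) || any(hba1c_mmol_mol < 0)) {
    stop("'hba1c_mmol_mol' must be non-negative", call. = FALSE)
  }
  0.09148 * hba1c_mmol_mol + 2.152
}

#' Classify glycaemia from fasting and 2-h OGTT glucose
#'
#' ADA criteria for a non-diabetic cohort: prediabetes if fasting glucose is
#' in \[5.6, 6.9\] mmol/l (impaired fasting glucose) or 2-h glucose is in
#' \[7.8, 11.0\] mmol/l (impaired glucose tolerance); otherwise
#' normoglycaemia. Diabetes-range values (fasting >= 7.0 or 2-h >= 11.1) are
#' rejected: the study population excludes diabetes.
#'
#' @param fasting_glucose fasting plasma glucose, mmol/l.
#' @param two_hour_glucose 2-h post-load glucose, mmol/l.
#' @param ifg_cutoff impaired-fasting-glucose lower bound, mmol/l
#'   (default 5.6, ADA; set 6.1 for the WHO rule).
#' @return `"prediabetes"` or `"normoglycaemia"`. Vectorised.
#' @export
classify_glycemia <- function(fasting_glucose, two_hour_glucose, ifg_cutoff = 5.6) {
  check_positive(fasting_glucose, "fasting_glucose")
  check_positive(two_hour_glucose, "two_hour_glucose")
  if (any(fasting_glucose >= 7.0) || any(two_hour_glucose >= 11.1)) {
    stop("diabetes-range glucose: outside the study population", call. = FALSE)
  }
  ifelse(fasting_glucose >= ifg_cutoff | two_hour_glucose >= 7.8,
         "prediabetes", "normoglycaemia")
}

#' All OGTT-derived indices for one participant
#'
#' @inheritParams matsuda_index
#' @return A one-row data.frame with columns `homa_ir`, `matsuda`,
#'   `insulinogenic`, `disposition`, `auc_glucose`, `auc_insulin`,
#'   `two_hour_glucose`.
#' @export
glycemic_indices <- function(ogtt) {
  validate_ogtt(ogtt, min_samples = 3L)
  g_series <- data.frame(time_min = ogtt$time_min, value = ogtt$glucose_mmol_l)
  i_series <- data.frame(time_min = ogtt$time_min, value = ogtt$insulin_pmol_l)
  mats <- matsuda_index(ogtt)
  insu <- insulinogenic_index(ogtt)
  data.frame(
    homa_ir = homa_ir(ogtt$glucose_mmol_l[1], ogtt$insulin_pmol_l[1]),
    matsuda = mats,
    insulinogenic = insu,
    disposition = insu * mats,
    auc_glucose = auc_trapezoid(g_series),
    auc_insulin = auc_trapezoid(i_series),
    two_hour_glucose = ogtt$glucose_mmol_l[ogtt$time_min == 120][1]
  )
}

# internal: structural checks shared by the OGTT index functions
validate_ogtt <- function(ogtt, min_samples = 3L) {
  need <- c("time_min", "glucose_mmol_l", "insulin_pmol_l")
  if (!all(need %in% names(ogtt))) {
    stop("OGTT table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(ogtt) < min_samples) stop("too few OGTT samples", call. = FALSE)
  if (ogtt$time_min[1] != 0) stop("first OGTT sample must be at 0 min", call. = FALSE)
  if (any(diff(ogtt$time_min) <= 0)) {
    stop("OGTT times must be strictly increasing", call. = FALSE)
  }
  if (any(ogtt$glucose_mmol_l < 0) || any(ogtt$insulin_pmol_l < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  invisible(ogtt)
}
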
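#' Per-tissue glucose uptake table from a Ki image
#'
#' Computes the mean net influx rate over each tissue mask and converts it
#' to a glucose metabolic rate via the tissue's lumped constant. Empty masks
#' yield an `NA` row (flagged missing, never zero). The output is
#' independent of the order in which masks are given.
#'
#' @param ki_image [voxel_image()] of Ki (`NA` outside the body), or a named
#'   numeric vector of ROI-level Ki values (ml ml^-1 min^-1).
#' @param masks named list of logical [voxel_image()] tissue masks
#'   (ignored when `ki_image` is already ROI-level).
#' @param plasma_glucose clamp steady-state plasma glucose, mmol/l.
#' @param lc_table named lumped constants covering every tissue
#'   (default [default_lumped_constants()]).
#' @param volumes_l optional named tissue volumes (litres) to carry along.
#' @return data.frame `tissue`, `ki`, `mrglu` (umol (100 ml)^-1 min^-1) and,
#'   if supplied, `volume_l`.
#' @export
tissue_uptake_table <- function(ki_image, masks = NULL, plasma_glucose,
                                lc_table = default_lumped_constants(),
                                volumes_l = NULL) {
  if (inherits(ki_image, "voxel_image")) {
    if (is.null(masks)) stop("tissue masks are required with a Ki image", call. = FALSE)
    ki <- vapply(masks, function(m) {
      check_same_grid(ki_image, m)
      sel <- m$data != 0
      if (!any(sel)) return(NA_real_)
      mean(ki_image$data[sel], na.rm = TRUE)
    }, numeric(1))
  } else {
    ki <- ki_image
    if (is.null(names(ki))) stop("ROI Ki values must be named by tissue", call. = FALSE)
  }
  tissues <- sort(names(ki))
  ki <- ki[tissues]
  missing_lc <- setdiff(tissues, names(lc_table))
  if (length(missing_lc)) {
    stop("no lumped constant for: ", paste(missing_lc, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    tissue = tissues,
    ki = unname(ki),
    mrglu = unname(ki_to_mrglu(ki, plasma_glucose, lc_table[tissues])),
    row.names = NULL
  )
  if (!is.null(volumes_l)) out$volume_l <- unname(volumes_l[tissues])
  out
}

#' Urinary FDG loss as a glucose-equivalent rate
#'
#' Renal FDG clearance (urine accrual rate over plasma activity) times the
#' plasma glucose concentration: the glucose-equivalent rate carried out of
#' the body in urine, umol/min.
#'
#' @param urine_rate_kBq_min steady-state bladder activity accrual, kBq/min.
#' @param plasma_activity_kBq_ml plasma activity at the same time, kBq/ml.
#' @param plasma_glucose plasma glucose, mmol/l (= umol/ml).
#' @return Loss rate, umol/min.
#' @export
urinary_glucose_loss <- function(urine_rate_kBq_min, plasma_activity_kBq_ml,
                                 plasma_glucose) {
  if (urine_rate_kBq_min < 0) stop("urine accrual must be non-negative", call. = FALSE)
  check_positive(plasma_activity_kBq_ml, "plasma_activity_kBq_ml")
  check_positive(plasma_glucose, "plasma_glucose")
  urine_rate_kBq_min / plasma_activity_kBq_ml * plasma_glucose
}

#' Whole-body glucose disposal (Rd)
#'
#' Tissue-integrated disposal: `Rd = sum_t MRglu_t * V_t / LBM`, with MRglu
#' in umol (100 ml)^-1 min^-1 and volumes in litres (1 l = 10 x 100 ml), so
#' Rd is in umol (kg LBM)^-1 min^-1. The glucose equivalent of urinary
#' tracer loss is subtracted from apparent uptake when
#' `urinary_correction = "subtract"` (the bladder itself must be excluded
#' from the tissue set).
#'
#' @param uptake data.frame with columns `mrglu` and `volume_l`
#'   (e.g. from [tissue_uptake_table()] with `volumes_l`).
#' @param lbm_kg lean body mass, kg.
#' @param urinary_loss_umol_min glucose-equivalent urinary loss, umol/min.
#' @param urinary_correction `"subtract"` or `"ignore"`.
#' @return Rd, umol (kg LBM)^-1 min^-1.
#' @export
whole_body_rd <- function(uptake, lbm_kg, urinary_loss_umol_min = 0,
                          urinary_correction = c("subtract", "ignore")) {
  urinary_correction <- match.arg(urinary_correction)
  check_positive(lbm_kg, "lbm_kg")
  if (!all(c("mrglu", "volume_l") %in% names(uptake))) {
    stop("'uptake' needs columns mrglu and volume_l", call. = FALSE)
  }
  if (any(is.na(uptake$mrglu)) || any(is.na(uptake$volume_l))) {
    stop("every tissue needs a finite MRglu and volume", call. = FALSE)
  }
  total <- sum(uptake$mrglu * uptake$volume_l * 10) # umol/min
  if (urinary_correction == "subtract") total <- total - urinary_loss_umol_min
  total / lbm_kg
}

#' Endogenous glucose production (EGP)
#'
#' Steady-state balance `EGP = Rd - GIR`, both in
#' umol (kg LBM)^-1 min^-1. Negative EGP (fully suppressed production under
#' hyperinsulinaemia plus estimation noise) is reported as-is with a warning.
#'
#' @param rd whole-body glucose disposal.
#' @param gir glucose infusion rate (same units).
#' @return EGP, umol (kg LBM)^-1 min^-1.
#' @export
egp <- function(rd, gir) {
  out <- rd - gir
  if (any(out < 0)) {
    warning("negative EGP: production fully suppressed (reported as-is)",
            call. = FALSE)
  }
  out
}

#' Whole-body turnover summary
#'
#' Bundles GIR, Rd and EGP with the per-tissue uptake table.
#'
#' @param uptake per-tissue table with `mrglu`, `volume_l`.
#' @param gir glucose infusion rate, umol (kg LBM)^-1 min^-1.
#' @param lbm_kg lean body mass, kg.
#' @param urinary_loss_umol_min glucose-equivalent urinary loss, umol/min.
#' @param urinary_correction `"subtract"` or `"ignore"`.
#' @return List of class `turnover_summary`: `gir`, `rd`, `egp`
#'   (umol (kg LBM)^-1 min^-1), `urinary_loss_umol_min`, `tissues`.
#' @export
turnover_summary <- function(uptake, gir, lbm_kg, urinary_loss_umol_min = 0,
                             urinary_correction = "subtract") {
  rd <- whole_body_rd(uptake, lbm_kg, urinary_loss_umol_min, urinary_correction)
  structure(
    list(gir = gir, rd = rd, egp = suppressWarnings(egp(rd, gir)),
         urinary_loss_umol_min = urinary_loss_umol_min, tissues = uptake),
    class = "turnover_summary"
  )
}

#' @export
print.turnover_summary <- function(x, ...) {
  cat(sprintf("<turnover GIR=%.1f Rd=%.1f EGP=%.1f umol/kgLBM/min>\n",
              x$gir, x$rd, x$egp))
  invisible(x)
}
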
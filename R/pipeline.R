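#' Simulate a full two-arm trial
#'
#' Generates the baseline cohort and applies the configured intervention
#' effects to every participant, returning pre and post records.
#'
#' @param config a [cohort_config()].
#' @return List with `pre` and `post` lists of `participant_record`s.
#' @export
simulate_trial <- function(config) {
  pre <- generate_cohort(config)
  post <- lapply(pre, apply_intervention)
  list(pre = pre, post = post)
}

#' Run the full quantification chain for one participant record
#'
#' Generates the raw data for the record (clamp traces, OGTT samples, FDG
#' session, optionally a voxel body phantom) and analyses them exactly as
#' real data would be: M value and GIR from the clamp steady state, OGTT
#' indices, Patlak Ki per organ from the whole-body pass samples, MRglu via
#' lumped constants, body composition from the water/fat images, and
#' whole-body Rd/EGP with urinary correction.
#'
#' @param record a `participant_record`.
#' @param seed integer seed passed to the generators.
#' @param use_phantom analyse voxel water/fat images for body composition
#'   (slower); otherwise ground-truth organ volumes are used directly.
#' @param vox_mm phantom voxel size when `use_phantom = TRUE`.
#' @return One-row data.frame of derived measurements.
#' @export
analyze_participant <- function(record, seed = NULL, use_phantom = FALSE,
                                vox_mm = 10) {
  cfg <- record$config
  if (is.null(seed)) seed <- cfg$seed

  clamp <- generate_clamp_trace(record, seed = seed)
  ss <- steady_state_window(clamp)
  lev <- clamp_steady_levels(clamp)
  m <- m_value(clamp)
  gir_u <- gir_micromol(clamp)

  ogtt <- generate_ogtt(record, seed = seed)
  gi <- glycemic_indices(ogtt)

  fdg <- generate_fdg_session(record, seed = seed)
  ki_est <- vapply(names(fdg$passes), function(o) {
    patlak_fit(fdg$passes[[o]], fdg$input_fn, t_star = cfg$pet$t_star)$ki
  }, numeric(1))

  if (use_phantom) {
    ph <- generate_body_phantom(record, vox_mm = vox_mm, seed = seed)
    comp <- body_composition(ph$water, ph$fat,
                             liver_mask = phantom_mask(ph, "liver"),
                             pancreas_mask = phantom_mask(ph, "pancreas"))
    vols <- ph$ground_truth$voxel_volumes_l
  } else {
    vols <- record$volumes_l
    comp <- data.frame(
      whole_body_volume_l = record$truth$body_volume_l,
      adipose_volume_l = record$truth$adipose_volume_l,
      non_adipose_volume_l = record$truth$body_volume_l -
        record$truth$adipose_volume_l,
      liver_fat_pct = record$vars[["liver_fat_pct"]],
      pancreas_fat_pct = record$vars[["pancreas_fat_pct"]]
    )
  }

  lc <- stats::setNames(cfg$organ_params$lc, cfg$organ_params$organ)
  uptake <- tissue_uptake_table(ki_est, plasma_glucose = lev$glucose_mmol_l,
                                lc_table = lc, volumes_l = vols)

  # urinary correction: accrual rate at the steady-state midpoint estimated
  # from the simulated bladder curve, converted to glucose equivalents
  t_ss <- mean(cfg$clamp$window)
  u <- fdg$urine
  du <- diff(stats::approx(u$time_min, u$value, xout = c(t_ss - 1, t_ss + 1))$y) / 2
  cp <- stats::approx(fdg$input_fn$time_min, fdg$input_fn$value, xout = t_ss)$y
  loss <- urinary_glucose_loss(du, cp, lev$glucose_mmol_l)

  turn <- turnover_summary(uptake, gir = gir_u, lbm_kg = record$vars[["lbm"]],
                           urinary_loss_umol_min = loss)

  g0 <- ogtt$glucose_mmol_l[1]
  g120 <- ogtt$glucose_mmol_l[ogtt$time_min == 120]
  glycemia <- classify_glycemia(min(g0, 6.9), min(g120, 11.0))

  mr <- stats::setNames(uptake$mrglu, paste0("mrglu_", uptake$tissue))
  out <- data.frame(
    id = record$id, arm = record$arm, timepoint = record$timepoint,
    weight = record$vars[["weight"]], bmi = record$vars[["bmi"]],
    lbm = record$vars[["lbm"]],
    fasting_glucose = record$vars[["fasting_glucose"]],
    fasting_insulin = record$vars[["fasting_insulin"]],
    hba1c_ifcc = record$vars[["hba1c_ifcc"]],
    hba1c_ngsp = hba1c_ifcc_to_ngsp(record$vars[["hba1c_ifcc"]]),
    clamp_steady = ss$steady, clamp_glucose = lev$glucose_mmol_l,
    clamp_insulin = lev$insulin_pmol_l,
    m_value = m, gir_umol = gir_u, rd = turn$rd, egp = turn$egp,
    urinary_loss = loss,
    comp,
    glycemia = glycemia,
    as.list(mr),
    gi,
    check.names = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Analyse a simulated trial end-to-end
#'
#' Runs [analyze_participant()] on every pre and post record and applies
#' the trial statistical layer: per-arm within-group paired tests and the
#' baseline-adjusted between-arm ANCOVA for each analysis variable (scale
#' chosen per variable by the normality gate on pooled baseline values),
#' plus Fisher's exact test on reversion from prediabetes to
#' normoglycaemia.
#'
#' @param sim a [simulate_trial()] result.
#' @param seed integer seed for the measurement-noise streams.
#' @param variables variables to compare (default: the main outcomes).
#' @param use_phantom,vox_mm see [analyze_participant()].
#' @return List: `participants` (long data.frame), `comparisons` (one row
#'   per variable x contrast), `reversion` (Fisher test + the 2x2 table).
#' @export
analyze_trial <- function(sim, seed = NULL,
                          variables = c("homa_ir", "matsuda", "m_value",
                                        "gir_umol", "rd", "egp", "weight",
                                        "adipose_volume_l", "liver_fat_pct",
                                        "mrglu_leg_muscle", "mrglu_heart",
                                        "mrglu_brain", "mrglu_liver",
                                        "mrglu_abd_adipose"),
                          use_phantom = FALSE, vox_mm = 10) {
  records <- c(sim$pre, sim$post)
  participants <- do.call(rbind, lapply(records, analyze_participant,
                                        seed = seed, use_phantom = use_phantom,
                                        vox_mm = vox_mm))
  comparisons <- compare_trial_variables(participants, variables)
  reversion <- reversion_table(participants)
  list(participants = participants, comparisons = comparisons,
       reversion = reversion)
}

# internal: within-arm paired tests and between-arm ANCOVA per variable
compare_trial_variables <- function(participants, variables) {
  rows <- list()
  for (v in variables) {
    wide <- merge(
      participants[participants$timepoint == "pre", c("id", "arm", v)],
      participants[participants$timepoint == "post", c("id", v)],
      by = "id", suffixes = c("_pre", "_post")
    )
    pre <- wide[[paste0(v, "_pre")]]
    post <- wide[[paste0(v, "_post")]]
    sc <- if (all(pre > 0) && all(post > 0)) normality_gate(pre) else "normal"
    for (arm in c("surgery", "lcd")) {
      sel <- wide$arm == arm
      if (sum(sel) < 3L) next
      r <- paired_change_test(pre[sel], post[sel], scale = sc)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(variable = v, arm = arm), r)
    }
    anc <- tryCatch(ancova_change(wide$arm, pre, post, scale = sc),
                    error = function(e) NULL)
    if (!is.null(anc)) {
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(variable = v, arm = "both"), anc)
    }
  }
  do.call(rbind, rows)
}

# internal: 2x2 reversion table (arm x reverted/not among baseline
# prediabetes) and its Fisher test
reversion_table <- function(participants) {
  wide <- merge(
    participants[participants$timepoint == "pre", c("id", "arm", "glycemia")],
    participants[participants$timepoint == "post", c("id", "glycemia")],
    by = "id", suffixes = c("_pre", "_post")
  )
  predm <- wide[wide$glycemia_pre == "prediabetes", ]
  tab <- matrix(0L, 2, 2,
                dimnames = list(arm = c("surgery", "lcd"),
                                outcome = c("reverted", "still_prediabetes")))
  for (arm in c("surgery", "lcd")) {
    sel <- predm$arm == arm
    tab[arm, "reverted"] <- sum(predm$glycemia_post[sel] == "normoglycaemia")
    tab[arm, "still_prediabetes"] <- sum(predm$glycemia_post[sel] == "prediabetes")
  }
  test <- if (all(rowSums(tab) > 0)) fisher_reversion_test(tab) else NULL
  list(table = tab, test = test)
}
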
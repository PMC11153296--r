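#' Convert a geometric mean with 95% CI to a log-scale SD
#'
#' Published geometric-mean summaries come as `gm (lo, hi)` for a given n;
#' the t-interval on the log scale gives
#' `sdlog = mean(log(hi/gm), log(gm/lo)) / t(0.975, n-1) * sqrt(n)`
#' (the two half-widths are averaged because printed intervals are rounded).
#'
#' @param gm geometric mean.
#' @param lo,hi 95% CI bounds.
#' @param n sample size behind the interval.
#' @return Log-scale SD.
#' @export
gm_ci_to_sdlog <- function(gm, lo, hi, n) {
  half <- mean(c(log(hi / gm), log(gm / lo)))
  half / stats::qt(0.975, n - 1) * sqrt(n)
}

# Baseline sampling distributions, one row per variable x arm.
# dist: "normal" (p1 = mean, p2 = SD, truncated at [lower, upper]),
#       "lognormal_gm" (p1 = geometric mean, p2 = sdlog),
#       "lognormal_mean" (p1 = arithmetic mean, p2 = CV).
default_baseline_params <- function() {
  sdw_s <- gm_ci_to_sdlog(110.6, 106.8, 114.7, 15)
  sdw_l <- gm_ci_to_sdlog(108.4, 97.6, 120.2, 9)
  sdi_s <- gm_ci_to_sdlog(67.9, 44.5, 103.6, 15)
  sdi_l <- gm_ci_to_sdlog(128.0, 72.9, 224.9, 9)
  sdt_s <- gm_ci_to_sdlog(1.09, 0.87, 1.37, 15)
  sdt_l <- gm_ci_to_sdlog(1.60, 1.19, 2.14, 9)
  sdlbm_s <- gm_ci_to_sdlog(50.5, 48.8, 52.3, 15)
  sdlbm_l <- gm_ci_to_sdlog(54.7, 50.0, 59.8, 9)
  sdfat_s <- gm_ci_to_sdlog(49.3, 47.3, 51.3, 15)
  sdfat_l <- gm_ci_to_sdlog(44.5, 39.6, 50.1, 9)
  sdliv_s <- gm_ci_to_sdlog(6.1, 4.5, 11.6, 15)
  sdliv_l <- gm_ci_to_sdlog(6.0, 1.8, 15.5, 9)
  sdpan_s <- gm_ci_to_sdlog(9.3, 5.9, 18.9, 15)
  sdpan_l <- gm_ci_to_sdlog(8.0, 4.5, 14.2, 9)
  row <- function(variable, arm, dist, p1, p2, lower = -Inf, upper = Inf) {
    data.frame(variable = variable, arm = arm, dist = dist,
               p1 = p1, p2 = p2, lower = lower, upper = upper)
  }
  rbind(
    row("age", "surgery", "normal", 43, 11, 18, 70),
    row("age", "lcd", "normal", 41, 8, 18, 70),
    row("bmi", "surgery", "normal", 40.7, 2.5, 33, 48),
    row("bmi", "lcd", "normal", 38.4, 2.8, 31, 47),
    row("weight", "surgery", "lognormal_gm", 110.6, sdw_s, 80, 150),
    row("weight", "lcd", "lognormal_gm", 108.4, sdw_l, 80, 150),
    row("lbm_pct", "surgery", "lognormal_gm", 50.5, sdlbm_s, 38, 68),
    row("lbm_pct", "lcd", "lognormal_gm", 54.7, sdlbm_l, 38, 68),
    row("fat_pct", "surgery", "lognormal_gm", 49.3, sdfat_s, 25, 60),
    row("fat_pct", "lcd", "lognormal_gm", 44.5, sdfat_l, 25, 60),
    row("fasting_glucose", "surgery", "normal", 5.6, 0.5, 4.2, 6.9),
    row("fasting_glucose", "lcd", "normal", 6.0, 1.0, 4.2, 6.9),
    row("fasting_insulin", "surgery", "lognormal_gm", 67.9, sdi_s, 15, 450),
    row("fasting_insulin", "lcd", "lognormal_gm", 128.0, sdi_l, 15, 450),
    row("hba1c_ifcc", "surgery", "normal", 35.3, 3.4, 25, 47),
    row("hba1c_ifcc", "lcd", "normal", 35.4, 4.8, 25, 47),
    row("cholesterol", "surgery", "normal", 4.6, 1.1, 2, 9),
    row("cholesterol", "lcd", "normal", 5.2, 1.0, 2, 9),
    row("hdl", "surgery", "normal", 1.24, 0.32, 0.5, 3),
    row("hdl", "lcd", "normal", 1.16, 0.26, 0.5, 3),
    row("ldl", "surgery", "normal", 2.9, 0.8, 0.8, 7),
    row("ldl", "lcd", "normal", 3.5, 0.8, 0.8, 7),
    row("triglycerides", "surgery", "lognormal_gm", 1.09, sdt_s, 0.4, 4.5),
    row("triglycerides", "lcd", "lognormal_gm", 1.60, sdt_l, 0.4, 4.5),
    row("two_hour_glucose", "surgery", "normal", 7.4, 1.5, 4.5, 11.0),
    row("two_hour_glucose", "lcd", "normal", 8.2, 1.4, 4.5, 11.0),
    row("m_value", "surgery", "lognormal_mean", 8.6, 0.50, 1.5, 30),
    row("m_value", "lcd", "lognormal_mean", 7.9, 0.60, 1.5, 30),
    row("egp_clamp", "surgery", "lognormal_mean", 12.2, 0.60, 2, 60),
    row("egp_clamp", "lcd", "lognormal_mean", 11.4, 0.70, 2, 60),
    row("liver_fat_pct", "surgery", "lognormal_gm", 6.1, sdliv_s, 1, 40),
    row("liver_fat_pct", "lcd", "lognormal_gm", 6.0, sdliv_l, 1, 40),
    row("pancreas_fat_pct", "surgery", "lognormal_gm", 9.3, sdpan_s, 1.5, 40),
    row("pancreas_fat_pct", "lcd", "lognormal_gm", 8.0, sdpan_l, 1.5, 40)
  )
}

#' Construct a single intervention effect
#'
#' @param variable variable name (see [cohort_config()] for the known set).
#' @param value effect size: percent change for `scale = "relative"`
#'   (must be > -100), additive shift for `"absolute"`.
#' @param scale `"relative"` or `"absolute"`.
#' @param arm `"surgery"`, `"lcd"` or `"both"`.
#' @param noise_sdlog between-subject SD of the individual effect on the
#'   log scale (relative effects only).
#' @return One-row data.frame.
#' @export
intervention_effect <- function(variable, value, scale = c("relative", "absolute"),
                                arm = c("surgery", "lcd", "both"),
                                noise_sdlog = 0) {
  scale <- match.arg(scale)
  arm <- match.arg(arm)
  if (scale == "relative" && value <= -100) {
    stop("relative effects must be > -100%", call. = FALSE)
  }
  data.frame(variable = variable, arm = arm, scale = scale,
             value = value, noise_sdlog = noise_sdlog)
}

# Default intervention effects: the two arms' pre -> post shifts.
default_effect_params <- function() {
  e <- intervention_effect
  rbind(
    e("weight", -7.7, "relative", "surgery", 0.015),
    e("weight", -7.4, "relative", "lcd", 0.023),
    e("fasting_glucose", -7.1, "relative", "surgery", 0.05),
    e("fasting_glucose", -6.7, "relative", "lcd", 0.07),
    e("fasting_insulin", -30.8, "relative", "surgery", 0.25),
    e("fasting_insulin", -28.1, "relative", "lcd", 0.30),
    e("hba1c_ifcc", -11.9, "relative", "surgery", 0.03),
    e("hba1c_ifcc", -5.1, "relative", "lcd", 0.04),
    e("cholesterol", -21.7, "relative", "surgery", 0.10),
    e("cholesterol", -25.0, "relative", "lcd", 0.10),
    e("hdl", -20.2, "relative", "surgery", 0.10),
    e("hdl", -14.7, "relative", "lcd", 0.10),
    e("ldl", -24.1, "relative", "surgery", 0.12),
    e("ldl", -28.6, "relative", "lcd", 0.12),
    e("triglycerides", -14.7, "relative", "surgery", 0.15),
    e("triglycerides", -27.5, "relative", "lcd", 0.15),
    e("fat_pct", -3.0, "relative", "surgery", 0.02),
    e("fat_pct", -3.1, "relative", "lcd", 0.03),
    e("lbm_pct", 2.8, "relative", "surgery", 0.02),
    e("lbm_pct", 2.4, "relative", "lcd", 0.03),
    e("m_value", -14.0, "relative", "surgery", 0.30),
    e("m_value", -24.0, "relative", "lcd", 0.30),
    e("egp_clamp", 16.4, "relative", "surgery", 0.30),
    e("egp_clamp", 16.7, "relative", "lcd", 0.30),
    e("liver_fat_pct", -34.4, "relative", "surgery", 0.35),
    e("liver_fat_pct", -30.0, "relative", "lcd", 0.35),
    e("pancreas_fat_pct", 8.6, "relative", "surgery", 0.30),
    e("pancreas_fat_pct", 28.8, "relative", "lcd", 0.30),
    e("two_hour_glucose", -5.4, "relative", "surgery", 0.12),
    e("two_hour_glucose", -2.4, "relative", "lcd", 0.12),
    e("ogtt_glucose_auc", 20.0, "relative", "surgery", 0.08),
    e("ogtt_peak_time", -37.5, "relative", "surgery", 0),
    e("ki_leg_muscle", 25.0, "relative", "surgery", 0.15),
    e("ki_leg_muscle", -4.4, "relative", "lcd", 0.15),
    e("ki_heart", -56.9, "relative", "surgery", 0.15),
    e("ki_heart", -19.1, "relative", "lcd", 0.15),
    e("ki_abd_adipose", -14.3, "relative", "surgery", 0.15),
    e("ki_abd_adipose", -13.8, "relative", "lcd", 0.15),
    e("ki_sat", -14.3, "relative", "surgery", 0.15),
    e("ki_sat", -13.8, "relative", "lcd", 0.15),
    e("ki_brain", 4.5, "relative", "surgery", 0.10),
    e("ki_brain", 23.5, "relative", "lcd", 0.10),
    e("ki_liver", 11.5, "relative", "surgery", 0.15),
    e("ki_liver", 8.0, "relative", "lcd", 0.15)
  )
}

# Measurement-noise defaults per modality (coefficients of variation unless
# stated otherwise).
default_noise_params <- function() {
  list(
    clamp_glucose_cv = 0.03,
    clamp_insulin_cv = 0.05,
    gir_cv = 0.03,
    ogtt_cv = 0.04,
    tac_cv = 0.03,
    ff_sd = 0
  )
}

# Organ table: lumped constant, 2TCM shape parameters (k2, k3, Vb), PET bed
# position, phantom fat fraction, and per-arm baseline MRglu with its
# between-subject CV. The residual lean compartment ("lean_other") has no
# baseline of its own: its uptake is solved per subject from the turnover
# balance (see finalize_record).
default_organ_params <- function() {
  data.frame(
    organ = c("brain", "heart", "liver", "pancreas", "abd_adipose",
              "sat", "leg_muscle", "lean_other"),
    lc = c(0.81, 1.00, 1.00, 1.00, 1.14, 1.14, 1.16, 1.00),
    k2 = c(0.13, 0.25, 0.55, 0.30, 0.30, 0.30, 0.25, 0.25),
    k3 = c(0.06, 0.12, 0.02, 0.05, 0.02, 0.02, 0.05, 0.06),
    vb = c(0.04, 0.10, 0.25, 0.10, 0.02, 0.02, 0.03, 0.05),
    bed = c(1L, 3L, 4L, 4L, 5L, 5L, 8L, 5L),
    ff = c(0.05, 0.05, NA, NA, 0.90, 0.90, 0.05, 0.10),
    mrglu_surgery = c(11.2, 10.2, 2.6, 2.5, 0.70, 0.70, 5.7, NA),
    mrglu_lcd = c(11.5, 8.9, 2.5, 2.5, 0.58, 0.58, 4.5, NA),
    cv = c(0.34, 0.47, 0.31, 0.35, 0.26, 0.26, 0.58, 0)
  )
}

#' Configuration of the synthetic two-arm cohort
#'
#' Defaults reproduce the study conditions: a surgery arm of 15 and a
#' low-calorie-diet arm of 9, baseline distributions and intervention
#' effects keyed to the trial's clinical tables, clamp targets of
#' 5.6 mmol/l glucose and 700 pmol/l insulin, a 20% post-surgery OGTT
#' glucose-AUC increase, and organ FDG kinetics whose net influx rates are
#' back-derived from the reported tissue glucose uptake rates.
#'
#' @param n_surgery,n_lcd arm sizes (>= 0).
#' @param seed integer seed; all generator streams derive from it.
#' @param baseline_params,effect_params,noise_params,organ_params override
#'   tables / lists; see the package vignette for their layout.
#' @param clamp protocol list: `duration_min`, `dt_min`, `equil_min`,
#'   `glucose_target`, `insulin_target`, `window`.
#' @param ogtt protocol list: `times_min`, `tp_glucose`, `p_glucose`,
#'   `tp_insulin`, `p_insulin`, `insulin_response`.
#' @param pet protocol list: `dose_mbq_per_kg`, `pass_starts`, `t_star`,
#'   `urinary_frac`, `urinary_tau`.
#' @param sex_male_frac male fraction per arm (named vector).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_surgery = 15, n_lcd = 9, seed = 1,
                          baseline_params = default_baseline_params(),
                          effect_params = default_effect_params(),
                          noise_params = default_noise_params(),
                          organ_params = default_organ_params(),
                          clamp = list(duration_min = 120, dt_min = 5,
                                       equil_min = 40, glucose_target = 5.6,
                                       insulin_target = 700, window = c(60, 120)),
                          ogtt = list(times_min = c(0, 30, 60, 90, 120),
                                      tp_glucose = 40, p_glucose = 1,
                                      tp_insulin = 90, p_insulin = 6,
                                      insulin_response = 10.5),
                          pet = list(dose_mbq_per_kg = 4,
                                     pass_starts = c(12, 30, 50, 70, 90),
                                     t_star = 10,
                                     urinary_frac = 0.03, urinary_tau = 120),
                          sex_male_frac = c(surgery = 1 / 15, lcd = 1 / 9)) {
  if (n_surgery < 0 || n_lcd < 0) stop("arm sizes must be >= 0", call. = FALSE)
  if (any(baseline_params$p2 < 0)) stop("baseline SDs must be >= 0", call. = FALSE)
  known <- c(unique(baseline_params$variable),
             paste0("ki_", organ_params$organ),
             "ogtt_glucose_auc", "ogtt_peak_time")
  bad <- setdiff(unique(effect_params$variable), known)
  if (length(bad)) {
    stop("effect refers to unknown variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (clamp$duration_min < clamp$window[2]) {
    stop("clamp duration shorter than the steady-state window", call. = FALSE)
  }
  structure(
    list(n_surgery = n_surgery, n_lcd = n_lcd, seed = as.integer(seed),
         baseline_params = baseline_params, effect_params = effect_params,
         noise_params = noise_params, organ_params = organ_params,
         clamp = clamp, ogtt = ogtt, pet = pet,
         sex_male_frac = sex_male_frac),
    class = "cohort_config"
  )
}

# internal: one truncated draw per element, by rejection
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(100)) {
    bad <- x < lower | x > upper
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

# internal: sample one baseline variable for n subjects of one arm
# (log-normal draws are truncated on the log scale at the physiological
# bounds, like the normal ones)
sample_baseline <- function(spec, n) {
  lo <- if (is.finite(spec$lower) && spec$lower > 0) log(spec$lower) else -Inf
  hi <- if (is.finite(spec$upper)) log(spec$upper) else Inf
  switch(spec$dist,
    normal = rtrunc_norm(n, spec$p1, spec$p2, spec$lower, spec$upper),
    lognormal_gm = exp(rtrunc_norm(n, log(spec$p1), spec$p2, lo, hi)),
    lognormal_mean = {
      sdlog <- sqrt(log(1 + spec$p2^2))
      exp(rtrunc_norm(n, log(spec$p1) - sdlog^2 / 2, sdlog, lo, hi))
    },
    stop("unknown distribution: ", spec$dist, call. = FALSE)
  )
}

#' Generate the baseline (pre-intervention) cohort
#'
#' Samples every participant's anthropometrics, fasting biochemistry,
#' insulin-sensitivity truth (M value, clamp EGP), organ fat fractions and
#' organ FDG kinetics from the configured per-arm distributions. Height is
#' derived from sampled weight and BMI (`height = sqrt(weight / bmi)`), so
#' the BMI identity holds exactly. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return List of `participant_record` objects (timepoint `"pre"`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  arms <- c(rep("surgery", config$n_surgery), rep("lcd", config$n_lcd))
  if (length(arms) == 0L) return(list())
  records <- vector("list", length(arms))
  idx_in_arm <- c(seq_len(config$n_surgery), seq_len(config$n_lcd))
  for (i in seq_along(arms)) {
    arm <- arms[i]
    n_male <- round(config$sex_male_frac[[arm]] *
                      if (arm == "surgery") config$n_surgery else config$n_lcd)
    sex <- if (idx_in_arm[i] <= n_male) "male" else "female"
    records[[i]] <- with_seed(
      derive_seed(config$seed, "baseline", arm, idx_in_arm[i]),
      sample_participant(config, arm, sprintf("%s_%02d", arm, idx_in_arm[i]), sex)
    )
  }
  records
}

# internal: draw one pre-timepoint participant
sample_participant <- function(config, arm, id, sex) {
  bp <- config$baseline_params[config$baseline_params$arm == arm, ]
  vars <- stats::setNames(
    vapply(seq_len(nrow(bp)), function(j) sample_baseline(bp[j, ], 1L), numeric(1)),
    bp$variable
  )
  org <- config$organ_params
  mr_col <- paste0("mrglu_", arm)
  ki <- stats::setNames(numeric(nrow(org)), org$organ)
  for (j in seq_len(nrow(org))) {
    if (is.na(org[[mr_col]][j])) { ki[j] <- NA_real_; next }
    sdlog <- sqrt(log(1 + org$cv[j]^2))
    mr <- exp(stats::rnorm(1, log(org[[mr_col]][j]) - sdlog^2 / 2, sdlog))
    ki[j] <- mr * org$lc[j] / (100 * config$clamp$glucose_target)
  }
  rec <- structure(
    list(id = id, arm = arm, sex = sex, timepoint = "pre",
         vars = vars, height = sqrt(vars[["weight"]] / vars[["bmi"]]),
         ki = ki,
         ogtt = list(tp_glucose = config$ogtt$tp_glucose,
                     p_glucose = config$ogtt$p_glucose,
                     tp_insulin = config$ogtt$tp_insulin,
                     p_insulin = config$ogtt$p_insulin,
                     insulin_response = config$ogtt$insulin_response,
                     auc_factor = 1),
         config = config),
    class = "participant_record"
  )
  finalize_record(rec)
}

# internal: recompute everything derived from the sampled variables:
# BMI/LBM, organ volumes, the residual lean compartment's uptake (solved so
# the tissue-integrated Rd matches the GIR + EGP truth plus urinary loss),
# full kinetic parameter sets, and the ground-truth block.
finalize_record <- function(rec) {
  cfg <- rec$config
  v <- rec$vars
  v[["bmi"]] <- v[["weight"]] / rec$height^2
  v[["lbm"]] <- v[["lbm_pct"]] / 100 * v[["weight"]]

  wscale <- v[["weight"]] / 110.6
  vol <- c(
    brain = 1.30, heart = 0.66 * wscale, liver = 1.80 * wscale,
    pancreas = 0.10 * wscale, bladder = 0.25,
    leg_muscle = 8.0 * wscale, abd_adipose = 5.0 * wscale
  )
  body_l <- 0.934 * v[["weight"]]
  adipose_l <- body_l * v[["fat_pct"]] * 1.325 / 100
  vol[["sat"]] <- adipose_l - vol[["abd_adipose"]]
  lean_named <- sum(vol[c("brain", "heart", "liver", "pancreas",
                          "bladder", "leg_muscle")])
  vol[["lean_other"]] <- body_l - adipose_l - lean_named
  if (vol[["sat"]] <= 0 || vol[["lean_other"]] <= 0) {
    stop("degenerate body composition draw", call. = FALSE)
  }

  # urinary FDG truth: glucose-equivalent loss at the steady-state midpoint
  dose_kbq <- cfg$pet$dose_mbq_per_kg * v[["weight"]] * 1000
  peak <- dose_kbq / (v[["weight"]] * 230)
  t_ss <- mean(cfg$clamp$window)
  cp_ss <- feng_input(t_ss, peak)$value
  urate <- cfg$pet$urinary_frac * dose_kbq / cfg$pet$urinary_tau *
    exp(-t_ss / cfg$pet$urinary_tau)
  urinary_loss <- urate / cp_ss * cfg$clamp$glucose_target

  # solve the residual lean compartment so Rd (tissue route) = GIR + EGP
  org <- cfg$organ_params
  g <- cfg$clamp$glucose_target
  gir_umol <- v[["m_value"]] * 1000 / 180.16
  total_umol_min <- (gir_umol + v[["egp_clamp"]]) * v[["lbm"]] + urinary_loss
  others <- setdiff(org$organ, "lean_other")
  lc <- stats::setNames(org$lc, org$organ)
  mrglu <- rec$ki[others] * g / lc[others] * 100
  sum_others <- sum(mrglu * vol[others] * 10)
  mr_other <- (total_umol_min - sum_others) / (vol[["lean_other"]] * 10)
  if (mr_other < 0.2) {
    # floor the residual compartment and absorb the shortfall into EGP truth
    mr_other <- 0.2
    total <- sum_others + mr_other * vol[["lean_other"]] * 10
    v[["egp_clamp"]] <- (total - urinary_loss) / v[["lbm"]] - gir_umol
  }
  rec$ki[["lean_other"]] <- mr_other * lc[["lean_other"]] / (100 * g)

  kin <- lapply(org$organ, function(o) {
    j <- match(o, org$organ)
    ki <- rec$ki[[o]]
    kinetic_params(K1 = ki * (org$k2[j] + org$k3[j]) / org$k3[j],
                   k2 = org$k2[j], k3 = org$k3[j], Vb = org$vb[j])
  })
  names(kin) <- org$organ

  rec$vars <- v
  rec$volumes_l <- vol
  rec$kinetics <- kin
  rec$truth <- list(
    ki = rec$ki,
    mrglu = stats::setNames(rec$ki * g / lc[names(rec$ki)] * 100, names(rec$ki)),
    gir_umol = gir_umol,
    egp = v[["egp_clamp"]],
    rd = gir_umol + v[["egp_clamp"]],
    urinary_loss_umol_min = urinary_loss,
    adipose_volume_l = adipose_l,
    body_volume_l = body_l
  )
  rec
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant %s: %s/%s %s, %.1f kg, BMI %.1f, M=%.1f>\n",
              x$id, x$arm, x$timepoint, x$sex, x$vars[["weight"]],
              x$vars[["bmi"]], x$vars[["m_value"]]))
  invisible(x)
}

#' Apply intervention effects to a baseline participant
#'
#' Produces the post-timepoint record: each configured effect matching the
#' participant's arm is applied to its variable (multiplicatively for
#' relative effects, with optional per-subject log-normal effect noise);
#' all derived quantities (BMI, LBM, organ volumes and kinetics, turnover
#' truth) are then recomputed. Variables without an effect are untouched.
#'
#' @param participant a pre-timepoint `participant_record`.
#' @param effects effect table (rows as from [intervention_effect()]);
#'   defaults to the participant's configured effects.
#' @param seed integer seed for the effect noise (derived per subject).
#' @return The post-timepoint `participant_record`.
#' @export
apply_intervention <- function(participant, effects = NULL, seed = NULL) {
  stopifnot(inherits(participant, "participant_record"))
  if (participant$timepoint != "pre") {
    stop("intervention can only be applied to a pre-timepoint record", call. = FALSE)
  }
  cfg <- participant$config
  if (is.null(effects)) effects <- cfg$effect_params
  if (is.null(seed)) seed <- cfg$seed
  eff <- effects[effects$arm %in% c(participant$arm, "both"), , drop = FALSE]
  rec <- participant
  rec$timepoint <- "post"
  # remember the pre-curve OGTT glucose AUC so a configured AUC effect can
  # be honoured exactly after fasting glucose has shifted
  rec$ogtt$pre_auc_glucose <- trapz(
    cfg$ogtt$times_min, ogtt_glucose_curve(participant, cfg$ogtt$times_min)
  )
  if (nrow(eff) == 0L) return(finalize_record(rec))
  with_seed(derive_seed(seed, "effect", participant$id), {
    for (j in seq_len(nrow(eff))) {
      e <- eff[j, ]
      mult <- if (e$scale == "relative") {
        (1 + e$value / 100) *
          if (e$noise_sdlog > 0) exp(stats::rnorm(1, 0, e$noise_sdlog)) else 1
      } else NA
      apply_one <- function(x) {
        if (e$scale == "relative") x * mult else x + e$value
      }
      if (e$variable %in% names(rec$vars)) {
        rec$vars[[e$variable]] <- apply_one(rec$vars[[e$variable]])
      } else if (e$variable == "ogtt_glucose_auc") {
        rec$ogtt$auc_factor <- rec$ogtt$auc_factor * (1 + e$value / 100) *
          if (e$noise_sdlog > 0) exp(stats::rnorm(1, 0, e$noise_sdlog)) else 1
      } else if (e$variable == "ogtt_peak_time") {
        rec$ogtt$tp_glucose <- apply_one(rec$ogtt$tp_glucose)
      } else if (startsWith(e$variable, "ki_")) {
        organ <- sub("^ki_", "", e$variable)
        if (!organ %in% names(rec$ki)) {
          stop("effect on unknown organ: ", organ, call. = FALSE)
        }
        rec$ki[[organ]] <- apply_one(rec$ki[[organ]])
      } else {
        stop("effect on unknown variable: ", e$variable, call. = FALSE)
      }
    }
  })
  finalize_record(rec)
}

#' Cohort as a long table
#'
#' One row per participant record with the scalar variables, ready for the
#' statistical layer or CSV export.
#'
#' @param records list of `participant_record`s.
#' @return data.frame with `id`, `arm`, `sex`, `timepoint` and one column
#'   per scalar variable (plus `height`, derived volumes and truth Rd/EGP).
#' @export
cohort_table <- function(records) {
  rows <- lapply(records, function(r) {
    data.frame(
      id = r$id, arm = r$arm, sex = r$sex, timepoint = r$timepoint,
      height = r$height,
      as.list(r$vars),
      adipose_volume_l = r$truth$adipose_volume_l,
      body_volume_l = r$truth$body_volume_l,
      rd_truth = r$truth$rd,
      check.names = FALSE
    )
  })
  do.call(rbind, rows)
}
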
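test_that("cohort generation is empty-safe, seeded and convergent", {
  expect_equal(generate_cohort(cohort_config(0, 0)), list())

  cfg <- small_config()
  t1 <- cohort_table(generate_cohort(cfg))
  t2 <- cohort_table(generate_cohort(cfg))
  expect_identical(t1, t2)

  # large-n sample mean converges to the configured baseline
  big <- cohort_config(n_surgery = 500, n_lcd = 0, seed = 12)
  tab <- cohort_table(generate_cohort(big))
  sem <- 2.5 / sqrt(500)
  expect_lt(abs(mean(tab$bmi) - 40.7), 2 * sem)
  # BMI identity holds by construction
  expect_equal(tab$bmi, tab$weight / tab$height^2, tolerance = 1e-12)
  expect_true(all(tab$lbm > 0 & tab$lbm < tab$weight))
})

test_that("configuration rejects unknown effect variables and bad sizes", {
  expect_error(cohort_config(-1, 5), ">= 0")
  expect_error(
    cohort_config(effect_params = intervention_effect("not_a_variable", -5)),
    "unknown variable"
  )
  expect_error(intervention_effect("weight", -150), "-100")
})

test_that("intervention on a post record is a state error; empty effects are identity", {
  rec <- small_cohort()[[1]]
  post <- apply_intervention(rec)
  expect_error(apply_intervention(post), "pre-timepoint")

  none <- apply_intervention(rec, effects = rec$config$effect_params[0, ])
  expect_equal(none$vars, rec$vars, tolerance = 1e-12)
  expect_equal(none$ki, rec$ki, tolerance = 1e-12)
  expect_equal(none$timepoint, "post")
})

test_that("a zero-noise relative weight effect reproduces the reported change", {
  rec <- small_cohort()[[1]]
  rec$vars[["weight"]] <- 110.6
  rec <- metaboscope:::finalize_record(rec)
  post <- apply_intervention(rec, intervention_effect("weight", -7.7, "relative",
                                                      "surgery", noise_sdlog = 0))
  expect_equal(round_half_up(post$vars[["weight"]], 1), 102.1)
  # only effect-bearing (and derived) variables changed
  expect_equal(post$vars[["fasting_glucose"]], rec$vars[["fasting_glucose"]])
  expect_equal(post$height, rec$height)
  # arm-specific effects skip the other arm
  lcd_eff <- intervention_effect("weight", -50, "relative", "lcd")
  same <- apply_intervention(rec, lcd_eff)
  expect_equal(same$vars[["weight"]], rec$vars[["weight"]])
})

test_that("Monte-Carlo effect means recover the configured effects (3 SEM)", {
  cfg <- cohort_config(n_surgery = 200, n_lcd = 0, seed = 33)
  pre <- generate_cohort(cfg)
  post <- lapply(pre, apply_intervention)
  for (v in c("weight", "fasting_insulin", "m_value")) {
    lr <- log(vapply(post, function(r) r$vars[[v]], 1) /
                vapply(pre, function(r) r$vars[[v]], 1))
    eff <- cfg$effect_params
    target <- log(1 + eff$value[eff$variable == v & eff$arm == "surgery"] / 100)
    expect_lt(abs(mean(lr) - target), 3 * sd(lr) / sqrt(length(lr)) + 1e-12)
  }
  # configured HOMA-IR input effects propagate to the derived index
  homa_pre <- vapply(pre, function(r)
    homa_ir(r$vars[["fasting_glucose"]], r$vars[["fasting_insulin"]]), 1)
  homa_post <- vapply(post, function(r)
    homa_ir(r$vars[["fasting_glucose"]], r$vars[["fasting_insulin"]]), 1)
  lr <- log(homa_post / homa_pre)
  target <- log(1 - 0.071) + log(1 - 0.308)
  expect_lt(abs(mean(lr) - target), 3 * sd(lr) / sqrt(length(lr)))
})

test_that("OGTT bundle honours its schedule, null response and AUC effect", {
  rec <- small_cohort()[[1]]
  og <- generate_ogtt(rec)
  expect_equal(og$time_min, c(0, 30, 60, 90, 120))
  expect_true(all(diff(og$time_min) > 0))
  expect_true(all(og$glucose_mmol_l >= 0 & og$insulin_pmol_l >= 0))
  expect_equal(og$glucose_mmol_l[1], rec$vars[["fasting_glucose"]])
  expect_equal(og$insulin_pmol_l[1], rec$vars[["fasting_insulin"]])

  # zero absorption effect, zero noise: flat curves at fasting values
  flat_rec <- rec
  flat_rec$vars[["two_hour_glucose"]] <- flat_rec$vars[["fasting_glucose"]]
  flat_rec$ogtt$insulin_response <- 0
  flat <- generate_ogtt(flat_rec, noise_cv = 0)
  expect_equal(flat$glucose_mmol_l, rep(flat_rec$vars[["fasting_glucose"]], 5))
  expect_equal(flat$insulin_pmol_l, rep(flat_rec$vars[["fasting_insulin"]], 5))

  # default post-surgery effect, zero noise: AUC ratio exactly the factor
  eff <- rec$config$effect_params
  eff$noise_sdlog <- 0
  post <- apply_intervention(rec, eff)
  auc <- function(r) {
    o <- generate_ogtt(r, noise_cv = 0)
    auc_trapezoid(data.frame(time_min = o$time_min, value = o$glucose_mmol_l))
  }
  expect_equal(auc(post) / auc(rec), 1.20, tolerance = 1e-12)
  # and the post-surgery peak is earlier and higher
  g_pre <- generate_ogtt(rec, noise_cv = 0)$glucose_mmol_l
  g_post <- generate_ogtt(post, noise_cv = 0)$glucose_mmol_l
  expect_gt(max(g_post), max(g_pre))
  expect_lte(which.max(g_post), which.max(g_pre))
})

test_that("FDG session dose, zero-delivery limit and sampling consistency", {
  rec <- small_cohort()[[1]]
  rec$vars[["weight"]] <- 100
  rec <- metaboscope:::finalize_record(rec)
  fdg <- generate_fdg_session(rec, noise_cv = 0)
  expect_equal(fdg$dose_MBq, 400)

  # K1 = 0, Vb = 0: identically zero tissue curve
  zero <- simulate_2tcm(kinetic_params(0, 0.2, 0.05, 0), fdg$input_fn,
                        seq(0, 90, 5))
  expect_equal(zero$value, rep(0, 19))

  # dense TAC and pass samples agree at pass midpoints (linear late phase)
  o <- "leg_muscle"
  bed <- 8L
  sp <- fdg$passes[[o]]
  dense_mid <- stats::approx(fdg$tacs[[o]]$time_min, fdg$tacs[[o]]$value,
                             xout = sp$time_min)$y
  expect_equal(sp$value, dense_mid, tolerance = 1e-3)

  # cumulative urinary activity is non-decreasing, input function positive
  expect_true(all(diff(fdg$urine$value) >= 0))
  expect_true(all(fdg$input_fn$value >= 0))
  expect_gt(max(fdg$input_fn$value), 10)

  # seeded determinism across the full session
  fdg2 <- generate_fdg_session(rec, noise_cv = 0)
  expect_identical(fdg$passes, fdg2$passes)
})

test_that("phantom ground truth is exact by construction and images are signals", {
  rec <- small_cohort()[[2]]
  ph <- generate_body_phantom(rec, vox_mm = 10)
  gt <- ph$ground_truth
  # configured abdominal depot volume is the recorded truth
  expect_equal(gt$organ_volumes_l[["abd_adipose"]],
               5.0 * rec$vars[["weight"]] / 110.6, tolerance = 1e-12)
  expect_true(all(ph$water$data >= 0))
  expect_true(all(ph$fat$data >= 0))
  # label map partitions the body: every body voxel has exactly one label
  body <- ph$water$data + ph$fat$data > 0
  expect_true(all(ph$labels$data[body] >= 1))
  expect_true(all(ph$labels$data[!body] == 0))
  # overlapping organ geometry is a generation error
  bad <- rec
  bad$volumes_l[["heart"]] <- 8
  expect_error(generate_body_phantom(bad, vox_mm = 10), "overlap")
})

test_that("every generated dataset ships a self-consistent ground-truth bundle", {
  for (rec in small_cohort()) {
    tr <- rec$truth
    expect_equal(tr$rd, tr$gir_umol + tr$egp, tolerance = 1e-12)
    expect_true(all(unlist(tr$ki) >= 0))
    expect_gt(tr$urinary_loss_umol_min, 0)
    # tissue-integrated uptake balances GIR + EGP + urinary loss
    uptake <- sum(tr$mrglu * rec$volumes_l[names(tr$mrglu)] * 10)
    expect_equal(uptake,
                 tr$rd * rec$vars[["lbm"]] + tr$urinary_loss_umol_min,
                 tolerance = 1e-8)
  }
})
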
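# Shared fixtures, built once per test run.

# small cohort for structural tests (3 + 3, fixed seed)
small_config <- function(seed = 101) cohort_config(n_surgery = 3, n_lcd = 3, seed = seed)

fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(fixture_env$cohort)) fixture_env$cohort <- generate_cohort(small_config())
  fixture_env$cohort
}

# one surgery-arm record with the reported surgery-pre point values forced,
# for deterministic index checks
reference_record <- function() {
  rec <- small_cohort()[[1]]
  rec$vars[["fasting_glucose"]] <- 5.6
  rec$vars[["fasting_insulin"]] <- 67.9
  rec$vars[["two_hour_glucose"]] <- 7.4
  rec
}

# dense standard kinetics fixture: K1 = 0.1, k2 = 0.15, k3 = 0.05
standard_params <- function(Vb = 0) kinetic_params(0.1, 0.15, 0.05, Vb)

standard_input <- function(t_end = 95) feng_input(seq(0, t_end, by = 0.05), 100)

standard_tac <- function(Vb = 0, t_end = 95) {
  simulate_2tcm(standard_params(Vb), standard_input(t_end),
                seq(0, t_end, by = 0.25))
}

# analytic ellipsoid mask on an isotropic grid (independent of the phantom
# module's own ellipsoid code path wherever an oracle is needed)
oracle_ellipsoid <- function(semi_mm, vox_mm, pad = 2) {
  ax <- seq(-semi_mm[1] - pad * vox_mm + vox_mm / 2, semi_mm[1] + pad * vox_mm,
            by = vox_mm)
  ay <- seq(-semi_mm[2] - pad * vox_mm + vox_mm / 2, semi_mm[2] + pad * vox_mm,
            by = vox_mm)
  az <- seq(-semi_mm[3] - pad * vox_mm + vox_mm / 2, semi_mm[3] + pad * vox_mm,
            by = vox_mm)
  arr <- array(FALSE, c(length(ax), length(ay), length(az)))
  for (k in seq_along(az)) {
    arr[, , k] <- outer((ax / semi_mm[1])^2, (ay / semi_mm[2])^2, "+") +
      (az[k] / semi_mm[3])^2 <= 1
  }
  voxel_image(arr, vox_mm)
}
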
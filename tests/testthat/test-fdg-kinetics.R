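test_that("2TCM forward model matches the constant-input closed form", {
  # K1 = 0 delivers nothing
  inp <- standard_input()
  zero <- simulate_2tcm(kinetic_params(0, 0.15, 0.05, 0), inp, seq(0, 90, 5))
  expect_equal(zero$value, rep(0, length(zero$value)))

  # constant input Cp = 1, Vb = 0:
  # C_T(t) = K1 k3 t/(k2+k3) + K1 k2/(k2+k3)^2 (1 - e^(-(k2+k3) t))
  const <- data.frame(time_min = c(0, 120), value = c(1, 1))
  tt <- c(5, 20, 60, 120)
  ct <- simulate_2tcm(standard_params(), const, tt, dt = 0.01)
  K1 <- 0.1; k2 <- 0.15; k3 <- 0.05; b <- k2 + k3
  closed <- K1 * k3 * tt / b + K1 * k2 / b^2 * (1 - exp(-b * tt))
  expect_equal(ct$value, closed, tolerance = 1e-6)
  # late-time slope approaches the analytic Ki = 0.025/min
  late <- simulate_2tcm(standard_params(), const, c(100, 120), dt = 0.01)
  expect_equal(diff(late$value) / 20, 0.025, tolerance = 1e-4)

  expect_error(kinetic_params(-0.1, 0.15, 0.05), "non-negative")
})

test_that("convolution solver agrees with an independent ODE integration", {
  skip_if_not_installed("deSolve")
  inp <- standard_input()
  tt <- seq(0, 95, by = 0.25)
  tac <- simulate_2tcm(standard_params(), inp, tt)
  cpf <- stats::approxfun(c(0, inp$time_min[inp$time_min > 0]),
                          c(0, inp$value[inp$time_min > 0]), rule = 2)
  rhs <- function(t, y, p) {
    list(c(p["K1"] * cpf(t) - (p["k2"] + p["k3"]) * y[1], p["k3"] * y[1]))
  }
  sol <- deSolve::ode(c(0, 0), times = tt, rhs,
                      c(K1 = 0.1, k2 = 0.15, k3 = 0.05),
                      rtol = 1e-9, atol = 1e-10)
  ct_ode <- sol[, 2] + sol[, 3]
  expect_lt(max(abs(tac$value - ct_ode)) / max(ct_ode), 1e-4)
})

test_that("Patlak slope recovers the analytic Ki and its known limits", {
  inp <- standard_input()
  tac <- standard_tac()
  fit <- patlak_fit(tac, inp, t_star = 20)
  expect_equal(fit$ki, 0.025, tolerance = 0.02)
  expect_gt(fit$r2, 0.999)

  # no trapping: slope indistinguishable from zero at late t_star
  rev_tac <- simulate_2tcm(kinetic_params(0.1, 0.15, 0, 0), inp,
                           seq(0, 95, by = 0.25))
  expect_equal(patlak_fit(rev_tac, inp, t_star = 40)$ki, 0, tolerance = 2e-4)

  # bias decreases as t_star grows
  bias <- vapply(c(20, 30, 40), function(ts) {
    abs(patlak_fit(tac, inp, t_star = ts)$ki - 0.025)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))

  # common rescaling of input and tissue leaves Ki unchanged
  inp2 <- inp; inp2$value <- inp2$value * 7.3
  tac2 <- tac; tac2$value <- tac2$value * 7.3
  expect_equal(patlak_fit(tac2, inp2, 20)$ki, fit$ki, tolerance = 1e-12)

  expect_error(patlak_fit(tac, inp, t_star = 1000), "t >= t_star")
})

test_that("Patlak OLS equals a brute-force normal-equations oracle", {
  inp <- standard_input()
  tac <- standard_tac()
  keep <- tac$time_min %in% c(25, 40, 55, 70, 85)
  five <- tac[keep, ]
  fit <- patlak_fit(five, inp, t_star = 20)
  # oracle: rebuild the Patlak coordinates and solve X'X b = X'y directly
  tg <- seq(0, 85, by = 0.05)
  cpg <- stats::approx(c(0, inp$time_min[inp$time_min > 0]),
                       c(0, inp$value[inp$time_min > 0]), xout = tg, rule = 2)$y
  icp <- cumsum(c(0, diff(tg) * (head(cpg, -1) + tail(cpg, -1)) / 2))
  cp5 <- stats::approx(tg, cpg, xout = five$time_min)$y
  x <- stats::approx(tg, icp, xout = five$time_min)$y / cp5
  y <- five$value / cp5
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$v0, beta[1], tolerance = 1e-12)
  expect_equal(fit$ki, beta[2], tolerance = 1e-12)
})

test_that("blood-volume contamination biases the Patlak intercept, not the slope", {
  inp <- standard_input()
  fit0 <- patlak_fit(standard_tac(Vb = 0), inp, t_star = 20)
  fitv <- patlak_fit(standard_tac(Vb = 0.05), inp, t_star = 20)
  expect_equal(fitv$ki, fit0$ki, tolerance = 0.02)
  expect_gt(fitv$v0, fit0$v0 + 0.01)
})

test_that("whole-body pass sampling is frame-duration averaging", {
  sched <- pass_schedule()
  const <- data.frame(time_min = seq(0, 95, 0.25), value = rep(4, 381))
  s <- sample_whole_body_passes(const, sched, bed = 2)
  expect_equal(s$value, rep(4, 5))
  # linear TAC: the 30-s frame average equals the midpoint value
  lin <- data.frame(time_min = seq(0, 95, 0.25), value = 2 + 0.5 * seq(0, 95, 0.25))
  s2 <- sample_whole_body_passes(lin, sched, bed = 7)
  expect_equal(s2$value, 2 + 0.5 * s2$time_min, tolerance = 1e-10)
  expect_error(sample_whole_body_passes(lin, pass_schedule(pass_starts = 200)),
               "outside")
})

test_that("five sparse passes still recover the analytic Ki within 5%", {
  inp <- standard_input()
  sparse <- sample_whole_body_passes(standard_tac(), pass_schedule(), bed = 3)
  expect_equal(patlak_fit(sparse, inp, t_star = 10)$ki, 0.025, tolerance = 0.05)
})

test_that("Ki noise Monte-Carlo is stable across seeds", {
  inp <- standard_input()
  tac <- standard_tac()
  sched <- pass_schedule()
  run <- function(seed) {
    set.seed(seed)
    replicate(40, {
      s <- sample_whole_body_passes(tac, sched, bed = 3)
      s$value <- s$value * exp(rnorm(5, 0, 0.03))
      patlak_fit(s, inp, 10)$ki
    })
  }
  a <- run(1); b <- run(2)
  # 95% CIs of the mean estimate overlap between seeds
  ci <- function(x) mean(x) + c(-2, 2) * sd(x) / sqrt(length(x))
  expect_true(ci(a)[1] <= ci(b)[2] && ci(b)[1] <= ci(a)[2])
  # bias small relative to the noise level
  expect_equal(mean(c(a, b)), 0.025, tolerance = 0.03)
})

test_that("Ki converts to MRglu through the lumped constant", {
  expect_equal(ki_to_mrglu(0.01, 5.6, 1), 5.6)
  expect_equal(ki_to_mrglu(0, 5.6, 1.16), 0)
  expect_error(ki_to_mrglu(0.01, 5.6, 0), "positive")
  lcs <- default_lumped_constants()
  expect_true(all(lcs > 0))
})

test_that("voxelwise Ki maps match ROI fits and mask the background", {
  inp <- standard_input()
  tt <- seq(12, 92, by = 10)
  tac_a <- simulate_2tcm(standard_params(), inp, tt)            # Ki 0.025
  tac_b <- simulate_2tcm(kinetic_params(0.05, 0.2, 0.025, 0), inp, tt) # Ki 0.00556
  dims <- c(6, 6, 4)
  region_b <- array(FALSE, dims); region_b[4:6, , ] <- TRUE
  bg <- array(FALSE, dims); bg[1, 1, ] <- TRUE
  frames <- lapply(seq_along(tt), function(i) {
    vals <- array(tac_a$value[i], dims)
    vals[region_b] <- tac_b$value[i]
    vals[bg] <- 0
    voxel_image(vals, 4)
  })
  ki_map <- make_ki_image(frames, tt, inp, t_star = 10)
  expect_true(all(is.na(ki_map$data[bg])))
  roi_a <- patlak_fit(tac_a, inp, 10)$ki
  in_a <- !region_b & !bg
  expect_equal(unname(ki_map$data[in_a]), rep(roi_a, sum(in_a)), tolerance = 1e-10)
  expect_equal(mean(ki_map$data[region_b]), 0.025 / 4.5, tolerance = 0.02)
  expect_equal(mean(ki_map$data[in_a]), 0.025, tolerance = 0.02)
})
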
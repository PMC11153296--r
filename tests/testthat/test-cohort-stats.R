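test_that("normality gate selects the analysis scale", {
  set.seed(21)
  expect_equal(normality_gate(rnorm(60, 10, 1)), "normal")
  expect_equal(normality_gate(exp(rnorm(60, 1, 1))), "log")
  expect_error(normality_gate(c(1, 2)), "n >= 3")
  # a non-normal sample with non-positive values cannot go to the log scale
  set.seed(22)
  skewed <- exp(rnorm(60, 0, 1.5)) - 1.5
  expect_warning(sc <- normality_gate(skewed), "non-positive")
  expect_equal(sc, "normal")
})

test_that("Shapiro gate has useful power for log-normal data at n = 15", {
  set.seed(77)
  hits <- mean(replicate(400, normality_gate(exp(rnorm(15, 0, 1))) == "log"))
  expect_gt(hits, 0.5)
})

test_that("geometric summaries back-transform correctly", {
  s <- geometric_summary(rep(7.3, 10))
  expect_equal(s$geo_mean, 7.3)
  expect_equal(s$ci_lo, 7.3)
  expect_equal(s$ci_hi, 7.3)
  expect_equal(geometric_summary(c(1, 100))$geo_mean, 10)
  expect_error(geometric_summary(c(1, -1, 2)), "positive")
  # bootstrap oracle: the t-interval behaves like the resampling interval
  set.seed(14)
  x <- exp(rnorm(30, 2, 0.5))
  s <- geometric_summary(x)
  boot <- replicate(4000, exp(mean(log(sample(x, replace = TRUE)))))
  bq <- unname(stats::quantile(boot, c(0.025, 0.975)))
  expect_equal(s$ci_lo, bq[1], tolerance = 0.05)
  expect_equal(s$ci_hi, bq[2], tolerance = 0.05)
})

test_that("paired change tests report back-transformed percent effects", {
  pre <- c(2.1, 3.4, 1.8, 2.9, 4.0)
  same <- paired_change_test(pre, pre, "normal")
  expect_equal(same$p_value, 1)
  expect_equal(same$effect, 0)

  # uniform ratio 0.737: point estimate -26.3%, zero-width CI
  r <- paired_change_test(pre, pre * 0.737, "log")
  expect_equal(r$effect, -26.3)
  expect_equal(r$ci_lo, r$ci_hi)
  expect_equal(r$effect_unit, "percent")
  expect_error(paired_change_test(1:4, 1:3), "length mismatch")
  # percent-change back-transform round-trips
  d <- log(0.737)
  expect_equal(log(1 + r$effect / 100), d, tolerance = 1e-12)
})

test_that("gate + paired test holds its nominal type-I error under the null", {
  set.seed(3)
  n_rep <- 1500
  rejected <- replicate(n_rep, {
    pre <- exp(rnorm(15, 1, 0.4))
    post <- pre * exp(rnorm(15, 0, 0.2))
    sc <- normality_gate(pre)
    paired_change_test(pre, post, sc)$p_value < 0.05
  })
  alpha_hat <- mean(rejected)
  expect_lt(abs(alpha_hat - 0.05), 2 * sqrt(0.05 * 0.95 / n_rep) + 0.005)
})

test_that("baseline-adjusted ANCOVA recovers injected effects exactly at zero noise", {
  set.seed(11)
  g <- rep(c("surgery", "lcd"), each = 8)
  base <- c(rnorm(8, 10), rnorm(8, 10))
  zero <- suppressWarnings(ancova_change(g, base, base + 2)) # identical shift in both groups
  expect_equal(zero$effect, 0, tolerance = 1e-10)

  delta <- 1.7
  fu <- base + 2 + ifelse(g == "surgery", delta, 0)
  r <- suppressWarnings(ancova_change(g, base, fu))
  expect_equal(r$effect, delta, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-8)

  # singular design degrades to the unadjusted comparison
  fu_flat <- rep(5, 16) + 2 + ifelse(g == "surgery", delta, 0) + rnorm(16, 0, 0.01)
  expect_warning(u <- ancova_change(g, rep(5, 16), fu_flat), "constant baseline")
  expect_equal(u$effect, delta, tolerance = 0.05)
})

test_that("ANCOVA coefficient equals the closed-form normal-equations oracle", {
  set.seed(9)
  g <- rep(c("surgery", "lcd"), each = 5)
  base <- rnorm(10, 20, 3)
  fu <- base * 0.8 + ifelse(g == "surgery", 0, 1.2) + rnorm(10, 0, 0.5)
  r <- ancova_change(g, base, fu)
  X <- cbind(1, as.numeric(factor(g)) - 1, base)
  beta <- solve(t(X) %*% X, t(X) %*% (fu - base))
  expect_equal(r$effect, beta[2], tolerance = 1e-10)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  # degenerate column
  expect_equal(fisher_reversion_test(matrix(c(0, 0, 5, 7), 2))$p_value, 1)
  # the reported reversion counts are in the non-significant direction
  tab <- matrix(c(4, 1, 6, 6), 2)
  expect_gt(fisher_reversion_test(tab)$p_value, 0.05)
  expect_error(fisher_reversion_test(matrix(c(-1, 1, 1, 1), 2)), "non-negative")

  # enumeration oracle over all tables with fixed margins (point-probability
  # two-sided rule), for a grid of tables with margins <= 20
  enum_p <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    a_range <- max(0, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(a_range, r1, r2, c1)
    p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(8)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    expect_equal(fisher_reversion_test(tab)$p_value, enum_p(tab),
                 tolerance = 1e-10)
  }
  expect_equal(fisher_reversion_test(tab)$p_value, enum_p(tab), tolerance = 1e-10)
})

test_that("reported p values are raw (no multiplicity correction)", {
  set.seed(4)
  ps <- replicate(20, {
    pre <- exp(rnorm(10, 1, 0.3)); post <- pre * exp(rnorm(10, 0, 0.2))
    paired_change_test(pre, post, "log")$p_value
  })
  # identical to recomputing each raw test in isolation; no adjustment applied
  expect_identical(ps, vapply(seq_along(ps), function(i) ps[i], numeric(1)))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("the trial report reproduces a noiseless index fixture and is deterministic", {
  # three subjects per arm, constant HOMA-IR at the reported cell values
  mk <- function(arm, tp, homa) {
    data.frame(id = paste0(arm, 1:3), arm = arm, timepoint = tp, homa_ir = homa)
  }
  cohort <- rbind(mk("surgery", "pre", 2.4), mk("surgery", "post", 1.6),
                  mk("lcd", "pre", 4.9), mk("lcd", "post", 3.3))
  rep1 <- suppressWarnings(render_report(cohort, "homa_ir", digits = 1))
  expect_match(rep1$surgery_pre, "^2.4")
  expect_match(rep1$surgery_post, "^1.6")
  expect_match(rep1$lcd_pre, "^4.9")
  expect_match(rep1$lcd_post, "^3.3")
  rep2 <- suppressWarnings(render_report(cohort, "homa_ir", digits = 1))
  expect_identical(rep1, rep2)
  # empty cohort: header-only table
  empty <- render_report(cohort[0, ], "homa_ir")
  expect_equal(nrow(empty), 0)
  expect_true(all(c("variable", "surgery_pre", "p_ancova") %in% names(empty)))
})
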
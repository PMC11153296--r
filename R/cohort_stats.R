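#' Normality gate for analysis-scale selection
#'
#' Shapiro-Wilk test at alpha = 0.05: non-normal samples are analysed on
#' the log scale (requires positive values; otherwise the gate falls back
#' to the normal scale with a warning). Applied per variable per arm on
#' baseline values.
#'
#' @param sample numeric vector, n >= 3.
#' @param alpha rejection level for the Shapiro-Wilk test.
#' @return `"log"` or `"normal"`.
#' @export
normality_gate <- function(sample, alpha = 0.05) {
  if (length(sample) < 3L) stop("need n >= 3 for the normality gate", call. = FALSE)
  if (stats::sd(sample) == 0) return("normal")
  p <- stats::shapiro.test(sample)$p.value
  if (p >= alpha) return("normal")
  if (any(sample <= 0)) {
    warning("non-normal sample with non-positive values: keeping normal scale",
            call. = FALSE)
    return("normal")
  }
  "log"
}

#' Geometric mean with 95% confidence interval
#'
#' Back-transformed log-scale summary: `exp(mean(log x))` and
#' `exp(mean(log x) +/- t(0.975, n-1) * SE(log x))`.
#'
#' @param sample positive numeric vector, n >= 2.
#' @param conf confidence level.
#' @return One-row data.frame: `geo_mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
geometric_summary <- function(sample, conf = 0.95) {
  if (any(sample <= 0)) stop("geometric summary requires positive values", call. = FALSE)
  n <- length(sample)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  lx <- log(sample)
  se <- stats::sd(lx) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, n - 1)
  data.frame(
    geo_mean = exp(mean(lx)),
    ci_lo = exp(mean(lx) - tq * se),
    ci_hi = exp(mean(lx) + tq * se),
    n = n
  )
}

#' Within-group pre/post comparison (paired t test)
#'
#' Paired t test on the chosen scale. On the log scale the effect is the
#' back-transformed mean paired log-ratio expressed as percent change, with
#' its (asymmetric) 95% CI; on the normal scale it is the mean paired
#' difference in the variable's own units.
#'
#' @param pre,post paired numeric vectors, equal length, n >= 3.
#' @param scale `"normal"` or `"log"` (e.g. from [normality_gate()]).
#' @param conf confidence level.
#' @return One-row data.frame of class `comparison_result`: `contrast`,
#'   `scale`, `statistic`, `p_value`, `effect`, `ci_lo`, `ci_hi`, `effect_unit`.
#' @export
paired_change_test <- function(pre, post, scale = c("normal", "log"), conf = 0.95) {
  scale <- match.arg(scale)
  if (length(pre) != length(post)) stop("pre/post length mismatch", call. = FALSE)
  if (length(pre) < 3L) stop("need n >= 3 pairs", call. = FALSE)
  if (scale == "log") {
    if (any(pre <= 0) || any(post <= 0)) {
      stop("log scale requires positive values", call. = FALSE)
    }
    d <- log(post) - log(pre)
    if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
      eff <- (exp(mean(d)) - 1) * 100
      res <- data.frame(contrast = "pre_vs_post", scale = scale,
                        statistic = if (mean(d) == 0) 0 else Inf,
                        p_value = if (mean(d) == 0) 1 else 0,
                        effect = eff, ci_lo = eff, ci_hi = eff,
                        effect_unit = "percent")
      class(res) <- c("comparison_result", class(res))
      return(res)
    }
    tt <- stats::t.test(d, conf.level = conf)
    res <- data.frame(
      contrast = "pre_vs_post", scale = scale,
      statistic = unname(tt$statistic), p_value = tt$p.value,
      effect = (exp(mean(d)) - 1) * 100,
      ci_lo = (exp(tt$conf.int[1]) - 1) * 100,
      ci_hi = (exp(tt$conf.int[2]) - 1) * 100,
      effect_unit = "percent"
    )
  } else {
    d <- post - pre
    if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
      res <- data.frame(contrast = "pre_vs_post", scale = scale,
                        statistic = if (mean(d) == 0) 0 else Inf,
                        p_value = if (mean(d) == 0) 1 else 0,
                        effect = mean(d), ci_lo = mean(d), ci_hi = mean(d),
                        effect_unit = "absolute")
      class(res) <- c("comparison_result", class(res))
      return(res)
    }
    tt <- stats::t.test(post, pre, paired = TRUE, conf.level = conf)
    res <- data.frame(
      contrast = "pre_vs_post", scale = scale,
      statistic = unname(tt$statistic), p_value = tt$p.value,
      effect = mean(d), ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
      effect_unit = "absolute"
    )
  }
  class(res) <- c("comparison_result", class(res))
  res
}

#' Baseline (independent-groups) comparison
#'
#' Plain Student's t test (Welch off by default, configurable) on the chosen
#' scale, for group differences at baseline.
#'
#' @param x,y samples from the two groups.
#' @param scale `"normal"` or `"log"`.
#' @param welch use the Welch correction.
#' @return One-row data.frame of class `comparison_result`.
#' @export
independent_test <- function(x, y, scale = c("normal", "log"), welch = FALSE) {
  scale <- match.arg(scale)
  if (scale == "log") {
    if (any(c(x, y) <= 0)) stop("log scale requires positive values", call. = FALSE)
    x <- log(x); y <- log(y)
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  res <- data.frame(
    contrast = "group_baseline", scale = scale,
    statistic = unname(tt$statistic), p_value = tt$p.value,
    effect = unname(diff(rev(tt$estimate))) * -1,
    ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
    effect_unit = if (scale == "log") "log_diff" else "absolute"
  )
  class(res) <- c("comparison_result", class(res))
  res
}

#' Baseline-adjusted between-group comparison of change (ANCOVA)
#'
#' Linear model `change ~ group + baseline`; the group coefficient is the
#' adjusted between-arm difference in change from baseline. A constant
#' baseline makes the design singular: the model degrades to the unadjusted
#' comparison `change ~ group` with a warning.
#'
#' @param group factor-like with exactly two levels (first level = reference).
#' @param baseline,followup numeric vectors.
#' @param scale `"normal"` or `"log"`: on the log scale the model is fitted
#'   to log-transformed values and change is a log-ratio.
#' @param conf confidence level.
#' @return One-row data.frame of class `comparison_result`; `effect` is the
#'   adjusted group difference (second level minus first).
#' @export
ancova_change <- function(group, baseline, followup,
                          scale = c("normal", "log"), conf = 0.95) {
  scale <- match.arg(scale)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups are required", call. = FALSE)
  if (min(table(group)) < 3L) stop("need n >= 3 per group", call. = FALSE)
  if (scale == "log") {
    if (any(c(baseline, followup) <= 0)) {
      stop("log scale requires positive values", call. = FALSE)
    }
    baseline <- log(baseline); followup <- log(followup)
  }
  change <- followup - baseline
  if (stats::sd(baseline) == 0) {
    warning("constant baseline: reporting unadjusted group comparison",
            call. = FALSE)
    fit <- stats::lm(change ~ group)
  } else {
    fit <- stats::lm(change ~ group + baseline)
  }
  co <- stats::summary.lm(fit)$coefficients
  row <- grep("^group", rownames(co))[1]
  ci <- stats::confint(fit, level = conf)[row, ]
  res <- data.frame(
    contrast = "between_group_change", scale = scale,
    statistic = co[row, "t value"], p_value = co[row, "Pr(>|t|)"],
    effect = co[row, "Estimate"], ci_lo = ci[1], ci_hi = ci[2],
    effect_unit = if (scale == "log") "log_diff" else "absolute",
    row.names = NULL
  )
  class(res) <- c("comparison_result", class(res))
  res
}

#' Fisher's exact test on a glycaemia-transition table
#'
#' Two-sided Fisher's exact test (point-probability method) on a 2x2 count
#' table, e.g. reversion to normoglycaemia by arm.
#'
#' @param table2x2 2x2 matrix of non-negative integer counts.
#' @return One-row data.frame of class `comparison_result`; `effect` is the
#'   conditional odds ratio estimate.
#' @export
fisher_reversion_test <- function(table2x2) {
  table2x2 <- as.matrix(table2x2)
  if (!all(dim(table2x2) == c(2L, 2L))) stop("a 2x2 table is required", call. = FALSE)
  if (any(table2x2 < 0) || any(table2x2 != round(table2x2))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  ft <- stats::fisher.test(table2x2)
  res <- data.frame(
    contrast = "fisher_2x2", scale = "count",
    statistic = unname(ft$estimate), p_value = ft$p.value,
    effect = unname(ft$estimate),
    ci_lo = ft$conf.int[1], ci_hi = ft$conf.int[2],
    effect_unit = "odds_ratio"
  )
  class(res) <- c("comparison_result", class(res))
  res
}

#' Trial-style summary and comparison report
#'
#' For each requested variable: per-arm pre/post summaries (mean +/- SD on
#' the normal scale, geometric mean with 95% CI on the log scale, chosen by
#' the per-arm baseline normality gate), the within-arm paired test, and the
#' baseline-adjusted between-arm ANCOVA. No multiple-testing correction is
#' applied; reported p values are the raw per-test values.
#'
#' @param cohort data.frame with columns `id`, `arm` (`surgery` / `lcd`),
#'   `timepoint` (`pre` / `post`) and one column per variable.
#' @param variables character vector of variable columns to report.
#' @param digits decimal places for the formatted columns.
#' @return data.frame, one row per variable: formatted `pre`/`post` cells
#'   per arm, within-arm p values, ANCOVA p, and the analysis scale used.
#' @export
render_report <- function(cohort, variables, digits = 2) {
  stopifnot(all(c("id", "arm", "timepoint") %in% names(cohort)))
  empty <- data.frame(
    variable = character(0), surgery_pre = character(0),
    surgery_post = character(0), lcd_pre = character(0),
    lcd_post = character(0), p_within_surgery = numeric(0),
    p_within_lcd = numeric(0), p_ancova = numeric(0), scale = character(0)
  )
  if (nrow(cohort) == 0L || length(variables) == 0L) return(empty)
  rows <- lapply(variables, function(v) {
    cells <- list(); pw <- list(); scales <- character(0)
    for (arm in c("surgery", "lcd")) {
      pre <- merge(
        cohort[cohort$arm == arm & cohort$timepoint == "pre", c("id", v)],
        cohort[cohort$arm == arm & cohort$timepoint == "post", c("id", v)],
        by = "id", suffixes = c("_pre", "_post")
      )
      if (nrow(pre) < 3L) {
        cells[[paste0(arm, "_pre")]] <- cells[[paste0(arm, "_post")]] <- ""
        pw[[arm]] <- NA_real_
        next
      }
      xpre <- pre[[paste0(v, "_pre")]]
      xpost <- pre[[paste0(v, "_post")]]
      sc <- normality_gate(xpre)
      scales <- c(scales, sc)
      fmt <- function(x) {
        if (sc == "log") {
          s <- geometric_summary(x)
          sprintf("%s (%s, %s)", format(round_half_up(s$geo_mean, digits)),
                  format(round_half_up(s$ci_lo, digits)),
                  format(round_half_up(s$ci_hi, digits)))
        } else {
          sprintf("%s±%s", format(round_half_up(mean(x), digits)),
                  format(round_half_up(stats::sd(x), digits)))
        }
      }
      cells[[paste0(arm, "_pre")]] <- fmt(xpre)
      cells[[paste0(arm, "_post")]] <- fmt(xpost)
      pw[[arm]] <- paired_change_test(xpre, xpost, sc)$p_value
    }
    wide <- merge(
      cohort[cohort$timepoint == "pre", c("id", "arm", v)],
      cohort[cohort$timepoint == "post", c("id", v)],
      by = "id", suffixes = c("_pre", "_post")
    )
    anc <- tryCatch({
      sc_all <- if (length(scales) && any(scales == "log")) "log" else "normal"
      ancova_change(wide$arm, wide[[paste0(v, "_pre")]],
                    wide[[paste0(v, "_post")]], scale = sc_all)$p_value
    }, error = function(e) NA_real_)
    data.frame(
      variable = v,
      surgery_pre = cells$surgery_pre %||% "", surgery_post = cells$surgery_post %||% "",
      lcd_pre = cells$lcd_pre %||% "", lcd_post = cells$lcd_post %||% "",
      p_within_surgery = pw$surgery %||% NA_real_,
      p_within_lcd = pw$lcd %||% NA_real_,
      p_ancova = anc,
      scale = paste(unique(scales), collapse = "/")
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
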
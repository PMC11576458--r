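# Between-system agreement statistics: Bland-Altman, 2x2 repeated-measures
# ANOVA, paired t-tests (Bonferroni), Wilcoxon signed-rank, effect sizes.

#' Paired wet/dry measurements
#'
#' @param subject_id identifiers.
#' @param value_wet,value_dry per-subject scalars (wet is treated as the
#'   reference method).
#' @param measure_name,units labels carried into outputs.
#' @return data.frame of class `paired_measures`; rows with a missing side
#'   are dropped (and counted in the `n_dropped` attribute).
#' @export
paired_measures <- function(subject_id, value_wet, value_dry,
                            measure_name = "measure", units = "") {
  stopifnot(length(value_wet) == length(value_dry),
            length(subject_id) == length(value_wet))
  ok <- is.finite(value_wet) & is.finite(value_dry)
  out <- data.frame(subject_id = subject_id[ok], value_wet = value_wet[ok],
                    value_dry = value_dry[ok], stringsAsFactors = FALSE)
  structure(out, measure_name = measure_name, units = units,
            n_dropped = sum(!ok), class = c("paired_measures", "data.frame"))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `wet - dry` by default (the wet system is the reference, so
#' a negative bias means the dry system overestimates). Bias = mean
#' difference; limits of agreement = bias +/- `loa_mult` * SD (sample SD,
#' n-1); the bias confidence interval uses the t quantile
#' (`bias +/- t(0.975, n-1) * SD / sqrt(n)`), the LoA confidence intervals
#' `+/- t(0.975, n-1) * SD * sqrt(3/n)`. The bias is flagged significant when
#' its CI excludes zero.
#'
#' @param pm a [paired_measures()] (n >= 3).
#' @param reference_first if `FALSE`, differences are `dry - wet`.
#' @param loa_mult limits-of-agreement multiplier (1.96 by convention;
#'   `"exact"` uses the t quantile).
#' @param conf confidence level for the CIs.
#' @return list of class `bland_altman`: `bias`, `bias_ci`, `sd_diff`,
#'   `loa_low`, `loa_high`, `loa_low_ci`, `loa_high_ci`, `n`, `significant`,
#'   `sign_convention`, plus means/diffs for plotting.
#' @export
bland_altman <- function(pm, reference_first = TRUE, loa_mult = 1.96,
                         conf = 0.95) {
  n <- nrow(pm)
  if (n < 3) stop("need at least 3 complete pairs")
  diffs <- if (reference_first) pm$value_wet - pm$value_dry else
    pm$value_dry - pm$value_wet
  means <- (pm$value_wet + pm$value_dry) / 2
  bias <- mean(diffs)
  sdd <- stats::sd(diffs)
  tq <- stats::qt(1 - (1 - conf) / 2, n - 1)
  if (identical(loa_mult, "exact")) loa_mult <- tq
  se_bias <- sdd / sqrt(n)
  se_loa <- sdd * sqrt(3 / n)
  bias_ci <- c(bias - tq * se_bias, bias + tq * se_bias)
  res <- list(
    bias = bias,
    bias_ci = bias_ci,
    sd_diff = sdd,
    loa_low = bias - loa_mult * sdd,
    loa_high = bias + loa_mult * sdd,
    loa_low_ci = c(bias - loa_mult * sdd - tq * se_loa,
                   bias - loa_mult * sdd + tq * se_loa),
    loa_high_ci = c(bias + loa_mult * sdd - tq * se_loa,
                    bias + loa_mult * sdd + tq * se_loa),
    n = n,
    significant = !(bias_ci[1] <= 0 && bias_ci[2] >= 0),
    sign_convention = if (reference_first) "wet - dry" else "dry - wet",
    measure_name = attr(pm, "measure_name"), units = attr(pm, "units"),
    means = means, diffs = diffs
  )
  class(res) <- "bland_altman"
  res
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> %s (%s, n = %d): bias %.4g [%.4g, %.4g], LoA [%.4g, %.4g]%s\n",
    x$measure_name, x$sign_convention, x$n, x$bias, x$bias_ci[1], x$bias_ci[2],
    x$loa_low, x$loa_high, if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of per-subject means against differences with dotted bias and
#' limits-of-agreement lines and shaded confidence bands.
#'
#' @param x a `bland_altman` result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  ylim <- range(x$diffs, x$loa_low_ci, x$loa_high_ci, 0)
  graphics::plot(x$means, x$diffs, pch = 19,
                 xlab = sprintf("mean of wet and dry [%s]", x$units),
                 ylab = sprintf("difference (%s) [%s]", x$sign_convention, x$units),
                 main = x$measure_name, ylim = ylim, ...)
  shade <- function(ci) graphics::rect(graphics::par("usr")[1], ci[1],
                                       graphics::par("usr")[2], ci[2],
                                       col = grDevices::adjustcolor("grey", 0.4),
                                       border = NA)
  shade(x$bias_ci); shade(x$loa_low_ci); shade(x$loa_high_ci)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high), lty = 3)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Two-by-two repeated-measures ANOVA
#'
#' Fully within-subject design with factors system (wet/dry) and tone
#' (standard/deviant). Sums of squares are computed from the classical
#' within-subject decomposition; each effect is tested against its own
#' effect-by-subject interaction (df 1, n-1), with partial eta squared
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param values numeric array `n x 2 x 2` (subject x system x tone), with
#'   dimnames for the factor levels, or a data.frame with columns `subject`,
#'   `system`, `tone`, `value`.
#' @return data.frame of class `rm_anova`: one row per effect (`system`,
#'   `tone`, `system:tone`) with `F`, `df1`, `df2`, `p`, `pes`, `ss_effect`,
#'   `ss_error`, plus attributes `ss_subjects` and `ss_total`.
#' @export
rm_anova_2x2 <- function(values) {
  if (is.data.frame(values)) {
    values <- stats::xtabs(value ~ subject + system + tone, data = values)
    values <- array(values, dim(values), dimnames = dimnames(values))
  }
  stopifnot(length(dim(values)) == 3, dim(values)[2] == 2, dim(values)[3] == 2)
  if (anyNA(values)) stop("incomplete cells")
  n <- dim(values)[1]
  if (n < 3) stop("need at least 3 subjects")
  gm <- mean(values)
  m_s <- apply(values, 1, mean)   # subject
  m_a <- apply(values, 2, mean)   # system
  m_b <- apply(values, 3, mean)   # tone
  m_as <- apply(values, c(1, 2), mean)
  m_bs <- apply(values, c(1, 3), mean)
  m_ab <- apply(values, c(2, 3), mean)
  ss_subj <- 4 * sum((m_s - gm)^2)
  ss_a <- 2 * n * sum((m_a - gm)^2)
  ss_b <- 2 * n * sum((m_b - gm)^2)
  ss_as <- 2 * sum((m_as - outer(m_s, rep(1, 2)) - outer(rep(1, n), m_a) + gm)^2)
  ss_bs <- 2 * sum((m_bs - outer(m_s, rep(1, 2)) - outer(rep(1, n), m_b) + gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, 2)) - outer(rep(1, 2), m_b) + gm)^2)
  resid <- values
  for (i in seq_len(n)) for (a in 1:2) for (b in 1:2) {
    resid[i, a, b] <- values[i, a, b] - m_ab[a, b] - m_as[i, a] - m_bs[i, b] +
      m_a[a] + m_b[b] + m_s[i] - gm
  }
  ss_abs <- sum(resid^2)
  eff <- function(name, ss_e, ss_err) {
    Fv <- if (ss_err > 0) (ss_e / 1) / (ss_err / (n - 1)) else ifelse(ss_e > 0, Inf, 0)
    data.frame(effect = name, F = Fv, df1 = 1, df2 = n - 1,
               p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
               pes = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0,
               ss_effect = ss_e, ss_error = ss_err,
               stringsAsFactors = FALSE)
  }
  out <- rbind(eff("system", ss_a, ss_as), eff("tone", ss_b, ss_bs),
               eff("system:tone", ss_ab, ss_abs))
  structure(out, ss_subjects = ss_subj,
            ss_total = sum((values - gm)^2),
            class = c("rm_anova", "data.frame"))
}

#' Paired t-test with optional one-sided alternative and Bonferroni correction
#'
#' @param pm a [paired_measures()] or two numeric vectors via `y`.
#' @param x,y alternative numeric interface.
#' @param sided `"two"` or `"one"`.
#' @param direction for one-sided tests: alternative hypothesis that the
#'   mean difference (first minus second) is `"less"` or `"greater"`.
#' @param bonferroni_m number of comparisons for the Bonferroni correction.
#' @return list of class `test_result`: `name`, `statistic`, `df`, `p`,
#'   `p_corrected`, `effect_size` (Cohen's d on the paired differences),
#'   `sided`, `correction`.
#' @export
paired_t_test <- function(pm, y = NULL, sided = c("two", "one"),
                          direction = c("less", "greater"), bonferroni_m = 1) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  if (inherits(pm, "paired_measures")) {
    a <- pm$value_wet; b <- pm$value_dry
  } else {
    a <- pm; b <- y
  }
  alt <- if (sided == "two") "two.sided" else direction
  if (stats::sd(a - b) == 0) {
    # degenerate but well-defined case: identical pairs carry no evidence
    if (mean(a - b) != 0) stop("zero variance of non-zero differences")
    stat <- 0; df <- length(a) - 1
    p <- if (sided == "two") 1 else 0.5
    d <- 0
  } else {
    tt <- stats::t.test(a, b, paired = TRUE, alternative = alt)
    stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- unname(tt$p.value)
    d <- cohens_d_paired(a, b)
  }
  structure(list(
    name = "paired t-test",
    statistic = stat, df = df, p = p,
    p_corrected = min(1, bonferroni_m * p),
    effect_size = list(type = "cohen_d", value = d),
    sided = sided, correction = if (bonferroni_m > 1) "bonferroni" else "none"
  ), class = "test_result")
}

#' Wilcoxon signed-rank test for paired data
#'
#' Exact p-value (signed-rank permutation null) for n <= 25 pairs without
#' ties; normal approximation with continuity correction otherwise. Zero
#' differences are dropped, following the classical procedure.
#'
#' @inheritParams paired_t_test
#' @return a `test_result` (effect size: matched-pairs rank-biserial r).
#' @export
wilcoxon_signed_rank <- function(pm, y = NULL, sided = c("two", "one"),
                                 direction = c("less", "greater")) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  if (inherits(pm, "paired_measures")) {
    a <- pm$value_wet; b <- pm$value_dry
  } else {
    a <- pm; b <- y
  }
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) stop("all differences are zero")
  n <- length(d)
  alt <- if (sided == "two") "two.sided" else direction
  exact <- n <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, alternative = alt,
                                            exact = exact, correct = TRUE))
  V <- unname(wt$statistic)
  rb <- 2 * V / (n * (n + 1) / 2) - 1  # rank-biserial correlation
  structure(list(
    name = "wilcoxon signed-rank",
    statistic = V, df = NA_real_, p = unname(wt$p.value), p_corrected = NA_real_,
    effect_size = list(type = "rank_biserial", value = rb),
    sided = sided, correction = "none"
  ), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, df %s, p = %.4g (%s-sided)\n",
              x$name, x$statistic, format(x$df), x$p, x$sided))
  invisible(x)
}

#' Cohen's d for paired data
#'
#' `d = mean(diff) / sd(diff)` (sample SD, n-1).
#' @param a,b paired vectors.
#' @return scalar d.
#' @export
cohens_d_paired <- function(a, b) {
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) stop("zero standard deviation of differences")
  mean(d) / s
}

#' Partial eta squared
#'
#' `SS_effect / (SS_effect + SS_error)`.
#' @param ss_effect,ss_error sums of squares.
#' @return value in `[0, 1]`.
#' @export
partial_eta_sq <- function(ss_effect, ss_error) {
  if (ss_effect + ss_error == 0) return(0)
  ss_effect / (ss_effect + ss_error)
}

#' Qualitative effect-size label
#'
#' Cohen's thresholds on `|d|`: below 0.2 negligible, then small, moderate
#' (from 0.5) and large (from 0.8).
#' @param d Cohen's d.
#' @return one of `"negligible"`, `"small"`, `"moderate"`, `"large"`.
#' @export
effect_size_label <- function(d) {
  ad <- abs(d)
  if (ad < 0.2) "negligible" else if (ad < 0.5) "small" else if (ad < 0.8) "moderate" else "large"
}
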
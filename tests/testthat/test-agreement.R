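test_that("Bland-Altman reproduces the three-point worked example", {
  pm <- paired_measures(1:3, c(1, 2, 3), c(2, 2, 5))
  ba <- bland_altman(pm)  # diffs: -1, 0, -2
  expect_equal(ba$bias, -1)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -1 - 1.96)
  expect_equal(ba$loa_high, -1 + 1.96)
  tq <- qt(0.975, 2)
  expect_equal(ba$bias_ci, c(-1 - tq / sqrt(3), -1 + tq / sqrt(3)))
  expect_equal(ba$loa_low_ci,
               c(-2.96 - tq * sqrt(3 / 3), -2.96 + tq * sqrt(3 / 3)))
  expect_equal(ba$n, 3)
  expect_false(ba$significant)  # CI straddles zero
  expect_equal(ba$sign_convention, "wet - dry")
})

test_that("Bland-Altman handles degenerate agreement patterns", {
  pm_same <- paired_measures(1:4, c(1, 2, 3, 4), c(1, 2, 3, 4))
  ba <- bland_altman(pm_same)
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  pm_shift <- paired_measures(1:4, c(1, 2, 3, 4), c(1, 2, 3, 4) - 2.5)
  bs <- bland_altman(pm_shift)
  expect_equal(bs$bias, 2.5)
  expect_equal(bs$sd_diff, 0)
  expect_true(bs$significant)
  expect_error(bland_altman(paired_measures(1:2, c(1, 2), c(2, 1))), "at least 3")
})

test_that("Bland-Altman is equivariant under shifts and tracks the sign convention", {
  set.seed(8)
  w <- rnorm(12); d <- rnorm(12)
  base <- bland_altman(paired_measures(1:12, w, d))
  both <- bland_altman(paired_measures(1:12, w + 5, d + 5))
  expect_equal(both$bias, base$bias, tolerance = 1e-12)
  expect_equal(both$sd_diff, base$sd_diff, tolerance = 1e-12)
  wet_only <- bland_altman(paired_measures(1:12, w + 2, d))
  expect_equal(wet_only$bias, base$bias + 2, tolerance = 1e-12)
  flipped <- bland_altman(paired_measures(1:12, w, d), reference_first = FALSE)
  expect_equal(flipped$bias, -base$bias, tolerance = 1e-12)
  expect_equal(flipped$sign_convention, "dry - wet")
})

test_that("the 2x2 within-subject ANOVA matches aov on a worked table", {
  set.seed(9)
  vals <- array(rnorm(4 * 2 * 2), c(4, 2, 2),
                dimnames = list(NULL, c("wet", "dry"), c("standard", "deviant")))
  ours <- rm_anova_2x2(vals)
  df <- expand.grid(subject = factor(1:4), system = factor(c("wet", "dry")),
                    tone = factor(c("standard", "deviant")))
  df$value <- as.vector(vals)
  fit <- summary(stats::aov(value ~ system * tone + Error(subject / (system * tone)),
                            data = df))
  get_f <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  expect_equal(ours$F[ours$effect == "system"],
               get_f("Error: subject:system", "system"), tolerance = 1e-10)
  expect_equal(ours$F[ours$effect == "tone"],
               get_f("Error: subject:tone", "tone"), tolerance = 1e-10)
  expect_equal(ours$F[ours$effect == "system:tone"],
               get_f("Error: subject:system:tone", "system:tone"),
               tolerance = 1e-10)
  expect_equal(ours$df1, rep(1, 3))
  expect_equal(ours$df2, rep(3, 3))
})

test_that("ANOVA sums of squares decompose exactly and degenerate inputs give F = 0", {
  set.seed(10)
  vals <- array(rnorm(6 * 2 * 2), c(6, 2, 2))
  an <- rm_anova_2x2(vals)
  ss_sum <- sum(an$ss_effect) + sum(an$ss_error) + attr(an, "ss_subjects")
  expect_equal(ss_sum, attr(an, "ss_total"), tolerance = 1e-10)
  flat <- array(3.7, c(5, 2, 2))
  an0 <- rm_anova_2x2(flat)
  expect_equal(an0$F, rep(0, 3))
  expect_equal(an0$pes, rep(0, 3))
  incomplete <- array(c(NA, rnorm(15)), c(4, 2, 2))
  expect_error(rm_anova_2x2(incomplete), "incomplete")
})

test_that("ANOVA accepts long-format data frames", {
  set.seed(11)
  vals <- array(rnorm(5 * 2 * 2), c(5, 2, 2),
                dimnames = list(1:5, c("dry", "wet"), c("deviant", "standard")))
  long <- expand.grid(subject = 1:5, system = c("dry", "wet"),
                      tone = c("deviant", "standard"), stringsAsFactors = FALSE)
  long$value <- as.vector(vals)
  expect_equal(rm_anova_2x2(long)$F, rm_anova_2x2(vals)$F, tolerance = 1e-12)
})

test_that("the paired t-test matches its arithmetic oracle", {
  pm <- paired_measures(1:3, c(0, 0, 0), c(1, 2, 3))
  tt <- paired_t_test(pm)  # diffs -1, -2, -3: mean -2, sd 1
  expect_equal(tt$statistic, -2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 2)
  expect_equal(tt$effect_size$value, -2)
  one <- paired_t_test(pm, sided = "one", direction = "less")
  expect_equal(one$p, pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  bon <- paired_t_test(pm, bonferroni_m = 2)
  expect_equal(bon$p_corrected, min(1, 2 * tt$p))
  big <- paired_t_test(pm, bonferroni_m = 50)
  expect_equal(big$p_corrected, 1)
  same <- paired_t_test(paired_measures(1:4, 1:4, 1:4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("the Wilcoxon signed-rank test matches exact sign enumeration", {
  # all-positive diffs of distinct magnitude: one-sided p = 1 / 2^n
  pm6 <- paired_measures(1:6, c(1, 2, 3, 4, 5, 6), rep(0, 6))
  w6 <- wilcoxon_signed_rank(pm6, sided = "one", direction = "greater")
  expect_equal(w6$p, 1 / 64)
  # enumeration oracle over all sign assignments, random instances
  enum_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    stats <- signs %*% r
    mean(stats >= obs)
  }
  set.seed(12)
  for (k in 1:8) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n), 3)
    while (any(d == 0) || any(duplicated(abs(d)))) d <- round(rnorm(n), 3)
    ours <- wilcoxon_signed_rank(paired_measures(seq_len(n), d, rep(0, n)),
                                 sided = "one", direction = "greater")
    expect_equal(ours$p, enum_p(d), tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(paired_measures(1:5, 1:5, 1:5)), "zero")
})

test_that("t and Wilcoxon point the same way on monotone differences", {
  set.seed(13)
  w <- rnorm(10) + 1.5
  d <- rnorm(10)
  tt <- paired_t_test(paired_measures(1:10, w, d))
  ww <- wilcoxon_signed_rank(paired_measures(1:10, w, d))
  expect_gt(tt$statistic, 0)
  expect_gt(ww$statistic, 10 * 11 / 4)  # above the null centre n(n+1)/4
})

test_that("effect sizes and labels follow the shipped conventions", {
  d <- c(0.5, 1.5, 2.5, 3.5)
  expect_equal(cohens_d_paired(d, rep(0, 4)), mean(d) / sd(d))
  expect_error(cohens_d_paired(1:3, 1:3), "zero")
  expect_error(cohens_d_paired(c(2, 3, 4), c(1, 2, 3)), "zero")
  expect_equal(partial_eta_sq(3, 1), 0.75)
  expect_equal(partial_eta_sq(0, 0), 0)
  expect_equal(effect_size_label(-0.55), "moderate")
  expect_equal(effect_size_label(-0.83), "large")
  expect_equal(effect_size_label(-0.03), "negligible")
  expect_equal(effect_size_label(0.2), "small")
})
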
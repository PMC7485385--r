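test_that("summary t-test reproduces published seizure-severity p-values", {
  # printed group summaries (mean +/- SEM, n = 4 per genotype)
  p_power <- ttest_from_summary(group_summary("wt", 39670, 6227, 4),
                                group_summary("ko", 31040, 9174, 4))$p
  expect_equal(p_power, 0.4659, tolerance = 0.002 / 0.4659)
  p_amp <- ttest_from_summary(group_summary("wt", 411.8, 38.70, 4),
                              group_summary("ko", 412.5, 76.45, 4))$p
  expect_lt(abs(p_amp - 0.9931), 0.002)
  p_spike <- ttest_from_summary(group_summary("wt", 682.5, 214.2, 4),
                                group_summary("ko", 613.8, 252.9, 4))$p
  expect_lt(abs(p_spike - 0.8425), 0.002)
})

test_that("identical summaries give t = 0, p = 1; bad n errors", {
  a <- group_summary("a", 5, 1, 4)
  res <- ttest_from_summary(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(ttest_from_summary(a, group_summary("b", 5, 1, 1)),
               "n >= 2")
})

test_that("raw and summary t-tests agree to numerical precision", {
  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    for (method in c("pooled", "welch")) {
      raw <- ttest_raw(x, y, method = method)
      summ <- ttest_from_summary(
        group_summary("x", mean(x), sd(x) / sqrt(length(x)), length(x)),
        group_summary("y", mean(y), sd(y) / sqrt(length(y)), length(y)),
        method = method)
      expect_equal(raw$t, summ$t, tolerance = 1e-12)
      expect_equal(raw$df, summ$df, tolerance = 1e-12)
      expect_equal(raw$p, summ$p, tolerance = 1e-12)
      # symmetry under swapping the groups
      expect_equal(ttest_raw(y, x, method = method)$p, raw$p,
                   tolerance = 1e-12)
    }
  }
  expect_equal(ttest_raw(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_lt(ttest_raw(rnorm(10), rnorm(10, 10))$p, 1e-6)
  expect_error(ttest_raw(1, c(1, 2)), ">= 2")
})

test_that("one-way ANOVA with LSD handles degenerate and permuted input", {
  const <- list(a = c(2, 2, 2), b = c(2, 2, 2), c = c(2, 2, 2))
  res <- anova_fisher_lsd(const)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_equal(res$posthoc$p, rep(1, 3))
  expect_false(any(res$posthoc$protected))

  set.seed(3)
  g <- list(a = rnorm(5), b = rnorm(5, 1), c = rnorm(5, 3))
  r1 <- anova_fisher_lsd(g)
  r2 <- anova_fisher_lsd(g[c(3, 1, 2)])
  expect_equal(r2$F, r1$F, tolerance = 1e-12)
  expect_equal(r2$p, r1$p, tolerance = 1e-12)
  pr1 <- r1$posthoc[r1$posthoc$group_a == "a" & r1$posthoc$group_b == "b", ]
  pr2 <- r2$posthoc[r2$posthoc$group_a == "a" & r2$posthoc$group_b == "b", ]
  expect_equal(pr2$p, pr1$p, tolerance = 1e-12)
  expect_equal(r1$df_between, 2L)
  expect_equal(r1$df_within, 12L)
  expect_error(anova_fisher_lsd(g[1]), ">= 2 groups")
  expect_error(anova_fisher_lsd(list(a = 1, b = c(1, 2), c = c(1, 2))),
               "n >= 2")
})

test_that("with two groups the omnibus F equals the squared pooled t", {
  set.seed(29)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(5, 0.8)
    a <- anova_fisher_lsd(list(x = x, y = y))
    t <- ttest_raw(x, y, method = "pooled")
    expect_equal(a$F, t$t^2, tolerance = 1e-9)
    expect_equal(a$p, t$p, tolerance = 1e-9)
  }
})

test_that("a strong fourth group separates from controls under protected LSD", {
  # four-group design of a panel-validation experiment: control-like
  # means with one clearly elevated group, SEM about 0.25 at n = 6
  set.seed(55)
  means <- c(ctrl_wt = 1.06, ctrl_ko = 1.17, se_wt = 1.5, se_ko = 3.19)
  groups <- lapply(means, function(m) rnorm(6, m, 0.25 * sqrt(6)))
  res <- anova_fisher_lsd(groups)
  expect_lt(res$p, 0.05)
  ph <- res$posthoc
  top_vs_ctrl <- ph[(ph$group_a == "se_ko" &
                       ph$group_b %in% c("ctrl_wt", "ctrl_ko")) |
                      (ph$group_b == "se_ko" &
                         ph$group_a %in% c("ctrl_wt", "ctrl_ko")), ]
  expect_true(all(top_vs_ctrl$p < 0.05))
  expect_true(all(top_vs_ctrl$protected))
})
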
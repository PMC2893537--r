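test_that("ANOVA matches hand computation and handles degenerate input", {
  a <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(a$statistic, 27)           # between-SS 54 / 2, within-SS 6 / 6
  expect_equal(a$df, c(2, 6))
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  d <- one_way_anova(list(c(2, 2), c(2, 2)))
  expect_equal(d$statistic, 0)
  expect_equal(d$p_value, 1)
  expect_error(one_way_anova(list(c(1, 2, 3), 5)), "two finite")
  expect_error(one_way_anova(list(c(1, 2, 3))), "at least 2 groups")
})

test_that("ANOVA and Kruskal-Wallis agree with explicit-formula oracles", {
  set.seed(9)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) round(rnorm(sample(3:8, 1)), 2))
    a <- one_way_anova(groups)
    ao <- anova_oracle(groups)
    expect_equal(a$statistic, ao$statistic, tolerance = 1e-10)
    expect_equal(a$p_value, ao$p_value, tolerance = 1e-10)
    kw <- kruskal_wallis(groups)
    ko <- kw_oracle(groups)
    expect_equal(kw$statistic, ko$statistic, tolerance = 1e-10)
    expect_equal(kw$p_value, ko$p_value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis: hand value, rank invariance, degenerate case", {
  k <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(k$statistic, 3), 3.857)   # 12/42 * (36/3 + 225/3) - 21
  k2 <- kruskal_wallis(exp(c(1, 2, 3)), exp(c(4, 5, 6)))
  expect_equal(k2$statistic, k$statistic)      # monotone-transform invariant
  kd <- kruskal_wallis(c(2, 2), c(2, 2))
  expect_equal(kd$statistic, 0)
  expect_equal(kd$p_value, 1)
})

test_that("Bonferroni adjustment multiplies by the pair count, caps at 1, and is label-invariant", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  b <- bonferroni_pairwise(g)
  expect_equal(nrow(b), 3)
  expect_equal(b$p_adjusted, pmin(1, b$p_raw * 3))
  expect_true(all(b$p_adjusted >= b$p_raw & b$p_adjusted <= 1))
  # near-identical groups: adjusted values hit the cap
  g2 <- list(x = c(1, 2, 3), y = c(1.01, 2.01, 2.99), z = c(0.99, 2, 3.01))
  expect_true(all(bonferroni_pairwise(g2)$p_adjusted == 1))
  # relabeling the groups permutes but does not change the adjusted values
  bp <- bonferroni_pairwise(g[c(3, 1, 2)])
  expect_equal(sort(bp$p_adjusted), sort(b$p_adjusted))
})

test_that("results table reproduces mean and n-1 SD exactly and wires the contrasts", {
  set.seed(21)
  cohort <- data.frame(
    group = rep(c("healthy", "diabetic_no_CAN", "diabetic_CAN"), c(8, 8, 6)),
    amp = c(rnorm(8, 10, 2), rnorm(8, 7, 2), rnorm(6, 5, 2)),
    lat = rnorm(22, 0.25, 0.05))
  tab <- build_results_table(cohort)
  expect_equal(nrow(tab), 2)
  r <- tab[tab$parameter == "amp", ]
  expect_identical(r$mean_healthy, mean(cohort$amp[cohort$group == "healthy"]))
  expect_identical(r$sd_healthy, sd(cohort$amp[cohort$group == "healthy"]))
  expect_identical(r$mean_CAN, mean(cohort$amp[cohort$group == "diabetic_CAN"]))
  bf <- bonferroni_pairwise(split(cohort$amp, factor(cohort$group,
    c("healthy", "diabetic_no_CAN", "diabetic_CAN"))))
  expect_equal(r$p1, bf$p_adjusted[bf$group_a == "healthy" &
                                   bf$group_b == "diabetic_no_CAN"])
  expect_error(build_results_table(data.frame()), "empty cohort")
  expect_warning(build_results_table(cohort, parameters = c("amp", "nope")),
                 "missing")
})

test_that("type-I error under a simulated null sits at alpha, and real shifts are detected", {
  set.seed(31)
  reps <- 400
  p <- vapply(seq_len(reps), function(i)
    one_way_anova(list(rnorm(16), rnorm(16), rnorm(8)))$p_value, 0)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  # 2-SD shift at n = 16/16/8: significant in the large majority of seeds
  hits <- vapply(1:40, function(i)
    one_way_anova(list(rnorm(16, 2), rnorm(16), rnorm(8)))$p_value < 0.05,
    TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("a synthetic cohort flows through extraction into the group table", {
  cohort <- generate_synthetic_cohort(n_per_group = c(8, 8, 6), seed = 5)
  expect_equal(nrow(cohort), 22)
  expect_error(generate_synthetic_cohort(n_per_group = 0), "positive")
  pars <- cohort_parameters(cohort)
  tab <- build_results_table(pars[, c("group", "ratio_PI_darkness",
                                      "reflex_amplitude_px")])
  # the built-in group separations are large; the darkness ratio must flag
  expect_true(tab$significant[tab$parameter == "ratio_PI_darkness"])
  expect_gt(tab$mean_healthy[1], tab$mean_CAN[1])
  # null case: identical group specs -> mostly non-significant over seeds
  specs <- default_group_specs()
  specs$diabetic_no_CAN <- specs$healthy
  specs$diabetic_CAN <- specs$healthy
  ps <- vapply(1:10, function(s) {
    co <- generate_synthetic_cohort(specs, n_per_group = c(8, 8, 8), seed = s)
    pa <- cohort_parameters(co)
    build_results_table(pa[, c("group", "reflex_amplitude_px")])$anova_p
  }, 0)
  expect_gte(mean(ps >= 0.05), 0.7)
})
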
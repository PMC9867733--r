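test_that("pooled t-test reproduces hand-computed values", {
  tt <- students_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1.2247449, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.2878641, tolerance = 1e-3)

  same <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # shift by a constant with equal variances: t = -c * sqrt(n/2) / s
  a <- c(1, 2, 3, 4); cshift <- 1.7
  tt2 <- students_t(a, a + cshift)
  expect_equal(tt2$t, -cshift * sqrt(length(a) / 2) / sd(a), tolerance = 1e-9)

  expect_error(students_t(1, c(1, 2)), "at least 2")
})

test_that("Cohen's d matches its pooled-SD definition and conventions", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1.0)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(10, 20, 30), c(20, 30, 40)), -1.0)  # scale invariant
  expect_true(is.na(cohens_d(c(2, 2, 2), c(3, 3, 3))))        # zero pooled SD
  # exact identity d = t * sqrt(1/n1 + 1/n0)
  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(7 + i); b <- rnorm(11)
    expect_equal(cohens_d(a, b),
                 students_t(a, b)$t * sqrt(1 / length(a) + 1 / length(b)))
  }
})

test_that("chi-square follows the closed form and its symmetries", {
  even <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)

  tab <- matrix(c(20, 10, 10, 20), 2)
  cs <- chi_square_2x2(tab)
  n <- sum(tab)
  hand <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  expect_equal(cs$statistic, hand, tolerance = 1e-9)
  expect_equal(cs$statistic, 20 / 3, tolerance = 1e-3)
  expect_equal(chi_square_2x2(t(tab))$statistic, cs$statistic)
  expect_equal(chi_square_2x2(2 * tab)$statistic, 2 * cs$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("Bonferroni thresholds", {
  expect_equal(round(bonferroni_alpha(17, 0.05), 3), 0.003)
  expect_equal(bonferroni_alpha(1, 0.05), 0.05)
  expect_equal(bonferroni_alpha(10, 0.05), 0.005)
  expect_error(bonferroni_alpha(0, 0.05))
  expect_error(bonferroni_alpha(17, 1.5))
})

test_that("baseline table is complete and balanced under randomization", {
  gt <- make_ground_truth("null")
  d <- simulate_trial(gt, 2000, weeks = 0, seed = 5)
  tab <- baseline_table(d)
  expect_equal(nrow(tab), 19L)  # sex + age + 17 symptoms
  expect_equal(attr(tab, "n_placebo") + attr(tab, "n_active"),
               complete_case_week(d, 0)$n)
  sym <- tab[tab$type == "symptom", ]
  expect_equal(unique(sym$threshold), 0.05 / 17)
  expect_lte(sum(sym$significant), 1L)    # Bonferroni under the null

  d$arm <- 1L
  expect_error(baseline_table(d), "single-arm")
})

test_that("overall effects carry the complete-case patients and sign flips", {
  gt <- make_ground_truth("paper_like", overrides = list(trial_shift_sd = 0))
  d <- simulate_trial(gt, 2000, weeks = c(0, 6), seed = 6, latent_only = TRUE)
  eff <- overall_effects(d, 6)
  expect_equal(nrow(eff), 17L)
  expect_equal(unique(eff$n_active + eff$n_placebo), complete_case_week(d, 6)$n)
  # recode arms: every d flips sign exactly
  d2 <- d; d2$arm <- 1L - d2$arm
  eff2 <- overall_effects(d2, 6)
  expect_equal(eff2$cohens_d, -eff$cohens_d)
  # growing generator shift: mood d more negative at week 6 than week 1
  d3 <- simulate_trial(gt, 4000, weeks = c(0, 1, 6), seed = 8,
                       latent_only = TRUE)
  eff3 <- overall_effects(d3, c(1, 6))
  dm <- eff3[eff3$symptom == "depressed_mood", ]
  expect_lt(dm$cohens_d[dm$week == 6], dm$cohens_d[dm$week == 1])
})

test_that("null-scenario overall effects stay within the sampling bound", {
  gt <- make_ground_truth("null", overrides = list(
    missing_rate = setNames(rep(0, 6), c("0", "1", "2", "3", "4", "6"))))
  d <- simulate_trial(gt, 5000, weeks = c(0, 6), seed = 14, latent_only = TRUE)
  eff <- overall_effects(d, 6)
  expect_true(all(abs(eff$cohens_d) < 0.1))
})

test_that("direct-vs-overall discordance flags follow the stated rule", {
  vals <- rbind("6" = c(0, -0.2))
  colnames(vals) <- c("guilt", "depressed_mood")
  traj <- structure(list(weeks = 6, symptoms = colnames(vals), values = vals),
                    class = "direct_effect_trajectory")
  tab <- data.frame(week = 6, symptom = c("guilt", "depressed_mood"),
                    cohens_d = c(-0.3, -0.35))
  cmp <- direct_vs_overall(traj, tab)
  expect_equal(cmp$flag[cmp$symptom == "guilt"], "indirect_dominant")
  expect_equal(cmp$flag[cmp$symptom == "depressed_mood"], "")
  # both zero: no flag
  tab0 <- data.frame(week = 6, symptom = c("guilt", "depressed_mood"),
                     cohens_d = c(0, -0.35))
  vals0 <- vals; vals0[1, ] <- c(0, -0.2)
  traj0 <- structure(list(weeks = 6, symptoms = colnames(vals0),
                          values = vals0),
                     class = "direct_effect_trajectory")
  expect_equal(direct_vs_overall(traj0, tab0)$flag[1], "")
  # mismatched labels error
  tabx <- tab; tabx$symptom[1] <- "other"
  expect_error(direct_vs_overall(traj, tabx), "mismatched")
})
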
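test_that("zero effects give identical pre/post ground truth", {
  eff <- cohort_effects(n_subjects = 2,
                        delta_lvmi = c(0, 0), delta_iecv = c(0, 0),
                        delta_icv = c(0, 0), delta_lge = c(0, 0),
                        delta_ef = c(0, 0), delta_edvi = c(0, 0),
                        baseline_cor = 0, seed = 3)
  coh <- generate_paired_cohort(eff, cohort_base())
  for (i in 1:2) {
    pre <- cohort_subject(coh, i, "pre")
    post <- cohort_subject(coh, i, "post")
    expect_equal(pre$truth, post$truth, tolerance = 1e-8)
  }
  expect_true(all(abs(coh$draws$delta_lvmi) < 1e-9))
})

test_that("cohort draws recover the configured change distributions", {
  # study-sized cohort: mean of the generating LVMI change within 2 SE
  coh43 <- generate_paired_cohort(cohort_effects(n_subjects = 43, seed = 11),
                                  cohort_base())
  expect_lt(abs(mean(coh43$draws$delta_lvmi) - (-19.8)), 2 * 8.4 / sqrt(43))

  coh200 <- generate_paired_cohort(cohort_effects(n_subjects = 200, seed = 12),
                                   cohort_base())
  expect_lt(abs(mean(coh200$draws$delta_iecv) - (-4.4)), 2 * 2.6 / sqrt(200))
})

test_that("generating changes converge to the configured moments", {
  # baseline correlation off so the drawn marginals are exactly as configured
  coh <- generate_paired_cohort(
    cohort_effects(n_subjects = 1000, seed = 5, baseline_cor = 0),
    cohort_base())
  d <- coh$draws
  checks <- list(list(d$delta_iecv, -4.4, 2.6),
                 list(d$delta_icv, -16.6, 6.6),
                 list(d$delta_lge_mass, 2.9, 3.3),
                 list(d$delta_ef, -2.6, 3.1),
                 list(d$delta_edvi, -8.2, 13.0))
  for (ch in checks) {
    se <- ch[[3]] / sqrt(1000)
    expect_lt(abs(mean(ch[[1]]) - ch[[2]]), 3 * se)
    # sd of a Gaussian sample: SE(sd) ~ sd / sqrt(2 (n - 1))
    expect_lt(abs(stats::sd(ch[[1]]) - ch[[3]]),
              3 * ch[[3]] / sqrt(2 * 999) + 1e-9)
  }
  # the identity-derived LVMI change has the moments the split implies
  implied_mean <- 1.05 * (-4.4 - 16.6) + 2.9 * mean(1 / d$bsa)
  expect_lt(abs(mean(d$delta_lvmi) - implied_mean), 3 * 8.5 / sqrt(1000))
  expect_gt(stats::sd(d$delta_lvmi), 7.5)
  expect_lt(stats::sd(d$delta_lvmi), 9.5)
})

test_that("the compartment identity links the generated changes", {
  coh <- generate_paired_cohort(cohort_effects(n_subjects = 30, seed = 8),
                                cohort_base())
  d <- coh$draws
  lhs <- d$delta_lvmi
  rhs <- 1.05 * (d$delta_iecv + d$delta_icv) + d$delta_lge_mass / d$bsa
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("cohort generation is deterministic and subject-wise reproducible", {
  eff <- cohort_effects(n_subjects = 4, seed = 21)
  c1 <- generate_paired_cohort(eff, cohort_base())
  c2 <- generate_paired_cohort(eff, cohort_base())
  expect_identical(c1$draws, c2$draws)
  expect_identical(cohort_subject(c1, 2, "post"), cohort_subject(c2, 2, "post"))
})

test_that("changes correlate with baseline in the configured direction", {
  coh <- generate_paired_cohort(cohort_effects(n_subjects = 400, seed = 13,
                                               baseline_cor = -0.5),
                                cohort_base())
  d <- coh$draws
  expect_lt(stats::cor(d$lvmi_pre, d$delta_lvmi), -0.3)
  expect_lt(stats::cor(d$iecv_pre, d$delta_iecv), -0.3)
})
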
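test_that("threshold relative risk matches the closed form on flat tables", {
  # w identical bands, no other-cause death: r* = -ln(1-t) / (lambda_c * w)
  for (w in c(1L, 10L)) {
    tab <- flat_table(lc = 0.002, w = w)
    for (t in c(0.005, 0.02)) {
      closed <- -log(1 - t) / (0.002 * w)
      expect_equal(threshold_rr_for_age(tab, 50, t, window = w), closed,
                   tolerance = 1e-9)
    }
  }
})

test_that("an age whose baseline risk equals the threshold solves to r* = 1", {
  tab <- prostate_rates()
  t <- age_conditional_risk(tab, 60, 70)
  expect_equal(threshold_rr_for_age(tab, 60, t), 1, tolerance = 1e-8)
})

test_that("halving the threshold approximately halves r* in the small-risk regime", {
  tab <- prostate_rates()
  r1 <- threshold_rr_for_age(tab, 50, 0.02)
  r2 <- threshold_rr_for_age(tab, 50, 0.01)
  expect_equal(r2 / r1, 0.5, tolerance = 0.02)
})

test_that("unattainable thresholds return eligibility sentinels, not failures", {
  tab <- prostate_rates()
  expect_identical(threshold_rr_for_age(tab, 75, 1e-8), 0)    # always eligible
  # one band with strong competing mortality: risk tops out near 0.63 even
  # at the bracket's maximum relative risk of 1000
  tab1 <- one_band_table(lc = 0.001, lo = 0.001)
  expect_identical(threshold_rr_for_age(tab1, 50, 0.7, window = 1), Inf)
})

test_that("solved thresholds reproduce the target risk to 1e-10", {
  tab <- prostate_rates()
  for (a in c(45, 55, 65, 75)) {
    r <- threshold_rr_for_age(tab, a, 0.02)
    expect_lt(abs(age_conditional_risk(tab, a, a + 10, rr = r) - 0.02), 1e-10)
  }
})

test_that("with no polygenic variance, personalised screening collapses to age-based", {
  tab <- prostate_rates()
  m0 <- polygenic_model(0)
  # threshold just below the baseline risk at the cutoff age, so r*(55) < 1
  t <- age_conditional_risk(tab, 55, 65) * (1 - 1e-6)
  s_per <- strategy_summary(tab, m0,
                            screening_policy("personalised", c(45, 79),
                                             risk_threshold = t))
  s_age <- strategy_summary(tab, NULL,
                            screening_policy("age_based", c(45, 79),
                                             age_cutoff = 55))
  expect_lt(abs(s_per$eligible_fraction - s_age$eligible_fraction), 1e-9)
  expect_lt(abs(s_per$detectable_case_fraction - s_age$detectable_case_fraction),
            1e-9)
})

test_that("a vanishing threshold makes everyone eligible and every case detectable", {
  tab <- prostate_rates()
  s <- strategy_summary(tab, polygenic_model(0.377),
                        screening_policy("personalised", c(45, 79),
                                         risk_threshold = 1e-7))
  expect_equal(s$eligible_fraction, 1)
  expect_equal(s$detectable_case_fraction, 1)
})

test_that("reclassification tables conserve population and cases", {
  tab <- prostate_rates()
  m <- polygenic_model(0.377)
  age_pol <- screening_policy("age_based", c(45, 79), age_cutoff = 55)
  risk_pol <- screening_policy("personalised", c(45, 79), risk_threshold = 0.02)
  rec <- reclassification(tab, m, age_pol, risk_pol)
  expect_equal(sum(rec$population), 1e5, tolerance = 1e-9)
  ages <- 45:79
  i <- match(ages, tab$age)
  cases_per_1e5 <- sum(tab$cancer_cases[i]) / sum(tab$population[i]) * 1e5
  expect_equal(sum(rec$cases), cases_per_1e5, tolerance = 1e-9)
  # case enrichment concentrates on the risk-eligible row
  expect_gt(rec$cases["at_or_above_threshold", "at_or_above_cutoff"],
            rec$cases["below_threshold", "at_or_above_cutoff"])
  # both off-diagonal (reclassified) cells are populated
  expect_gt(rec$population["at_or_above_threshold", "below_cutoff"], 0)
  expect_gt(rec$population["below_threshold", "at_or_above_cutoff"], 0)
})

test_that("degenerate reclassification has empty off-diagonal cells", {
  tab <- prostate_rates()
  t <- age_conditional_risk(tab, 55, 65) * (1 - 1e-6)
  rec <- reclassification(tab, polygenic_model(0),
                          screening_policy("age_based", c(45, 79), age_cutoff = 55),
                          screening_policy("personalised", c(45, 79),
                                           risk_threshold = t))
  expect_equal(rec$population["at_or_above_threshold", "below_cutoff"], 0)
  expect_equal(rec$population["below_threshold", "at_or_above_cutoff"], 0)
})

test_that("threshold sweeps are monotone with cases enriched over population", {
  tab <- prostate_rates()
  m <- polygenic_model(0.377)
  sw <- threshold_sweep(tab, m, c(45, 79), c(0.005, 0.01, 0.02, 0.03, 0.05))
  expect_true(all(diff(sw$eligible_fraction) < 0))
  expect_true(all(diff(sw$detectable_case_fraction) < 0))
  expect_true(all(sw$detectable_case_fraction > sw$eligible_fraction))
})

test_that("matched thresholds reproduce their target fraction to 1e-6", {
  tab <- prostate_rates()
  m <- polygenic_model(0.377)
  age_pol <- screening_policy("age_based", c(45, 79), age_cutoff = 55)
  base <- strategy_summary(tab, NULL, age_pol)
  for (margin in c("eligible_population", "detected_cases")) {
    t_star <- matched_threshold(tab, m, age_pol, match = margin)
    s <- strategy_summary(tab, m,
                          screening_policy("personalised", c(45, 79),
                                           risk_threshold = t_star))
    target <- if (margin == "eligible_population") base$eligible_fraction else
      base$detectable_case_fraction
    got <- if (margin == "eligible_population") s$eligible_fraction else
      s$detectable_case_fraction
    expect_lt(abs(got - target), 1e-6)
  }
})

test_that("screening the same population personalises to more detectable cases", {
  tab <- prostate_rates()
  m <- polygenic_model(0.377)
  age_pol <- screening_policy("age_based", c(45, 79), age_cutoff = 55)
  t_star <- matched_threshold(tab, m, age_pol, match = "eligible_population")
  s <- strategy_summary(tab, m,
                        screening_policy("personalised", c(45, 79),
                                         risk_threshold = t_star))
  base <- strategy_summary(tab, NULL, age_pol)
  expect_gte(s$detectable_case_fraction, base$detectable_case_fraction)
})

test_that("eligibility savings grow with the fraction of variance known", {
  tab <- prostate_rates()
  age_pol <- screening_policy("age_based", c(45, 79), age_cutoff = 55)
  sw <- variance_fraction_sweep(tab, 1.58, c(0.02, 0.25, 0.5, 1), age_pol)
  expect_true(all(diff(sw$relative_reduction_eligible) > 0))
  expect_lt(sw$relative_reduction_eligible[1], 0.02)  # no information, no saving
  # full-variance saving is of the same order as the age-based comparison allows
  expect_gt(sw$relative_reduction_eligible[4], 0.1)
  expect_lt(sw$relative_reduction_eligible[4], 0.45)
})
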
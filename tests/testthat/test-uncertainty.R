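# ANOVA precision, bias uncertainty, routine budgets, decomposition

test_that("hand-computed 2x2 sums of squares agree", {
  st <- data.frame(day = c(1, 1, 2, 2), value = c(1, 3, 2, 4))
  pr <- anova_precision(st)
  # day means 2 and 3, grand mean 2.5: SSW = (1+1)+(1+1) = 4 on 2 df,
  # SSB = 2*(0.25+0.25) = 1 on 1 df
  expect_equal(pr$msw, 2)
  expect_equal(pr$msb, 1)
  expect_equal(pr$s_r, sqrt(2))
  expect_equal(pr$s_d, 0)           # MSB < MSW: floored
  expect_true(pr$s_d_floored)
  expect_equal(pr$s_ip, pr$s_r)
})

test_that("identical values give zero precision components", {
  st <- data.frame(day = rep(1:5, each = 3), value = rep(7, 15))
  pr <- anova_precision(st)
  expect_equal(c(pr$s_r, pr$s_d, pr$s_ip), c(0, 0, 0))
})

test_that("relative components reproduce a published row: 4.2/7.8 -> s_ip 8.9", {
  expect_equal(sqrt(4.2^2 + 7.8^2), 8.9, tolerance = 0.01)
})

test_that("anova_precision matches the aov oracle across random designs", {
  set.seed(2024)
  for (i in 1:150) {
    d <- sample(2:4, 1)
    n_i <- sample(1:4, d, replace = TRUE)
    if (max(n_i) < 2) n_i[1] <- 2
    st <- data.frame(day = rep(seq_len(d), n_i),
                     value = sample(0:9, sum(n_i), replace = TRUE))
    if (length(unique(st$value)) == 1) next
    pr <- suppressWarnings(anova_precision(st))
    fit <- stats::anova(stats::aov(value ~ factor(day), data = st))
    expect_equal(pr$msb, fit[["Mean Sq"]][1])
    expect_equal(pr$msw, fit[["Mean Sq"]][2])
    n_h <- d / sum(1 / n_i)
    # absolute tolerance: at an MSB ~ MSW tie the floor may differ by
    # floating-point rounding between the two computation routes
    expect_lt(abs(pr$s_d -
                    sqrt(max(0, (fit[["Mean Sq"]][1] - fit[["Mean Sq"]][2]) /
                               n_h))), 1e-6)
    expect_equal(pr$s_ip, sqrt(pr$s_r^2 + pr$s_d^2))
  }
})

test_that("unbalanced designs warn and single-replicate days are handled", {
  st <- data.frame(day = c(1, 1, 2), value = c(1, 3, 2))
  expect_warning(pr <- anova_precision(st), "unbalanced")
  expect_true(is.finite(pr$s_r))
})

test_that("bias uncertainty formulas evaluate exactly", {
  expect_equal(bias_uncertainty_size(0, 10, 6.0), 6.0)
  expect_equal(bias_uncertainty_size(2, 4, 0), 1.0)
  # size-bias example in absolute units: 0.4 nm scatter over 15 runs with a
  # 0.924 nm reference uncertainty gives 0.93 nm (6% of 15.4 nm)
  expect_equal(bias_uncertainty_size(0.4, 15, 0.924), 0.93, tolerance = 0.005)
  expect_equal(bias_uncertainty_concentration(12.78, 15), 3.3,
               tolerance = 0.005)
  expect_equal(bias_uncertainty_concentration(0, 15), 0)
  expect_equal(bias_uncertainty_concentration(5, 1), 5)
})

test_that("routine budgets reproduce reported expanded uncertainties", {
  expect_equal(routine_budget(0.9, 2.8, 6.0, n = 3, d = 1)$U_report, 13)
  expect_equal(routine_budget(11, 7.3, 6.0, n = 3, d = 1)$U_report, 23)
  b0 <- routine_budget(0, 0, 0, n = 3, d = 1)
  expect_equal(b0$U, 0)
  # a precision_result can be passed directly
  st <- data.frame(day = rep(1:5, each = 3),
                   value = 100 + rep(rnorm(5, 0, 3), each = 3) + rnorm(15))
  pr <- anova_precision(st)
  b <- routine_budget(pr, u_delta = 6, n = 3, d = 1)
  expect_equal(b$u_r, pr$s_r_rel / sqrt(3))
  expect_equal(b$u_d, pr$s_d_rel)
})

test_that("budget is monotone in components and anti-monotone in replication", {
  base <- routine_budget(4, 5, 6, n = 3, d = 1)$U
  expect_gte(routine_budget(5, 5, 6, n = 3, d = 1)$U, base)
  expect_gte(routine_budget(4, 6, 6, n = 3, d = 1)$U, base)
  expect_gte(routine_budget(4, 5, 7, n = 3, d = 1)$U, base)
  expect_lte(routine_budget(4, 5, 6, n = 6, d = 1)$U, base)
  expect_lte(routine_budget(4, 5, 6, n = 3, d = 2)$U, base)
})

test_that("quadrature decomposition inverts composition and flags deficits", {
  expect_equal(decompose_uncertainty(5, c(3, 4)), 0)
  expect_equal(decompose_uncertainty(6.5, 6.5), 0)
  for (a in c(0, 1.5, 4)) {
    for (b in c(0, 2, 7)) {
      expect_equal(decompose_uncertainty(sqrt(a^2 + b^2), a), b)
    }
  }
  expect_error(decompose_uncertainty(3, c(4)), "deficit")
})

test_that("sample-preparation uncertainty derives from the 16%/13% budgets", {
  expect_equal(signif_away(decompose_uncertainty(16 / 2, 13 / 2), 2), 4.7)
})

test_that("theoretical concentrations follow from content and corrections", {
  m154 <- sphere_mass(15.4, 10.49)
  theo <- theoretical_concentration(0.1016, 0.22, m154,
                                    undetected_number_fraction = 0.14,
                                    undetected_mass_fraction = 0.015)
  expect_equal(signif_away(theo$C_m_theo_mg_g, 2), 79)
  expect_equal(signif_away(theo$C_p_theo_per_g, 2), 3.4e15)
  # corrections off: simple division
  plain <- theoretical_concentration(0.01, 0, 1e-17)
  expect_equal(plain$C_m_theo_mg_g, 10)
  expect_equal(plain$C_p_theo_per_g, 1e15)
  # the undetected mass fraction only applies on request
  applied <- theoretical_concentration(0.1016, 0.22, m154,
                                       undetected_mass_fraction = 0.015,
                                       apply_undetected_mass = TRUE)
  expect_lt(applied$C_m_theo_mg_g, theo$C_m_theo_mg_g)
})

test_that("recovery is a plain percentage", {
  expect_equal(recovery(1.73e15, 3.4e15), 51, tolerance = 0.005)
  expect_equal(recovery(5, 5), 100)
  expect_equal(signif_away(recovery(44, 79), 2), 56)
  expect_error(recovery(1, 0), "theoretical")
})

test_that("report rounding is 2 significant figures, half away from zero", {
  expect_equal(signif_away(13.28), 13)
  expect_equal(signif_away(12.5), 13)
  expect_equal(signif_away(22.77), 23)
  expect_equal(signif_away(4.664), 4.7)
  expect_equal(signif_away(0.0125), 0.013)
  expect_equal(signif_away(-12.5), -13)
  expect_equal(signif_away(0), 0)
  expect_equal(signif_away(3.397e15), 3.4e15)
})

test_that("simulated studies are recovered by the ANOVA within sampling bands", {
  des <- study_design(5, 3, between_day_sd = 0.028, within_day_sd = 0.009)
  est <- vapply(1:400, function(s) {
    pr <- anova_precision(simulate_validation_study(des, 100, seed = s))
    c(pr$msw, (pr$msb - pr$msw) / 3)
  }, numeric(2))
  # unbiased variance-component estimators: check means against truth with
  # 3-sigma Monte-Carlo bands (MSW ~ sr^2 chi2_10/10; var of the between-day
  # contrast from the chi2_4 of MSB)
  sr2 <- 0.9^2; sd2 <- 2.8^2
  se_msw <- sqrt(2 * sr2^2 / 10 / ncol(est))
  se_msb <- sqrt((2 * (3 * sd2 + sr2)^2 / 4 + 2 * sr2^2 / 10) / 9 / ncol(est))
  expect_lt(abs(mean(est[1, ]) - sr2), 3 * se_msw)
  expect_lt(abs(mean(est[2, ]) - sd2), 3 * se_msb)
})
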
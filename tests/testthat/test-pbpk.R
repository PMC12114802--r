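test_that("metabolic rate follows Michaelis-Menten kinetics", {
  s <- default_substance()
  expect_equal(metabolic_rate(0, s), 0)
  expect_equal(metabolic_rate(11.7, s), 1221.7 / 2)  # half saturation
  expect_lt(abs(metabolic_rate(1e7, s) - 1221.7), 1.5e-3)  # saturation limit
  expect_error(metabolic_rate(-1, s), "non-negative")
})

test_that("derivatives vanish for an empty body and at the analytic steady state", {
  phys <- default_physiology(49)
  s <- default_substance()
  nt <- nrow(phys$tissues)
  d0 <- pbpk_derivatives(0, rep(0, nt + 3), phys, s, input_rate = 0)[[1]]
  expect_equal(d0, rep(0, nt + 3))

  rate <- 4612 / 24
  ss <- steady_state_analytic(rate, phys, s)
  state <- c(phys$tissues$partition * ss$c_arterial, ss$c_venous,
             ss$c_arterial, 0)
  state[which(phys$tissues$metabolizing)] <-
    phys$tissues$partition[phys$tissues$metabolizing] * ss$cv_liver
  d <- pbpk_derivatives(0, state, phys, s, input_rate = rate)[[1]]
  # every concentration derivative ~ 0; metabolism balances the input
  expect_lt(max(abs(d[seq_len(nt + 2)])), 1e-10)
  expect_equal(d[nt + 3], rate)
})

test_that("derivatives conserve mass for arbitrary states", {
  phys <- default_physiology(73)
  s <- default_substance()
  nt <- nrow(phys$tissues)
  set.seed(42)
  for (i in 1:20) {
    state <- c(runif(nt + 2, 0, 30), 0)
    rate <- runif(1, 0, 2000)
    d <- pbpk_derivatives(0, state, phys, s, input_rate = rate)[[1]]
    flux <- sum(phys$tissues$volume_L * d[seq_len(nt)]) +
      phys$venous_blood_volume_L * d[nt + 1] +
      phys$arterial_blood_volume_L * d[nt + 2] + d[nt + 3] - rate
    expect_lt(abs(flux), 1e-9)
  }
  expect_error(pbpk_derivatives(0, rep(0, 5), phys, s), "length")
})

test_that("compiled and R right-hand sides integrate to the same profile", {
  reg <- dosing_regimen(dose_mg = 500, duration_h = 2)
  phys <- default_physiology(60)
  pc <- simulate_profile(reg, phys, t_end_h = 6, engine = "compiled",
                         dt_dosing_h = 0.05, dt_washout_h = 0.1)
  pr <- simulate_profile(reg, phys, t_end_h = 6, engine = "R",
                         dt_dosing_h = 0.05, dt_washout_h = 0.1)
  expect_equal(pc$c_venous_mg_per_L, pr$c_venous_mg_per_L, tolerance = 1e-7)
  expect_equal(pc$amount_metabolized_mg, pr$amount_metabolized_mg,
               tolerance = 1e-7)
})

test_that("analytic steady state solves the saturable elimination balance", {
  phys <- default_physiology(49)
  s <- default_substance()
  rate <- 4612 / 24
  ss <- steady_state_analytic(rate, phys, s)
  expect_equal(ss$cv_liver, rate * 11.7 / (1221.7 - rate))
  expect_equal(ss$c_arterial, ss$cv_liver + rate / 99.5)
  expect_equal(ss$c_arterial, 4.1152, tolerance = 1e-4)
  # at half of Vmax the liver venous concentration equals Km
  expect_equal(steady_state_analytic(1221.7 / 2, phys, s)$cv_liver, 11.7)
  # the erroneous schedule's rate exceeds the metabolic capacity
  expect_error(steady_state_analytic(3052 / 2, phys, s),
               "no finite steady state")
  expect_error(steady_state_analytic(0, phys, s), "positive")
})

test_that("a zero-dose regimen yields an identically zero profile", {
  prof <- simulate_profile(dosing_regimen(dose_mg = 0, duration_h = 1),
                           t_end_h = 4, dt_dosing_h = 0.1)
  expect_true(all(prof$c_venous_mg_per_L == 0))
  expect_true(all(prof$amount_metabolized_mg == 0))
})

test_that("simulated profiles close their mass balance", {
  for (reg in list(patient_erroneous(), patient_planned(),
                   dosing_regimen(dose_mg = 1000))) {  # incl. an iv bolus
    prof <- simulate_profile(reg, default_physiology(49),
                             dt_dosing_h = 0.02, dt_washout_h = 0.1)
    expect_lt(attr(prof, "mass_balance_rel_error"), 1e-3)
    expect_true(all(prof$c_venous_mg_per_L >= 0))
    expect_true(all(diff(prof$amount_metabolized_mg) >= -1e-9))
  }
})

test_that("a long constant infusion converges to the analytic steady state", {
  phys <- default_physiology(73)
  rate <- 100  # mg/h, well below Vmax
  # effective half-life is ~1 h; 48 h is far beyond 10 half-times
  prof <- simulate_profile(dosing_regimen(dose_mg = rate * 48,
                                          duration_h = 48),
                           phys, t_end_h = 49, dt_dosing_h = 0.05)
  ss <- steady_state_analytic(rate, phys)
  plateau <- as.numeric(css_observed(prof))
  expect_lt(abs(plateau - ss$c_venous) / ss$c_venous, 0.005)
})

test_that("AUC is linear in dose at sub-saturating concentrations", {
  phys <- default_physiology(73)
  a1 <- pk_auc(simulate_profile(dosing_regimen(dose_mg = 5, duration_h = 1),
                                phys, t_end_h = 25))
  a2 <- pk_auc(simulate_profile(dosing_regimen(dose_mg = 10, duration_h = 1),
                                phys, t_end_h = 25))
  expect_lt(abs(a2 / a1 - 2), 0.01 * 2)
})

test_that("AUC per unit dose grows with dose as metabolism saturates", {
  phys <- default_physiology(73)
  doses <- c(100, 1000, 3000)
  aucd <- vapply(doses, function(d)
    pk_auc(simulate_profile(dosing_regimen(dose_mg = d, duration_h = 2),
                            phys, dt_dosing_h = 0.02)) / d, numeric(1))
  expect_true(all(diff(aucd) > 0))
})

test_that("simulate_profile rejects impossible requests with clear errors", {
  expect_error(simulate_profile(dosing_regimen(dose_mg = 100, duration_h = 4),
                                t_end_h = 2), "beyond the last dosing event")
  expect_error(simulate_profile(data.frame(dose_mg = 1)), "fu_regimen")
})
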
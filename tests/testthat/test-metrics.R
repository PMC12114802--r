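test_that("trapezoidal AUC reproduces closed-form integrals", {
  flat <- fake_profile(seq(0, 24, by = 0.5), rep(2, 49))
  expect_equal(pk_auc(flat, 0, 24), 48)
  # single-exponential decay: AUC[0,inf) = C0/k
  tt <- seq(0, 20, by = 0.001)
  expo <- fake_profile(tt, 10 * exp(-tt))
  expect_equal(pk_auc(expo, 0, 20), 10 * (1 - exp(-20)), tolerance = 1e-6)
  # full-profile horizon stops once the curve falls below 0.1% of Cmax
  expect_equal(pk_auc(expo), 10, tolerance = 0.005)
  expect_error(pk_auc(expo, 5, 3), "less than")
  expect_error(pk_auc(expo, -2, 5), "outside")
})

test_that("AUC is additive over adjacent intervals on a shared grid", {
  prof <- simulate_profile(dosing_regimen(dose_mg = 800, duration_h = 3),
                           t_end_h = 12, dt_dosing_h = 0.05,
                           dt_washout_h = 0.05)
  expect_equal(pk_auc(prof, 0, 2) + pk_auc(prof, 2, 9), pk_auc(prof, 0, 9))
})

test_that("cmax is the grid maximum and occurs at the end of a rising infusion", {
  expect_equal(pk_cmax(fake_profile(0:10, rep(2, 11))), 2)
  expect_error(pk_cmax(fake_profile(numeric(0), numeric(0))), "empty")
  prof <- simulate_profile(dosing_regimen(dose_mg = 2000, duration_h = 4),
                           t_end_h = 10, dt_dosing_h = 0.01)
  t_peak <- prof$time_h[which.max(prof$c_venous_mg_per_L)]
  expect_lte(abs(t_peak - 4), 0.01 + 1e-9)
})

test_that("Css from AUC is the published division, with its rounding", {
  expect_equal(css_from_auc(40, 24), 1.666667, tolerance = 1e-6)
  expect_equal(css_from_auc(24, 24), 1)
  expect_equal(css_from_auc(77.5, 24), 3.229167, tolerance = 1e-6)
  expect_error(css_from_auc(40, 0), "positive")
  expect_error(css_from_auc(-1, 24), "non-negative")
})

test_that("css_observed averages the plateau and flags drifting windows", {
  reg <- dosing_regimen(dose_mg = 240, duration_h = 24)
  flat <- fake_profile(seq(0, 24, by = 0.1), rep(3, 241), regimen = reg)
  v <- css_observed(flat)
  expect_equal(as.numeric(v), 3)
  expect_false(attr(v, "no_plateau"))
  ramp <- fake_profile(seq(0, 24, by = 0.1), seq(0, 24, by = 0.1) / 4,
                       regimen = reg)
  expect_true(attr(css_observed(ramp), "no_plateau"))
  expect_error(css_observed(flat, window_h = 20), "final third")
  bolus <- fake_profile(0:5, rep(1, 6), regimen = dosing_regimen(dose_mg = 10))
  expect_error(css_observed(bolus), "constant-rate infusion")
})

test_that("fraction of steady state rises from 0 to ~1 over a long infusion", {
  prof <- simulate_profile(patient_planned(), default_physiology(49),
                           dt_dosing_h = 0.02)
  expect_equal(fraction_of_steady_state(prof, 0), 0)
  expect_gt(fraction_of_steady_state(prof, 23.9), 0.99)
  f1 <- fraction_of_steady_state(prof, 1)
  expect_gt(f1, 0.3)
  expect_lt(f1, 0.7)
  # forecast inverts attainment: cdyn / true fraction returns the plateau
  cdyn <- approx(prof$time_h, prof$c_venous_mg_per_L, 1)$y
  expect_equal(predict_css_from_cdyn(cdyn, f1),
               as.numeric(css_observed(prof)))
  # no steady state exists above the metabolic capacity
  err <- simulate_profile(patient_erroneous(), default_physiology(49),
                          dt_dosing_h = 0.02)
  expect_error(fraction_of_steady_state(err, 1), "metabolic capacity")
})

test_that("Cdyn-based forecasting doubles a half-plateau sample", {
  expect_equal(predict_css_from_cdyn(1.5), 3.0)
  expect_equal(predict_css_from_cdyn(3.0), 6.0)
  expect_equal(predict_css_from_cdyn(0), 0)
  expect_error(predict_css_from_cdyn(1, 0), "fraction")
  expect_error(predict_css_from_cdyn(1, 1.2), "fraction")
})

test_that("plateau AUC over one hour matches the plateau concentration", {
  prof <- simulate_profile(patient_planned(), default_physiology(49),
                           dt_dosing_h = 0.02)
  css <- as.numeric(css_observed(prof))
  expect_lt(abs(css_from_auc(pk_auc(prof, 23, 24), 1) - css) / css, 0.01)
})

test_that("exposure_summary collects the monitoring metrics in one row", {
  prof <- simulate_profile(patient_planned(), default_physiology(49),
                           dt_dosing_h = 0.02)
  s <- exposure_summary(prof)
  expect_named(s, c("cmax_mg_per_L", "auc_mg_h_per_L", "css_mg_per_L",
                    "no_plateau", "cdyn_mg_per_L", "t_sample_h"))
  expect_false(s$no_plateau)
  expect_gte(s$cmax_mg_per_L, s$css_mg_per_L)
  expect_equal(s$cdyn_mg_per_L / s$css_mg_per_L, 0.52, tolerance = 0.05)
})
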
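obs_grid <- function(t_end = 8, dt = 0.5) {
  data.frame(t_h = seq(0, t_end, by = dt), growth_h_1 = NA_real_,
             fluor_au = NA_real_)
}

test_that("the three-phase protocol starts at the ambient steady state", {
  e_flat <- shift_experiment(200, 200, observations = obs_grid())
  pred <- simulate_protocol(calibrated, 200, e_flat)
  ss <- photophilic_steady_state(calibrated, light = 200)
  expect_equal(pred$lambda, rep(ss$lambda, length(pred$t_h)), tolerance = 1e-6)
  expect_equal(pred$fluor,
               rep(calibrated$params$fluor_scale * ss$state[["C"]],
                   length(pred$t_h)),
               tolerance = 1e-6)
  e_shift <- shift_experiment(800, 0, observations = obs_grid(t_end = 10))
  pred2 <- simulate_protocol(calibrated, 100, e_shift)
  expect_equal(pred2$lambda[1],
               photophilic_steady_state(calibrated, light = 100)$lambda,
               tolerance = 1e-8)
  # the switch at 6 h shows up as a direction change
  expect_gt(pred2$lambda[pred2$t_h == 6], pred2$lambda[1])
  expect_lt(pred2$lambda[pred2$t_h == 10], pred2$lambda[pred2$t_h == 6])
})

test_that("L0 estimation inverts the dose response", {
  expect_equal(estimate_L0(calibrated,
                           photophilic_steady_state(calibrated, light = 0)$lambda),
               0)
  lam400 <- photophilic_steady_state(calibrated, light = 400)$lambda
  expect_equal(estimate_L0(calibrated, lam400), 400, tolerance = 0.5)
  expect_error(estimate_L0(calibrated, 2.5), "outside")
  # monotone dose response makes the root unique: perturbing the target
  # moves the estimate in one direction only
  lams <- seq(1.3, 1.8, by = 0.1)
  L0s <- vapply(lams, function(l) estimate_L0(calibrated, l), 0)
  expect_true(all(diff(L0s) > 0))
})

test_that("noiseless data generated at the truth gives a near-zero residual", {
  exps <- list(
    generate_shift_dataset(calibrated, L0 = 50, light_phase1 = 800,
                           light_phase2 = 100, t_end = 8,
                           noise_sd_growth = 0, rel_sd_fluor = 0),
    generate_shift_dataset(calibrated, L0 = 50, light_phase1 = 0,
                           light_phase2 = 800, t_end = 8,
                           noise_sd_growth = 0, rel_sd_fluor = 0))
  fr <- fit_photophilic(calibrated, exps, n_starts = 1, maxit = 5,
                        rounds = 1)
  expect_lt(fr$residual_norm, 1e-3)
  expect_equal(unname(fr$parameters["K_L"]), calibrated$params$K_L,
               tolerance = 1e-3)
  expect_lte(fr$residual_norm, fr$start_residual_norm)
})

test_that("the fit is invariant to the ordering of experiments", {
  exps <- list(
    generate_shift_dataset(calibrated, L0 = 50, light_phase1 = 800,
                           light_phase2 = 0, t_end = 8, seed = 41),
    generate_shift_dataset(calibrated, L0 = 50, light_phase1 = 0,
                           light_phase2 = 800, t_end = 8, seed = 42))
  f1 <- fit_photophilic(calibrated, exps, n_starts = 1, maxit = 40, seed = 2)
  f2 <- fit_photophilic(calibrated, rev(exps), n_starts = 1, maxit = 40,
                        seed = 2)
  expect_equal(f1$residual_norm, f2$residual_norm, tolerance = 1e-6)
  expect_equal(f1$parameters, f2$parameters, tolerance = 1e-4)
})

test_that("shift experiment and dataset generation validate and reproduce", {
  expect_error(shift_experiment(800, 0, observations = data.frame(x = 1)))
  d1 <- generate_shift_dataset(calibrated, seed = 5)
  d2 <- generate_shift_dataset(calibrated, seed = 5)
  expect_identical(d1$observations, d2$observations)
  d0 <- generate_shift_dataset(calibrated, L0 = 100, light_phase1 = 800,
                               light_phase2 = 0, noise_sd_growth = 0,
                               rel_sd_fluor = 0)
  pred <- simulate_protocol(
    calibrated, 100,
    shift_experiment(800, 0, observations = d0$observations))
  expect_equal(d0$observations$growth_h_1, pred$lambda, tolerance = 1e-9)
  expect_equal(d0$observations$fluor_au, pred$fluor, tolerance = 1e-9)
})
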
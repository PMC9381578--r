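test_that("light activation rate is saturating and monotone", {
  p <- photophilic_params(ka_dark = 0.01, ka_light = 0.2, K_L = 200)
  expect_equal(light_activation_rate(0, p), 0.01)
  expect_equal(light_activation_rate(200, p), 0.01 + 0.1)
  grid <- light_activation_rate(seq(0, 800, by = 25), p)
  expect_true(all(diff(grid) > 0))
  expect_error(light_activation_rate(900, p))
})

test_that("algebraic steady state agrees with long integration", {
  for (L in c(0, 150, 800)) {
    alg <- photophilic_steady_state(calibrated, light = L)
    tr <- simulate_light_program(calibrated, light_program(0, L), t_end = 60,
                                 init = c(D = 0.1, A = 0, C = 0, c_in = 0),
                                 dt_out = 60)
    final <- unlist(tr[nrow(tr), c("D", "A", "C", "c_in")])
    expect_equal(final, alg$state, tolerance = 1e-5)
    expect_equal(tr$lambda_h_1[nrow(tr)], alg$lambda, tolerance = 1e-6)
  }
})

test_that("generic pure-R route reproduces the compiled trajectory", {
  circ <- build_photophilic_model(calibrated)
  sys <- assemble_system(circ, calibrated$host, calibrated$env)
  init <- photophilic_steady_state(calibrated, light = 0)$state
  names(init) <- sys$state_names
  trR <- integrate_circuit(sys, init = init, t_span = c(0, 2),
                           program = light_program(0, 800), dt_out = 0.25)
  trC <- simulate_light_program(calibrated, light_program(0, 800), t_end = 2,
                                init = init, dt_out = 0.25)
  expect_equal(trR$C, trC$C, tolerance = 1e-6)
  expect_equal(trR$lambda_h_1, trC$lambda_h_1, tolerance = 1e-6)
})

test_that("dimer mass balance: monomer equivalents obey production minus dilution", {
  circ <- build_photophilic_model(calibrated)
  sys <- assemble_system(circ, calibrated$host, calibrated$env)
  f <- sys$rhs_factory(light = 300)
  set.seed(3)
  for (i in 1:20) {
    y <- c(runif(1, 0, 2), runif(1, 0, 0.1), runif(1, 0, 0.2), runif(1, 0, 10))
    dy <- f(0, y)
    envL <- calibrated$env; envL$light <- 300
    lam <- sys$lambda_of(y, envL)
    expect_equal(dy[1] + 2 * dy[2],
                 calibrated$params$beta_T7 * lam^2 / calibrated$env$nu -
                   lam * (y[1] + 2 * y[2]),
                 tolerance = 1e-10)
  }
})

test_that("steady-state growth orderings match the biology", {
  lam_no_ab <- photophilic_steady_state(calibrated, light = 0, c_ext = 0)$lambda
  lam_dark <- photophilic_steady_state(calibrated, light = 0)$lambda
  lam_max <- photophilic_steady_state(calibrated, light = 800)$lambda
  expect_gt(lam_no_ab, lam_max)
  expect_gt(lam_max, lam_dark)
  m_nores <- calibrated
  m_nores$params$beta_CAT <- 0
  expect_lt(photophilic_steady_state(m_nores, light = 800)$lambda, lam_dark)
  # more antibiotic always slows growth
  expect_lt(photophilic_steady_state(calibrated, light = 400, c_ext = 21)$lambda,
            photophilic_steady_state(calibrated, light = 400, c_ext = 10.5)$lambda)
})

test_that("dose response is monotone and consistent with single steady states", {
  dr <- dose_response(calibrated, seq(0, 800, by = 100))
  expect_true(all(diff(dr$lambda_h_1) >= 0))
  expect_equal(dose_response(calibrated, 300)$lambda_h_1,
               photophilic_steady_state(calibrated, light = 300)$lambda)
  # resistance is the upstream variable: CAT fold change exceeds growth fold
  # change, and intracellular antibiotic falls as CAT rises
  ss <- lapply(c(0, 200, 400, 800),
               function(L) photophilic_steady_state(calibrated, light = L))
  C <- vapply(ss, function(s) s$state[["C"]], 0)
  c_in <- vapply(ss, function(s) s$state[["c_in"]], 0)
  lam <- vapply(ss, function(s) s$lambda, 0)
  expect_true(all(diff(C) > 0))
  expect_true(all(diff(c_in) < 0))
  expect_gt(C[4] / C[1], lam[4] / lam[1])
})

test_that("endpoint calibration hits its targets and is idempotent", {
  expect_equal(photophilic_steady_state(calibrated, light = 0)$lambda, 1.0,
               tolerance = 1e-6)
  expect_equal(photophilic_steady_state(calibrated, light = 800)$lambda, 1.9,
               tolerance = 1e-6)
  expect_equal(photophilic_steady_state(calibrated, light = 0, c_ext = 0)$lambda,
               2.0, tolerance = 1e-6)
  again <- calibrate_endpoints(calibrated)
  expect_equal(again$params$ka_dark, calibrated$params$ka_dark,
               tolerance = 1e-4)
  expect_equal(again$params$ka_light, calibrated$params$ka_light,
               tolerance = 1e-4)
  expect_error(
    calibrate_endpoints(photophilic_model(),
                        targets = c(lambda_dark = 1.9, lambda_max = 1.0,
                                    lambda_no_ab = 2.0)),
    "lambda_dark < lambda_max")
})

test_that("a constant program from its own steady state stays flat", {
  tr <- simulate_light_program(calibrated, light_program(0, 400), t_end = 5)
  expect_lt(diff(range(tr$lambda_h_1)), 1e-6)
  expect_lt(diff(range(tr$C)) / tr$C[1], 1e-6)
  expect_equal(tr$fluor_au, calibrated$params$fluor_scale * tr$C)
})

test_that("an upshift approaches the new steady state monotonically after onset", {
  tr <- simulate_light_program(calibrated, light_program(0, 800), t_end = 8,
                               init_light = 0)
  lam <- tr$lambda_h_1
  expect_true(all(diff(lam) > -1e-8))
  expect_equal(lam[length(lam)],
               photophilic_steady_state(calibrated, light = 800)$lambda,
               tolerance = 1e-4)
})
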
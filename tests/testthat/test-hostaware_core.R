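host <- host_params()
env <- culture_env(nu = 10, c_ext = 0, light = 0)

one_gene <- function(omega = 150, alpha = 100, delta = 10, n_aa = 300) {
  circuit_model(genes = list(gene_spec("rep", omega, alpha, delta, n_aa)))
}

test_that("synthetic fraction is linear with the stated conversion", {
  expect_equal(synthetic_fraction(c(0, 0), c(300, 600), 3e6), 0)
  a <- 2; b <- 5
  expect_equal(synthetic_fraction(c(a, b), c(300, 600), 3e6),
               (300 * a + 600 * b) / 3e6)
  expect_equal(synthetic_fraction(c(2 * a, 2 * b), c(300, 600), 3e6),
               2 * synthetic_fraction(c(a, b), c(300, 600), 3e6))
  expect_error(synthetic_fraction(c(1e5, 0), c(300, 600), 3e6, host = host),
               class = "optoculture_burden_error")
})

test_that("an empty circuit has zero derivatives and the burden-free growth rate", {
  circ <- circuit_model(genes = list(gene_spec("g", 0, 0, 1, 300)))
  sys <- assemble_system(circ, host, env)
  f <- sys$rhs_factory()
  expect_equal(f(0, c(0, 0)), c(0, 0))
  expect_equal(sys$lambda_of(c(0, 0)),
               growth_rate(0, env$nu, host$gamma0, host))
})

test_that("one constitutive gene reaches the predicted self-consistent steady state", {
  circ <- one_gene()
  sys <- assemble_system(circ, host, env)
  # independent oracle: fixed-point iteration on (lambda, m, X)
  g <- circ$genes[[1]]
  lam <- growth_rate(0, env$nu, host$gamma0, host)
  for (i in 1:200) {
    m <- g$omega * (lam / env$nu) / g$delta
    X <- g$alpha * m
    lam_new <- growth_rate(g$n_aa * X / host$rho_cell, env$nu, host$gamma0, host)
    if (abs(lam_new - lam) < 1e-14) break
    lam <- lam_new
  }
  expect_gt(g$n_aa * X / host$rho_cell, 0.01)  # burden actually bites
  ss <- steady_state(sys, light = 0)
  expect_lt(attr(ss, "deriv_norm"), 1e-8)
  expect_equal(unname(ss[["m_rep"]]), m, tolerance = 1e-6)
  expect_equal(unname(ss[["rep"]]), X, tolerance = 1e-6)
  expect_equal(attr(ss, "lambda"), lam, tolerance = 1e-6)
  # the steady state is invariant to the initial condition
  ss2 <- steady_state(sys, init = c(m_rep = 5 * m, rep = 3 * X), light = 0)
  expect_equal(as.numeric(ss2), as.numeric(ss), tolerance = 1e-6)
})

test_that("mRNA carries no growth-dilution term", {
  # adding lambda to delta must change the dynamics: guards against a
  # -lambda*m term sneaking into the mRNA equation
  circ1 <- one_gene(delta = 10)
  sys1 <- assemble_system(circ1, host, env)
  lam_ss <- attr(steady_state(sys1, light = 0), "lambda")
  circ2 <- one_gene(delta = 10 + lam_ss)
  sys2 <- assemble_system(circ2, host, env)
  tr1 <- integrate_circuit(sys1, t_span = c(0, 1), dt_out = 0.2)
  tr2 <- integrate_circuit(sys2, t_span = c(0, 1), dt_out = 0.2)
  expect_gt(max(abs(tr1$m_rep - tr2$m_rep)), 1e-3)
})

test_that("frozen-host mode reproduces textbook exponential relaxation", {
  r <- 4; lam_frozen <- 1.3
  circ <- circuit_model(proteins = list(
    protein_species("P", 300, function(st, lambda, env) r)))
  sys <- assemble_system(circ, host, env, frozen_lambda = lam_frozen)
  tt <- seq(0, 3, by = 0.25)
  tr <- integrate_circuit(sys, t_span = c(0, 3), dt_out = 0.25)
  analytic <- (r / lam_frozen) * (1 - exp(-lam_frozen * tt))
  expect_equal(tr$P, analytic, tolerance = 1e-6)
  expect_true(all(tr$lambda_h_1 == lam_frozen))
})

test_that("integration satisfies the semigroup property and converges in tolerance", {
  circ <- one_gene()
  sys <- assemble_system(circ, host, env)
  one_shot <- integrate_circuit(sys, t_span = c(0, 2), dt_out = 0.5)
  first <- integrate_circuit(sys, t_span = c(0, 1), dt_out = 0.5)
  y_mid <- unlist(first[nrow(first), sys$state_names])
  second <- integrate_circuit(sys, init = y_mid, t_span = c(1, 2), dt_out = 0.5)
  expect_equal(unlist(second[nrow(second), sys$state_names]),
               unlist(one_shot[nrow(one_shot), sys$state_names]),
               tolerance = 1e-6)
  tight <- integrate_circuit(sys, t_span = c(0, 2), dt_out = 0.5,
                             rtol = 5e-8, atol = 5e-11)
  expect_equal(tight$rep, one_shot$rep, tolerance = 1e-5)
})

test_that("proteome conservation holds along trajectories", {
  circ <- one_gene()
  sys <- assemble_system(circ, host, env)
  tr <- integrate_circuit(sys, t_span = c(0, 4), dt_out = 0.2)
  for (i in seq_len(nrow(tr))) {
    phi_S <- 300 * tr$rep[i] / host$rho_cell
    gamma <- host$gamma0
    st <- proteome_state(phi_S, tr$lambda_h_1[i], gamma, host)
    expect_equal(st$phi_R + st$phi_P + st$phi_Q + st$phi_S, 1,
                 tolerance = 1e-9)
  }
})

test_that("orthogonal transcription bypasses the host-machinery factor", {
  mk <- function(host_tx) {
    circuit_model(genes = list(gene_spec("g", omega = 1, alpha = 1,
                                         delta = 10, n_aa = 300,
                                         host_transcription = host_tx)))
  }
  sys_host <- assemble_system(mk(TRUE), host, env)
  sys_orth <- assemble_system(mk(FALSE), host, env)
  lam <- sys_host$lambda_of(c(0, 0))
  # at zero state dm/dt is omega*(lambda/nu) vs omega
  expect_equal(sys_host$rhs_factory()(0, c(0, 0))[1], lam / env$nu)
  expect_equal(sys_orth$rhs_factory()(0, c(0, 0))[1], 1)
})
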
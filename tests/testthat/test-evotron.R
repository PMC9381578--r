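test_that("turbidostat dilution timing matches the closed form", {
  cfg <- turbidostat_config(od_noise_sd = 0)
  tb <- simulate_turbidostat(1.4, cfg, t_end = 10)
  expect_equal(diff(tb$dilutions),
               rep(log(0.15 / 0.10) / 1.4, length(tb$dilutions) - 1),
               tolerance = 1e-9)
  expect_equal(max(tb$readings$od_true), cfg$od_high)
  # a reading right after each dilution sits at od_low
  post <- vapply(tb$dilutions, function(td) {
    tb$readings$od_true[which(tb$readings$time_h > td)[1]]
  }, 0)
  expect_equal(post, rep(cfg$od_low, length(post)), tolerance = 1e-6)
  # no growth, no dilutions
  expect_length(simulate_turbidostat(0, cfg, t_end = 10)$dilutions, 0)
})

test_that("growth-rate estimation from log-OD is exact on clean segments", {
  tt <- seq(0, 0.25, by = 0.02)
  expect_equal(estimate_growth_rate(tt, 0.1 * exp(1.2 * tt)), 1.2,
               tolerance = 1e-10)
  expect_equal(estimate_growth_rate(tt, rep(0.12, length(tt))), 0,
               tolerance = 1e-12)
  expect_error(estimate_growth_rate(c(0, 0.1), c(0.1, 0.12)), "at least 3")
  expect_error(estimate_growth_rate(c(0, 0.1, 0.2), c(0.14, 0.15, 0.10)),
               "dilution")
})

test_that("noisy growth estimates hit the truth within standard errors", {
  set.seed(31)
  lam <- 1.3
  tt <- seq(0, 0.275, by = 0.025)  # 12 readings in one rising segment
  errs <- replicate(100, {
    od <- 0.1 * exp(lam * tt) * exp(rnorm(length(tt), 0, 0.01))
    fit <- stats::lm(log(od) ~ tt)
    (stats::coef(fit)[2] - lam) / summary(fit)$coefficients[2, 2]
  })
  expect_gt(mean(abs(errs) <= 3), 0.95)
  # and the package estimator agrees with the direct regression
  od <- 0.1 * exp(lam * tt) * exp(rnorm(length(tt), 0, 0.01))
  expect_equal(estimate_growth_rate(tt, od),
               unname(stats::coef(stats::lm(log(od) ~ tt))[2]))
})

test_that("segments from a simulated run recover a time-varying growth rate", {
  tb <- simulate_turbidostat(function(t) 1 + 0.5 * (t > 5),
                             turbidostat_config(od_noise_sd = 0), t_end = 10)
  seg_ids <- unique(tb$readings$segment)
  early <- subset(tb$readings, segment == 2)
  late <- subset(tb$readings, segment == seg_ids[length(seg_ids) - 1])
  expect_equal(estimate_growth_rate(early$time_h, early$od_true), 1,
               tolerance = 1e-3)
  expect_equal(estimate_growth_rate(late$time_h, late$od_true), 1.5,
               tolerance = 1e-3)
})

test_that("threshold gating recovers the strain fraction", {
  mm <- separated_cytometry()
  expect_equal(cytometry_sample(0, mm, seed = 1)$phi_hat, 0)
  expect_equal(cytometry_sample(1, mm, seed = 1)$phi_hat, 1)
  s <- cytometry_sample(0.5, mm, seed = 2)
  expect_equal(nrow(s$events), mm$n_events)
  expect_identical(cytometry_sample(0.5, mm, seed = 3)$phi_hat,
                   cytometry_sample(0.5, mm, seed = 3)$phi_hat)
  # misclassification emerges from overlap with the default distributions
  big <- measurement_model(n_events = 20000)
  s0 <- cytometry_sample(0, big, seed = 4)
  expect_gt(s0$phi_hat, 0)
  expect_lt(s0$phi_hat, 0.06)
})

test_that("phi_hat is a consistent estimator as events grow", {
  err_at <- function(n) {
    mm <- separated_cytometry(n_events = n)
    mean(abs(vapply(1:30, function(s)
      cytometry_sample(0.42, mm, seed = s)$phi_hat, 0) - 0.42))
  }
  errs <- vapply(c(1e2, 1e3, 1e4), err_at, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.005)
})
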
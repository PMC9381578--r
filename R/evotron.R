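#' Turbidostat configuration
#'
#' @param od_low,od_high OD600 dilution band; the culture grows to `od_high`
#'   and is instantaneously diluted back to `od_low` (defaults 0.10--0.15).
#' @param od_noise_sd Multiplicative (log-normal) measurement noise standard
#'   deviation on OD readings; default 0.01.
#' @param read_interval OD sensor cadence (h); default 0.05.
#' @return A `turbidostat_config` object.
#' @export
turbidostat_config <- function(od_low = 0.10, od_high = 0.15,
                               od_noise_sd = 0.01, read_interval = 0.05) {
  if (!(od_low > 0 && od_low < od_high)) {
    stop("turbidostat_config: need 0 < od_low < od_high")
  }
  if (od_noise_sd < 0 || read_interval <= 0) {
    stop("turbidostat_config: invalid noise or read interval")
  }
  structure(list(od_low = od_low, od_high = od_high,
                 od_noise_sd = od_noise_sd, read_interval = read_interval),
            class = "turbidostat_config")
}

#' Simulate turbidostat optical-density dynamics
#'
#' OD grows as `dOD/dt = lambda(t) * OD` between dilutions; whenever the
#' noise-free OD reaches `od_high` an instantaneous dilution resets it to
#' `od_low`. Readings (noisy and noise-free) are emitted on the sensor grid
#' plus at the exact pre- and post-dilution instants, so the noise-free trace
#' attains `od_high` exactly at each dilution.
#'
#' @param lambda_fn `function(t)` returning the growth rate (1/h, >= 0), or
#'   a single number for constant growth.
#' @param config A [turbidostat_config()].
#' @param t_end Horizon (h).
#' @param od0 Initial OD; default `od_low`.
#' @param seed Optional seed for the measurement-noise stream.
#' @return List with `readings` (data.frame `time_h`, `od` (noisy),
#'   `od_true`, `segment` id of the rising segment) and `dilutions` (times of
#'   dilution events, h).
#' @export
simulate_turbidostat <- function(lambda_fn, config = turbidostat_config(),
                                 t_end = 20, od0 = NULL, seed = NULL) {
  if (is.numeric(lambda_fn)) {
    lam_const <- lambda_fn
    if (lam_const < 0) stop("simulate_turbidostat: lambda must be >= 0")
    lambda_fn <- function(t) rep(lam_const, length(t))
  }
  if (is.null(od0)) od0 <- config$od_low
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  # cumulative growth integral on a fine grid; log OD is piecewise this
  dt <- min(config$read_interval / 4, 0.01)
  grid <- seq(0, t_end, by = dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  lam <- lambda_fn(grid)
  if (any(lam < 0)) stop("simulate_turbidostat: lambda_fn must be >= 0")
  cumI <- c(0, cumsum(diff(grid) * (utils::head(lam, -1) + utils::tail(lam, -1)) / 2))
  growth_integral <- stats::approxfun(grid, cumI)   # piecewise-linear in t

  log_jump <- log(config$od_high / config$od_low)
  # dilution times: solve growth_integral(t) = I_reset + needed
  dilutions <- numeric(0)
  t_reset <- 0
  I_reset <- 0
  log_od_reset <- log(od0)
  seg_starts <- 0
  repeat {
    need <- log(config$od_high) - log_od_reset
    target <- I_reset + need
    if (cumI[length(cumI)] < target - 1e-15) break
    idx <- which(cumI >= target - 1e-15)[1]
    if (idx == 1) {
      t_dil <- grid[1]
    } else {
      # invert the trapezoid piece: cumI is quadratic in t on the subinterval,
      # but linear interpolation of cumI is accurate at the grid resolution
      t_dil <- grid[idx - 1] + (target - cumI[idx - 1]) /
        (cumI[idx] - cumI[idx - 1]) * (grid[idx] - grid[idx - 1])
    }
    dilutions <- c(dilutions, t_dil)
    t_reset <- t_dil
    I_reset <- target
    log_od_reset <- log(config$od_low)
    seg_starts <- c(seg_starts, t_dil)
  }
  od_true_at <- function(t) {
    seg <- findInterval(t, seg_starts)
    lo <- ifelse(seg == 1, log(od0), log(config$od_low))
    I0 <- c(0, vapply(dilutions, growth_integral, 0))[seg]
    pmin(exp(lo + growth_integral(t) - I0), config$od_high)
  }
  read_times <- seq(0, t_end, by = config$read_interval)
  # include exact pre-/post-dilution instants
  tt <- sort(unique(c(read_times, dilutions, dilutions + 1e-12)))
  tt <- tt[tt <= t_end]
  od_true <- od_true_at(tt)
  # pre-dilution sample sits at od_high exactly
  od_true[tt %in% dilutions] <- config$od_high
  noise <- if (config$od_noise_sd > 0) {
    exp(stats::rnorm(length(tt), 0, config$od_noise_sd))
  } else rep(1, length(tt))
  segment <- findInterval(tt, c(seg_starts[-1]) + 1e-12) + 1L
  readings <- data.frame(time_h = tt, od = od_true * noise,
                         od_true = od_true, segment = segment)
  list(readings = readings, dilutions = dilutions)
}

#' Growth-rate estimate from one rising OD segment
#'
#' Least-squares slope of `log(OD)` against time. The readings must all come
#' from a single inter-dilution segment; a segment spanning a dilution event
#' (detected as a drop of more than 25 percent between consecutive readings)
#' is an error -- split at events first.
#'
#' @param time_h Reading times (h), >= 3 values.
#' @param od OD readings, all positive.
#' @return Estimated growth rate (1/h).
#' @export
estimate_growth_rate <- function(time_h, od) {
  if (length(time_h) < 3) stop("estimate_growth_rate: need at least 3 readings")
  if (any(od <= 0)) stop("estimate_growth_rate: OD readings must be positive")
  if (any(diff(log(od)) < log(0.75))) {
    stop("estimate_growth_rate: segment spans a dilution event; split at events first")
  }
  unname(stats::coef(stats::lm(log(od) ~ time_h))[2])
}

#' Flow-cytometry measurement model
#'
#' Event-level emulation of the strain-fraction readout: each event is
#' photophilic with probability `phi_p`; its GFP-channel (mVenus) intensity
#' is drawn from a log-normal positive or negative distribution; the fraction
#' estimate is the share of events above the fixed threshold gate.
#'
#' @param n_events Events per sample; default 10000.
#' @param gate_threshold GFP-A threshold separating the mVenus-positive
#'   photophilic population; default 6500.
#' @param pos_meanlog,pos_sdlog Log-normal parameters of the positive
#'   population (defaults: median 2e4, geometric SD 1.8).
#' @param neg_meanlog,neg_sdlog Same for the negative population (median
#'   2e3). Misclassification emerges from whatever overlap the distributions
#'   have; separation is not assumed.
#' @return A `measurement_model` object.
#' @export
measurement_model <- function(n_events = 10000, gate_threshold = 6500,
                              pos_meanlog = log(2e4), pos_sdlog = log(1.8),
                              neg_meanlog = log(2e3), neg_sdlog = log(1.8)) {
  if (n_events < 1) stop("measurement_model: n_events must be >= 1")
  structure(list(n_events = as.integer(n_events),
                 gate_threshold = gate_threshold,
                 pos_meanlog = pos_meanlog, pos_sdlog = pos_sdlog,
                 neg_meanlog = neg_meanlog, neg_sdlog = neg_sdlog),
            class = "measurement_model")
}

#' Draw one cytometry sample and the gated fraction estimate
#'
#' @param phi_p True photophilic fraction in `[0, 1]`.
#' @param model A [measurement_model()].
#' @param seed Optional seed.
#' @return List with `events` (data.frame `photophilic`, `gfp_au`) and
#'   `phi_hat` (fraction of events above the gate).
#' @export
cytometry_sample <- function(phi_p, model = measurement_model(), seed = NULL) {
  if (phi_p < 0 || phi_p > 1) stop("cytometry_sample: phi_p must be in [0, 1]")
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  is_pos <- stats::runif(model$n_events) < phi_p
  gfp <- numeric(model$n_events)
  gfp[is_pos] <- stats::rlnorm(sum(is_pos), model$pos_meanlog, model$pos_sdlog)
  gfp[!is_pos] <- stats::rlnorm(sum(!is_pos), model$neg_meanlog, model$neg_sdlog)
  list(events = data.frame(photophilic = is_pos, gfp_au = gfp),
       phi_hat = mean(gfp > model$gate_threshold))
}

#' Generate a synthetic upshift/downshift dataset
#'
#' Simulates the three-phase characterization protocol (pre-culture at
#' ambient light `L0` to equilibrium, first light phase of `t_switch` hours,
#' second light phase to the horizon) and adds measurement noise: additive
#' Gaussian on growth rate, relative Gaussian on fluorescence. The output is
#' the fixture consumed by [fit_photophilic()].
#'
#' @param model A [photophilic_model()] (the generating truth).
#' @param L0 Ambient pre-culture light (arb units).
#' @param light_phase1,light_phase2 Applied light in the two phases.
#' @param t_switch Phase-1 duration (h); default 6.
#' @param t_end Horizon (h); default 12.
#' @param dt Observation spacing (h); default 0.5.
#' @param noise_sd_growth Additive SD on growth observations (1/h).
#' @param rel_sd_fluor Relative SD on fluorescence observations.
#' @param seed Optional seed (deterministic dataset per seed).
#' @return A `shift_experiment`: list with the light settings and
#'   `observations` (data.frame `t_h`, `growth_h_1`, `fluor_au`).
#' @export
generate_shift_dataset <- function(model, L0 = 100, light_phase1 = 800,
                                   light_phase2 = 0, t_switch = 6,
                                   t_end = 12, dt = 0.5,
                                   noise_sd_growth = 0.05,
                                   rel_sd_fluor = 0.05, seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  obs_t <- seq(0, t_end, by = dt)
  pred <- simulate_protocol(model, L0,
                            shift_experiment(light_phase1, light_phase2,
                                             t_switch = t_switch,
                                             observations = data.frame(
                                               t_h = obs_t,
                                               growth_h_1 = NA_real_,
                                               fluor_au = NA_real_)))
  growth <- pred$lambda + stats::rnorm(length(obs_t), 0, noise_sd_growth)
  fluor <- pred$fluor * (1 + stats::rnorm(length(obs_t), 0, rel_sd_fluor))
  shift_experiment(light_phase1, light_phase2, t_switch = t_switch,
                   observations = data.frame(t_h = obs_t,
                                             growth_h_1 = pmax(growth, 0),
                                             fluor_au = pmax(fluor, 0)))
}
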
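#' PID controller gains
#'
#' Defaults are the gains used for the closed-loop composition-control
#' experiments: `Kp = 5.9055e3`, `Ki = 3.0382`, `Kd = 2.3427e5`,
#' `Kbc = 0.01 * Ki` (back-calculation anti-windup gain).
#'
#' @param kp Proportional gain (arb units per unit fraction error).
#' @param ki Integral gain (1/h).
#' @param kd Derivative gain (h).
#' @param kbc Back-calculation gain (>= 0); feeds the actuator saturation
#'   error back into the integrator.
#' @return A `pid_gains` object.
#' @export
pid_gains <- function(kp = 5.9055e3, ki = 3.0382, kd = 2.3427e5,
                      kbc = 0.01 * ki) {
  vals <- c(kp = kp, ki = ki, kd = kd, kbc = kbc)
  if (any(!is.finite(vals))) stop("pid_gains: gains must be finite")
  if (kbc < 0) stop("pid_gains: kbc must be >= 0")
  structure(as.list(vals), class = "pid_gains")
}

#' Fresh PID controller state
#' @return A `pid_state` object with zero integrator and no error memory.
#' @export
pid_state_new <- function() {
  structure(list(integral = 0, prev_error = NA_real_,
                 prev_measurement = NA_real_,
                 last_u_raw = NA_real_, last_u_sat = NA_real_,
                 initialized = FALSE),
            class = "pid_state")
}

#' One discrete PID update with saturation and back-calculation anti-windup
#'
#' Computes `e = setpoint - measurement`,
#' `u_raw = kp*e + ki*integral + kd*(e - prev_error)/dt` (derivative term 0 on
#' the first call), clamps `u_raw` into `u_bounds`, and updates the
#' integrator with `integral <- integral + e*dt + kbc*(u - u_raw)*dt` so that
#' saturation bleeds the integrator instead of winding it up.
#'
#' @details The controller arithmetic uses seconds internally (`dt` is given
#'   in hours and converted). The default gain set only makes dimensional
#'   sense on that time base: `Kd / Kp` is about 40 s of derivative time and
#'   `Kp / Ki` about 1940 s (roughly the 30-minute sampling period) of
#'   integral time. Read on an hour base the same numbers would imply a 40 h
#'   derivative time, which saturates the actuator on every sample and feeds
#'   large back-calculation corrections into the integrator.
#'
#' @param state A `pid_state`.
#' @param gains A [pid_gains()].
#' @param setpoint Target fraction.
#' @param measurement Measured fraction in `[0, 1]`.
#' @param dt Sampling interval (h), > 0.
#' @param u_bounds Actuator range (arb units); default `c(0, 800)`.
#' @param derivative_on_measurement If `TRUE`, the derivative acts on
#'   `-measurement` instead of the error (avoids derivative kick at setpoint
#'   steps); default `FALSE`, plain first difference of the error.
#' @return List `u` (applied light, arb units) and `state` (updated).
#' @export
pid_step <- function(state, gains, setpoint, measurement, dt,
                     u_bounds = c(0, 800),
                     derivative_on_measurement = FALSE) {
  stopifnot(inherits(state, "pid_state"), inherits(gains, "pid_gains"))
  if (dt <= 0) stop("pid_step: dt must be > 0")
  if (measurement < 0 || measurement > 1) {
    stop("pid_step: measurement must be in [0, 1]")
  }
  dt_s <- dt * 3600  # controller arithmetic is second-based (see Details)
  e <- setpoint - measurement
  d_term <- if (!state$initialized) 0 else if (derivative_on_measurement) {
    -gains$kd * (measurement - state$prev_measurement) / dt_s
  } else {
    gains$kd * (e - state$prev_error) / dt_s
  }
  pd_term <- gains$kp * e + d_term
  u_raw <- pd_term + gains$ki * state$integral
  u <- min(max(u_raw, u_bounds[1]), u_bounds[2])
  if (u == u_raw) {
    state$integral <- state$integral + e * dt_s
  } else {
    # implicit (backward-Euler) back-calculation: unconditionally stable for
    # any kbc * ki * dt, and identical to the explicit update
    # integral += e*dt + kbc*(u - u_raw)*dt to first order in kbc*ki*dt
    state$integral <- (state$integral + e * dt_s +
                         gains$kbc * dt_s * (u - pd_term)) /
      (1 + gains$kbc * gains$ki * dt_s)
  }
  state$prev_error <- e
  state$prev_measurement <- measurement
  state$last_u_raw <- u_raw
  state$last_u_sat <- u
  state$initialized <- TRUE
  list(u = u, state = state)
}

#' Piecewise-constant setpoint program
#'
#' @param times Breakpoints (h), starting at 0, strictly increasing.
#' @param values Target photophilic fractions in `(0, 1)`.
#' @return A `setpoint_program`; evaluate with [setpoint_at()].
#' @examples
#' setpoint_program(c(0, 10, 30), c(0.2, 0.8, 0.4))
#' @export
setpoint_program <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("setpoint_program: times must be strictly increasing")
  }
  if (any(values <= 0 | values >= 1)) {
    stop("setpoint_program: setpoints must lie strictly inside (0, 1)")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "setpoint_program")
}

#' @rdname setpoint_program
#' @param program A `setpoint_program`.
#' @param t Time (h).
#' @export
setpoint_at <- function(program, t) {
  program$values[pmax(findInterval(t, program$times), 1L)]
}

#' Closed-loop simulation of composition control
#'
#' Samples the co-culture every `dt_sample` hours, passes the measured (exact
#' or cytometry-estimated) photophilic fraction through the PID controller,
#' and holds the commanded light constant until the next sample (zero-order
#' hold), while the full strain circuit and the composition ODE evolve in
#' continuous time.
#'
#' @param model A calibrated [photophilic_model()].
#' @param lambda_c Constitutive growth rate (1/h).
#' @param phi0 Initial photophilic fraction.
#' @param gains A [pid_gains()].
#' @param setpoints A [setpoint_program()] or a single value in `(0, 1)`.
#' @param dt_sample Sampling period (h); default 0.5 (30-minute sampling).
#' @param t_end Horizon (h).
#' @param measurement `"exact"` or `"cytometry"`.
#' @param meas_model [measurement_model()] used when
#'   `measurement = "cytometry"`.
#' @param seed Optional integer seed for the cytometry noise stream.
#' @param init_light Pre-culture light for the strain state (default 0: dark
#'   pre-culture).
#' @param u_bounds Actuator range, default `c(0, 800)`.
#' @param dt_out Resolution of the continuous trajectory (h).
#' @param derivative_on_measurement Passed to [pid_step()].
#' @return List with `samples` (audit log: `time_h`, `phi_p`, `phi_hat`,
#'   `error`, `u_raw`, `u`), `trajectory` (`time_h`, strain states, `phi_p`,
#'   `lambda_p_h_1`, `lambda_bar_h_1`, `light_au`), and `generations`
#'   (integral of the composition-weighted mean growth rate over `ln 2`).
#' @export
run_closed_loop <- function(model, lambda_c = 1.5, phi0 = 0.5,
                            gains = pid_gains(), setpoints = 0.7,
                            dt_sample = 0.5, t_end = 30,
                            measurement = c("exact", "cytometry"),
                            meas_model = NULL, seed = NULL,
                            init_light = 0, u_bounds = c(0, 800),
                            dt_out = 0.05,
                            derivative_on_measurement = FALSE) {
  measurement <- match.arg(measurement)
  if (dt_sample <= 0) stop("run_closed_loop: dt_sample must be > 0")
  if (phi0 < 0 || phi0 > 1) stop("run_closed_loop: phi0 must be in [0, 1]")
  if (is.numeric(setpoints)) setpoints <- setpoint_program(0, setpoints)
  if (measurement == "cytometry" && is.null(meas_model)) {
    meas_model <- measurement_model()
  }
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()), add = TRUE)
    set.seed(seed)
  }

  y <- c(photophilic_steady_state(model, light = init_light)$state, phi0)
  ctrl <- pid_state_new()
  t_grid <- seq(0, t_end, by = dt_sample)
  n_samp <- length(t_grid) - 1L
  samples <- data.frame(time_h = t_grid[seq_len(n_samp)], phi_p = NA_real_,
                        phi_hat = NA_real_, setpoint = NA_real_,
                        error = NA_real_, u_raw = NA_real_, u = NA_real_)
  traj <- vector("list", n_samp)
  for (k in seq_len(n_samp)) {
    t_k <- t_grid[k]
    phi_now <- min(max(y[5], 0), 1)
    phi_hat <- if (measurement == "exact") phi_now else
      cytometry_sample(phi_now, meas_model)$phi_hat
    sp <- setpoint_at(setpoints, t_k)
    upd <- pid_step(ctrl, gains, sp, phi_hat, dt_sample, u_bounds,
                    derivative_on_measurement)
    ctrl <- upd$state
    samples[k, c("phi_p", "phi_hat", "setpoint", "error", "u_raw", "u")] <-
      c(phi_now, phi_hat, sp, sp - phi_hat, ctrl$last_u_raw, upd$u)
    segs <- data.frame(start = t_k, end = t_grid[k + 1], light = upd$u)
    tt <- unique(c(seq(t_k, t_grid[k + 1], by = dt_out), t_grid[k + 1]))
    res <- strain_integrate(model, y, segs, tt, with_phi = TRUE,
                            lambda_c = lambda_c)
    y <- res$y_end
    df <- data.frame(time_h = tt, res$y)
    names(df)[-1] <- c("D", "A", "C", "c_in", "phi_p")
    df$lambda_p_h_1 <- res$lambda
    df$light_au <- upd$u
    traj[[k]] <- if (k < n_samp) df[-nrow(df), ] else df
  }
  trajectory <- do.call(rbind, traj)
  trajectory$phi_p <- pmin(pmax(trajectory$phi_p, 0), 1)
  trajectory$lambda_bar_h_1 <- trajectory$phi_p * trajectory$lambda_p_h_1 +
    (1 - trajectory$phi_p) * lambda_c
  gen <- trapz(trajectory$time_h, trajectory$lambda_bar_h_1) / log(2)
  list(samples = samples, trajectory = trajectory, generations = gen,
       final_state = y, controller = ctrl)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
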
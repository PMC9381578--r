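#' Adaptive Dormand-Prince 5(4) integration
#'
#' General-purpose explicit Runge-Kutta integrator with embedded error
#' control and cubic-Hermite dense output. Used by the host-aware core for
#' arbitrary user circuits; the concrete photophilic-strain system has a
#' compiled fast path with the same algorithm.
#'
#' @param f Right-hand side, `f(t, y)` returning `dy/dt` (numeric vector).
#' @param y0 Initial state.
#' @param times Strictly increasing output times; integration runs over
#'   `range(times)`.
#' @param rtol,atol Relative and absolute local error tolerances.
#' @param max_step Maximum step size (h).
#' @param nonneg Indices of components clipped at zero (solver-tolerance
#'   excursions below `-1e-6` are treated as integration failures).
#' @return Matrix with `length(times)` rows; columns are state components,
#'   with attribute `"times"`.
#' @keywords internal
#' @export
ode_rk45 <- function(f, y0, times, rtol = 1e-7, atol = 1e-10,
                     max_step = Inf, nonneg = integer(0)) {
  stopifnot(length(times) >= 1, !is.unsorted(times, strictly = TRUE))
  # Dormand-Prince coefficients
  c2 <- 1 / 5; c3 <- 3 / 10; c4 <- 4 / 5; c5 <- 8 / 9
  a21 <- 1 / 5
  a31 <- 3 / 40; a32 <- 9 / 40
  a41 <- 44 / 45; a42 <- -56 / 15; a43 <- 32 / 9
  a51 <- 19372 / 6561; a52 <- -25360 / 2187; a53 <- 64448 / 6561; a54 <- -212 / 729
  a61 <- 9017 / 3168; a62 <- -355 / 33; a63 <- 46732 / 5247; a64 <- 49 / 176
  a65 <- -5103 / 18656
  b1 <- 35 / 384; b3 <- 500 / 1113; b4 <- 125 / 192; b5 <- -2187 / 6784
  b6 <- 11 / 84
  e1 <- 71 / 57600; e3 <- -71 / 16695; e4 <- 71 / 1920; e5 <- -17253 / 339200
  e6 <- 22 / 525; e7 <- -1 / 40

  t0 <- times[1]; t_end <- times[length(times)]
  y <- as.numeric(y0)
  n <- length(y)
  out <- matrix(NA_real_, nrow = length(times), ncol = n)
  colnames(out) <- names(y0)
  out[1, ] <- y
  if (length(times) == 1) return(structure(out, times = times))

  k1 <- f(t0, y)
  if (any(!is.finite(k1))) stop("ode_rk45: non-finite derivative at initial state")
  h <- min(max_step, (t_end - t0) / 100, 1e-2)
  t <- t0
  next_out <- 2L
  max_steps <- 1e6
  for (step in seq_len(max_steps)) {
    if (t >= t_end) break
    h <- min(h, t_end - t)
    repeat {
      y2 <- y + h * a21 * k1
      k2 <- f(t + c2 * h, y2)
      y3 <- y + h * (a31 * k1 + a32 * k2)
      k3 <- f(t + c3 * h, y3)
      y4 <- y + h * (a41 * k1 + a42 * k2 + a43 * k3)
      k4 <- f(t + c4 * h, y4)
      y5 <- y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4)
      k5 <- f(t + c5 * h, y5)
      y6 <- y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5)
      k6 <- f(t + h, y6)
      ynew <- y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6)
      k7 <- f(t + h, ynew)
      err_vec <- h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7)
      sc <- atol + rtol * pmax(abs(y), abs(ynew))
      err <- sqrt(mean((err_vec / sc)^2))
      if (!is.finite(err)) err <- 2  # force rejection on NaN excursions
      if (err <= 1) break
      h <- h * max(0.2, 0.9 * err^(-0.2))
      if (h < 1e-14 * max(1, abs(t))) {
        stop(sprintf("ode_rk45: step size underflow at t = %g", t))
      }
    }
    t_new <- t + h
    if (length(nonneg)) {
      bad <- ynew[nonneg] < -1e-6
      if (any(bad)) {
        stop(sprintf("ode_rk45: state went negative beyond tolerance at t = %g (min %g)",
                     t_new, min(ynew[nonneg])))
      }
      ynew[nonneg] <- pmax(ynew[nonneg], 0)
    }
    # dense output: cubic Hermite on [t, t_new] using k1, k7
    while (next_out <= length(times) && times[next_out] <= t_new + 1e-14) {
      s <- (times[next_out] - t) / h
      h00 <- (1 + 2 * s) * (1 - s)^2
      h10 <- s * (1 - s)^2
      h01 <- s^2 * (3 - 2 * s)
      h11 <- s^2 * (s - 1)
      yi <- h00 * y + h10 * h * k1 + h01 * ynew + h11 * h * k7
      if (length(nonneg)) yi[nonneg] <- pmax(yi[nonneg], 0)
      out[next_out, ] <- yi
      next_out <- next_out + 1L
    }
    y <- ynew
    k1 <- k7  # FSAL
    t <- t_new
    h <- min(max_step, h * min(5, max(0.2, 0.9 * err^(-0.2))))
    if (step == max_steps) stop("ode_rk45: maximum number of steps exceeded")
  }
  out[length(times), ] <- y
  structure(out, times = times)
}

#' Piecewise-constant light program
#'
#' @param times Segment start times (h), beginning at the start of the
#'   simulation; strictly increasing.
#' @param levels Light intensity (arb units, 0--800) applied from each start
#'   time until the next (the last level holds to the end).
#' @return An object of class `light_program`.
#' @examples
#' light_program(c(0, 6), c(800, 0))  # upshift then downshift at 6 h
#' @export
light_program <- function(times, levels) {
  stopifnot(length(times) == length(levels), length(times) >= 1)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("light_program: times must be strictly increasing")
  }
  if (any(levels < 0 | levels > 800)) {
    stop("light_program: levels must lie within [0, 800] arb units")
  }
  structure(list(times = as.numeric(times), levels = as.numeric(levels)),
            class = "light_program")
}

#' Evaluate a light program
#' @param program A [light_program()].
#' @param t Time (h), scalar or vector.
#' @return Light level(s) at `t` (constant before the first breakpoint).
#' @export
light_at <- function(program, t) {
  idx <- findInterval(t, program$times)
  program$levels[pmax(idx, 1L)]
}

# Split [t0, t1] at the interior breakpoints of a light program.
# Returns data.frame(start, end, light).
program_segments <- function(program, t0, t1) {
  brk <- program$times[program$times > t0 & program$times < t1]
  starts <- c(t0, brk)
  ends <- c(brk, t1)
  data.frame(start = starts, end = ends, light = light_at(program, starts))
}
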
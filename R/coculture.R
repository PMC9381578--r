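#' Co-culture composition derivative
#'
#' Replicator-equation dynamics of the photophilic fraction in a turbidostat
#' co-culture of the photophilic and constitutive strains:
#' `dphi_p/dt = (lambda_p - lambda_c) * (1 - phi_p) * phi_p`.
#'
#' @param phi_p Photophilic fraction, in `[0, 1]`.
#' @param lambda_p Photophilic growth rate (1/h).
#' @param lambda_c Constitutive growth rate (1/h).
#' @return Time derivative of `phi_p` (1/h).
#' @export
composition_derivative <- function(phi_p, lambda_p, lambda_c) {
  if (any(phi_p < 0 | phi_p > 1)) stop("composition_derivative: phi_p must be in [0, 1]")
  (lambda_p - lambda_c) * (1 - phi_p) * phi_p
}

#' Closed-form composition trajectory at constant growth-rate difference
#'
#' Logistic solution of the composition ODE when `delta_lambda` is constant;
#' used as the independent oracle for the numerical path.
#'
#' @param phi0 Initial fraction in `(0, 1)`.
#' @param delta_lambda Constant `lambda_p - lambda_c` (1/h).
#' @param t Time (h), scalar or vector.
#' @return `phi_p(t)`.
#' @export
analytic_logistic_solution <- function(phi0, delta_lambda, t) {
  if (phi0 <= 0 || phi0 >= 1) stop("analytic_logistic_solution: phi0 must be in (0, 1)")
  g <- exp(delta_lambda * t)
  phi0 * g / (1 - phi0 + phi0 * g)
}

#' Stability of the composition fixed points
#'
#' @param lambda_p,lambda_c Strain growth rates (1/h).
#' @return List with entries `phi0` and `phi1` labeled `"stable"`,
#'   `"unstable"` or `"marginal"`; when the rates are equal every composition
#'   is a (marginal) fixed point.
#' @export
classify_fixed_points <- function(lambda_p, lambda_c) {
  if (lambda_p > lambda_c) {
    list(phi0 = "unstable", phi1 = "stable")
  } else if (lambda_p < lambda_c) {
    list(phi0 = "stable", phi1 = "unstable")
  } else {
    list(phi0 = "marginal", phi1 = "marginal")
  }
}

#' Open-loop co-culture simulation
#'
#' Couples the composition ODE to the growth rate of the photophilic strain
#' produced by the full circuit model under a constant light input. The
#' strain's internal state starts at the steady state belonging to
#' `init_light` (ambient pre-culture) and adapts to the applied light.
#'
#' @param model A [photophilic_model()].
#' @param lambda_c Constitutive strain growth rate (1/h); default 1.5,
#'   strictly inside the calibrated photophilic range (1.0--1.9) and above
#'   its midpoint, so that the growth rates are more dissimilar in the dark
#'   than under maximal light and dark convergence is the faster one.
#' @param phi0 Initial photophilic fraction in `[0, 1]`.
#' @param light Constant applied light (arb units).
#' @param t_end Horizon (h).
#' @param init_light Pre-culture light for the strain's internal state;
#'   defaults to `light` (pre-adapted strain, so `lambda_p` is constant).
#' @param dt_out Output resolution (h).
#' @return Data.frame: `time_h`, `phi_p`, `lambda_p_h_1`, strain states,
#'   `light_au`.
#' @export
simulate_open_loop <- function(model, lambda_c = 1.5, phi0 = 0.5,
                               light = 800, t_end = 40,
                               init_light = NULL, dt_out = 0.02) {
  if (phi0 < 0 || phi0 > 1) stop("simulate_open_loop: phi0 must be in [0, 1]")
  if (is.null(init_light)) init_light <- light
  strain0 <- photophilic_steady_state(model, light = init_light)$state
  segs <- data.frame(start = 0, end = t_end, light = light)
  t_out <- unique(c(seq(0, t_end, by = dt_out), t_end))
  res <- strain_integrate(model, c(strain0, phi0), segs, t_out,
                          with_phi = TRUE, lambda_c = lambda_c)
  df <- data.frame(time_h = t_out, res$y)
  names(df)[-1] <- c("D", "A", "C", "c_in", "phi_p")
  df$phi_p <- pmin(pmax(df$phi_p, 0), 1)
  df$lambda_p_h_1 <- res$lambda
  df$light_au <- light
  df
}
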
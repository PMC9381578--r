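#' Host (proteome-partition) parameters
#'
#' Constants of the coarse-grained proteome-partition description of the
#' *E. coli* host. The proteome is divided into a fixed house-keeping sector
#' `Phi_Q = 1 - phi_R_max`, a ribosomal sector `Phi_R`, a catabolic sector
#' `Phi_P`, and a synthetic sector `Phi_S` occupied by circuit proteins.
#' Growth rate follows the growth-law relation
#' \deqn{\lambda = (\Phi_R^{max} - \Phi_{R0} - \Phi_S)\,\frac{\gamma\nu}{\gamma+\nu}}
#' where `gamma` is the translational capacity and `nu` the nutrient quality.
#'
#' @param phi_R_max Maximal ribosomal proteome fraction (dimensionless, in
#'   `(0, 1]`). Default 0.55.
#' @param phi_R0 Growth-independent ribosomal offset (dimensionless,
#'   `0 <= phi_R0 < phi_R_max`). Default 0.066.
#' @param gamma0 Uninhibited translational capacity (1/h per unit proteome
#'   fraction). Default 5.9.
#' @param rho_cell Cellular protein density expressed as the total
#'   concentration of protein-bound amino acids (uM amino acids). Circuit
#'   protein concentrations are carried in uM, so
#'   `Phi_S = sum(n_aa * X) / rho_cell` is dimensionless. Default 3e6
#'   (about 2.7 M amino acids in protein, typical for *E. coli* cytoplasm).
#' @return An object of class `host_params`.
#' @examples
#' h <- host_params()
#' growth_rate(phi_S = 0, nu = 10, gamma = h$gamma0, host = h)
#' @export
host_params <- function(phi_R_max = 0.55, phi_R0 = 0.066, gamma0 = 5.9,
                        rho_cell = 3e6) {
  stopifnot(is.numeric(phi_R_max), is.numeric(phi_R0), is.numeric(gamma0),
            is.numeric(rho_cell))
  if (!(phi_R0 >= 0 && phi_R0 < phi_R_max && phi_R_max <= 1)) {
    stop("host_params: need 0 <= phi_R0 < phi_R_max <= 1")
  }
  if (gamma0 <= 0) stop("host_params: gamma0 must be > 0")
  if (rho_cell <= 0) stop("host_params: rho_cell must be > 0")
  structure(list(phi_R_max = phi_R_max, phi_R0 = phi_R0, gamma0 = gamma0,
                 rho_cell = rho_cell),
            class = "host_params")
}

#' @export
print.host_params <- function(x, ...) {
  cat("Host proteome-partition parameters\n")
  cat(sprintf("  phi_R_max = %g, phi_R0 = %g, gamma0 = %g 1/h, rho_cell = %g uM aa\n",
              x$phi_R_max, x$phi_R0, x$gamma0, x$rho_cell))
  invisible(x)
}

#' Culture environment
#'
#' @param nu Nutrient quality (1/h); summarizes medium richness and is
#'   calibrated with [calibrate_nu()] so that the antibiotic-free growth rate
#'   matches observation.
#' @param c_ext External chloramphenicol concentration (uM). The working
#'   concentration in this system is 10.5 uM (3.4 ug/mL).
#' @param light Illumination intensity in LED digital levels (arb. units,
#'   0--800).
#' @return An object of class `culture_env`.
#' @export
culture_env <- function(nu = 13.8, c_ext = 10.5, light = 0) {
  if (nu < 0) stop("culture_env: nu must be >= 0")
  if (c_ext < 0) stop("culture_env: c_ext must be >= 0")
  if (light < 0 || light > 800) {
    stop("culture_env: light must be within [0, 800] arb units")
  }
  structure(list(nu = nu, c_ext = c_ext, light = light), class = "culture_env")
}

#' Burden-dependent growth rate
#'
#' Growth-law prediction of the growth rate given the synthetic proteome
#' fraction occupied by circuit proteins, the nutrient quality and the
#' (possibly antibiotic-inhibited) translational capacity.
#'
#' @param phi_S Synthetic proteome fraction (dimensionless).
#' @param nu Nutrient quality (1/h).
#' @param gamma Translational capacity (1/h); use
#'   [effective_translation_capacity()] under chloramphenicol.
#' @param host A [host_params()] object.
#' @return Growth rate (1/h).
#' @details An infeasible burden (`phi_S > phi_R_max - phi_R0`, which would
#'   give negative growth) raises an error of class `optoculture_burden_error`
#'   rather than being clamped.
#' @export
growth_rate <- function(phi_S, nu, gamma, host = host_params()) {
  if (any(phi_S < 0)) stop("growth_rate: phi_S must be >= 0")
  if (any(nu < 0)) stop("growth_rate: nu must be >= 0")
  if (any(gamma <= 0)) stop("growth_rate: gamma must be > 0")
  room <- host$phi_R_max - host$phi_R0
  if (any(phi_S > room + 1e-12)) {
    stop(structure(class = c("optoculture_burden_error", "error", "condition"),
                   list(message = sprintf(
                     "infeasible gene-expression burden: phi_S = %g exceeds phi_R_max - phi_R0 = %g",
                     max(phi_S), room), call = sys.call())))
  }
  (room - pmin(phi_S, room)) * gamma * nu / (gamma + nu)
}

#' Translational capacity under chloramphenicol
#'
#' Reversible-inhibition reduction of the translational capacity by
#' intracellular chloramphenicol: `gamma = gamma0 / (1 + c_in / i50)`.
#'
#' @param gamma0 Uninhibited capacity (1/h).
#' @param c_in Intracellular chloramphenicol concentration (uM).
#' @param i50 Half-inhibition concentration (uM).
#' @return Effective translational capacity (1/h).
#' @export
effective_translation_capacity <- function(gamma0, c_in, i50) {
  if (any(gamma0 < 0) || any(c_in < 0)) {
    stop("effective_translation_capacity: arguments must be >= 0")
  }
  if (any(i50 <= 0)) stop("effective_translation_capacity: i50 must be > 0")
  gamma0 / (1 + c_in / i50)
}

#' Calibrate nutrient quality from a target growth rate
#'
#' Analytic inversion of the growth law: finds the `nu` at which a strain
#' carrying synthetic fraction `phi_S` grows at `lambda_target` with
#' uninhibited translation.
#'
#' @param lambda_target Target growth rate (1/h), observed without
#'   chloramphenicol.
#' @param phi_S Synthetic proteome fraction of the strain in that condition.
#' @param host A [host_params()] object.
#' @return Nutrient quality `nu` (1/h).
#' @export
calibrate_nu <- function(lambda_target, phi_S = 0, host = host_params()) {
  if (lambda_target < 0) stop("calibrate_nu: lambda_target must be >= 0")
  room <- host$phi_R_max - host$phi_R0 - phi_S
  lambda_asym <- room * host$gamma0
  if (lambda_target >= lambda_asym) {
    stop(sprintf(
      "calibrate_nu: lambda_target = %g is at or above the asymptotic maximum %g; no finite nu exists",
      lambda_target, lambda_asym))
  }
  lambda_target * host$gamma0 / (room * host$gamma0 - lambda_target)
}

#' Proteome sector composition at a given growth state
#'
#' @param phi_S Synthetic fraction.
#' @param lambda Growth rate (1/h), consistent with `phi_S` and `gamma` via
#'   [growth_rate()].
#' @param gamma Translational capacity (1/h).
#' @param host A [host_params()] object.
#' @return A `proteome_state` list with sectors `phi_R`, `phi_P`, `phi_Q`,
#'   `phi_S` summing to 1.
#' @details `phi_R = phi_R0 + lambda / gamma` (translation law);
#'   `phi_Q = 1 - phi_R_max` is fixed; the catabolic sector absorbs the rest,
#'   `phi_P = phi_R_max - phi_R - phi_S`.
#' @export
proteome_state <- function(phi_S, lambda, gamma, host = host_params()) {
  if (lambda < 0) stop("proteome_state: lambda must be >= 0")
  phi_R <- host$phi_R0 + lambda / gamma
  phi_Q <- 1 - host$phi_R_max
  phi_P <- host$phi_R_max - phi_R - phi_S
  sectors <- c(phi_R = phi_R, phi_P = phi_P, phi_Q = phi_Q, phi_S = phi_S)
  if (any(sectors < -1e-12)) {
    stop(sprintf("proteome_state: inconsistent arguments give negative sector (%s = %g)",
                 names(sectors)[which.min(sectors)], min(sectors)))
  }
  structure(as.list(pmax(sectors, 0)), class = "proteome_state")
}

#' Convert a chloramphenicol mass concentration to molarity
#'
#' @param ug_per_ml Mass concentration in ug/mL.
#' @param mw Molecular weight (g/mol); chloramphenicol is 323.13.
#' @return Concentration in uM. The working 3.4 ug/mL corresponds to 10.5 uM.
#' @export
chloramphenicol_uM <- function(ug_per_ml, mw = 323.13) {
  if (any(ug_per_ml < 0) || mw <= 0) stop("chloramphenicol_uM: invalid input")
  ug_per_ml / mw * 1000
}
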
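#' Photophilic-strain circuit parameters
#'
#' Parameters of the light-controlled growth circuit: split-T7 polymerase
#' halves (modeled as homodimerizing monomers `D`) form active dimers `A` in a
#' light-stimulated reaction; active dimers drive orthogonal (non-host)
#' transcription of chloramphenicol acetyltransferase (CAT, `C`), which
#' inactivates intracellular chloramphenicol `c_in` and thereby relieves
#' translation inhibition and speeds up growth.
#'
#' Concentrations are in uM; time in hours; light in arb units (0--800).
#'
#' @param beta_T7 Monomer production scale (uM/h at unit growth factors);
#'   host-transcribed, so effective production is `beta_T7 * lambda^2 / nu`.
#' @param ka_dark Basal (dark) dimerization rate (1/uM/h).
#' @param ka_light Light-stimulated dimerization gain (1/uM/h at saturation).
#' @param K_L Light half-saturation (arb units).
#' @param k_off Dimer dissociation rate (1/h); fast OFF kinetics.
#' @param beta_CAT CAT expression scale per active dimer (dimensionless gain;
#'   production is `beta_CAT * A * lambda`, orthogonal transcription so no
#'   `lambda/nu` factor).
#' @param n_T7 Monomer length (aa); an active dimer counts `2 * n_T7`.
#' @param n_CAT CAT--mCherry fusion length (aa).
#' @param k_perm Membrane permeation rate of chloramphenicol (1/h).
#' @param k_cat CAT turnover number (1/h).
#' @param K_M CAT Michaelis constant (uM).
#' @param i50 Half-inhibition of translation by intracellular
#'   chloramphenicol (uM). The default 6.5 uM places the calibrated dark
#'   state in the permeation-limited regime, which reproduces the measured
#'   transient asymmetry (upshift settles in about 2 h, downshift in about
#'   4 h, removal of CAT being dilution-limited); see the methods vignette.
#' @param fluor_scale mCherry readout, arb units per uM CAT.
#' @return An object of class `photophilic_params`.
#' @export
photophilic_params <- function(beta_T7 = 10, ka_dark = 6e-3, ka_light = 4e-2,
                               K_L = 200, k_off = 6, beta_CAT = 10,
                               n_T7 = 883, n_CAT = 450, k_perm = 20,
                               k_cat = 3.6e5, K_M = 12, i50 = 6.5,
                               fluor_scale = 1e5) {
  vals <- c(beta_T7 = beta_T7, ka_dark = ka_dark, ka_light = ka_light,
            K_L = K_L, k_off = k_off, beta_CAT = beta_CAT, n_T7 = n_T7,
            n_CAT = n_CAT, k_perm = k_perm, k_cat = k_cat, K_M = K_M,
            i50 = i50, fluor_scale = fluor_scale)
  if (any(vals < 0)) stop("photophilic_params: all parameters must be >= 0")
  if (K_L <= 0 || K_M <= 0 || i50 <= 0) {
    stop("photophilic_params: K_L, K_M and i50 must be > 0")
  }
  structure(as.list(vals), class = "photophilic_params")
}

#' Photophilic strain model
#'
#' Bundles circuit parameters, host constants and environment into the
#' simulation object used throughout the package.
#'
#' @param params A [photophilic_params()].
#' @param host A [host_params()].
#' @param env A [culture_env()]; `env$c_ext` is the working chloramphenicol
#'   concentration and `env$nu` the (calibratable) nutrient quality.
#' @return An object of class `photophilic_model`.
#' @seealso [calibrate_endpoints()], [dose_response()],
#'   [simulate_light_program()]
#' @export
photophilic_model <- function(params = photophilic_params(),
                              host = host_params(),
                              env = culture_env()) {
  stopifnot(inherits(params, "photophilic_params"),
            inherits(host, "host_params"), inherits(env, "culture_env"))
  structure(list(params = params, host = host, env = env),
            class = "photophilic_model")
}

#' @export
print.photophilic_model <- function(x, ...) {
  cat("Photophilic strain model (opto-T7 -> CAT -> chloramphenicol resistance)\n")
  cat(sprintf("  nu = %.4g 1/h, c_ext = %.4g uM\n", x$env$nu, x$env$c_ext))
  cat(sprintf("  ka_dark = %.4g, ka_light = %.4g 1/uM/h, K_L = %g au\n",
              x$params$ka_dark, x$params$ka_light, x$params$K_L))
  invisible(x)
}

#' Light-dependent dimerization rate
#'
#' Saturating (hyperbolic) dose dependence of the split-T7 association rate
#' on blue-light intensity: `ka(L) = ka_dark + ka_light * L / (K_L + L)`.
#'
#' @param L Light intensity (arb units, 0--800).
#' @param params A [photophilic_params()].
#' @return Association rate (1/uM/h).
#' @export
light_activation_rate <- function(L, params) {
  if (any(L < 0 | L > 800)) stop("light_activation_rate: L must be in [0, 800]")
  params$ka_dark + params$ka_light * L / (params$K_L + L)
}

# 12-vector passed to the compiled integrator (fixed order).
strain_param_vector <- function(params) {
  unlist(params[c("beta_T7", "ka_dark", "ka_light", "K_L", "k_off",
                  "beta_CAT", "n_T7", "n_CAT", "k_perm", "k_cat", "K_M",
                  "i50")])
}

host_param_vector <- function(host) {
  unlist(host[c("phi_R_max", "phi_R0", "gamma0", "rho_cell")])
}

#' Algebraic steady state of the photophilic strain
#'
#' Solves the equilibrium of the strain circuit at constant light by
#' one-dimensional root finding on the growth rate (all other species follow
#' in closed form), which is fast enough for calibration and dose-response
#' grids. Verified against long ODE integration in the test suite.
#'
#' @param model A [photophilic_model()].
#' @param light Light level (arb units); defaults to `model$env$light`.
#' @param c_ext Chloramphenicol (uM); defaults to `model$env$c_ext`.
#' @return List with `state` (named `D`, `A`, `C`, `c_in`, uM) and `lambda`
#'   (1/h).
#' @export
photophilic_steady_state <- function(model, light = NULL, c_ext = NULL) {
  p <- model$params; h <- model$host
  nu <- model$env$nu
  if (is.null(light)) light <- model$env$light
  if (is.null(c_ext)) c_ext <- model$env$c_ext
  ka <- light_activation_rate(light, p)
  room <- h$phi_R_max - h$phi_R0

  state_given_lambda <- function(lambda) {
    prod_D <- p$beta_T7 * lambda^2 / nu
    a <- 2 * ka * lambda / (p$k_off + lambda)
    D <- if (a < 1e-300) prod_D / lambda else
      (-lambda + sqrt(lambda^2 + 4 * a * prod_D)) / (2 * a)
    A <- ka * D^2 / (p$k_off + lambda)
    C <- p$beta_CAT * A
    # (k_perm + lambda) c^2 + ((k_perm + lambda) K_M + k_cat C - k_perm c_ext) c
    #   - k_perm c_ext K_M = 0
    aa <- p$k_perm + lambda
    bb <- aa * p$K_M + p$k_cat * C - p$k_perm * c_ext
    cc <- -p$k_perm * c_ext * p$K_M
    c_in <- if (c_ext == 0) 0 else (-bb + sqrt(bb^2 - 4 * aa * cc)) / (2 * aa)
    list(D = D, A = A, C = C, c_in = c_in)
  }
  resid <- function(lambda) {
    st <- state_given_lambda(lambda)
    phi_S <- (p$n_T7 * (st$D + 2 * st$A) + p$n_CAT * st$C) / h$rho_cell
    if (phi_S >= room) return(-lambda)  # infeasible: push root downwards
    gamma <- h$gamma0 / (1 + st$c_in / p$i50)
    (room - phi_S) * gamma * nu / (gamma + nu) - lambda
  }
  hi <- room * h$gamma0 * nu / (h$gamma0 + nu)
  r <- stats::uniroot(resid, lower = 1e-9, upper = hi, tol = 1e-13)
  lambda <- r$root
  st <- state_given_lambda(lambda)
  list(state = c(D = st$D, A = st$A, C = st$C, c_in = st$c_in),
       lambda = lambda)
}

#' Generic host-aware representation of the photophilic circuit
#'
#' Expresses the strain model as a [circuit_model()] so that the generic
#' pure-R machinery ([assemble_system()], [integrate_circuit()],
#' [steady_state()]) can integrate it. Serves as the slow, independent route
#' against which the compiled fast path is checked.
#'
#' @param model A [photophilic_model()].
#' @return A [circuit_model()].
#' @export
build_photophilic_model <- function(model) {
  p <- model$params
  ka_of <- function(env) light_activation_rate(env$light, p)
  circuit_model(
    proteins = list(
      protein_species("D", p$n_T7, function(st, lambda, env) {
        p$beta_T7 * lambda^2 / env$nu -
          2 * ka_of(env) * st$X[["D"]]^2 + 2 * p$k_off * st$X[["A"]]
      }),
      protein_species("A", 2 * p$n_T7, function(st, lambda, env) {
        ka_of(env) * st$X[["D"]]^2 - p$k_off * st$X[["A"]]
      }),
      protein_species("C", p$n_CAT, function(st, lambda, env) {
        p$beta_CAT * st$X[["A"]] * lambda
      })
    ),
    aux = list(
      aux_species("c_in", function(st, lambda, env) {
        c_in <- st$aux[["c_in"]]
        p$k_perm * (env$c_ext - c_in) -
          p$k_cat * st$X[["C"]] * c_in / (p$K_M + c_in) - lambda * c_in
      })
    ),
    gamma_fn = function(st, env, host) {
      host$gamma0 / (1 + st$aux[["c_in"]] / p$i50)
    }
  )
}

# Run the compiled integrator over the segments of a light program.
# init: length-4 strain state (or 5 with phi). Returns list(times, y, lambda,
# light, y_end, lambda_end).
strain_integrate <- function(model, init, segments, t_out,
                             with_phi = FALSE, lambda_c = 0,
                             rtol = 1e-7, atol = 1e-10) {
  res <- cpp_simulate_strain(
    as.numeric(init), segments$start, segments$end, segments$light,
    as.numeric(t_out), strain_param_vector(model$params),
    host_param_vector(model$host), model$env$nu, model$env$c_ext,
    lambda_c, with_phi, rtol, atol)
  if (!isTRUE(res$ok)) {
    stop(sprintf("strain integration failed in the interval starting at t = %g h",
                 res$fail_t))
  }
  res
}

#' Simulate the photophilic strain under a light program
#'
#' @param model A [photophilic_model()].
#' @param program A [light_program()] (must start at or before 0).
#' @param t_end End time (h).
#' @param init Initial strain state `c(D, A, C, c_in)` in uM, or `NULL` to
#'   start from the steady state under `init_light`.
#' @param init_light Pre-culture light level used when `init` is `NULL`;
#'   defaults to the first level of `program`.
#' @param dt_out Output resolution (h).
#' @param rtol,atol Solver tolerances.
#' @return A data.frame: `time_h`, `D`, `A`, `C`, `c_in`, `lambda_h_1`,
#'   `fluor_au` (`fluor_scale * C`), `light_au`.
#' @export
simulate_light_program <- function(model, program, t_end, init = NULL,
                                   init_light = NULL, dt_out = 0.02,
                                   rtol = 1e-7, atol = 1e-10) {
  stopifnot(inherits(program, "light_program"), t_end > 0)
  if (program$times[1] > 0) stop("simulate_light_program: program must cover t = 0")
  if (is.null(init)) {
    if (is.null(init_light)) init_light <- program$levels[1]
    init <- photophilic_steady_state(model, light = init_light)$state
  }
  segs <- program_segments(program, 0, t_end)
  t_out <- unique(c(seq(0, t_end, by = dt_out), t_end))
  res <- strain_integrate(model, init, segs, t_out, rtol = rtol, atol = atol)
  df <- data.frame(time_h = t_out, res$y)
  names(df)[-1] <- c("D", "A", "C", "c_in")
  df$lambda_h_1 <- res$lambda
  df$fluor_au <- model$params$fluor_scale * df$C
  df$light_au <- light_at(program, t_out)
  df
}

#' Steady-state dose response of growth rate to light
#'
#' @param model A [photophilic_model()].
#' @param L_grid Light intensities (arb units, within 0--800).
#' @return Data.frame with `light_au` and `lambda_h_1`.
#' @export
dose_response <- function(model, L_grid = seq(0, 800, by = 50)) {
  if (any(L_grid < 0 | L_grid > 800)) stop("dose_response: grid must be in [0, 800]")
  lam <- vapply(L_grid, function(L) photophilic_steady_state(model, light = L)$lambda,
                0)
  data.frame(light_au = L_grid, lambda_h_1 = lam)
}

#' Calibrate the strain model to dose-response endpoints
#'
#' Anchors the model to the three growth rates that summarize the measured
#' dose response at the working chloramphenicol concentration: the dark rate
#' `lambda_dark` (about 1.0 1/h), the maximally illuminated rate `lambda_max`
#' (about 1.9 1/h), and the antibiotic-free rate `lambda_no_ab` (default
#' 2.0 1/h). Nutrient quality `nu` is set from `lambda_no_ab` via
#' [calibrate_nu()] (iterated to self-consistency with the strain's own
#' burden), then `ka_dark` and `ka_light` are found by nested 1-D root
#' finding on the algebraic steady state.
#'
#' @param model A [photophilic_model()] providing starting parameters.
#' @param targets Named vector `c(lambda_dark, lambda_max, lambda_no_ab)`
#'   (1/h), strictly increasing.
#' @param tol Relative tolerance on each endpoint (contract: 1e-2; the
#'   implementation achieves much better).
#' @return A calibrated `photophilic_model` (updated `ka_dark`, `ka_light`
#'   and `env$nu`).
#' @export
calibrate_endpoints <- function(model,
                                targets = c(lambda_dark = 1.0,
                                            lambda_max = 1.9,
                                            lambda_no_ab = 2.0),
                                tol = 1e-2) {
  stopifnot(all(c("lambda_dark", "lambda_max", "lambda_no_ab") %in% names(targets)))
  ld <- targets[["lambda_dark"]]; lm <- targets[["lambda_max"]]
  ln <- targets[["lambda_no_ab"]]
  if (!(ld < lm && lm < ln)) {
    stop("calibrate_endpoints: need lambda_dark < lambda_max < lambda_no_ab")
  }
  m <- model
  resid3 <- function(m) {
    c(photophilic_steady_state(m, light = 0)$lambda / ld - 1,
      photophilic_steady_state(m, light = 800)$lambda / lm - 1,
      photophilic_steady_state(m, light = 0, c_ext = 0)$lambda / ln - 1)
  }
  root_log <- function(fn, lo, hi, target_name) {
    flo <- fn(lo); fhi <- fn(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
      stop(sprintf("calibrate_endpoints: cannot bracket target '%s' (f(%g) = %g, f(%g) = %g)",
                   target_name, lo, flo, hi, fhi))
    }
    stats::uniroot(fn, lower = lo, upper = hi, tol = 1e-12)$root
  }
  for (outer in 1:25) {
    # 1) nutrient quality from the antibiotic-free growth rate, iterating the
    #    burden to self-consistency
    for (i in 1:40) {
      ss0 <- photophilic_steady_state(m, light = 0, c_ext = 0)
      phi_S <- (m$params$n_T7 * (ss0$state[["D"]] + 2 * ss0$state[["A"]]) +
                  m$params$n_CAT * ss0$state[["C"]]) / m$host$rho_cell
      nu_new <- calibrate_nu(ln, phi_S, m$host)
      done <- abs(nu_new / m$env$nu - 1) < 1e-12
      m$env$nu <- nu_new
      if (done) break
    }
    # 2) dark endpoint via basal dimerization
    fd <- function(x) {
      mm <- m; mm$params$ka_dark <- 10^x
      photophilic_steady_state(mm, light = 0)$lambda - ld
    }
    m$params$ka_dark <- 10^root_log(fd, -9, 3, "lambda_dark")
    # 3) bright endpoint via light-stimulated dimerization
    fl <- function(x) {
      mm <- m; mm$params$ka_light <- 10^x
      photophilic_steady_state(mm, light = 800)$lambda - lm
    }
    m$params$ka_light <- 10^root_log(fl, -9, 4, "lambda_max")
    if (max(abs(resid3(m))) < min(tol, 1e-8)) break
  }
  r <- resid3(m)
  if (max(abs(r)) > tol) {
    stop(sprintf("calibrate_endpoints: did not reach targets (relative residuals %s)",
                 paste(sprintf("%.2e", r), collapse = ", ")))
  }
  m
}

#' 5-percent settling time of a growth-rate trajectory
#'
#' Earliest time after which the growth rate enters and remains within a
#' relative band around its final steady-state value.
#'
#' @param time_h,lambda Trajectory samples.
#' @param lambda_final Final steady-state growth rate (1/h).
#' @param frac Relative band half-width (default 0.05).
#' @return Settling time (h); `NA` if never settled.
#' @export
settling_time <- function(time_h, lambda, lambda_final, frac = 0.05) {
  inside <- abs(lambda - lambda_final) <= frac * lambda_final
  if (!inside[length(inside)]) return(NA_real_)
  last_out <- max(c(0, which(!inside)))
  if (last_out == length(inside)) return(NA_real_)
  time_h[last_out + 1L]
}
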
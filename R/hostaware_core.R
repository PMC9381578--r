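#' Gene specification for a host-aware circuit
#'
#' A gene contributes an mRNA/protein pair with dynamics
#' \deqn{dm_i/dt = \omega_i T_i(\cdot)\,(\lambda/\nu) + F_i(\cdot) - \delta_i m_i}
#' \deqn{dX_i/dt = \alpha_i m_i \lambda + G_i(\cdot) - \lambda X_i}
#' The `lambda/nu` transcription factor and the `lambda` translation factor
#' couple expression to the availability of host machinery; growth-mediated
#' dilution is deliberately absent from the mRNA equation (active degradation
#' dominates). Genes transcribed by an orthogonal polymerase (e.g. T7) set
#' `host_transcription = FALSE`, which drops the `lambda/nu` factor.
#'
#' @param name Unique gene name.
#' @param omega Transcription rate constant.
#' @param alpha Translation rate constant.
#' @param delta mRNA degradation rate (1/h), must be > 0.
#' @param n_aa Protein length in amino acids (>= 1).
#' @param transcription_regulation Optional `function(state, lambda, env)`
#'   returning a dimensionless factor multiplying `omega` (default 1:
#'   constitutive). `state` is a list with named vectors `m`, `X`, `aux`.
#' @param post_transcriptional Optional `function(state, lambda, env)` added
#'   to the mRNA rate.
#' @param post_translational Optional `function(state, lambda, env)` added to
#'   the protein rate.
#' @param host_transcription Does transcription use host machinery?
#' @return A `gene_spec` object.
#' @export
gene_spec <- function(name, omega, alpha, delta, n_aa,
                      transcription_regulation = NULL,
                      post_transcriptional = NULL,
                      post_translational = NULL,
                      host_transcription = TRUE) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (omega < 0 || alpha < 0) stop("gene_spec: omega and alpha must be >= 0")
  if (delta <= 0) stop("gene_spec: delta must be > 0 when an mRNA species is modeled")
  if (n_aa < 1) stop("gene_spec: n_aa must be >= 1")
  structure(list(name = name, omega = omega, alpha = alpha, delta = delta,
                 n_aa = n_aa,
                 transcription_regulation = transcription_regulation,
                 post_transcriptional = post_transcriptional,
                 post_translational = post_translational,
                 host_transcription = isTRUE(host_transcription)),
            class = "gene_spec")
}

#' Lumped protein-level species
#'
#' For circuits modeled at the protein level (mRNA at quasi-steady state) a
#' species carries a custom net production contract; growth dilution
#' `-lambda * X` is applied automatically and the species contributes
#' `n_aa * X / rho_cell` to the synthetic proteome fraction.
#'
#' @param name Unique species name.
#' @param n_aa Amino-acid count attributed to one unit of the species (for a
#'   homodimer, twice the monomer length).
#' @param rate `function(state, lambda, env)` returning the net
#'   non-dilution rate.
#' @return A `protein_species` object.
#' @export
protein_species <- function(name, n_aa, rate) {
  stopifnot(is.character(name), nzchar(name), is.function(rate), n_aa >= 0)
  structure(list(name = name, n_aa = n_aa, rate = rate),
            class = "protein_species")
}

#' Auxiliary (non-protein) state
#'
#' Auxiliary states (e.g. intracellular antibiotic) evolve by their own rate
#' contract, receive no automatic dilution, and do not count towards the
#' synthetic fraction.
#'
#' @param name Unique state name.
#' @param rate `function(state, lambda, env)` returning the full rate.
#' @return An `aux_species` object.
#' @export
aux_species <- function(name, rate) {
  stopifnot(is.character(name), nzchar(name), is.function(rate))
  structure(list(name = name, rate = rate), class = "aux_species")
}

#' Host-aware circuit model
#'
#' @param genes List of [gene_spec()] objects.
#' @param proteins List of [protein_species()] objects.
#' @param aux List of [aux_species()] objects.
#' @param gamma_fn Optional `function(state, env, host)` returning the
#'   effective translational capacity (1/h); defaults to the uninhibited
#'   `host$gamma0`. Used to couple e.g. intracellular chloramphenicol to
#'   translation.
#' @return A `circuit_model` object.
#' @export
circuit_model <- function(genes = list(), proteins = list(), aux = list(),
                          gamma_fn = NULL) {
  nm <- c(vapply(genes, `[[`, "", "name"),
          vapply(proteins, `[[`, "", "name"),
          vapply(aux, `[[`, "", "name"))
  if (anyDuplicated(nm)) stop("circuit_model: species names must be unique")
  structure(list(genes = genes, proteins = proteins, aux = aux,
                 gamma_fn = gamma_fn),
            class = "circuit_model")
}

#' Synthetic proteome fraction
#'
#' Converts circuit protein concentrations to the proteome fraction they
#' occupy: `Phi_S = sum(n_aa * X) / rho_cell`.
#'
#' @param X Protein concentrations (uM), non-negative.
#' @param n_aa Matching amino-acid counts.
#' @param rho_cell Cellular amino-acid density (uM aa).
#' @param host Optional [host_params()]; if given, a fraction exceeding
#'   `phi_R_max - phi_R0` raises the infeasible-burden condition.
#' @return Dimensionless fraction.
#' @export
synthetic_fraction <- function(X, n_aa, rho_cell, host = NULL) {
  if (length(X) != length(n_aa)) stop("synthetic_fraction: length mismatch")
  if (any(X < 0)) stop("synthetic_fraction: X must be >= 0 elementwise")
  phi_S <- sum(n_aa * X) / rho_cell
  if (!is.null(host) && phi_S > host$phi_R_max - host$phi_R0) {
    stop(structure(class = c("optoculture_burden_error", "error", "condition"),
                   list(message = sprintf(
                     "infeasible burden: Phi_S = %g exceeds phi_R_max - phi_R0 = %g",
                     phi_S, host$phi_R_max - host$phi_R0), call = sys.call())))
  }
  phi_S
}

#' Assemble the coupled host-circuit ODE system
#'
#' Embeds a circuit into the host context: the growth rate is recomputed
#' algebraically at every derivative evaluation from the current synthetic
#' fraction (quasi-steady growth adaptation), and feeds back on transcription,
#' translation and dilution.
#'
#' @param circuit A [circuit_model()].
#' @param host A [host_params()].
#' @param env A [culture_env()]; `env$light` is the default illumination and
#'   can be overridden per integration segment.
#' @param frozen_lambda If non-`NULL`, the growth rate is frozen at this value
#'   (1/h), reducing the system to a conventional constant-dilution model.
#' @return A `hostaware_system` list with elements `state_names`,
#'   `rhs_factory(light)` (returns `f(t, y)`), `lambda_of(y)`, `init`
#'   (zero state), and the inputs.
#' @export
assemble_system <- function(circuit, host, env, frozen_lambda = NULL) {
  stopifnot(inherits(circuit, "circuit_model"), inherits(host, "host_params"),
            inherits(env, "culture_env"))
  genes <- circuit$genes
  u <- length(genes)
  gene_names <- vapply(genes, `[[`, "", "name")
  prot_names <- vapply(circuit$proteins, `[[`, "", "name")
  aux_names <- vapply(circuit$aux, `[[`, "", "name")
  state_names <- c(if (u) paste0("m_", gene_names), gene_names,
                   prot_names, aux_names)
  n_aa_all <- c(vapply(genes, `[[`, 0, "n_aa"),
                vapply(circuit$proteins, `[[`, 0, "n_aa"))
  idx_m <- seq_len(u)
  idx_X <- u + seq_len(u)
  idx_P <- 2 * u + seq_along(prot_names)
  idx_aux <- 2 * u + length(prot_names) + seq_along(aux_names)
  idx_prot_all <- c(idx_X, idx_P)
  gamma_fn <- circuit$gamma_fn
  room <- host$phi_R_max - host$phi_R0

  unpack <- function(y) {
    list(m = stats::setNames(y[idx_m], gene_names),
         X = stats::setNames(c(y[idx_X], y[idx_P]), c(gene_names, prot_names)),
         aux = stats::setNames(y[idx_aux], aux_names))
  }
  lambda_of <- function(y, env_now = env) {
    if (!is.null(frozen_lambda)) return(frozen_lambda)
    st <- unpack(y)
    phi_S <- sum(n_aa_all * pmax(y[idx_prot_all], 0)) / host$rho_cell
    if (phi_S > room) {
      stop(structure(class = c("optoculture_burden_error", "error", "condition"),
                     list(message = sprintf(
                       "infeasible burden during integration: Phi_S = %g (state: %s)",
                       phi_S, paste(sprintf("%s=%.3g", state_names, y), collapse = ", ")),
                       call = NULL)))
    }
    gamma <- if (is.null(gamma_fn)) host$gamma0 else gamma_fn(st, env_now, host)
    (room - phi_S) * gamma * env_now$nu / (gamma + env_now$nu)
  }

  rhs_factory <- function(light = env$light) {
    env_now <- env
    env_now$light <- light
    function(t, y) {
      y <- pmax(y, 0)
      st <- unpack(y)
      lambda <- lambda_of(y, env_now)
      dy <- numeric(length(y))
      for (i in seq_len(u)) {
        g <- genes[[i]]
        Tfac <- if (is.null(g$transcription_regulation)) 1
                else g$transcription_regulation(st, lambda, env_now)
        Ffac <- if (is.null(g$post_transcriptional)) 0
                else g$post_transcriptional(st, lambda, env_now)
        Gfac <- if (is.null(g$post_translational)) 0
                else g$post_translational(st, lambda, env_now)
        mach <- if (g$host_transcription) lambda / env_now$nu else 1
        dy[idx_m[i]] <- g$omega * Tfac * mach + Ffac - g$delta * y[idx_m[i]]
        dy[idx_X[i]] <- g$alpha * y[idx_m[i]] * lambda + Gfac - lambda * y[idx_X[i]]
      }
      for (j in seq_along(circuit$proteins)) {
        p <- circuit$proteins[[j]]
        dy[idx_P[j]] <- p$rate(st, lambda, env_now) - lambda * y[idx_P[j]]
      }
      for (k in seq_along(circuit$aux)) {
        dy[idx_aux[k]] <- circuit$aux[[k]]$rate(st, lambda, env_now)
      }
      dy
    }
  }

  structure(list(state_names = state_names, rhs_factory = rhs_factory,
                 lambda_of = lambda_of, unpack = unpack,
                 init = stats::setNames(numeric(length(state_names)), state_names),
                 circuit = circuit, host = host, env = env,
                 frozen_lambda = frozen_lambda),
            class = "hostaware_system")
}

#' Integrate a host-aware system under a light program
#'
#' Integration is restarted at every light-program discontinuity (accurate
#' step inputs rather than stiff stepping across jumps).
#'
#' @param system A `hostaware_system` from [assemble_system()].
#' @param init Named initial state (defaults to `system$init`).
#' @param t_span Length-2 increasing time interval (h).
#' @param program Optional [light_program()]; default holds `env$light`.
#' @param dt_out Output resolution (h).
#' @param rtol,atol Solver tolerances.
#' @return A data.frame: `time_h`, one column per state, `lambda_h_1`,
#'   `light_au`.
#' @export
integrate_circuit <- function(system, init = NULL, t_span, program = NULL,
                              dt_out = 0.02, rtol = 1e-7, atol = 1e-10) {
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1])
  y <- if (is.null(init)) system$init else init
  if (length(y) != length(system$state_names)) {
    stop("integrate_circuit: initial state has wrong length")
  }
  if (is.null(program)) {
    program <- light_program(t_span[1], system$env$light)
  }
  segs <- program_segments(program, t_span[1], t_span[2])
  pieces <- vector("list", nrow(segs))
  for (s in seq_len(nrow(segs))) {
    tt <- unique(c(seq(segs$start[s], segs$end[s], by = dt_out), segs$end[s]))
    f <- system$rhs_factory(segs$light[s])
    sol <- ode_rk45(f, y, tt, rtol = rtol, atol = atol,
                    nonneg = seq_along(y))
    env_now <- system$env
    env_now$light <- segs$light[s]
    lam <- apply(sol, 1, system$lambda_of, env_now = env_now)
    df <- data.frame(time_h = tt, sol, check.names = FALSE)
    names(df)[-1] <- system$state_names
    df$lambda_h_1 <- lam
    df$light_au <- segs$light[s]
    y <- stats::setNames(sol[nrow(sol), ], system$state_names)
    # drop duplicated boundary row except in last segment
    pieces[[s]] <- if (s < nrow(segs)) df[-nrow(df), ] else df
  }
  do.call(rbind, pieces)
}

#' Steady state of a host-aware system at constant environment
#'
#' Long integration with equilibrium detection, followed by a damped-Newton
#' polish (numerical Jacobian) seeded at the integration endpoint.
#'
#' @param system A `hostaware_system`.
#' @param init Optional initial state; defaults to `system$init`.
#' @param light Constant light level (defaults to `env$light`).
#' @param tol Max-norm tolerance on the derivative at the returned state.
#' @param t_cap Time cap (h) for the integration phase.
#' @return Named state vector with attributes `lambda` and `deriv_norm`.
#' @export
steady_state <- function(system, init = NULL, light = NULL, tol = 1e-8,
                         t_cap = 2000) {
  if (is.null(light)) light <- system$env$light
  f <- system$rhs_factory(light)
  y <- if (is.null(init)) system$init else init
  t <- 0
  chunk <- 25
  repeat {
    d <- f(t, y)
    if (max(abs(d)) < tol) break
    if (t >= t_cap) {
      y2 <- newton_polish(f, y, tol)
      if (is.null(y2)) {
        stop(sprintf("steady_state: no convergence within t = %g h (deriv norm %g); last state: %s",
                     t_cap, max(abs(d)),
                     paste(sprintf("%.4g", y), collapse = ", ")))
      }
      y <- y2
      break
    }
    sol <- ode_rk45(f, y, c(t, t + chunk), rtol = 1e-9, atol = 1e-12,
                    nonneg = seq_along(y))
    y <- sol[2, ]
    t <- t + chunk
    if (t > 100) {  # speed convergence once close
      y2 <- newton_polish(f, y, tol)
      if (!is.null(y2)) { y <- y2; break }
    }
  }
  env_now <- system$env
  env_now$light <- light
  structure(stats::setNames(y, system$state_names),
            lambda = system$lambda_of(y, env_now),
            deriv_norm = max(abs(f(0, y))))
}

# Damped Newton on f(., y) = 0 with forward-difference Jacobian.
# Returns NULL on failure.
newton_polish <- function(f, y, tol, max_iter = 30) {
  n <- length(y)
  for (it in seq_len(max_iter)) {
    d <- tryCatch(f(0, y), error = function(e) NULL)
    if (is.null(d) || any(!is.finite(d))) return(NULL)
    if (max(abs(d)) < tol) return(pmax(y, 0))
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(1e-8, 1e-7 * abs(y[j]))
      yp <- y; yp[j] <- yp[j] + h
      dp <- tryCatch(f(0, yp), error = function(e) NULL)
      if (is.null(dp)) return(NULL)
      J[, j] <- (dp - d) / h
    }
    step <- tryCatch(solve(J, -d), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    alpha <- 1
    repeat {
      y_new <- pmax(y + alpha * step, 0)
      d_new <- tryCatch(f(0, y_new), error = function(e) NULL)
      if (!is.null(d_new) && all(is.finite(d_new)) &&
          max(abs(d_new)) < max(abs(d))) break
      alpha <- alpha / 2
      if (alpha < 1e-6) return(NULL)
    }
    y <- y_new
  }
  NULL
}
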
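#' Configuration of the computational gain screen
#'
#' @param ranges Named list of length-2 log-uniform sampling bounds for
#'   `kp`, `ki`, `kd`. Defaults bracket the adopted optimum by roughly 1.5
#'   decades each way: `kp` in `[1e2, 1e5]`, `ki` in `[1e-1, 1e2]`, `kd` in
#'   `[1e3, 1e6]`. `kbc` is tied to `0.01 * ki`.
#' @param n_samples Number of gain sets to draw (default 200).
#' @param seed Random seed.
#' @param setpoints Reference targets; default `c(0.3, 0.7)`.
#' @param horizon Closed-loop horizon per simulation (h).
#' @param score_window Time window (h) of the deviation integral; default the
#'   whole horizon (the reference trajectory is the setpoint itself from
#'   `t = 0`, so the score jointly penalizes transient duration, overshoot
#'   and residual oscillation).
#' @return A `screen_config` object.
#' @export
screen_config <- function(ranges = list(kp = c(1e2, 1e5),
                                        ki = c(1e-1, 1e2),
                                        kd = c(1e3, 1e6)),
                          n_samples = 200, seed = 1,
                          setpoints = c(0.3, 0.7), horizon = 16,
                          score_window = NULL) {
  stopifnot(all(c("kp", "ki", "kd") %in% names(ranges)))
  for (nm in c("kp", "ki", "kd")) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] >= r[2]) {
      stop(sprintf("screen_config: ranges$%s must be positive and ordered", nm))
    }
  }
  if (n_samples < 1) stop("screen_config: n_samples must be >= 1")
  if (is.null(score_window)) score_window <- c(0, horizon)
  structure(list(ranges = ranges, n_samples = as.integer(n_samples),
                 seed = seed, setpoints = setpoints, horizon = horizon,
                 score_window = score_window),
            class = "screen_config")
}

#' Draw random PID gain sets
#'
#' Log-uniform sampling within the configured ranges, reproducible for a
#' fixed seed; `kbc = 0.01 * ki` throughout.
#'
#' @param config A [screen_config()].
#' @return Data.frame with columns `kp`, `ki`, `kd`, `kbc`.
#' @export
sample_gains <- function(config) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(config$seed)
  draw <- function(r) exp(stats::runif(config$n_samples, log(r[1]), log(r[2])))
  out <- data.frame(kp = draw(config$ranges$kp), ki = draw(config$ranges$ki),
                    kd = draw(config$ranges$kd))
  out$kbc <- 0.01 * out$ki
  out
}

#' Score a closed-loop trajectory against a setpoint trajectory
#'
#' Trapezoidal integral of the absolute tracking deviation over the scoring
#' window; zero iff tracking is perfect there. Non-finite trajectories
#' (diverged or failed simulations) score `Inf`.
#'
#' @param time_h Common time grid of both trajectories.
#' @param phi Simulated composition.
#' @param phi_set Target composition on the same grid.
#' @param window Length-2 time window (h).
#' @return Non-negative score (fraction x h).
#' @export
score_trajectory <- function(time_h, phi, phi_set, window) {
  if (length(phi) != length(time_h) || length(phi_set) != length(time_h)) {
    stop("score_trajectory: trajectories must share one time grid")
  }
  if (any(!is.finite(phi))) return(Inf)
  keep <- time_h >= window[1] & time_h <= window[2]
  if (sum(keep) < 2) stop("score_trajectory: window contains fewer than 2 points")
  trapz(time_h[keep], abs(phi[keep] - phi_set[keep]))
}

#' Run the computational gain screen
#'
#' Simulates the closed loop (exact measurement) for every sampled gain set
#' and every reference setpoint, scores each trajectory with
#' [score_trajectory()], and ranks gain sets by total score. Individual
#' simulation failures score `Inf` and never abort the screen.
#'
#' @param config A [screen_config()].
#' @param model A calibrated [photophilic_model()].
#' @param lambda_c Constitutive growth rate (1/h).
#' @param phi0 Initial fraction for the reference simulations.
#' @param extra_gains Optional data.frame of gain sets (columns `kp`, `ki`,
#'   `kd`, `kbc`) appended to the random sample, e.g. to rank a candidate.
#' @param dt_sample Sampling period (h).
#' @return Data.frame, ascending in `total`: the gains, one `score_<target>`
#'   column per setpoint, `total`, and `rank`; attributes `config` and
#'   `seed` record the provenance.
#' @export
run_screen <- function(config, model, lambda_c = 1.5, phi0 = 0.5,
                       extra_gains = NULL, dt_sample = 0.5) {
  gains_tab <- sample_gains(config)
  gains_tab$sampled <- TRUE
  if (!is.null(extra_gains)) {
    extra_gains <- extra_gains[, c("kp", "ki", "kd", "kbc")]
    extra_gains$sampled <- FALSE
    gains_tab <- rbind(gains_tab, extra_gains)
  }
  score_cols <- paste0("score_", config$setpoints)
  for (sc in score_cols) gains_tab[[sc]] <- NA_real_
  for (i in seq_len(nrow(gains_tab))) {
    g <- pid_gains(kp = gains_tab$kp[i], ki = gains_tab$ki[i],
                   kd = gains_tab$kd[i], kbc = gains_tab$kbc[i])
    for (j in seq_along(config$setpoints)) {
      sp <- config$setpoints[j]
      res <- tryCatch(
        run_closed_loop(model, lambda_c = lambda_c, phi0 = phi0, gains = g,
                        setpoints = sp, dt_sample = dt_sample,
                        t_end = config$horizon, measurement = "exact",
                        dt_out = 0.1),
        error = function(e) NULL)
      gains_tab[i, score_cols[j]] <- if (is.null(res)) Inf else
        score_trajectory(res$trajectory$time_h, res$trajectory$phi_p,
                         rep(sp, nrow(res$trajectory)), config$score_window)
    }
  }
  gains_tab$total <- rowSums(as.matrix(gains_tab[, score_cols, drop = FALSE]))
  gains_tab <- gains_tab[order(gains_tab$total), ]
  gains_tab$rank <- seq_len(nrow(gains_tab))
  rownames(gains_tab) <- NULL
  structure(gains_tab, config = config, seed = config$seed)
}
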
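#' Default experiment configuration
#'
#' Nested configuration covering every tunable of the package, with all
#' defaults embedded. Sections: `host`, `environment`, `strain`, `coculture`,
#' `controller`, `screen`, `evotron`, `run`.
#'
#' @return A named nested list of class `experiment_config`.
#' @export
default_config <- function() {
  structure(list(
    host = unclass(host_params()),
    environment = unclass(culture_env()),
    strain = unclass(photophilic_params()),
    coculture = list(lambda_c = 1.5, phi0 = 0.5),
    controller = c(unclass(pid_gains()),
                   list(dt_sample = 0.5, u_min = 0, u_max = 800)),
    screen = list(kp_range = c(1e2, 1e5), ki_range = c(1e-1, 1e2),
                  kd_range = c(1e3, 1e6), n_samples = 200,
                  setpoints = c(0.3, 0.7), horizon = 16),
    evotron = c(unclass(turbidostat_config()),
                list(n_events = 10000, gate_threshold = 6500)),
    run = list(mode = "closed-loop", t_end = 30, seed = 1, out = "out.tsv")
  ), class = "experiment_config")
}

#' Load and validate an experiment configuration
#'
#' Reads a JSON configuration file, rejects unknown keys (with their full
#' paths), merges the given values over the embedded defaults, and
#' range-checks the result through the same constructors used by the
#' simulation code. An empty file or empty object yields all defaults.
#'
#' @param path Path to a JSON file.
#' @return A validated `experiment_config`.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.list(user)) stop("load_config: top level must be an object")
  cfg <- default_config()
  merge_section <- function(base, given, prefix) {
    if (is.null(given)) return(base)
    if (!is.list(given)) stop(sprintf("load_config: section '%s' must be an object", prefix))
    unknown <- setdiff(names(given), names(base))
    if (length(unknown)) {
      stop(sprintf("load_config: unknown key(s): %s",
                   paste0(prefix, ".", unknown, collapse = ", ")))
    }
    for (nm in names(given)) base[[nm]] <- given[[nm]]
    base
  }
  unknown_sections <- setdiff(names(user), names(cfg))
  if (length(unknown_sections)) {
    stop("load_config: unknown section(s): ",
         paste(unknown_sections, collapse = ", "))
  }
  for (sec in names(user)) {
    cfg[[sec]] <- merge_section(cfg[[sec]], user[[sec]], sec)
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  do.call(host_params, cfg$host)
  tryCatch(do.call(culture_env, cfg$environment),
           error = function(e) stop("environment: ", conditionMessage(e),
                                    call. = FALSE))
  do.call(photophilic_params, cfg$strain)
  with(cfg$coculture, {
    if (lambda_c <= 0) stop("coculture.lambda_c must be > 0")
    if (phi0 < 0 || phi0 > 1) stop("coculture.phi0 must be in [0, 1]")
  })
  pid_gains(cfg$controller$kp, cfg$controller$ki, cfg$controller$kd,
            cfg$controller$kbc)
  if (cfg$controller$dt_sample <= 0) stop("controller.dt_sample must be > 0")
  turbidostat_config(cfg$evotron$od_low, cfg$evotron$od_high,
                     cfg$evotron$od_noise_sd, cfg$evotron$read_interval)
  invisible(cfg)
}

#' Materialize model objects from a configuration
#' @param cfg An `experiment_config`.
#' @return A [photophilic_model()] built from the config's host, environment
#'   and strain sections.
#' @export
config_model <- function(cfg) {
  photophilic_model(do.call(photophilic_params, cfg$strain),
                    do.call(host_params, cfg$host),
                    do.call(culture_env, cfg$environment))
}

#' Serialize a configuration to JSON
#' @param cfg An `experiment_config`.
#' @param path Output path; if `NULL`, the JSON text is returned.
#' @export
dump_config <- function(cfg, path = NULL) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Write a trajectory table
#'
#' Tab-delimited text with a header; the first column must be `time_h` and
#' strictly increasing. [read_timeseries()] is its exact inverse (round trip
#' to full double precision, locale-independent).
#'
#' @param trajectory Data.frame whose first column is `time_h`.
#' @param path Output path.
#' @export
write_timeseries <- function(trajectory, path) {
  stopifnot(is.data.frame(trajectory))
  if (names(trajectory)[1] != "time_h") {
    stop("write_timeseries: first column must be time_h")
  }
  if (nrow(trajectory) > 1 && is.unsorted(trajectory$time_h, strictly = TRUE)) {
    stop("write_timeseries: time_h must be strictly increasing")
  }
  out <- trajectory
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @return `read_timeseries()` returns the trajectory data.frame.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 1 || names(df)[1] != "time_h") {
    stop("read_timeseries: malformed header (first column must be time_h)")
  }
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num) || all(is.na(num) == (df[[j]] %in% c("NA", "")))) {
      df[[j]] <- num
    }
  }
  if (nrow(df) > 1 && is.unsorted(df$time_h, strictly = TRUE)) {
    stop("read_timeseries: time_h not strictly increasing")
  }
  df
}
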
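#' Run configurations
#'
#' A `run_config` is the flat, serializable description of a simulation run:
#' model kind, lattice and scale parameters, model parameters, ensemble
#' size, seed, and which analyses to perform.  It round-trips losslessly
#' through JSON (and YAML, when the yaml package is available); unknown keys
#' are rejected so that a typo cannot silently change a run.
#'
#' @param model One of `"classical"`, `"persistent"`, `"time_correlated"`,
#'   `"generalized"`.
#' @param b Number of velocity channels.
#' @param v,D_rw Physical scales (see [lattice_scales()]).
#' @param n_particles,n_steps,seed Ensemble size and RNG seed.
#' @param beta Sensitivity (persistent only).
#' @param vacf_family,C0,Delta,phi VACF parameters (time-correlated /
#'   generalized only); `vacf_family` is `"power_law"` or
#'   `"piecewise_ballistic"`.
#' @param ballistic_extension See [tc_probabilities()].
#' @param analyses Character subset of
#'   `c("vacf", "msd", "regime", "theory_overlay")`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(model, b = 4, v = 16, D_rw = 1,
                       n_particles = 1000, n_steps = 100, seed = 1,
                       beta = NULL, vacf_family = NULL, C0 = NULL,
                       Delta = NULL, phi = NULL,
                       ballistic_extension = FALSE,
                       analyses = c("vacf", "msd")) {
  rc <- list(model = model, b = b, v = v, D_rw = D_rw,
             n_particles = n_particles, n_steps = n_steps, seed = seed,
             beta = beta, vacf_family = vacf_family, C0 = C0,
             Delta = Delta, phi = phi,
             ballistic_extension = ballistic_extension,
             analyses = analyses)
  validate_run_config(rc)
}

run_config_fields <- c("model", "b", "v", "D_rw", "n_particles", "n_steps",
                       "seed", "beta", "vacf_family", "C0", "Delta", "phi",
                       "ballistic_extension", "analyses")

validate_run_config <- function(rc) {
  unknown <- setdiff(names(rc), run_config_fields)
  if (length(unknown)) {
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  required <- c("model", "b", "v", "D_rw", "n_particles", "n_steps", "seed")
  missing <- setdiff(required, names(rc)[!vapply(rc, is.null, logical(1))])
  if (length(missing)) {
    stop("run_config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!rc$model %in% c("classical", "persistent", "time_correlated",
                       "generalized")) {
    stop("unknown model kind: ", rc$model, call. = FALSE)
  }
  if (rc$model == "persistent" && is.null(rc$beta)) {
    stop("persistent model requires field `beta`", call. = FALSE)
  }
  if (rc$model %in% c("time_correlated", "generalized")) {
    for (f in c("vacf_family", "C0", "Delta", "phi")) {
      if (is.null(rc[[f]])) {
        stop(sprintf("%s model requires field `%s`", rc$model, f),
             call. = FALSE)
      }
    }
  }
  if (is.null(rc$ballistic_extension)) rc$ballistic_extension <- FALSE
  if (is.null(rc$analyses)) rc$analyses <- c("vacf", "msd")
  # building the model objects performs the deep validity checks
  # (e.g. Delta <= tau for a bare power-law time-correlated model)
  as_model_config(rc)
  # canonical field order with absent optionals as NULL, so configs compare
  # and round-trip cleanly
  out <- stats::setNames(lapply(run_config_fields, function(f) rc[[f]]),
                         run_config_fields)
  structure(out, class = "run_config")
}

#' Build the model objects described by a run_config
#'
#' @param rc A `run_config` (or compatible list).
#' @return A [model_config()].
#' @export
as_model_config <- function(rc) {
  set <- channel_set(rc$b)
  scales <- lattice_scales(v = rc$v, D_rw = rc$D_rw, d = set$d)
  vacf <- if (!is.null(rc$vacf_family)) {
    vacf_spec(rc$vacf_family, C0 = rc$C0, Delta = rc$Delta, phi = rc$phi)
  }
  model_config(rc$model, set, scales, beta = rc$beta, vacf = vacf,
               ballistic_extension = isTRUE(rc$ballistic_extension))
}

#' @rdname run_config
#' @param path File path; `.json` or `.yaml`/`.yml`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rc <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_run_config(rc)
}

#' @rdname run_config
#' @param rc A `run_config`.
#' @export
write_run_config <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  drop_null <- rc[!vapply(rc, is.null, logical(1))]
  jsonlite::write_json(drop_null, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Curve CSV input/output
#'
#' Theory curves are written with columns `(t, value)` plus an
#' `equation_id` column taken from the curve metadata; estimator series with
#' columns `(k, t, value, sem, n)`.  Full double precision is preserved.
#'
#' @param curve An `lgca_curve` or `curve_series` tibble.
#' @param path Output path.
#' @export
write_curve_csv <- function(curve, path) {
  df <- as.data.frame(curve)
  meta <- attr(curve, "meta")
  if (!is.null(meta$model) && !"equation_id" %in% names(df)) {
    df$equation_id <- paste0(meta$kind, "_", meta$model)
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @return `read_curve_csv()` returns a tibble with the stored columns.
#' @export
read_curve_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Trajectory CSV input/output
#'
#' Trajectories are stored long: one row per particle per step with columns
#' `(particle_id, step, channel, x, y)`, plus a JSON metadata sidecar
#' carrying the full run configuration and seed so the ensemble is exactly
#' reproducible and re-loadable.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param path CSV output path.
#' @param metadata_path JSON sidecar path (default: `path` with
#'   `.meta.json` appended).
#' @export
write_trajectories <- function(ensemble, path,
                               metadata_path = paste0(path, ".meta.json")) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  td <- tidy(ensemble)
  df <- data.frame(particle_id = td$particle, step = td$step,
                   channel = td$channel,
                   x = format(td$x, digits = 17, trim = TRUE),
                   y = format(td$y, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cfg <- ensemble$config
  meta <- list(model = cfg$model, b = cfg$channels$b,
               v = cfg$scales$v, D_rw = cfg$scales$D_rw,
               beta = cfg$beta,
               vacf_family = cfg$vacf$family, C0 = cfg$vacf$C0,
               Delta = cfg$vacf$Delta, phi = cfg$vacf$phi,
               ballistic_extension = cfg$ballistic_extension,
               n_particles = ensemble$n_particles,
               n_steps = ensemble$n_steps, seed = ensemble$seed,
               ballistic_extended_steps = ensemble$ballistic_extended_steps,
               theory = list(
                 vacf = paste0("vacf_", cfg$model),
                 msd = paste0("msd_", cfg$model)))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectories
#' @return `read_trajectories()` reconstructs the `trajectory_ensemble`
#'   (channel and position matrices, configuration, seed).
#' @export
read_trajectories <- function(path,
                              metadata_path = paste0(path, ".meta.json")) {
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  n <- meta$n_particles
  k1 <- meta$n_steps + 1L
  df <- df[order(df$particle_id, df$step), ]
  cfg <- as_model_config(list(
    model = meta$model, b = meta$b, v = meta$v, D_rw = meta$D_rw,
    beta = meta$beta, vacf_family = meta$vacf_family, C0 = meta$C0,
    Delta = meta$Delta, phi = meta$phi,
    ballistic_extension = isTRUE(meta$ballistic_extension)))
  structure(list(
    channels = matrix(as.integer(df$channel), nrow = n, byrow = TRUE),
    x = matrix(df$x, nrow = n, byrow = TRUE),
    y = matrix(df$y, nrow = n, byrow = TRUE),
    config = cfg, n_particles = n, n_steps = meta$n_steps,
    seed = meta$seed, align = alignment_matrix(cfg$channels),
    ballistic_extended_steps =
      as.integer(meta$ballistic_extended_steps %||% integer(0))),
    class = "trajectory_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the canned reference ensembles
#'
#' Writes one seeded ensemble per model at the reference parameter point
#' used throughout the test suite (square lattice, `v = 16`, `D_rw = 1`;
#' persistent `beta = 5`; time-correlated and generalized `C0 = 0.5`,
#' `Delta = 0.016` with `phi = 1` and `phi = 0.1` respectively), each as a
#' trajectory CSV plus metadata sidecar naming the matching theory curves.
#' Regeneration with the same seed is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param seed Base seed; the four ensembles use `seed`, `seed + 1`, ...
#' @param n_particles,n_steps Ensemble dimensions.
#' @return Invisibly, the paths of the four CSV files.
#' @export
make_fixtures <- function(dir, seed = 1000, n_particles = 1000,
                          n_steps = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rcs <- list(
    classical = run_config("classical", n_particles = n_particles,
                           n_steps = n_steps, seed = seed),
    persistent = run_config("persistent", beta = 5,
                            n_particles = n_particles, n_steps = n_steps,
                            seed = seed + 1),
    time_correlated = run_config("time_correlated",
                                 vacf_family = "piecewise_ballistic",
                                 C0 = 0.5, Delta = 0.016, phi = 1,
                                 n_particles = n_particles,
                                 n_steps = n_steps, seed = seed + 2),
    generalized = run_config("generalized", vacf_family = "power_law",
                             C0 = 0.5, Delta = 0.016, phi = 0.1,
                             n_particles = n_particles, n_steps = n_steps,
                             seed = seed + 3))
  paths <- vapply(names(rcs), function(nm) {
    rc <- rcs[[nm]]
    ens <- simulate_ensemble(as_model_config(rc), rc$n_particles,
                             rc$n_steps, rc$seed)
    p <- file.path(dir, paste0(nm, ".csv"))
    write_trajectories(ens, p)
    write_run_config(rc, file.path(dir, paste0(nm, ".config.json")))
    p
  }, character(1))
  invisible(paths)
}
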
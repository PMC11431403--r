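#' Built-in regime presets
#'
#' Named parameter sets emulating the qualitative regimes of the model:
#' \describe{
#'   \item{`tet`}{pure TET degeneracy: \eqn{E_D = E_A = 0}, balanced
#'     couplings, \eqn{\epsilon_x = 0}. The donor-localized equilibrium start
#'     is an exact stationary point of the deterministic flow, so transfer in
#'     this preset is noise-driven.}
#'   \item{`near_tet`}{TET balance kept, small symmetry breaking
#'     (\eqn{E_D - E_A = 0.5}, \eqn{\epsilon_x = -0.001}) that seeds transfer
#'     and, with damping, makes it irreversible at zero temperature. The
#'     dynamical "TET regime" used for transfer demonstrations.}
#'   \item{`marcus_normal`}{diabatic crossing between the parabola minima;
#'     thermally activated transfer with barrier decreasing with
#'     exothermicity.}
#'   \item{`marcus_inverted`}{crossing outside the inter-minimum interval.}
#'   \item{`away`}{strong coupling imbalance
#'     (\eqn{k_z^2/\Omega_z^2 = 25\,k_x^2/\Omega_x^2}); far from the TET
#'     degeneracy, activated transfer obeying the Arrhenius law.}
#' }
#' Values are package choices (the regimes are qualitative); all fields can
#' be overridden via [load_config()] or by building [dimer_params()] directly.
#'
#' @param name preset name.
#' @return An object of class `regime_preset`: list with `name`, `params`
#'   (a [dimer_params()]) and a short `description`.
#' @examples
#' regime_preset("tet")$params
#' @export
regime_preset <- function(name = c("tet", "near_tet", "marcus_normal",
                                   "marcus_inverted", "away")) {
  name <- match.arg(name)
  params <- switch(name,
    tet = dimer_params(),
    near_tet = dimer_params(E_D = 0.5, eps_x = -0.001),
    marcus_normal = dimer_params(E_D = 1, E_A = 0, k_z = 1, k_x = 0.2,
                                 eps_x = -0.05),
    marcus_inverted = dimer_params(E_D = 3, E_A = 0, k_z = 1, k_x = 0.2,
                                   eps_x = -0.05),
    away = dimer_params(E_D = 0.5, E_A = 0, k_z = 5, k_x = 1, eps_x = -0.1))
  description <- switch(name,
    tet = "symmetric TET degeneracy (conical intersection at the origin)",
    near_tet = "TET balance with small symmetry breaking (zero-T transfer)",
    marcus_normal = "Marcus normal regime (crossing between diabatic minima)",
    marcus_inverted = "Marcus inverted regime (crossing beyond the minima)",
    away = "far from TET: 25-fold coupling-balance mismatch")
  structure(list(name = name, params = params, description = description),
            class = "regime_preset")
}

#' @export
print.regime_preset <- function(x, ...) {
  cat(sprintf("Preset '%s': %s\n", x$name, x$description))
  print(x$params)
  invisible(x)
}

config_defaults <- function() {
  list(preset = NULL,
       params = list(),
       integrator = list(dt = 0.001, t_max = 200, stride = NULL,
                         renormalize = FALSE, norm_tol = 1e-6,
                         strict_transfer_sign = FALSE),
       noise = list(kBT = 0, seed = NULL),
       sweep = list(kBT_values = c(0.5, 1, 1.5, 2, 3), n_runs = 20,
                    base_seed = 1, completion = 0.9))
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "))
}

#' Resolve a run specification from a configuration list
#'
#' Fills defaults, validates every field, rejects unknown keys and returns a
#' fully resolved specification. The configuration has sections `preset`
#' (name of a [regime_preset()]), `params` (full [dimer_params()] fields, or
#' overrides applied on top of the preset), `integrator`, `noise` and
#' `sweep`.
#'
#' @param config a (possibly nested) list.
#' @return An object of class `run_spec`: list with `params`
#'   ([dimer_params()]), `integrator` ([integrator_config()]), `noise`
#'   ([noise_model()]), `sweep` (validated list) and `preset` (name or `NA`).
#' @export
resolve_config <- function(config) {
  stopifnot(is.list(config))
  defs <- config_defaults()
  check_keys(config, names(defs), "config")
  if (!is.null(config$params)) check_keys(config$params,
                                          names(formals(dimer_params)),
                                          "config$params")
  if (!is.null(config$integrator)) check_keys(config$integrator,
                                              names(formals(integrator_config)),
                                              "config$integrator")
  if (!is.null(config$noise)) check_keys(config$noise, c("kBT", "seed"),
                                         "config$noise")
  if (!is.null(config$sweep)) check_keys(config$sweep,
                                         c("kBT_values", "n_runs",
                                           "base_seed", "completion"),
                                         "config$sweep")
  base_params <- if (!is.null(config$preset))
    unclass(regime_preset(config$preset)$params) else list()
  params <- do.call(dimer_params,
                    modifyList(base_params, as.list(config$params)))
  integ <- do.call(integrator_config,
                   modifyList(defs$integrator,
                              as.list(config$integrator),
                              keep.null = TRUE))
  noise_args <- modifyList(defs$noise, as.list(config$noise), keep.null = TRUE)
  noise <- noise_model(noise_args$kBT, noise_args$seed)
  sweep <- modifyList(defs$sweep, as.list(config$sweep))
  stopifnot(length(sweep$kBT_values) >= 1, all(sweep$kBT_values >= 0),
            sweep$n_runs >= 1, sweep$completion > 0, sweep$completion <= 1)
  structure(list(preset = if (is.null(config$preset)) NA_character_
                 else config$preset,
                 params = params, integrator = integ, noise = noise,
                 sweep = sweep),
            class = "run_spec")
}

#' Load and resolve a JSON run configuration
#'
#' Reads a JSON file with the [resolve_config()] schema, fills defaults and
#' validates; schema violations are reported with their field path. The
#' resolved specification is echoed to `stderr` when `verbose = TRUE`.
#'
#' @param path path to a JSON configuration file.
#' @param verbose echo the resolved specification to stderr.
#' @return A `run_spec` (see [resolve_config()]).
#' @export
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  config <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  spec <- resolve_config(config)
  if (verbose)
    message("resolved config: ",
            jsonlite::toJSON(spec_to_list(spec), auto_unbox = TRUE,
                             null = "null"))
  spec
}

spec_to_list <- function(spec) {
  list(preset = if (is.na(spec$preset)) NULL else spec$preset,
       params = unclass(spec$params),
       integrator = unclass(spec$integrator),
       noise = unclass(spec$noise),
       sweep = spec$sweep)
}

#' Write a resolved run specification back to JSON
#'
#' Round-trips with [load_config()]: reloading the written file resolves to
#' an identical specification.
#'
#' @param spec a `run_spec` from [resolve_config()] or [load_config()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_config <- function(spec, path) {
  stopifnot(inherits(spec, "run_spec"))
  jsonlite::write_json(spec_to_list(spec), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run a named analysis stage and write its outputs
#'
#' Thin driver behind the command-line interface. Subcommands:
#' \describe{
#'   \item{`pes`}{PES grid CSV (`pes.csv`) + conical point, TET residuals and
#'     regime label in `pes_summary.json`.}
#'   \item{`simulate`}{one trajectory -> `trajectory.csv` (+ JSON sidecar).}
#'   \item{`ensemble`}{member trajectories `member_<i>.csv` + pointwise
#'     ensemble statistics `ensemble_stats.csv`.}
#'   \item{`sweep`}{temperature sweep -> `sweep.csv` and `sweep.json`.}
#'   \item{`arrhenius`}{sweep + Arrhenius fit -> `sweep.csv`,
#'     `arrhenius.json`.}
#' }
#' Every output directory receives `resolved_config.json`, the full resolved
#' specification (reproducibility contract).
#'
#' @param subcommand one of `"pes"`, `"simulate"`, `"ensemble"`, `"sweep"`,
#'   `"arrhenius"`.
#' @param spec a `run_spec` (see [resolve_config()]).
#' @param out_dir output directory, created if missing.
#' @return Invisibly, a character vector of the files written.
#' @export
run_command <- function(subcommand = c("pes", "simulate", "ensemble",
                                       "sweep", "arrhenius"),
                        spec, out_dir) {
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(spec, "run_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_config(spec, file.path(out_dir, "resolved_config.json"))
  written <- file.path(out_dir, "resolved_config.json")
  p <- spec$params
  if (subcommand == "pes") {
    grid <- adiabatic_surfaces(p)
    f1 <- file.path(out_dir, "pes.csv")
    write_pes_csv(grid, f1)
    cp <- tryCatch(unclass(conical_point(p)), error = function(e) NULL)
    summary <- list(conical_point = cp,
                    tet = unclass(check_tet(p)),
                    regime = classify_regime(p))
    f2 <- file.path(out_dir, "pes_summary.json")
    jsonlite::write_json(summary, f2, auto_unbox = TRUE, digits = NA,
                         null = "null")
    written <- c(written, f1, f2)
  } else if (subcommand == "simulate") {
    tr <- integrate_dimer(initial_state(p, "donor"), p, spec$noise,
                          spec$integrator)
    f1 <- file.path(out_dir, "trajectory.csv")
    write_trajectory_csv(tr, f1)
    written <- c(written, f1, paste0(f1, ".json"))
  } else if (subcommand == "ensemble") {
    sw <- spec$sweep
    ens <- run_ensemble(p, spec$noise$kBT, sw$n_runs,
                        if (is.null(spec$noise$seed)) sw$base_seed
                        else spec$noise$seed,
                        spec$integrator)
    for (i in seq_along(ens)) {
      fi <- file.path(out_dir, sprintf("member_%03d.csv", i))
      write_trajectory_csv(ens[[i]], fi)
      written <- c(written, fi, paste0(fi, ".json"))
    }
    f2 <- file.path(out_dir, "ensemble_stats.csv")
    write.csv(ensemble_stats(ens), f2, row.names = FALSE)
    written <- c(written, f2)
  } else {
    sw <- spec$sweep
    res <- temperature_sweep(p, sw$kBT_values, sw$n_runs, sw$base_seed,
                             spec$integrator, sw$completion)
    f1 <- file.path(out_dir, "sweep.csv")
    write.csv(as.data.frame(res), f1, row.names = FALSE)
    written <- c(written, f1)
    if (subcommand == "sweep") {
      f2 <- file.path(out_dir, "sweep.json")
      jsonlite::write_json(as.data.frame(res), f2, digits = NA)
      written <- c(written, f2)
    } else {
      fit <- arrhenius_fit(res)
      f2 <- file.path(out_dir, "arrhenius.json")
      jsonlite::write_json(list(ln_A = fit$ln_A, E_a = fit$E_a,
                                slope = fit$slope,
                                r_squared = fit$r_squared,
                                rates = fit$data),
                           f2, auto_unbox = TRUE, digits = NA)
      written <- c(written, f2)
    }
  }
  invisible(written)
}
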
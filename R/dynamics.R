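#' Integrator configuration
#'
#' The Langevin system is advanced with the Dormand-Prince Runge-Kutta 5(4)
#' pair used as a *fixed-step* method: adaptive step-size control would break
#' the stated per-step noise variance, so the embedded 4th-order solution is
#' kept only as an accuracy diagnostic (`max_embed_err` on the trajectory).
#'
#' @param dt fixed time step (default 0.001).
#' @param t_max final time (default 200, about ten times the
#'   zero-temperature transfer time of the near-TET preset).
#' @param stride sampling stride: the trajectory records every `stride`-th
#'   step (plus the final step). `NULL` picks a stride giving about 4000
#'   samples.
#' @param renormalize if `TRUE`, rescale the electronic amplitudes to unit
#'   norm after every step; by default drift is only monitored and bounded.
#' @param norm_tol hard bound on the norm drift when `renormalize = FALSE`.
#' @param strict_transfer_sign if `TRUE`, a sign change of the effective
#'   transfer integral \eqn{\epsilon_x + k_x u_x} (a linear-coupling artifact)
#'   is an error; otherwise it is reported as a warning.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 0.001, t_max = 200, stride = NULL,
                              renormalize = FALSE, norm_tol = 1e-6,
                              strict_transfer_sign = FALSE) {
  stopifnot(is.numeric(dt), dt > 0, is.numeric(t_max), t_max >= dt,
            is.numeric(norm_tol), norm_tol > 0)
  if (!is.null(stride))
    stopifnot(is.numeric(stride), stride >= 1, stride == round(stride))
  structure(list(dt = dt, t_max = t_max, stride = stride,
                 renormalize = isTRUE(renormalize), norm_tol = norm_tol,
                 strict_transfer_sign = isTRUE(strict_transfer_sign)),
            class = "integrator_config")
}

#' Thermal noise model for the Langevin baths
#'
#' At each macro-step the integrator draws one Gaussian force per mode with
#' mean 0 and variance \eqn{2\gamma k_B T/\delta t} (the discrete-time
#' realization of white noise obeying the fluctuation-dissipation relation
#' \eqn{\langle\eta(t)\eta(t')\rangle = 2\gamma k_B T\,\delta(t-t')}), frozen
#' across the internal Runge-Kutta stages of that step. With `kBT = 0` no
#' random numbers are consumed and the dynamics is deterministic.
#'
#' @param kBT bath temperature in energy units (\eqn{k_B T \ge 0}).
#' @param seed integer PRNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kBT = 0, seed = NULL) {
  stopifnot(is.numeric(kBT), length(kBT) == 1L, is.finite(kBT), kBT >= 0)
  if (!is.null(seed))
    stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
  structure(list(kBT = kBT, seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_model")
}

#' Equilibrium initial condition with a localized electron
#'
#' Places the electron fully on the chosen site with zero phase and sets each
#' mode at the stationary point of its driven oscillator equation:
#' \eqn{u_x = -(k_x/\Omega_x^2)\, 2\mathrm{Re}(\varphi_D^\ast\varphi_A)}
#' (which is exactly 0 for a localized electron) and
#' \eqn{u_z = -(k_z/\Omega_z^2)(|\varphi_A|^2 - |\varphi_D|^2)}; both
#' velocities zero. For a donor-localized electron this state is a stationary
#' point of the deterministic flow whenever \eqn{\epsilon_x = 0}.
#'
#' @param params a [dimer_params()].
#' @param electron_on `"donor"` or `"acceptor"`.
#' @return A [system_state()] at \eqn{t = 0}.
#' @examples
#' initial_state(dimer_params(), "donor")$u_z   # +k_z/Omega_z^2
#' @export
initial_state <- function(params, electron_on = c("donor", "acceptor")) {
  stopifnot(inherits(params, "dimer_params"))
  electron_on <- match.arg(electron_on)
  phi_D <- if (electron_on == "donor") 1 + 0i else 0 + 0i
  phi_A <- if (electron_on == "donor") 0 + 0i else 1 + 0i
  C <- Mod(phi_A)^2 - Mod(phi_D)^2
  X <- 2 * Re(Conj(phi_D) * phi_A)
  system_state(phi_D = phi_D, phi_A = phi_A,
               u_z = -params$k_z / params$Omega_z^2 * C + 0,  # + 0 drops -0
               u_x = -params$k_x / params$Omega_x^2 * X + 0,
               p_z = 0, p_x = 0, t = 0)
}

#' Integrate the dimer equations of motion
#'
#' Fixed-step Runge-Kutta 5(4) advance of the 8 real state components. With
#' a noisy bath (`noise$kBT > 0`) one pair of Gaussian forces
#' \eqn{(\eta_z, \eta_x)} of variance \eqn{2\gamma k_B T/\delta t} is drawn
#' per macro-step (in that order) and held constant across the internal
#' stages; runs with equal seeds are bitwise identical.
#'
#' @param state0 initial [system_state()], normalized within
#'   `config$norm_tol`.
#' @param params a [dimer_params()].
#' @param noise a [noise_model()] (default: zero temperature).
#' @param config an [integrator_config()].
#' @return An object of class `trajectory`: list with `times`, `P_D`, `P_A`,
#'   `energy`, the complex amplitude series `phi_D`, `phi_A`, mode series
#'   `u_z`, `u_x`, `p_z`, `p_x`, plus diagnostics `final_norm`,
#'   `max_norm_dev`, `max_embed_err`, `n_sign_flips` and the inputs
#'   (`params`, `noise`, `config`).
#' @examples
#' p <- dimer_params(E_D = 0.5, eps_x = -0.001)
#' tr <- integrate_dimer(initial_state(p, "donor"), p,
#'                       config = integrator_config(t_max = 5))
#' max(tr$P_A)
#' @export
integrate_dimer <- function(state0, params, noise = noise_model(0),
                            config = integrator_config()) {
  stopifnot(inherits(state0, "system_state"), inherits(params, "dimer_params"),
            inherits(noise, "noise_model"), inherits(config, "integrator_config"))
  nrm0 <- Mod(state0$phi_D)^2 + Mod(state0$phi_A)^2
  if (abs(nrm0 - 1) > config$norm_tol)
    stop("initial state not normalized within norm_tol")
  n_steps <- as.integer(round(config$t_max / config$dt))
  stride <- config$stride
  if (is.null(stride)) stride <- max(1L, as.integer(floor(n_steps / 4000)))
  if (!is.null(noise$seed) && noise$kBT > 0) set.seed(noise$seed)
  raw <- integrate_core(state_vector(state0), params_vector(params),
                        noise$kBT, config$dt, n_steps, as.integer(stride),
                        config$renormalize, config$norm_tol)
  if (raw$n_sign_flips > 0) {
    msg <- sprintf(
      "effective transfer integral eps_x + k_x*u_x changed sign in %d step(s): linear-coupling artifact",
      raw$n_sign_flips)
    if (config$strict_transfer_sign) stop(msg) else warning(msg)
  }
  structure(list(
    times = raw$times,
    phi_D = complex(real = raw$Y[, 1], imaginary = raw$Y[, 2]),
    phi_A = complex(real = raw$Y[, 3], imaginary = raw$Y[, 4]),
    u_z = raw$Y[, 5], p_z = raw$Y[, 6], u_x = raw$Y[, 7], p_x = raw$Y[, 8],
    P_D = raw$P_D, P_A = raw$P_A, energy = raw$energy,
    final_norm = raw$final_norm, max_norm_dev = raw$max_norm_dev,
    max_embed_err = raw$max_embed_err, n_sign_flips = raw$n_sign_flips,
    params = params, noise = noise, config = config, stride = stride),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Dimer trajectory: %d samples, t in [0, %g], dt = %g, kBT = %g\n",
              length(x$times), max(x$times), x$config$dt, x$noise$kBT))
  cat(sprintf("  final P_A = %.4f, max P_A = %.4f\n",
              x$P_A[length(x$P_A)], max(x$P_A)))
  cat(sprintf("  norm drift %.2e, embedded-pair error %.2e\n",
              x$max_norm_dev, x$max_embed_err))
  invisible(x)
}

#' Export a trajectory as CSV with a JSON sidecar
#'
#' CSV columns: `t`, real/imaginary parts of both amplitudes, `P_D`, `P_A`,
#' `u_z`, `u_x`, `p_z`, `p_x`, `energy`. The sidecar (`<path>.json`) records
#' the full resolved specification: parameters, temperature, seed and
#' integrator settings.
#'
#' @param traj a [integrate_dimer()] trajectory.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(t = traj$times,
                   re_phi_D = Re(traj$phi_D), im_phi_D = Im(traj$phi_D),
                   re_phi_A = Re(traj$phi_A), im_phi_A = Im(traj$phi_A),
                   P_D = traj$P_D, P_A = traj$P_A,
                   u_z = traj$u_z, u_x = traj$u_x,
                   p_z = traj$p_z, p_x = traj$p_x,
                   energy = traj$energy)
  write.csv(df, path, row.names = FALSE)
  meta <- list(params = unclass(traj$params),
               kBT = traj$noise$kBT, seed = traj$noise$seed,
               dt = traj$config$dt, t_max = traj$config$t_max,
               stride = traj$stride,
               renormalize = traj$config$renormalize)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run an ensemble of independently seeded trajectories
#'
#' Member `i` (1-based) integrates with seed `base_seed + i - 1`; all members
#' share the parameter set, temperature and time grid. Any member failure
#' aborts the ensemble with a message naming the offending seed.
#'
#' @param params a [dimer_params()].
#' @param kBT bath temperature.
#' @param n_runs number of members (>= 1).
#' @param base_seed integer seed of the first member.
#' @param config an [integrator_config()].
#' @param electron_on initial localization site, as in [initial_state()].
#' @return An object of class `trajectory_ensemble`: list of `trajectory`
#'   objects with shared `times`.
#' @export
run_ensemble <- function(params, kBT, n_runs, base_seed,
                         config = integrator_config(),
                         electron_on = "donor") {
  stopifnot(inherits(params, "dimer_params"), n_runs >= 1)
  s0 <- initial_state(params, electron_on)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    seed_i <- as.integer(base_seed + i - 1L)
    runs[[i]] <- tryCatch(
      integrate_dimer(s0, params, noise_model(kBT, seed = seed_i), config),
      error = function(e)
        stop("ensemble member with seed ", seed_i, " failed: ",
             conditionMessage(e), call. = FALSE))
  }
  structure(runs, class = "trajectory_ensemble",
            kBT = kBT, base_seed = base_seed)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d members, kBT = %g, base seed %d\n",
              length(x), attr(x, "kBT"), attr(x, "base_seed")))
  invisible(x)
}
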
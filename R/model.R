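#' Total energy of the dimer
#'
#' Evaluates the model Hamiltonian
#' \deqn{H = E_D|\varphi_D|^2 + E_A|\varphi_A|^2
#'   + k_z u_z (|\varphi_A|^2 - |\varphi_D|^2)
#'   + (\epsilon_x + k_x u_x)\, 2\mathrm{Re}(\varphi_D^\ast \varphi_A)
#'   + \tfrac12 p_z^2 + \tfrac12 \Omega_z^2 u_z^2
#'   + \tfrac12 p_x^2 + \tfrac12 \Omega_x^2 u_x^2.}
#'
#' @param state a [system_state()].
#' @param params a [dimer_params()].
#' @return The total energy (scalar, \eqn{\hbar = 1} units).
#' @examples
#' p <- dimer_params(E_D = 0.5)
#' total_energy(system_state(1, 0), p)  # = E_D
#' @export
total_energy <- function(state, params) {
  stopifnot(inherits(state, "system_state"), inherits(params, "dimer_params"))
  nD <- Mod(state$phi_D)^2
  nA <- Mod(state$phi_A)^2
  X <- 2 * Re(Conj(state$phi_D) * state$phi_A)
  e <- params$E_D * nD + params$E_A * nA +
    params$k_z * state$u_z * (nA - nD) +
    (params$eps_x + params$k_x * state$u_x) * X +
    0.5 * state$p_z^2 + 0.5 * params$Omega_z^2 * state$u_z^2 +
    0.5 * state$p_x^2 + 0.5 * params$Omega_x^2 * state$u_x^2
  if (!is.finite(e)) stop("non-finite energy from state/parameters")
  e
}

#' Electronic Hamiltonian matrix at fixed mode coordinates
#'
#' The 2x2 real symmetric matrix generating the electronic dynamics at frozen
#' nuclear coordinates: diagonal \eqn{E_D - k_z u_z} and \eqn{E_A + k_z u_z},
#' off-diagonal the effective transfer integral \eqn{\epsilon_x + k_x u_x}.
#' Its eigenvalues (plus the harmonic energy) are the adiabatic surfaces.
#'
#' @param u_x,u_z mode coordinates.
#' @param params a [dimer_params()].
#' @return A 2x2 symmetric numeric matrix, rows/cols ordered (donor, acceptor).
#' @examples
#' electronic_matrix(0, 0, dimer_params(E_D = 1, eps_x = -0.1))
#' @export
electronic_matrix <- function(u_x, u_z, params) {
  stopifnot(inherits(params, "dimer_params"),
            is.finite(u_x), is.finite(u_z))
  g <- params$eps_x + params$k_x * u_x
  matrix(c(params$E_D - params$k_z * u_z, g,
           g, params$E_A + params$k_z * u_z),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("D", "A"), c("D", "A")))
}

#' Equations of motion of the dimer
#'
#' Right-hand side of the coupled electron-phonon system:
#' \deqn{i\dot\varphi_D = (E_D - k_z u_z)\varphi_D + (\epsilon_x + k_x u_x)\varphi_A}
#' \deqn{i\dot\varphi_A = (E_A + k_z u_z)\varphi_A + (\epsilon_x + k_x u_x)\varphi_D}
#' \deqn{\ddot u_z + \gamma_z \dot u_z + \Omega_z^2 u_z
#'   + k_z(|\varphi_A|^2 - |\varphi_D|^2) = \eta_z(t)}
#' \deqn{\ddot u_x + \gamma_x \dot u_x + \Omega_x^2 u_x
#'   + 2 k_x \mathrm{Re}(\varphi_D^\ast\varphi_A) = \eta_x(t)}
#' with the mode forces being the gradients of the Hamiltonian coupling terms.
#' Pass `noise_z = noise_x = 0` for deterministic evolution.
#'
#' @param state a [system_state()].
#' @param params a [dimer_params()].
#' @param noise_z,noise_x instantaneous Langevin forces on the two modes.
#' @return A list with components `d_phi_D`, `d_phi_A` (complex), `d_u_z`,
#'   `d_p_z`, `d_u_x`, `d_p_x`.
#' @export
equations_of_motion <- function(state, params, noise_z = 0, noise_x = 0) {
  stopifnot(inherits(state, "system_state"), inherits(params, "dimer_params"),
            is.finite(noise_z), is.finite(noise_x))
  g <- params$eps_x + params$k_x * state$u_x
  hD <- params$E_D - params$k_z * state$u_z
  hA <- params$E_A + params$k_z * state$u_z
  C <- Mod(state$phi_A)^2 - Mod(state$phi_D)^2
  X <- 2 * Re(Conj(state$phi_D) * state$phi_A)
  list(
    d_phi_D = -1i * (hD * state$phi_D + g * state$phi_A),
    d_phi_A = -1i * (hA * state$phi_A + g * state$phi_D),
    d_u_z = state$p_z,
    d_p_z = -params$gamma_z * state$p_z - params$Omega_z^2 * state$u_z -
      params$k_z * C + noise_z,
    d_u_x = state$p_x,
    d_p_x = -params$gamma_x * state$p_x - params$Omega_x^2 * state$u_x -
      params$k_x * X + noise_x)
}
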
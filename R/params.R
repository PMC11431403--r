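#' Dimer model parameters
#'
#' Container for all constants of the donor-acceptor dimer: on-site energies,
#' the couplings of the two vibrational modes, the bare transfer integral, the
#' mode frequencies and the Langevin damping rates. Units are the rescaled
#' \eqn{\hbar = 1} units used throughout the package.
#'
#' @param E_D on-site donor energy.
#' @param E_A on-site acceptor energy.
#' @param k_z coupling of the antisymmetric (ionic) mode to the charge
#'   imbalance \eqn{|\varphi_A|^2 - |\varphi_D|^2}.
#' @param k_x coupling of the symmetric (covalent) mode to the bond order
#'   \eqn{2\,\mathrm{Re}(\varphi_D^\ast \varphi_A)}.
#' @param eps_x bare transfer integral \eqn{\epsilon_x}; the effective
#'   transfer integral is \eqn{\epsilon_x + k_x u_x}.
#' @param Omega_z,Omega_x mode angular frequencies; must be positive.
#' @param gamma_z,gamma_x Langevin damping rates; must be non-negative.
#'
#' @return An object of class `dimer_params` (a named list of scalars).
#' @examples
#' p <- dimer_params(E_D = 0.5, eps_x = -0.001)
#' p$E_D
#' @export
dimer_params <- function(E_D = 0, E_A = 0, k_z = 1, k_x = 1, eps_x = 0,
                         Omega_z = 1, Omega_x = 1,
                         gamma_z = 0.1, gamma_x = 0.1) {
  p <- list(E_D = E_D, E_A = E_A, k_z = k_z, k_x = k_x, eps_x = eps_x,
            Omega_z = Omega_z, Omega_x = Omega_x,
            gamma_z = gamma_z, gamma_x = gamma_x)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar")
    p[[nm]] <- as.numeric(v)
  }
  if (p$Omega_z <= 0) stop("parameter 'Omega_z' must be positive")
  if (p$Omega_x <= 0) stop("parameter 'Omega_x' must be positive")
  if (p$gamma_z < 0) stop("parameter 'gamma_z' must be non-negative")
  if (p$gamma_x < 0) stop("parameter 'gamma_x' must be non-negative")
  structure(p, class = "dimer_params")
}

#' @export
print.dimer_params <- function(x, ...) {
  cat("Donor-acceptor dimer parameters (hbar = 1 units)\n")
  cat(sprintf("  on-site:    E_D = %g, E_A = %g  (reaction energy E_D - E_A = %g)\n",
              x$E_D, x$E_A, x$E_D - x$E_A))
  cat(sprintf("  couplings:  k_z = %g, k_x = %g, eps_x = %g\n",
              x$k_z, x$k_x, x$eps_x))
  cat(sprintf("  modes:      Omega_z = %g, Omega_x = %g\n", x$Omega_z, x$Omega_x))
  cat(sprintf("  damping:    gamma_z = %g, gamma_x = %g\n", x$gamma_z, x$gamma_x))
  invisible(x)
}

params_vector <- function(params) {
  stopifnot(inherits(params, "dimer_params"))
  unlist(params)
}

#' Serialize dimer parameters to JSON
#'
#' Field names in the JSON object match the `dimer_params` fields exactly;
#' [params_from_json()] rejects unknown keys.
#'
#' @param params a [dimer_params()] object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "dimer_params"))
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname params_to_json
#' @param json a JSON string or the path to a JSON file.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  allowed <- names(formals(dimer_params))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  do.call(dimer_params, x)
}

#' Instantaneous dynamical state of the dimer
#'
#' The state joins the two complex electronic amplitudes with the coordinates
#' and velocities of the two vibrational modes. The electronic amplitudes must
#' satisfy the normalization \eqn{|\varphi_D|^2 + |\varphi_A|^2 = 1} within
#' `norm_tol`.
#'
#' @param phi_D,phi_A complex electronic amplitudes on donor and acceptor.
#' @param u_z,u_x mode coordinates.
#' @param p_z,p_x mode velocities (unit masses, so also momenta).
#' @param t time.
#' @param norm_tol tolerance on the normalization invariant.
#' @return An object of class `system_state`.
#' @examples
#' s <- system_state(phi_D = 1, phi_A = 0, u_z = 1)
#' @export
system_state <- function(phi_D, phi_A, u_z = 0, u_x = 0, p_z = 0, p_x = 0,
                         t = 0, norm_tol = 1e-6) {
  phi_D <- as.complex(phi_D); phi_A <- as.complex(phi_A)
  vals <- c(Re(phi_D), Im(phi_D), Re(phi_A), Im(phi_A), u_z, u_x, p_z, p_x, t)
  if (length(vals) != 9L || any(!is.finite(vals)))
    stop("all state components must be finite scalars")
  nrm <- Mod(phi_D)^2 + Mod(phi_A)^2
  if (abs(nrm - 1) > norm_tol)
    stop(sprintf("electronic amplitudes not normalized: |phi_D|^2+|phi_A|^2 = %.8f", nrm))
  structure(list(phi_D = phi_D, phi_A = phi_A, u_z = u_z, u_x = u_x,
                 p_z = p_z, p_x = p_x, t = t),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("Dimer state at t = %g\n", x$t))
  cat(sprintf("  phi_D = %.6f%+.6fi  (P_D = %.6f)\n",
              Re(x$phi_D), Im(x$phi_D), Mod(x$phi_D)^2))
  cat(sprintf("  phi_A = %.6f%+.6fi  (P_A = %.6f)\n",
              Re(x$phi_A), Im(x$phi_A), Mod(x$phi_A)^2))
  cat(sprintf("  u_z = %g, p_z = %g;  u_x = %g, p_x = %g\n",
              x$u_z, x$p_z, x$u_x, x$p_x))
  invisible(x)
}

state_vector <- function(state) {
  c(Re(state$phi_D), Im(state$phi_D), Re(state$phi_A), Im(state$phi_A),
    state$u_z, state$p_z, state$u_x, state$p_x)
}

state_from_vector <- function(y, t = 0, norm_tol = Inf) {
  structure(list(phi_D = complex(real = y[1], imaginary = y[2]),
                 phi_A = complex(real = y[3], imaginary = y[4]),
                 u_z = y[5], u_x = y[7], p_z = y[6], p_x = y[8], t = t),
            class = "system_state")
}

#' Test the targeted-energy-transfer resonance conditions
#'
#' TET (resonant, near-complete transfer through a degenerate ground state)
#' requires three simultaneous conditions: equal on-site energies
#' \eqn{E_A = E_D}, balanced mode couplings
#' \eqn{k_z^2/\Omega_z^2 = k_x^2/\Omega_x^2}, and a vanishing bare transfer
#' integral \eqn{\epsilon_x = 0}. This returns the three residuals and a flag.
#'
#' @param params a [dimer_params()] object.
#' @param tol tolerance applied to each residual magnitude.
#' @return An object of class `tet_residual` with fields `d_energy`
#'   (\eqn{E_A - E_D}), `d_balance`
#'   (\eqn{k_z^2/\Omega_z^2 - k_x^2/\Omega_x^2}), `d_transfer`
#'   (\eqn{\epsilon_x}) and logical `is_tet`.
#' @examples
#' check_tet(dimer_params())          # satisfies all three conditions
#' check_tet(dimer_params(E_D = 0.5)) # energy residual -0.5
#' @export
check_tet <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "dimer_params"), is.numeric(tol), tol > 0)
  r <- list(
    d_energy   = params$E_A - params$E_D,
    d_balance  = params$k_z^2 / params$Omega_z^2 -
                 params$k_x^2 / params$Omega_x^2,
    d_transfer = params$eps_x)
  r$is_tet <- abs(r$d_energy) <= tol && abs(r$d_balance) <= tol &&
    abs(r$d_transfer) <= tol
  r$tol <- tol
  structure(r, class = "tet_residual")
}

#' @export
print.tet_residual <- function(x, ...) {
  cat("TET degeneracy residuals:\n")
  cat(sprintf("  E_A - E_D                  = %g\n", x$d_energy))
  cat(sprintf("  k_z^2/Oz^2 - k_x^2/Ox^2    = %g\n", x$d_balance))
  cat(sprintf("  eps_x                      = %g\n", x$d_transfer))
  cat(sprintf("  TET at tol %g: %s\n", x$tol, if (x$is_tet) "yes" else "no"))
  invisible(x)
}
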
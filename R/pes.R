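#' Adiabatic potential-energy surfaces over the two mode coordinates
#'
#' At each grid node \eqn{(u_x, u_z)} the lower/upper adiabatic surfaces are
#' the harmonic energy plus the eigenvalues of [electronic_matrix()]:
#' \deqn{V_\pm = \tfrac12\Omega_z^2 u_z^2 + \tfrac12\Omega_x^2 u_x^2
#'   + \frac{E_D + E_A}{2} \pm
#'   \sqrt{\Big(\frac{E_D - E_A}{2} - k_z u_z\Big)^2
#'         + (\epsilon_x + k_x u_x)^2}.}
#' The two surfaces touch only at the conical intersection.
#'
#' @param params a [dimer_params()].
#' @param ux_axis,uz_axis strictly increasing coordinate vectors (>= 2 points).
#'   Defaults sample \eqn{[-3, 3]} with 201 points, bracketing the stationary
#'   points \eqn{\pm k_z/\Omega_z^2} of all built-in presets.
#' @return An object of class `pes_grid`: list with `ux_axis`, `uz_axis`,
#'   matrices `lower` and `upper` (rows index `ux_axis`, columns `uz_axis`)
#'   and the `params` snapshot.
#' @examples
#' g <- adiabatic_surfaces(dimer_params(), ux_axis = seq(-2, 2, length.out = 41),
#'                         uz_axis = seq(-2, 2, length.out = 41))
#' range(g$upper - g$lower)
#' @export
adiabatic_surfaces <- function(params,
                               ux_axis = seq(-3, 3, length.out = 201),
                               uz_axis = seq(-3, 3, length.out = 201)) {
  stopifnot(inherits(params, "dimer_params"))
  for (ax in list(ux_axis, uz_axis)) {
    if (length(ax) < 2L || any(!is.finite(ax)) || any(diff(ax) <= 0))
      stop("grid axes must be strictly increasing with at least 2 points")
  }
  harm <- outer(0.5 * params$Omega_x^2 * ux_axis^2,
                0.5 * params$Omega_z^2 * uz_axis^2, "+")
  mid <- (params$E_D + params$E_A) / 2
  half_gap <- sqrt(outer((params$eps_x + params$k_x * ux_axis)^2,
                         ((params$E_D - params$E_A) / 2 -
                            params$k_z * uz_axis)^2, "+"))
  structure(list(ux_axis = ux_axis, uz_axis = uz_axis,
                 lower = harm + mid - half_gap,
                 upper = harm + mid + half_gap,
                 params = params),
            class = "pes_grid")
}

#' @export
print.pes_grid <- function(x, ...) {
  cat(sprintf("Adiabatic PES grid: %d x %d nodes, ux in [%g, %g], uz in [%g, %g]\n",
              length(x$ux_axis), length(x$uz_axis),
              min(x$ux_axis), max(x$ux_axis), min(x$uz_axis), max(x$uz_axis)))
  cat(sprintf("  lower surface range: [%.4f, %.4f]\n", min(x$lower), max(x$lower)))
  cat(sprintf("  minimum gap on grid: %.3e\n", min(x$upper - x$lower)))
  invisible(x)
}

#' Export a PES grid as delimited text
#'
#' Long-format CSV with columns `ux`, `uz`, `lower`, `upper`.
#'
#' @param grid a `pes_grid` from [adiabatic_surfaces()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pes_csv <- function(grid, path) {
  stopifnot(inherits(grid, "pes_grid"))
  df <- data.frame(
    ux = rep(grid$ux_axis, times = length(grid$uz_axis)),
    uz = rep(grid$uz_axis, each = length(grid$ux_axis)),
    lower = as.vector(grid$lower),
    upper = as.vector(grid$upper))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Conical intersection of the two adiabatic surfaces
#'
#' The gap closes where both the detuning and the effective transfer integral
#' vanish: \eqn{u_x^\ast = -\epsilon_x/k_x},
#' \eqn{u_z^\ast = (E_D - E_A)/(2 k_z)}. Requires both couplings nonzero;
#' otherwise the degeneracy is a line rather than an isolated point.
#'
#' @param params a [dimer_params()].
#' @return An object of class `conical_point`: list with `ux_star`, `uz_star`,
#'   `energy` (common surface value there) and `gap` (residual gap, 0 to
#'   machine precision).
#' @examples
#' conical_point(dimer_params())                 # origin for the symmetric case
#' conical_point(dimer_params(E_D = 0.5))        # shifted along uz only
#' @export
conical_point <- function(params) {
  stopifnot(inherits(params, "dimer_params"))
  if (params$k_z == 0 || params$k_x == 0)
    stop("no isolated conical point: k_z and k_x must both be nonzero")
  ux <- -params$eps_x / params$k_x
  uz <- (params$E_D - params$E_A) / (2 * params$k_z)
  gap <- 2 * sqrt(((params$E_D - params$E_A) / 2 - params$k_z * uz)^2 +
                    (params$eps_x + params$k_x * ux)^2)
  energy <- 0.5 * params$Omega_z^2 * uz^2 + 0.5 * params$Omega_x^2 * ux^2 +
    (params$E_D + params$E_A) / 2
  structure(list(ux_star = ux, uz_star = uz, energy = energy, gap = gap),
            class = "conical_point")
}

#' @export
print.conical_point <- function(x, ...) {
  cat(sprintf("Conical intersection at (ux, uz) = (%g, %g), energy %g, gap %g\n",
              x$ux_star, x$uz_star, x$energy, x$gap))
  invisible(x)
}

#' Anti-adiabatic dimer energy at fixed occupation and relative phase
#'
#' In the fast-mode (anti-adiabatic) limit the mode coordinates follow the
#' electronic variables instantaneously and the energy reduces to a function
#' of the acceptor occupation \eqn{\rho = |\varphi_A|^2} and the relative
#' phase \eqn{\Delta = \alpha_A - \alpha_D}:
#' \deqn{H_{aa}(\rho, \Delta) = -\tfrac12\frac{k_z^2}{\Omega_z^2}(2\rho-1)^2
#'   - 2\frac{k_x^2}{\Omega_x^2}\rho(1-\rho)\cos^2\Delta
#'   + E_D(1-\rho) + E_A\rho
#'   + 2\epsilon_x\sqrt{\rho(1-\rho)}\cos\Delta.}
#'
#' @param rho acceptor occupation in \eqn{[0, 1]}.
#' @param phase relative phase \eqn{\alpha_A - \alpha_D}.
#' @param params a [dimer_params()].
#' @return The anti-adiabatic energy (vectorized over `rho`/`phase`).
#' @export
antiadiabatic_energy <- function(rho, phase, params) {
  stopifnot(inherits(params, "dimer_params"))
  if (any(rho < 0 | rho > 1)) stop("'rho' must lie in [0, 1]")
  cz <- params$k_z^2 / params$Omega_z^2
  cx <- params$k_x^2 / params$Omega_x^2
  -0.5 * cz * (2 * rho - 1)^2 -
    2 * cx * rho * (1 - rho) * cos(phase)^2 +
    params$E_D * (1 - rho) + params$E_A * rho +
    2 * params$eps_x * sqrt(rho * (1 - rho)) * cos(phase)
}

#' Reduced potential over the acceptor occupation
#'
#' Minimizing [antiadiabatic_energy()] over the relative phase (the minimizing
#' phase is \eqn{\Delta = 0} for \eqn{\epsilon_x < 0} and \eqn{\Delta = \pi}
#' for \eqn{\epsilon_x > 0}) gives the one-dimensional potential
#' \deqn{F(\rho) = -\tfrac12\frac{k_z^2}{\Omega_z^2}(2\rho-1)^2
#'   - 2\frac{k_x^2}{\Omega_x^2}\rho(1-\rho) + E_D(1-\rho) + E_A\rho
#'   - 2|\epsilon_x|\sqrt{\rho(1-\rho)}.}
#' Under the TET conditions ([check_tet()]) every \eqn{\rho}-dependent term
#' cancels and \eqn{F} is flat: the degenerate reaction path.
#'
#' @param rho acceptor occupation(s) in \eqn{[0, 1]}; vectorized.
#' @param params a [dimer_params()].
#' @return \eqn{F(\rho)}, same length as `rho`.
#' @examples
#' reduced_potential_F(c(0, 0.5, 1), dimer_params())   # flat under TET
#' @export
reduced_potential_F <- function(rho, params) {
  stopifnot(inherits(params, "dimer_params"))
  if (any(!is.finite(rho)) || any(rho < 0 | rho > 1))
    stop("'rho' must lie in [0, 1]")
  cz <- params$k_z^2 / params$Omega_z^2
  cx <- params$k_x^2 / params$Omega_x^2
  -0.5 * cz * (2 * rho - 1)^2 - 2 * cx * rho * (1 - rho) +
    params$E_D * (1 - rho) + params$E_A * rho -
    2 * abs(params$eps_x) * sqrt(rho * (1 - rho))
}

#' Classify the transfer regime of a parameter set
#'
#' Order of precedence:
#' \enumerate{
#'   \item `"tet"` if all three TET residuals pass [check_tet()] at `tol`;
#'   \item `"near_tet"` if the coupling balance and bare transfer residuals
#'     are small (\eqn{\le} `near_tol`) and the reaction energy satisfies
#'     \eqn{0 < |E_D - E_A| \le 1};
#'   \item `"away"` if the coupling-balance residual is large
#'     (\eqn{\ge} `away_balance`), the strongly imbalanced regime where the
#'     gap survives everywhere off the \eqn{u_x = -\epsilon_x/k_x} line;
#'   \item otherwise Marcus-type: the diabatic parabolas restricted to
#'     \eqn{u_x = 0}, \eqn{V_D(u_z) = \tfrac12\Omega_z^2u_z^2 + E_D - k_z u_z}
#'     and \eqn{V_A(u_z) = \tfrac12\Omega_z^2u_z^2 + E_A + k_z u_z}, cross at
#'     \eqn{u_z^\ast = (E_D - E_A)/(2k_z)}; `"marcus_normal"` when the
#'     crossing falls strictly between the two parabola minima
#'     \eqn{\pm k_z/\Omega_z^2}, `"marcus_inverted"` when it falls outside.
#' }
#'
#' @param params a [dimer_params()].
#' @param tol strict TET tolerance (default 1e-9).
#' @param near_tol looser tolerance on the balance and bare-transfer
#'   residuals for the near-TET label (default 0.05).
#' @param away_balance coupling-balance residual magnitude beyond which the
#'   set is labelled `"away"` (default 10).
#' @return One of `"tet"`, `"near_tet"`, `"marcus_normal"`,
#'   `"marcus_inverted"`, `"away"`.
#' @examples
#' classify_regime(dimer_params())                        # "tet"
#' classify_regime(dimer_params(E_D = 0.5, eps_x = -1e-3)) # "near_tet"
#' @export
classify_regime <- function(params, tol = 1e-9, near_tol = 0.05,
                            away_balance = 10) {
  stopifnot(inherits(params, "dimer_params"), tol > 0)
  r <- check_tet(params, tol)
  if (r$is_tet) return("tet")
  if (abs(r$d_balance) <= near_tol && abs(r$d_transfer) <= near_tol &&
      abs(r$d_energy) > 0 && abs(r$d_energy) <= 1)
    return("near_tet")
  if (abs(r$d_balance) >= away_balance) return("away")
  if (params$k_z == 0) return("away")
  uz_cross <- (params$E_D - params$E_A) / (2 * params$k_z)
  uz_min <- abs(params$k_z) / params$Omega_z^2
  if (abs(uz_cross) < uz_min) "marcus_normal" else "marcus_inverted"
}

#' Angular profile of the adiabatic surfaces around the conical point
#'
#' Samples both surfaces on a circle of given radius centered at the conical
#' intersection in the frequency-scaled plane
#' \eqn{(\Omega_x u_x, \Omega_z u_z)}: the path
#' \eqn{u_x(\alpha) = u_x^\ast + (r/\Omega_x)\cos\alpha},
#' \eqn{u_z(\alpha) = u_z^\ast + (r/\Omega_z)\sin\alpha}.
#' Under the TET degeneracy conditions the gap
#' \eqn{2r\sqrt{(k_z/\Omega_z)^2\sin^2\alpha + (k_x/\Omega_x)^2\cos^2\alpha}}
#' is independent of \eqn{\alpha} (cylindrical symmetry); breaking
#' \eqn{E_A = E_D} makes it vary with the rotation angle.
#'
#' @param params a [dimer_params()].
#' @param radius circle radius in the scaled plane; must be positive.
#' @param n_angles number of equally spaced angles in \eqn{[0, 2\pi)}.
#' @return A data frame with columns `angle`, `lower`, `upper`, `gap`.
#' @export
reaction_path <- function(params, radius = 0.5, n_angles = 360) {
  stopifnot(inherits(params, "dimer_params"), radius > 0, n_angles >= 2)
  cp <- conical_point(params)
  angle <- seq(0, 2 * pi, length.out = n_angles + 1)[seq_len(n_angles)]
  ux <- cp$ux_star + radius * cos(angle) / params$Omega_x
  uz <- cp$uz_star + radius * sin(angle) / params$Omega_z
  harm <- 0.5 * params$Omega_z^2 * uz^2 + 0.5 * params$Omega_x^2 * ux^2
  mid <- (params$E_D + params$E_A) / 2
  half_gap <- sqrt(((params$E_D - params$E_A) / 2 - params$k_z * uz)^2 +
                     (params$eps_x + params$k_x * ux)^2)
  data.frame(angle = angle,
             lower = harm + mid - half_gap,
             upper = harm + mid + half_gap,
             gap = 2 * half_gap)
}
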
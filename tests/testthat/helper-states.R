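# Random normalized system states and a minimal synthetic trajectory object
# used to test observables on closed-form probability series.

random_state <- function() {
  a <- rnorm(4)
  nrm <- sqrt(sum(a^2))
  a <- a / nrm
  system_state(phi_D = complex(real = a[1], imaginary = a[2]),
               phi_A = complex(real = a[3], imaginary = a[4]),
               u_z = rnorm(1), u_x = rnorm(1),
               p_z = rnorm(1), p_x = rnorm(1))
}

random_params <- function() {
  dimer_params(E_D = rnorm(1), E_A = rnorm(1),
               k_z = rnorm(1, sd = 2), k_x = rnorm(1, sd = 2),
               eps_x = rnorm(1, sd = 0.5),
               Omega_z = runif(1, 0.5, 2), Omega_x = runif(1, 0.5, 2),
               gamma_z = runif(1, 0, 0.5), gamma_x = runif(1, 0, 0.5))
}

synthetic_trajectory <- function(times, P_A) {
  structure(list(times = times, P_A = P_A, P_D = 1 - P_A),
            class = "trajectory")
}

# Exchange map (E_D <-> E_A, phi_D <-> phi_A, u_z -> -u_z, p_z -> -p_z)
swap_params <- function(p) {
  dimer_params(E_D = p$E_A, E_A = p$E_D, k_z = p$k_z, k_x = p$k_x,
               eps_x = p$eps_x, Omega_z = p$Omega_z, Omega_x = p$Omega_x,
               gamma_z = p$gamma_z, gamma_x = p$gamma_x)
}

swap_state <- function(s) {
  system_state(phi_D = s$phi_A, phi_A = s$phi_D,
               u_z = -s$u_z, u_x = s$u_x,
               p_z = -s$p_z, p_x = s$p_x, t = s$t)
}
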
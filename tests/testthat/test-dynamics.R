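near_tet <- regime_preset("near_tet")$params

test_that("the equilibrium initial condition follows the stationary formulas", {
  p <- dimer_params(k_z = 1.3, k_x = 0.7, Omega_z = 1.1, Omega_x = 0.9)
  s <- initial_state(p, "donor")
  expect_identical(s$u_x, 0)                       # bond order vanishes exactly
  expect_equal(s$u_z, p$k_z / p$Omega_z^2)         # -(k_z/Oz^2) * (0 - 1)
  expect_equal(Mod(s$phi_D)^2 + Mod(s$phi_A)^2, 1)
  sa <- initial_state(p, "acceptor")
  expect_equal(sa$u_z, -p$k_z / p$Omega_z^2)
  expect_equal(initial_state(dimer_params(), "donor")$u_z, 1)
})

test_that("undamped deterministic runs conserve the total energy", {
  p <- dimer_params(E_D = 0.5, eps_x = -0.001, gamma_z = 0, gamma_x = 0)
  tr <- suppressWarnings(
    integrate_dimer(initial_state(p, "donor"), p,
                    config = integrator_config(t_max = 50)))
  expect_lt(max(abs(tr$energy - tr$energy[1])), 1e-8)
})

test_that("damped runs dissipate at the rate -gamma_z*pz^2 - gamma_x*px^2", {
  tr <- suppressWarnings(
    integrate_dimer(initial_state(near_tet, "donor"), near_tet,
                    config = integrator_config(t_max = 5, stride = 1)))
  expect_true(all(diff(tr$energy) <= 1e-12))       # monotone non-increasing
  n <- length(tr$times)
  i <- 2:(n - 1)
  dHdt <- (tr$energy[i + 1] - tr$energy[i - 1]) / (2 * tr$config$dt)
  power <- -near_tet$gamma_z * tr$p_z[i]^2 - near_tet$gamma_x * tr$p_x[i]^2
  expect_lt(max(abs(dHdt - power)), 1e-4)
})

test_that("deterministic norm drift stays below 1e-6 on all presets", {
  for (nm in c("tet", "near_tet", "marcus_normal", "marcus_inverted", "away")) {
    p <- regime_preset(nm)$params
    tr <- suppressWarnings(
      integrate_dimer(initial_state(p, "donor"), p,
                      config = integrator_config(t_max = 1000)))
    expect_lt(tr$max_norm_dev, 1e-6)
  }
})

test_that("noisy runs are reproducible by seed and differ across seeds", {
  p <- regime_preset("tet")$params
  cfg <- integrator_config(t_max = 5)
  a <- integrate_dimer(initial_state(p, "donor"), p, noise_model(1, 7), cfg)
  b <- integrate_dimer(initial_state(p, "donor"), p, noise_model(1, 7), cfg)
  c <- integrate_dimer(initial_state(p, "donor"), p, noise_model(1, 8), cfg)
  expect_identical(a$P_A, b$P_A)
  expect_identical(a$u_z, b$u_z)
  expect_false(identical(a$P_A, c$P_A))
})

test_that("zero temperature consumes no random numbers", {
  p <- regime_preset("tet")$params
  set.seed(123)
  before <- .Random.seed
  invisible(integrate_dimer(initial_state(p, "donor"), p, noise_model(0),
                            integrator_config(t_max = 1)))
  expect_identical(.Random.seed, before)
})

test_that("halving the step shrinks the trajectory error by ~2^5", {
  p <- dimer_params(E_D = 0.5, eps_x = -0.001, gamma_z = 0, gamma_x = 0)
  s0 <- initial_state(p, "donor")
  final_phi <- function(dt) {
    tr <- suppressWarnings(
      integrate_dimer(s0, p, config = integrator_config(dt = dt, t_max = 10,
                                                        stride = 1e9)))
    c(tr$phi_D[length(tr$phi_D)], tr$phi_A[length(tr$phi_A)])
  }
  ref <- final_phi(0.0025)
  e1 <- max(Mod(final_phi(0.04) - ref))
  e2 <- max(Mod(final_phi(0.02) - ref))
  expect_lt(e2, e1 / 16)   # 5th-order: factor 32, allow discretization slack
})

test_that("a decoupled damped mode equilibrates to the equipartition value", {
  p <- dimer_params(k_z = 0, k_x = 0, gamma_z = 0.5, gamma_x = 0.5)
  kBT <- 0.8
  tr <- integrate_dimer(initial_state(p, "donor"), p, noise_model(kBT, 7),
                        integrator_config(t_max = 2000, stride = 10))
  sel <- tr$times >= 200
  vz <- 0.5 * p$Omega_z^2 * mean(tr$u_z[sel]^2)
  vx <- 0.5 * p$Omega_x^2 * mean(tr$u_x[sel]^2)
  expect_lt(abs(vz - kBT / 2), 0.15 * kBT / 2)
  expect_lt(abs(vx - kBT / 2), 0.15 * kBT / 2)
})

test_that("exchange symmetry: swapped parameters mirror the occupation series", {
  p <- near_tet
  tra <- suppressWarnings(
    integrate_dimer(initial_state(p, "donor"), p,
                    config = integrator_config(t_max = 30)))
  trb <- suppressWarnings(
    integrate_dimer(initial_state(swap_params(p), "acceptor"), swap_params(p),
                    config = integrator_config(t_max = 30)))
  expect_equal(trb$P_D, tra$P_A, tolerance = 1e-10)
  expect_equal(trb$P_A, tra$P_D, tolerance = 1e-10)
})

test_that("norm guard, renormalization option and input validation work", {
  p <- regime_preset("tet")$params
  bad <- structure(list(phi_D = 0.9 + 0i, phi_A = 0 + 0i, u_z = 0, u_x = 0,
                        p_z = 0, p_x = 0, t = 0), class = "system_state")
  expect_error(integrate_dimer(bad, p), "normalized")
  tr <- integrate_dimer(initial_state(p, "donor"), p, noise_model(1.5, 3),
                        integrator_config(t_max = 5, renormalize = TRUE))
  expect_lt(abs(tr$final_norm - 1), 1e-12)
  expect_error(integrator_config(dt = -0.1))
  expect_error(noise_model(kBT = -1))
})

test_that("a sign change of the transfer integral is flagged", {
  expect_warning(
    integrate_dimer(initial_state(near_tet, "donor"), near_tet,
                    config = integrator_config(t_max = 20)),
    "transfer integral")
  expect_error(
    integrate_dimer(initial_state(near_tet, "donor"), near_tet,
                    config = integrator_config(t_max = 20,
                                               strict_transfer_sign = TRUE)),
    "transfer integral")
})

test_that("ensembles reproduce single runs and degenerate without noise", {
  p <- regime_preset("tet")$params
  cfg <- integrator_config(t_max = 5)
  ens <- run_ensemble(p, 1, 1, base_seed = 42, cfg)
  single <- integrate_dimer(initial_state(p, "donor"), p, noise_model(1, 42),
                            cfg)
  expect_identical(ens[[1]]$P_A, single$P_A)
  ens0 <- run_ensemble(p, 0, 5, base_seed = 1, cfg)
  for (i in 2:5) expect_identical(ens0[[i]]$P_A, ens0[[1]]$P_A)
})
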
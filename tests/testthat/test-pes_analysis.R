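test_that("adiabatic surfaces match the eigensolver plus harmonic offset", {
  p <- dimer_params(E_D = 0.6, E_A = -0.1, k_z = 1.3, k_x = 0.8, eps_x = -0.15)
  ax <- seq(-2, 2, length.out = 41)
  g <- adiabatic_surfaces(p, ax, ax)
  err <- 0
  for (i in seq_along(ax)) for (j in seq_along(ax)) {
    ev <- eigen(electronic_matrix(ax[i], ax[j], p), symmetric = TRUE)$values
    harm <- 0.5 * p$Omega_z^2 * ax[j]^2 + 0.5 * p$Omega_x^2 * ax[i]^2
    err <- max(err, abs(g$lower[i, j] - (harm + min(ev))),
               abs(g$upper[i, j] - (harm + max(ev))))
  }
  expect_lt(err, 1e-10)
  expect_true(all(g$upper >= g$lower))
})

test_that("symmetric TET surfaces touch at the origin with known values", {
  p <- dimer_params(gamma_z = 0, gamma_x = 0)
  g <- adiabatic_surfaces(p, ux_axis = c(-1, 0, 1), uz_axis = c(-1, 0, 1))
  expect_equal(g$lower[2, 2], 0)
  expect_equal(g$upper[2, 2], 0)
  # at (ux=0, uz=1): 1/2 -+ 1
  expect_equal(g$lower[2, 3], -0.5)
  expect_equal(g$upper[2, 3], 1.5)
})

test_that("conical point location and gap follow the degeneracy conditions", {
  expect_equal(unclass(conical_point(dimer_params()))[c("ux_star", "uz_star")],
               list(ux_star = 0, uz_star = 0))
  cp <- conical_point(dimer_params(E_D = 0.5))
  expect_equal(cp$ux_star, 0)
  expect_equal(cp$uz_star, 0.25)    # shift only along uz
  cp2 <- conical_point(dimer_params(eps_x = -0.001))
  expect_equal(cp2$ux_star, 0.001)
  expect_equal(cp2$uz_star, 0)
  expect_lt(cp2$gap, 1e-12)
  expect_error(conical_point(dimer_params(k_z = 0)), "conical")
})

test_that("reduced potential F is flat under TET and matches hand values", {
  rho <- seq(0, 1, length.out = 1001)
  Ftet <- reduced_potential_F(rho, dimer_params())
  expect_lt(max(Ftet) - min(Ftet), 1e-12)
  expect_equal(Ftet[1], 0 - 0.5)  # E_D - k_z^2/(2 Omega_z^2)
  p <- dimer_params(E_D = 0, E_A = 0.5)
  expect_equal(reduced_potential_F(0, p), -0.5)
  expect_equal(reduced_potential_F(1, p), 0)
  expect_error(reduced_potential_F(1.2, p), "rho")
})

test_that("F equals the phase-minimum of the anti-adiabatic energy", {
  set.seed(51)
  phases <- seq(-pi, pi, length.out = 2001)
  for (i in 1:10) {
    p <- random_params()
    for (rho in c(0, 0.123, 0.5, 0.87, 1)) {
      expect_equal(reduced_potential_F(rho, p),
                   min(antiadiabatic_energy(rho, phases, p)),
                   tolerance = 1e-6)
    }
  }
})

test_that("anti-adiabatic energy endpoints and minimizing phase behave", {
  p <- dimer_params(E_D = 0.4, E_A = -0.2, eps_x = -0.3, k_z = 1.2)
  cz <- p$k_z^2 / p$Omega_z^2
  expect_equal(antiadiabatic_energy(0, 1.234, p), p$E_D - cz / 2)
  expect_equal(antiadiabatic_energy(1, -2.1, p), p$E_A - cz / 2)
  phases <- seq(-pi, pi, length.out = 4001)
  # eps_x < 0: minimizing phase 0; eps_x > 0: minimizing phase pi
  h_neg <- antiadiabatic_energy(0.3, phases, p)
  expect_lt(abs(phases[which.min(h_neg)]), 2e-3)
  p_pos <- dimer_params(E_D = 0.4, E_A = -0.2, eps_x = 0.3, k_z = 1.2)
  h_pos <- antiadiabatic_energy(0.3, phases, p_pos)
  expect_lt(pi - abs(phases[which.min(h_pos)]), 2e-3)
})

test_that("regimes classify as TET, near-TET, Marcus normal/inverted, away", {
  expect_identical(classify_regime(dimer_params()), "tet")
  expect_identical(classify_regime(regime_preset("near_tet")$params),
                   "near_tet")
  expect_identical(classify_regime(regime_preset("marcus_normal")$params),
                   "marcus_normal")
  expect_identical(classify_regime(regime_preset("marcus_inverted")$params),
                   "marcus_inverted")
  expect_identical(classify_regime(regime_preset("away")$params), "away")
})

test_that("the Marcus normal preset has a genuine double-well reduced potential", {
  p <- regime_preset("marcus_normal")$params
  rho <- seq(0, 1, length.out = 2001)
  f <- reduced_potential_F(rho, p)
  interior <- 2:(length(rho) - 1)
  minima <- interior[f[interior] < f[interior - 1] & f[interior] < f[interior + 1]]
  expect_gte(length(minima), 2)         # two wells separated by a barrier
  expect_gt(max(f) , max(f[minima]))    # barrier above both wells
  # crossing of the diabatic parabolas lies between their minima
  uz_cross <- (p$E_D - p$E_A) / (2 * p$k_z)
  expect_lt(abs(uz_cross), abs(p$k_z) / p$Omega_z^2)
})

test_that("the gap around the conical point is cylindrically symmetric under TET", {
  rp <- reaction_path(dimer_params(), radius = 0.5, n_angles = 720)
  expect_lt(max(rp$gap) - min(rp$gap), 1e-9)
  expect_equal(rp$gap[1], 2 * 0.5)   # 2 r k_z / Omega_z
  # balance condition holds even with unequal frequencies
  rp2 <- reaction_path(dimer_params(k_z = 2, Omega_z = 2), radius = 0.3,
                       n_angles = 360)
  expect_lt(max(rp2$gap) - min(rp2$gap), 1e-9)
})

test_that("breaking E_A = E_D tilts the surfaces along the circular path", {
  p <- dimer_params(E_D = 0.5, gamma_z = 0)
  rp <- reaction_path(p, radius = 0.4, n_angles = 721)
  expect_lt(max(rp$gap) - min(rp$gap), 1e-9)   # gap still constant (balance)
  # surface energies vary ~ sin(angle): monotone over the rising quarter-circle
  expect_gt(max(rp$lower) - min(rp$lower), 1e-3)
  rising <- rp$lower[rp$angle >= 0 & rp$angle <= pi / 2]
  expect_true(all(diff(rising) > 0))
})

test_that("the gap shrinks to zero with the circle radius", {
  p <- dimer_params(E_D = 0.2, eps_x = -0.05)
  for (r in c(1e-2, 1e-4, 1e-6)) {
    rp <- reaction_path(p, radius = r, n_angles = 90)
    expect_lt(max(rp$gap), 3 * r)
  }
})

test_that("away from TET the gap can close only on the ux = -eps_x/kx line", {
  p <- regime_preset("away")$params
  ax <- seq(-3, 3, length.out = 121)   # includes ux = 0.1 = -eps_x/kx node
  g <- adiabatic_surfaces(p, ax, ax)
  gap <- g$upper - g$lower
  on_line <- abs(ax - (-p$eps_x / p$k_x)) < 1e-12
  expect_true(any(on_line))
  expect_gt(min(gap[!on_line, ]), 0.01)  # bounded away from zero off the line
  cp <- conical_point(p)
  expect_equal(cp$gap, 0)
})

test_that("PES grids export to CSV and degenerate axes are rejected", {
  g <- adiabatic_surfaces(dimer_params(), seq(-1, 1, length.out = 5),
                          seq(-1, 1, length.out = 4))
  f <- tempfile(fileext = ".csv")
  write_pes_csv(g, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 20)
  expect_equal(max(abs(df$upper - df$lower - as.vector(g$upper - g$lower))), 0)
  expect_error(adiabatic_surfaces(dimer_params(), c(0, 0, 1), c(0, 1)),
               "increasing")
})
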
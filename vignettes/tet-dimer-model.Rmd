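---
title: "The donor-acceptor dimer model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The donor-acceptor dimer model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetdimer)
```

## The model and its assumptions

An electron (or any two-state quantum excitation) is shared between a donor
and an acceptor orbital, $\varphi_D(t)\,|D\rangle + \varphi_A(t)\,|A\rangle$
with $|\varphi_D|^2 + |\varphi_A|^2 = 1$. Its environment is reduced to two
classical harmonic coordinates with unit mass: an antisymmetric mode $u_z$
coupled to the charge imbalance $|\varphi_A|^2 - |\varphi_D|^2$ (it shifts
the effective on-site energies, the "ionic" interaction), and a symmetric
mode $u_x$ coupled to the bond order
$2\,\mathrm{Re}(\varphi_D^\ast\varphi_A)$ (it modulates the orbital overlap
and hence the transfer integral, the "covalent" interaction). The total
energy is the Hamiltonian evaluated by `total_energy()`; the coupled
equations of motion (`equations_of_motion()`) are the Hamilton equations of
that Hamiltonian with Langevin damping and noise added to each mode:

$$i\dot\varphi_D = (E_D - k_z u_z)\varphi_D + (\epsilon_x + k_x u_x)\varphi_A$$
$$i\dot\varphi_A = (E_A + k_z u_z)\varphi_A + (\epsilon_x + k_x u_x)\varphi_D$$
$$\ddot u_z + \gamma_z\dot u_z + \Omega_z^2 u_z + k_z(|\varphi_A|^2-|\varphi_D|^2) = \eta_z(t)$$
$$\ddot u_x + \gamma_x\dot u_x + \Omega_x^2 u_x + 2k_x\mathrm{Re}(\varphi_D^\ast\varphi_A) = \eta_x(t)$$

This is an Ehrenfest-like mixed quantum-classical treatment: the electron is
quantum, the nuclei classical, and the infinite bath is replaced by damping
plus white noise obeying the fluctuation-dissipation relation
$\langle\eta(t)\eta(t')\rangle = 2\gamma k_BT\,\delta(t-t')$. Everything is
expressed in rescaled units with $\hbar = 1$: energies and frequencies share
one unit, time is its reciprocal, and temperature enters only as the energy
$k_BT$. A physical anchor for the energy unit is the scale of elementary
biochemical reaction energies (a few tenths of an eV), but nothing in the
package depends on that identification.

Two textual ambiguities in the printed source equations were resolved on
consistency grounds, and the package documents them as model definitions:
the acceptor on-site term is $E_A|\varphi_A|^2$ (the variant
$E_A|\varphi_D|^2$ is inconsistent with the equations of motion and with
normalization), and the mode-force terms use the moduli squared
$|\varphi_A|^2 - |\varphi_D|^2$ (the gradient of the Hamiltonian coupling
term), not the squares of the complex amplitudes.

## Static analysis: surfaces, conical intersection, reduced potential

At frozen nuclear coordinates the electronic Hamiltonian is the real
symmetric $2\times 2$ matrix returned by `electronic_matrix()`. Its
eigenvalues plus the harmonic energy give the two adiabatic surfaces in
closed form (`adiabatic_surfaces()`); the closed form is verified against a
numerical eigensolver in the tests to below $10^{-10}$. The surfaces touch
at the conical intersection $u_x^\ast = -\epsilon_x/k_x$,
$u_z^\ast = (E_D - E_A)/(2k_z)$, which exists as an isolated point only when
both couplings are nonzero; `conical_point()` errors otherwise.

In the anti-adiabatic (fast-mode) limit the modes follow the electron
instantaneously and the energy reduces to $H_{aa}(\rho, \Delta)$ over the
acceptor occupation $\rho = |\varphi_A|^2$ and relative phase $\Delta$
(`antiadiabatic_energy()`). Minimizing over the phase ($\Delta = 0$ for
$\epsilon_x < 0$, $\Delta = \pi$ for $\epsilon_x > 0$) gives the reduced
potential $F(\rho)$ (`reduced_potential_F()`). The $\epsilon_x$ term
carries the amplitude $\sqrt{\rho(1-\rho)}$ — this is forced by $H_{aa}$
being the expectation value of the Hamiltonian at
$\varphi_A = \sqrt{\rho}\,e^{i\alpha_A}$ — and the tests verify
$F(\rho) = \min_\Delta H_{aa}(\rho, \Delta)$ against a dense phase grid.
Under the TET conditions

$$E_A = E_D, \qquad k_z^2/\Omega_z^2 = k_x^2/\Omega_x^2, \qquad \epsilon_x = 0$$

every $\rho$-dependent term of $F$ cancels algebraically: the ground state
is degenerate along the whole transfer path, which is the mechanism behind
barrierless, temperature-independent transfer. `check_tet()` reports the
three residuals; the strict tolerance defaults to $10^{-9}$.

### Regime classification

`classify_regime()` proceeds in order of precedence: `tet` (all residuals
within $10^{-9}$); `near_tet` (balance and bare-transfer residuals within
0.05 while $0 < |E_D - E_A| \le 1$ — the regime of small symmetry breaking
that still supports fast transfer); `away` (balance residual $\ge 10$, the
strongly imbalanced regime); otherwise Marcus-type, discriminated by the
diabatic parabolas restricted to $u_x = 0$:
$V_D = \tfrac12\Omega_z^2u_z^2 + E_D - k_zu_z$ and
$V_A = \tfrac12\Omega_z^2u_z^2 + E_A + k_zu_z$ cross at
$u_z^\ast = (E_D-E_A)/(2k_z)$, and the label is `marcus_normal` when the
crossing lies strictly between the parabola minima $\pm k_z/\Omega_z^2$,
`marcus_inverted` when it lies outside. The diabatic construction is used
(rather than counting wells of $F(\rho)$) because in the inverted regime
$F$ is monotone apart from the boundary wells created by the
$\sqrt{\rho(1-\rho)}$ term, so a well-counting rule cannot see the
normal/inverted distinction. The thresholds (0.05, 1, 10) are package
choices, configurable in the call.

## Dynamics: the stochastic integrator

`integrate_dimer()` advances the 8 real components (4 for the amplitudes, 4
for the modes) with the Dormand-Prince 5(4) pair at a **fixed** step,
$\delta t = 0.001$ by default. Fixed, because the thermal force is
discretized as one Gaussian draw per macro-step with variance
$2\gamma k_BT/\delta t$ (the Euler-Maruyama-consistent scaling of white
noise), held frozen across the internal stages; adaptive step-size control
would silently change that variance. The embedded 4th-order solution is
evaluated but used only as an accuracy diagnostic (`max_embed_err`). Draws
are ordered $(\eta_z, \eta_x)$ per step through R's own RNG, so a run is
fully determined by `set.seed`-style integer seeds, and at $k_BT = 0$ no
random numbers are consumed at all.

Numerical safeguards:

* **Norm drift.** The electronic norm is conserved analytically (the
  generator is Hermitian); numerically it drifts by integrator error only.
  By default the drift is monitored and a hard error is raised (naming the
  offending time) if it exceeds `norm_tol` ($10^{-6}$); optional per-step
  renormalization exists for very long noisy runs but is off by default,
  because renormalizing would mask integrator error instead of exposing it.
  In practice the drift is $\sim 10^{-13}$ over $10^6$ steps on all presets.
* **Energy budget.** With $\gamma > 0$ and no noise the total energy obeys
  $\dot H = -\gamma_z\dot u_z^2 - \gamma_x\dot u_x^2$; the tests verify
  the identity against finite differences of the energy series and exact
  conservation ($<10^{-8}$) at $\gamma = 0$.
* **Linear-coupling guard.** The linear transfer integral
  $\epsilon_x + k_xu_x$ is an expansion of an exponential overlap and
  becomes unphysical if it changes sign; the integrator counts sign changes
  and warns (or errors, under `strict_transfer_sign`). With
  $\epsilon_x = -0.001$ sign changes are unavoidable and harmless in the
  regimes studied here; the flag exists to make the artifact visible.
* **Degenerate inputs.** Non-normalized initial states, non-finite states
  during integration, non-positive frequencies and negative dampings are
  all rejected with diagnostics rather than propagated.

The equilibrium initial condition (`initial_state()`) localizes the electron
on one site with zero phase and places each mode at the stationary point of
its driven oscillator: $u_x = 0$ exactly, $u_z = \mp k_z/\Omega_z^2$. A
consequence worth stating plainly: for the **pure** TET preset
($\epsilon_x = 0$) the donor-localized equilibrium start is an exact
stationary point of the deterministic flow — every force cancels, and the
test suite asserts this. Zero-temperature transfer therefore cannot start
from rest in the pure preset; it is demonstrated in the near-TET preset
($\epsilon_x = -0.001$, $E_D - E_A = 0.5$), where the tiny bare transfer
integral seeds the dynamics and the positive reaction energy plus damping
make the transfer irreversible. The pure preset shows its TET character
under noise, where any $k_BT > 0$ un-pins the stationary start.

## Presets as study conditions

The built-in presets (`regime_preset()`) are the package's fixed study
conditions, not tuning knobs:

| preset | $E_D$ | $E_A$ | $k_z$ | $k_x$ | $\epsilon_x$ | regime |
|---|---|---|---|---|---|---|
| `tet` | 0 | 0 | 1 | 1 | 0 | exact degeneracy |
| `near_tet` | 0.5 | 0 | 1 | 1 | $-0.001$ | dynamical TET |
| `marcus_normal` | 1 | 0 | 1 | 0.2 | $-0.05$ | activated, normal |
| `marcus_inverted` | 3 | 0 | 1 | 0.2 | $-0.05$ | activated, inverted |
| `away` | 0.5 | 0 | 5 | 1 | $-0.1$ | 25-fold imbalance |

with $\Omega_z = \Omega_x = 1$ and $\gamma_z = \gamma_x = 0.1$ everywhere.
The near-TET values sit inside the regime window
$0 < E_D - E_A \le 1$ with $\epsilon_x = -0.001$; the `away` preset realizes
the 25-fold coupling-balance mismatch; the damping 0.1 puts the
zero-temperature near-TET transfer in the underdamped-to-crossover window
(transfer time $\approx 20$ time units to first reach $P_A = 0.9$), and the
default horizon $t_{\max} = 200$ is about ten times that transfer time.
The Marcus presets use a small covalent coupling ($k_x = 0.2$), consistent
with the convention that Marcus theory neglects it.

What these synthetic conditions do **not** emulate: quantum nuclei (no
zero-point motion or tunneling of the modes), a structured many-oscillator
bath (no memory friction), the exponential distance dependence of the
transfer integral (linear expansion with the sign guard instead), and any
system-specific parameterization of a real donor-acceptor pair. Passing
tests therefore validate the model's internal consistency and its kinetic
phenomenology — not quantitative predictions for a particular molecule.

## Kinetic observables and the Arrhenius analysis

For each trajectory `transfer_summary()` reports $p_{\max} = \max_t P_A(t)$
and the transfer time $\tau$, the earliest sampled time attaining that
maximum (ties broken toward the earliest sample). `ensemble_stats()` gives
pointwise means and population standard deviations across independently
seeded runs; `temperature_sweep()` repeats ensembles across temperatures
with disjoint seed blocks so the whole sweep is reproducible from one base
seed.

Rate definition: the package fits the Arrhenius law
$k_{ET} = A e^{-E_a/k_BT}$ by least squares of $\ln k_{ET}$ on $1/k_BT$
(`arrhenius_fit()`), with $k_{ET}$ the reciprocal of the mean
**first-passage time** to the completion threshold ($P_A \ge 0.9$ by
default), averaged over completed runs only so blocked runs cannot
contribute spurious finite rates. The simpler surrogate $1/\bar\tau$ using
the time-of-maximum is available (`rate_def = "inverse_tau"`) but is not the
default, for a measurable reason: in a long noisy run the running maximum of
$P_A$ keeps being re-attained by later fluctuation peaks, so $\tau$ is
distributed over the whole post-transfer window and its mean saturates near
the horizon length regardless of temperature — on the `away` preset sweep it
yields $r^2 \approx 0.3$ where the first-passage rate yields
$r^2 \approx 0.97$. The first-passage time is the quantity that measures the
activated waiting process.

The activated-kinetics study conditions on the `away` preset are
$k_BT \in \{2.5, 3, 3.5, 4, 5, 6\}$ with 40 runs per temperature and
$t_{\max} = 1000$: the preset's diabatic barrier is
$\tfrac12\Omega_z^2(u_z^\ast - k_z/\Omega_z^2)^2 \approx 12$ energy units,
so below $k_BT \approx 2.5$ the mean waiting time exceeds the horizon and
the first-passage estimate would be censored at $t_{\max}$, biasing the
fit; above $k_BT \approx 6$ the waiting time approaches the prefactor scale
and the Arrhenius regime ends. Within the window the fitted line is clean
(the acceptance suite asserts $r^2 > 0.9$).

## Problem sizes and runtime

The test suite runs deterministic trajectories of up to $10^6$ steps, a
50-member ensemble at $k_BT = 1.5$ over $2\times10^5$ steps for the
late-time symmetric average, a $2\times10^6$-step equipartition check of
the bath discretization ($\tfrac12\Omega^2\langle u^2\rangle \to k_BT/2$ on
a mode decoupled from the electron), and the 240-run activated sweep; the
whole suite completes in about a minute on one core thanks to the compiled
integrator. These sizes were chosen to make sampling errors comfortably
smaller than the asserted tolerances (e.g. the 50-run late-time average has
a standard error of $\approx 0.006$ against a 3-standard-error band around
0.5).

## Known limitations

* Ehrenfest-style mean-field dynamics cannot describe wave-packet branching
  on the two surfaces; it is adequate here because the interesting regimes
  funnel through the conical intersection or a single activated crossing.
* The white-noise Langevin bath has no memory; damping values are treated
  as free parameters ($\gamma = 0.1$ by default) since no physical spectral
  density is modeled.
* The $F(\rho)$ analysis is anti-adiabatic (fast modes); for
  $\Omega \sim 1$ it is a guide to the energy landscape, not a quantitative
  free-energy surface.
* First-passage statistics near the edges of the activated window are
  horizon-limited; widen `t_max` before trusting rates at lower
  temperatures.
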
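Package: tetdimer
Title: Targeted Electron Transfer in a Donor-Acceptor Dimer with Langevin
    Phonon Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mixed quantum-classical electron transfer in a two-site
    donor-acceptor dimer whose electronic amplitudes are coupled to two classical
    vibrational modes (an antisymmetric "ionic" mode and a symmetric "covalent"
    mode), each attached to a Langevin bath. Provides the static potential-energy
    surface analysis that exposes the conical intersection and the targeted-energy-
    transfer (TET) degeneracy conditions, a fixed-step stochastic Runge-Kutta 5(4)
    integrator for the Langevin equations of motion, and kinetic observables
    (transfer time, maximum acceptor occupation, ensemble statistics, temperature
    sweeps and Arrhenius fits) used to contrast resonant TET with thermally
    activated Marcus-type transfer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
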
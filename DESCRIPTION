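Package: vibraman
Title: Nonadiabatic Vibrational Resonance Raman and Absorption Spectra from
    Linear Vibronic Coupling Models
Version: 0.1.0
Authors@R:
    person("Vibraman", "Developers", email = "vibraman@example.org",
           role = c("aut", "cre"))
Description: Computes vibrational resonance Raman (vRR) and absorption spectra
    of molecules described by linear vibronic coupling (LVC) models with
    several close-lying, possibly coupled excited electronic states. Exact
    wavepacket propagation in a truncated harmonic-oscillator product basis
    yields time-dependent cross-correlation functions whose damped
    half-Fourier transforms give the transition polarizability tensor; vRR
    intensities follow from its rotational invariants. Three comparison
    protocols are provided (fully nonadiabatic LVC, uncoupled with
    interference VG-Int, uncoupled without interference VG-Sum), along with
    closed-form single-state vertical-gradient correlation functions, a
    sum-over-states oracle, Herzberg-Teller dipole expansions, a seeded
    synthetic-model generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
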
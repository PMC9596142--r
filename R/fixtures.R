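# Hand-built few-mode fixture models. These are the canonical desk-scale
# test systems: small enough for exact diagonalization, rich enough to
# exercise displacement, interstate coupling, symmetry selection rules and
# interference between quasi-resonant states.

#' Canonical fixture models
#'
#' @description
#' * `fixture_displaced()`: one mode, one bright state, Huang-Rhys factor
#'   `S` (default 0.5) -- the textbook displaced oscillator.
#' * `fixture_three_mode()`: three totally symmetric modes, one bright
#'   state, mixed displacements -- the single-state vertical-gradient
#'   reference system.
#' * `fixture_conical()`: two modes / two states in conical-intersection
#'   style, one tuning mode (opposite gradients) and one coupling mode
#'   carrying the single nonzero interstate coupling component.
#' * `fixture_cs()`: Cs-symmetry three-state model -- a bright A' state, a
#'   weak ("dark") A'' state, a second A' state -- with an A'' coupling
#'   mode linking A' and A''. Constructed to pass [symmetry_audit()] with
#'   zero warnings; the A'' fundamental is Raman-active only through the
#'   interstate coupling.
#'
#' @param S Huang-Rhys factor of the displaced mode.
#' @param energy vertical energy in eV.
#' @param dipole transition dipole 3-vector.
#' @return an `lvc_model`.
#' @export
fixture_displaced <- function(S = 0.5, energy = 4.5, dipole = c(1, 0, 0)) {
  omega <- 1200 / .CM1_PER_EV
  lam <- omega * sqrt(2 * S)
  lvc_model(omega, list(lvc_state("S1", energy, lam, dipole)))
}

#' @rdname fixture_displaced
#' @export
fixture_three_mode <- function(energy = 4.8, dipole = c(1, 0.3, 0)) {
  omega <- c(600, 1200, 1600) / .CM1_PER_EV
  S <- c(0.3, 0.5, 0.2)
  lam <- omega * sqrt(2 * S)
  lvc_model(omega, list(lvc_state("S1", energy, lam, dipole)))
}

#' @rdname fixture_displaced
#' @param coupling interstate coupling gradient on the coupling mode (eV).
#' @export
fixture_conical <- function(coupling = 0.08) {
  omega <- c(1400, 900) / .CM1_PER_EV
  lam1 <- c(omega[1] * sqrt(2 * 0.4), 0)
  lam2 <- c(-omega[1] * sqrt(2 * 0.3), 0)
  states <- list(
    lvc_state("S1", 4.8, lam1, c(1, 0, 0)),
    lvc_state("S2", 5.2, lam2, c(0.6, 0.2, 0))
  )
  lvc_model(omega, states,
            list(lvc_coupling("S1", "S2", c(0, coupling))))
}

#' @rdname fixture_displaced
#' @param coupling_a2 A'-A'' coupling gradient on the A'' mode (eV); set to
#'   0 to switch the nonadiabatic activation of the A'' mode off.
#' @param dark_dipole transition dipole of the weak A'' state.
#' @export
fixture_cs <- function(coupling_a2 = 0.08, dark_dipole = c(0, 0, 0.05)) {
  omega <- c(1300, 1600, 900) / .CM1_PER_EV # modes: A', A', A''
  msym <- c("A'", "A'", "A''")
  grad_bright <- c(omega[1] * sqrt(2 * 0.4), omega[2] * sqrt(2 * 0.25), 0)
  grad_dark <- c(omega[1] * sqrt(2 * 0.1), 0, 0)
  grad_b2 <- c(0, omega[2] * sqrt(2 * 0.3), 0)
  states <- list(
    lvc_state("pipi1", 5.0, grad_bright, c(1, 0, 0), symmetry = "A'"),
    lvc_state("npi", 5.25, grad_dark, dark_dipole, symmetry = "A''"),
    lvc_state("pipi2", 5.6, grad_b2, c(0.5, 0.3, 0), symmetry = "A'")
  )
  couplings <- list(
    lvc_coupling("pipi1", "npi", c(0, 0, coupling_a2)),
    lvc_coupling("pipi1", "pipi2", c(0.05, 0, 0))
  )
  lvc_model(omega, states, couplings, mode_symmetry = msym)
}

#' Write the canonical fixture set to model files
#'
#' Emits the four hand-built fixtures plus `n_random` seeded random models
#' as JSON model files. Deterministic for a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the random members.
#' @param n_random number of random 2-mode/2-state models to include.
#' @return character vector of the files written.
#' @export
write_fixture_set <- function(dir, seed = 1L, n_random = 2L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    displaced_1mode = file.path(dir, "displaced_1mode.json"),
    three_mode = file.path(dir, "three_mode.json"),
    conical_2mode = file.path(dir, "conical_2mode.json"),
    cs_three_state = file.path(dir, "cs_three_state.json")
  )
  write_lvc_model(fixture_displaced(), files[["displaced_1mode"]])
  write_lvc_model(fixture_three_mode(), files[["three_mode"]])
  write_lvc_model(fixture_conical(), files[["conical_2mode"]])
  write_lvc_model(fixture_cs(), files[["cs_three_state"]])
  for (i in seq_len(n_random)) {
    f <- file.path(dir, sprintf("random_%02d.json", i))
    write_lvc_model(random_model(2, 2, seed = seed + i - 1L), f)
    files[[sprintf("random_%02d", i)]] <- f
  }
  files
}
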
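# Cross-correlation functions and the sum-over-states oracle.
#
# For a propagation started as |Psi(0)> = |d_m; 0>, the quantities feeding
# the Raman pipeline are
#
#   C^{km}_f(t) = <d_k; 0 + 1_f | exp(-i H t) | d_m; 0>
#   C^{km}_0(t) = <d_k; 0       | exp(-i H t) | d_m; 0>   (absorption)
#
# i.e. the amplitudes of the basis elements (k, e_f) and (k, 0) along the
# trajectory. No extra phase factor is attached here; the e^{+i E_g0 t}
# factor enters at half-Fourier-transform time.

#' Extract cross-correlation functions from a trajectory
#'
#' Reads off `C^{km}_f(t)` for every electronic state `k` and every
#' fundamental `f` (plus `f = 0`, the autocorrelation row used for
#' absorption) as amplitudes of the corresponding basis elements.
#'
#' @param traj a `wavepacket_trajectory` from [propagate()], started from
#'   `|d_m; 0>`.
#' @return a list with elements `tgrid`, `C0` (nstates x ntimes complex
#'   matrix) and `Cf` (nstates x nmodes x ntimes complex array).
#' @export
cross_correlations <- function(traj) {
  basis <- traj$basis
  nt <- length(traj$tgrid)
  ns <- basis$nstates
  nm <- basis$nmodes
  v0 <- .vib_ground(basis)
  vf <- vapply(seq_len(nm), function(f) .vib_fundamental(basis, f),
               integer(1))
  C0 <- matrix(complex(1), ns, nt)
  Cf <- array(complex(1), c(ns, nm, nt))
  for (k in seq_len(ns)) {
    o <- (k - 1L) * basis$nvib
    C0[k, ] <- traj$amp[o + v0, ]
    Cf[k, , ] <- traj$amp[o + vf, , drop = FALSE]
  }
  list(tgrid = traj$tgrid, C0 = C0, Cf = Cf)
}

# Same quantities straight from the eigendecomposition, without storing the
# full trajectory: C_sel(t) = sum_l V[sel, l] c_l exp(-i E_l t) with
# c = V^T psi0. Returns list(C0, Cf) as in cross_correlations().
.cross_correlations_eigen <- function(h, m, tgrid) {
  basis <- h$basis
  eig <- ham_eigen(h)
  nt <- length(tgrid)
  ns <- basis$nstates
  nm <- basis$nmodes
  v0 <- .vib_ground(basis)
  vf <- vapply(seq_len(nm), function(f) .vib_fundamental(basis, f),
               integer(1))
  sel <- as.vector(outer(c(v0, vf), (seq_len(ns) - 1L) * basis$nvib, "+"))
  i0 <- basis_index(basis, m, rep(0L, nm))
  coef <- eig$vectors[sel, , drop = FALSE] *
    rep(eig$vectors[i0, ], each = length(sel))
  C <- matrix(complex(1), length(sel), nt)
  chunk <- max(1L, floor(4e6 / length(eig$values)))
  for (start in seq(1L, nt, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nt)
    C[, idx] <- coef %*% exp(outer(eig$values, tgrid[idx],
                                   function(e, t) -1i * e * t))
  }
  # sel ordering: (f-row within state) fastest over c(0, 1..nmodes)
  C <- array(C, c(nm + 1L, ns, nt))
  list(tgrid = tgrid,
       C0 = array(C[1L, , , drop = FALSE], c(ns, nt)),
       Cf = aperm(array(C[-1L, , , drop = FALSE], c(nm, ns, nt)),
                  c(2L, 1L, 3L)))
}

#' Transition polarizability by explicit sum over vibronic states
#'
#' The brute-force route: diagonalize the full vibronic Hamiltonian and
#' assemble
#' `alpha_{rho sigma}^{f0}(omega_I) = sum_l mu_rho(l; f) mu_sigma(l; 0) /
#'  (E_l - i gamma - E_g0 - omega_I)`
#' with effective moments `mu_rho(l; f) = sum_k mu_rho^{gk} <d_k; 0+1_f|l>`.
#' Serves as the independent oracle for the time-dependent route; the
#' lifetime width `gamma` is state-independent.
#'
#' @param model an `lvc_model`.
#' @param basis a `vibronic_basis` (dimension capped at 4000 for full
#'   diagonalization).
#' @param omega_grid excitation energies omega_I (eV).
#' @param gamma Lorentzian damping (eV, > 0).
#' @param f final-mode index (fundamental `|0 + 1_f>`), or 0 for the
#'   Rayleigh/absorption tensor.
#' @return complex array `3 x 3 x length(omega_grid)`.
#' @export
sum_over_states_alpha <- function(model, basis, omega_grid, gamma, f) {
  stopifnot(gamma > 0)
  h <- build_hamiltonian(model, basis)
  eig <- ham_eigen(h)
  mu <- dipole_matrix(model)
  ns <- basis$nstates
  vf <- if (f == 0) .vib_ground(basis) else .vib_fundamental(basis, f)
  v0 <- .vib_ground(basis)
  rows_f <- (seq_len(ns) - 1L) * basis$nvib + vf
  rows_0 <- (seq_len(ns) - 1L) * basis$nvib + v0
  bf <- mu %*% eig$vectors[rows_f, , drop = FALSE] # 3 x dim
  b0 <- mu %*% eig$vectors[rows_0, , drop = FALSE]
  e0 <- zpe(model)
  out <- array(complex(1), c(3, 3, length(omega_grid)))
  for (iw in seq_along(omega_grid)) {
    denom <- 1 / (eig$values - 1i * gamma - e0 - omega_grid[iw])
    out[, , iw] <- (bf * rep(denom, each = 3)) %*% t(b0)
  }
  out
}

#' Apply a (Herzberg-Teller) transition-dipole operator to a wavepacket
#'
#' Applies `mu(q) = mu0 + sum_j muprime[, j] q_j` with
#' `q_j = (a_j + a_j^dag)/sqrt(2)` to the vibrational amplitudes `psi`,
#' returning one amplitude vector per Cartesian component. The coordinate
#' dependence (`muprime`) is only meaningful for single-state (adiabatic)
#' calculations; in the diabatic LVC picture dipoles are constant.
#'
#' Ladder steps that leave the truncated basis are dropped; the dropped
#' squared amplitude is accumulated per component and reported, never
#' silently ignored.
#'
#' @param mu0 constant (Franck-Condon) dipole, length 3.
#' @param muprime dipole derivatives, 3 x nmodes matrix, or `NULL` for the
#'   pure FC limit.
#' @param psi complex vibrational amplitude vector (length `basis$nvib`).
#' @param basis the `vibronic_basis` describing the vibrational space.
#' @return list with `components` (nvib x 3 complex matrix, one column per
#'   Cartesian component) and `dropped` (length-3 squared amplitude lost to
#'   basis truncation).
#' @export
apply_dipole_operator <- function(mu0, muprime, psi, basis) {
  stopifnot(length(mu0) == 3L, length(psi) == basis$nvib)
  out <- outer(as.complex(psi), as.complex(mu0))
  dropped <- numeric(3)
  if (!is.null(muprime)) {
    muprime <- matrix(muprime, nrow = 3L)
    stopifnot(ncol(muprime) == basis$nmodes)
    for (j in seq_len(basis$nmodes)) {
      if (all(muprime[, j] == 0)) next
      up <- basis$raise[, j]
      amp_up <- sqrt((basis$occ[, j] + 1) / 2)
      ok <- !is.na(up)
      qpsi <- complex(basis$nvib)
      qpsi[up[ok]] <- qpsi[up[ok]] + amp_up[ok] * psi[ok]
      lost <- sum(Mod(amp_up[!ok] * psi[!ok])^2)
      down <- basis$lower[, j]
      okd <- !is.na(down)
      qpsi[down[okd]] <- qpsi[down[okd]] +
        sqrt(basis$occ[okd, j] / 2) * psi[okd]
      for (rho in 1:3) {
        out[, rho] <- out[, rho] + muprime[rho, j] * qpsi
        dropped[rho] <- dropped[rho] + Mod(muprime[rho, j])^2 * lost
      }
    }
  }
  list(components = out, dropped = dropped)
}

#' Check basis convergence of a spectrum computation
#'
#' Recomputes the named observable with the total-quanta cap raised by 2
#' and reports the maximum relative change (normalized by the maximum
#' intensity of the refined result); flags the computation as unconverged
#' when the change exceeds `tol`.
#'
#' @param model an `lvc_model`.
#' @param spec a [basis_spec()] giving the production truncation.
#' @param observable `"vrr"` or `"absorption"`.
#' @param settings a [spectrum_settings()] list; its `n_tot` is overridden
#'   by `spec`.
#' @param tol relative-change threshold (default 1e-3).
#' @param ... passed to [compute_vrr()] / [absorption_spectrum()].
#' @return list with `max_rel_change`, `converged`, and the two truncation
#'   levels compared.
#' @export
convergence_check <- function(model, spec, observable = c("vrr", "absorption"),
                              settings = spectrum_settings(), tol = 1e-3,
                              ...) {
  observable <- match.arg(observable)
  run <- function(n_tot) {
    s <- settings
    s$n_tot <- n_tot
    if (observable == "vrr") {
      compute_vrr(model, protocol = "lvc", settings = s, ...)$intensity
    } else {
      absorption_spectrum(model, protocol = "lvc", settings = s,
                          ...)$intensity
    }
  }
  i1 <- run(spec$n_tot)
  i2 <- run(spec$n_tot + 2L)
  denom <- max(abs(i2))
  change <- if (denom == 0) 0 else max(abs(i1 - i2)) / denom
  list(n_tot = spec$n_tot, n_tot_refined = spec$n_tot + 2L,
       max_rel_change = change, converged = change <= tol, tol = tol)
}
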
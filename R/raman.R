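# The resonance-Raman pipeline: tensor correlation functions, damped
# half-Fourier transform to the transition polarizability, rotational
# invariants, intensities, and the three comparison protocols.
#
#   LVC     full nonadiabatic propagation; interstate couplings and
#           interference between quasi-resonant states both included.
#   VG-Int  couplings zeroed; per-state correlation tensors are summed
#           before the invariants are taken (interference kept).
#   VG-Sum  couplings zeroed; intensities computed per state and then
#           summed (interference discarded).

#' Spectrum computation settings
#'
#' @param gamma_ev Lorentzian damping / lifetime width (eV). 0.04 eV is a
#'   typical homogeneous width; 0.12 eV additionally mimics inhomogeneous
#'   broadening.
#' @param omega_ev explicit excitation-energy grid (eV), or `NULL` to span
#'   `[min E_i - omega_pad_ev, max E_i + omega_pad_ev]` in steps of
#'   `omega_step_ev`.
#' @param omega_step_ev,omega_pad_ev grid construction parameters (eV).
#' @param dt time step in hbar/eV (default 0.05, about 0.033 fs — ample
#'   Nyquist margin for a ~10 eV spectral span).
#' @param tmax propagation length in hbar/eV; default
#'   `max(300 fs, 10 hbar/gamma)` so the damped correlation tail is below
#'   `exp(-10)`.
#' @param n_tot,n_max basis truncation (see [basis_spec()]).
#' @param basis_cap hard cap on the basis dimension.
#' @param vg_route `"analytic"` (closed-form correlation functions) or
#'   `"numerical"` (per-state propagation) for the VG protocols at FC
#'   level; Herzberg-Teller states always use the numerical route.
#' @param ht_dipole_deriv named list (by state label) of 3 x nmodes dipole
#'   derivative matrices for Herzberg-Teller states.
#' @return a list of settings with class `spectrum_settings`.
#' @export
spectrum_settings <- function(gamma_ev = 0.04, omega_ev = NULL,
                              omega_step_ev = 0.005, omega_pad_ev = 1,
                              dt = 0.05, tmax = NULL,
                              n_tot = 10L, n_max = Inf, basis_cap = 2e5,
                              vg_route = c("analytic", "numerical"),
                              ht_dipole_deriv = NULL) {
  stopifnot(gamma_ev > 0, dt > 0)
  structure(list(gamma_ev = gamma_ev, omega_ev = omega_ev,
                 omega_step_ev = omega_step_ev, omega_pad_ev = omega_pad_ev,
                 dt = dt, tmax = tmax, n_tot = as.integer(n_tot),
                 n_max = n_max, basis_cap = basis_cap,
                 vg_route = match.arg(vg_route),
                 ht_dipole_deriv = ht_dipole_deriv),
            class = "spectrum_settings")
}

.resolve_tgrid <- function(s) {
  tmax <- if (is.null(s$tmax)) {
    max(300 / .FS_PER_HBAR_EV, 10 / s$gamma_ev)
  } else {
    s$tmax
  }
  seq(0, tmax, by = s$dt)
}

.resolve_omega_grid <- function(model, s) {
  if (!is.null(s$omega_ev)) return(s$omega_ev)
  er <- range(vapply(model$states, function(x) x$energy, numeric(1)))
  seq(er[1] - s$omega_pad_ev, er[2] + s$omega_pad_ev, by = s$omega_step_ev)
}

.single_state_model <- function(model, label) {
  lvc_model(model$modes$omega, list(model$states[[label]]),
            mode_symmetry = model$modes$symmetry)
}

.zero_coupling_model <- function(model) {
  model$couplings <- list()
  model
}

#' Compose the 3 x 3 tensor correlation function
#'
#' `chi_{rho sigma}^f(t) = sum_{k, m in K} mu_rho^{gk} mu_sigma^{gm}
#'  C^{km}_f(t)` for every fundamental `f` (and the `f = 0` tensor used by
#' absorption). The tensor is stored undamped and unconvolved; damping is
#' applied at transform time by [half_fourier_alpha()].
#'
#' @param corrs named list of [cross_correlations()] results, one per
#'   initial state `m`, names being the state indices as characters.
#' @param dipoles 3 x nstates matrix of transition dipoles.
#' @param K integer vector of state indices included in the double sum
#'   (both as initial states `m` — which must be present in `corrs` — and
#'   as bra states `k`).
#' @param diagonal_only keep only the `k = m` terms (the interference-free
#'   building block of the VG protocols).
#' @param zpe_ev ground-state zero-point energy `E_g0` (recorded for the
#'   transform phase).
#' @return an object of class `corr_tensor`: `tgrid`, `chi`
#'   (3 x 3 x nmodes x ntimes), `chi0` (3 x 3 x ntimes), `zpe_ev`,
#'   provenance.
#' @export
compose_tensor_correlation <- function(corrs, dipoles, K,
                                       diagonal_only = FALSE, zpe_ev = 0) {
  K <- as.integer(K)
  missing_m <- setdiff(as.character(K), names(corrs))
  if (length(missing_m)) {
    stop("missing cross-correlations for initial state(s) ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  first <- corrs[[as.character(K[1])]]
  nt <- length(first$tgrid)
  nm <- dim(first$Cf)[2]
  chi <- array(complex(1), c(3, 3, nm, nt))
  chi0 <- array(complex(1), c(3, 3, nt))
  for (m in K) {
    cc <- corrs[[as.character(m)]]
    kset <- if (diagonal_only) m else K
    # D[rho, f, t] = sum_{k in kset} mu[rho, k] C[k, f, t]
    Cf <- matrix(cc$Cf[kset, , , drop = FALSE], nrow = length(kset))
    C0 <- matrix(cc$C0[kset, , drop = FALSE], nrow = length(kset))
    D <- array(dipoles[, kset, drop = FALSE] %*% Cf, c(3, nm, nt))
    D0 <- dipoles[, kset, drop = FALSE] %*% C0
    for (sig in 1:3) {
      for (rho in 1:3) {
        chi[rho, sig, , ] <- chi[rho, sig, , ] + D[rho, , ] * dipoles[sig, m]
      }
      chi0[, sig, ] <- chi0[, sig, ] + D0 * dipoles[sig, m]
    }
  }
  structure(list(tgrid = first$tgrid, chi = chi, chi0 = chi0,
                 zpe_ev = zpe_ev,
                 provenance = list(K = K, diagonal_only = diagonal_only)),
            class = "corr_tensor")
}

# out[omega, p] = i sum_t w_t exp((i (omega + e0) - gamma) t) X[p, t]
# trapezoidal quadrature, chunked over time to bound memory.
.half_fourier <- function(X, tgrid, omega, gamma, e0) {
  nt <- length(tgrid)
  w <- rep(tgrid[2] - tgrid[1], nt)
  w[c(1, nt)] <- w[1] / 2
  damp <- exp(-gamma * tgrid) * w
  out <- matrix(complex(1), length(omega), nrow(X))
  chunk <- max(1L, floor(4e6 / length(omega)))
  for (start in seq(1L, nt, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nt)
    ph <- exp(outer(omega + e0, tgrid[idx], function(o, t) 1i * o * t))
    out <- out + ph %*% (t(X[, idx, drop = FALSE]) * damp[idx])
  }
  1i * out
}

#' Half-Fourier transform of a tensor correlation function
#'
#' `alpha_{rho sigma}^{f0}(omega_I) = i int_0^Inf dt
#'  e^{i (omega_I + E_g0) t} e^{-gamma t} chi_{rho sigma}^f(t)` by
#' trapezoidal quadrature on the stored grid.
#'
#' @param chi a `corr_tensor` from [compose_tensor_correlation()].
#' @param omega_grid strictly increasing excitation energies (eV).
#' @param gamma Lorentzian damping (eV, > 0).
#' @return an object of class `polarizability_grid`: `omega_ev`, `gamma_ev`
#'   and `alpha` (3 x 3 x nmodes x length(omega_grid) complex array).
#' @export
half_fourier_alpha <- function(chi, omega_grid, gamma) {
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (is.unsorted(omega_grid, strictly = TRUE)) {
    stop("omega grid must be strictly increasing", call. = FALSE)
  }
  Tmax <- max(chi$tgrid)
  if (exp(-gamma * Tmax) >= 1e-6) {
    warning("time grid too short for gamma = ", gamma,
            " eV: exp(-gamma*T) = ", signif(exp(-gamma * Tmax), 3),
            " >= 1e-6; the damped tail is truncated")
  }
  nm <- dim(chi$chi)[3]
  nt <- dim(chi$chi)[4]
  X <- matrix(aperm(chi$chi, c(4, 1, 2, 3)), nrow = nt) # t x (rho sigma f)
  out <- .half_fourier(t(X), chi$tgrid, omega_grid, gamma, chi$zpe_ev)
  alpha <- aperm(array(t(out), c(3, 3, nm, length(omega_grid))),
                 c(1, 2, 3, 4))
  structure(list(omega_ev = omega_grid, gamma_ev = gamma, alpha = alpha),
            class = "polarizability_grid")
}

#' Rotational invariants of a complex polarizability tensor
#'
#' With `aS = (alpha + t(alpha))/2`, `aA = (alpha - t(alpha))/2` and
#' `a = Tr(alpha)/3`: the isotropic part is `|a|^2`, the symmetric
#' anisotropy `g2 = (3/2) sum |aS - a I|^2`, and the antisymmetric
#' anisotropy `d2 = (3/2) sum |aA|^2`. All three are invariant under a
#' simultaneous 3D rotation of the tensor.
#'
#' @param alpha a 3 x 3 complex matrix.
#' @return list with `a` (complex), `g2`, `d2` (real, nonnegative).
#' @export
rotational_invariants <- function(alpha) {
  stopifnot(is.matrix(alpha), all(dim(alpha) == c(3, 3)),
            all(is.finite(Mod(alpha))))
  aS <- (alpha + t(alpha)) / 2
  aA <- (alpha - t(alpha)) / 2
  a <- sum(diag(alpha)) / 3
  list(a = a,
       g2 = 1.5 * sum(Mod(aS - a * diag(3))^2),
       d2 = 1.5 * sum(Mod(aA)^2))
}

# vectorized invariants over a polarizability grid slice [3, 3, n]
.invariants_grid <- function(alpha) {
  n <- dim(alpha)[3]
  a <- (alpha[1, 1, ] + alpha[2, 2, ] + alpha[3, 3, ]) / 3
  g2 <- numeric(n)
  d2 <- numeric(n)
  for (r in 1:3) {
    for (s in 1:3) {
      sym <- (alpha[r, s, ] + alpha[s, r, ]) / 2
      asym <- (alpha[r, s, ] - alpha[s, r, ]) / 2
      if (r == s) sym <- sym - a
      g2 <- g2 + 1.5 * Mod(sym)^2
      d2 <- d2 + 1.5 * Mod(asym)^2
    }
  }
  list(a2 = Mod(a)^2, g2 = g2, d2 = d2)
}

#' Resonance-Raman intensity from the rotational invariants
#'
#' `I = omega_I (omega_I - omega_f)^3 (45 |a|^2 + 7 g2 + 5 d2) / 45` with
#' global prefactor 1 (arbitrary units; only relative intensities are
#' meaningful).
#'
#' @param inv invariants from [rotational_invariants()].
#' @param omega_I excitation energy (eV); must exceed `omega_f`.
#' @param omega_f vibrational (Raman-shift) energy of the final fundamental
#'   (eV, >= 0).
#' @return nonnegative intensity (arbitrary units).
#' @export
vrr_intensity <- function(inv, omega_I, omega_f) {
  if (any(omega_f < 0) || any(omega_I <= omega_f)) {
    stop("require omega_I > omega_f >= 0 (resonant Stokes scattering)",
         call. = FALSE)
  }
  omega_I * (omega_I - omega_f)^3 *
    (45 * Mod(inv$a)^2 + 7 * inv$g2 + 5 * inv$d2) / 45
}

# chi tensor for a single-state model (index 1), FC or HT route.
# Returns list(chi [3,3,nm,nt], chi0 [3,3,nt], notes)
.single_state_chi <- function(sub, settings, tgrid, ht = FALSE) {
  nm <- nmodes(sub)
  mu0 <- sub$states[[1]]$dipole
  notes <- character(0)
  if (!ht && settings$vg_route == "analytic") {
    pars <- .vg_params(sub, state_labels(sub)[1])
    bare <- exp(-1i * zpe(sub) * tgrid)
    C0 <- vg_autocorrelation_fc(pars, tgrid) * bare
    chi0 <- outer(outer(mu0, mu0), C0)
    chi <- array(complex(1), c(3, 3, nm, length(tgrid)))
    for (f in seq_len(nm)) {
      Cf <- vg_cross_correlation_fc(pars, f, tgrid) * bare
      chi[, , f, ] <- outer(outer(mu0, mu0), Cf)
    }
    return(list(chi = chi, chi0 = chi0, notes = notes))
  }
  basis1 <- enumerate_basis(nm, basis_spec(settings$n_tot, settings$n_max),
                            1L, cap = settings$basis_cap)
  h1 <- build_hamiltonian(sub, basis1)
  if (!ht) {
    cc <- .cross_correlations_eigen(h1, 1L, tgrid)
    corrs <- stats::setNames(list(cc), "1")
    ct <- compose_tensor_correlation(corrs, matrix(mu0, 3, 1), 1L,
                                     zpe_ev = zpe(sub))
    return(list(chi = ct$chi, chi0 = ct$chi0, notes = notes))
  }
  muprime <- settings$ht_dipole_deriv[[state_labels(sub)[1]]]
  if (is.null(muprime)) {
    stop("no dipole derivatives supplied for HT state '",
         state_labels(sub)[1], "' (settings$ht_dipole_deriv)", call. = FALSE)
  }
  eig <- ham_eigen(h1)
  e0vec <- complex(basis1$nvib)
  e0vec[.vib_ground(basis1)] <- 1 + 0i
  ph_s <- apply_dipole_operator(mu0, muprime, e0vec, basis1)
  if (max(ph_s$dropped) > 0) {
    notes <- c(notes, sprintf(
      "HT ladder truncation at basis boundary: dropped |amp|^2 up to %.3e",
      max(ph_s$dropped)))
  }
  B <- crossprod(eig$vectors, ph_s$components) # dim x 3 (sigma)
  nt <- length(tgrid)
  chi <- array(complex(1), c(3, 3, nm, nt))
  chi0 <- array(complex(1), c(3, 3, nt))
  project <- function(vibvec) {
    # coef[(rho,sigma), l] -> time series via exp(-i E_l t)
    A <- crossprod(eig$vectors, Conj(vibvec)) # dim x 3 (rho)
    coef <- matrix(complex(1), 9, length(eig$values))
    for (rho in 1:3) {
      for (sig in 1:3) {
        coef[(sig - 1) * 3 + rho, ] <- A[, rho] * B[, sig]
      }
    }
    coef %*% exp(outer(eig$values, tgrid, function(e, t) -1i * e * t))
  }
  chi0[] <- project(ph_s$components)
  for (f in seq_len(nm)) {
    efvec <- complex(basis1$nvib)
    efvec[.vib_fundamental(basis1, f)] <- 1 + 0i
    ph_f <- apply_dipole_operator(mu0, muprime, efvec, basis1)
    if (max(ph_f$dropped) > 0) {
      notes <- c(notes, sprintf(
        "HT ladder truncation (f = %d): dropped |amp|^2 up to %.3e",
        f, max(ph_f$dropped)))
    }
    chi[, , f, ] <- project(ph_f$components)
  }
  list(chi = chi, chi0 = chi0, notes = unique(notes))
}

# intensities [nmodes x nomega] from a chi tensor
.chi_to_intensity <- function(chi_arr, tgrid, omega_grid, gamma, e0,
                              omega_f) {
  nm <- dim(chi_arr)[3]
  ct <- structure(list(tgrid = tgrid, chi = chi_arr,
                       chi0 = array(complex(1), c(3, 3, length(tgrid))),
                       zpe_ev = e0), class = "corr_tensor")
  pol <- half_fourier_alpha(ct, omega_grid, gamma)
  intensity <- matrix(0, nm, length(omega_grid))
  for (f in seq_len(nm)) {
    inv <- .invariants_grid(array(pol$alpha[, , f, ],
                                  c(3, 3, length(omega_grid))))
    intensity[f, ] <- omega_grid * (omega_grid - omega_f[f])^3 *
      (45 * inv$a2 + 7 * inv$g2 + 5 * inv$d2) / 45
  }
  intensity
}

#' Compute a 2D vibrational resonance Raman spectrum
#'
#' Runs the full pipeline — propagation (or closed-form correlation
#' functions), tensor composition, damped half-Fourier transform,
#' rotational invariants, intensities — for every fundamental on the
#' excitation grid, under one of the three protocols `"lvc"`, `"vg_int"`,
#' `"vg_sum"` (see the package vignette). For the VG protocols the
#' interstate couplings are zeroed; states listed in `ht_states` use a
#' Herzberg-Teller dipole `mu(q) = mu0 + mu' q` (dipole derivatives taken
#' from `settings$ht_dipole_deriv`).
#'
#' @param model an `lvc_model`.
#' @param protocol `"lvc"`, `"vg_int"` or `"vg_sum"`.
#' @param bright character vector of initial ("bright") state labels;
#'   default: every state with a nonzero transition dipole.
#' @param settings a [spectrum_settings()] list.
#' @param ht_states labels treated at Herzberg-Teller level (VG protocols
#'   only; the diabatic LVC route is FC by construction).
#' @param scale post hoc Raman-shift scaling factor applied to the
#'   reported axis (see [scale_raman_axis()]).
#' @return an object of class `vrr_spectrum`: excitation grid `omega_ev`,
#'   per-mode Raman-shift positions `shift_cm1`, intensity matrix
#'   `intensity` (nmodes x nomega), protocol and settings metadata.
#' @export
compute_vrr <- function(model, protocol = c("lvc", "vg_int", "vg_sum"),
                        bright = NULL, settings = spectrum_settings(),
                        ht_states = NULL, scale = 1) {
  protocol <- match.arg(protocol)
  .stop_if_invalid(model)
  mu <- dipole_matrix(model)
  labs <- state_labels(model)
  if (is.null(bright)) bright <- labs[colSums(mu^2) > 0]
  if (!length(bright)) stop("bright subset must be non-empty", call. = FALSE)
  unknown <- setdiff(bright, labs)
  if (length(unknown)) {
    stop("unknown bright state(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(ht_states) && protocol == "lvc") {
    stop("Herzberg-Teller dipoles are only meaningful for the single-state ",
         "VG protocols; the LVC route uses constant diabatic dipoles",
         call. = FALSE)
  }
  tgrid <- .resolve_tgrid(settings)
  omega_grid <- .resolve_omega_grid(model, settings)
  gamma <- settings$gamma_ev
  e0 <- zpe(model)
  omega_f <- model$modes$omega
  notes <- character(0)
  if (protocol == "lvc") {
    basis <- enumerate_basis(nmodes(model),
                             basis_spec(settings$n_tot, settings$n_max),
                             nstates(model), cap = settings$basis_cap)
    h <- build_hamiltonian(model, basis)
    bright_idx <- match(bright, labs)
    corrs <- stats::setNames(
      lapply(bright_idx, function(m) .cross_correlations_eigen(h, m, tgrid)),
      as.character(bright_idx))
    # bra sum runs over every state; zero dipoles drop out automatically
    chi <- array(complex(1), c(3, 3, nmodes(model), length(tgrid)))
    for (m in bright_idx) {
      cc <- corrs[[as.character(m)]]
      Cf <- matrix(cc$Cf, nrow = nstates(model))
      D <- array(mu %*% Cf, c(3, nmodes(model), length(tgrid)))
      for (sig in 1:3) {
        for (rho in 1:3) {
          chi[rho, sig, , ] <- chi[rho, sig, , ] + D[rho, , ] * mu[sig, m]
        }
      }
    }
    intensity <- .chi_to_intensity(chi, tgrid, omega_grid, gamma, e0,
                                   omega_f)
  } else {
    base <- .zero_coupling_model(model)
    chis <- lapply(bright, function(lb) {
      out <- .single_state_chi(.single_state_model(base, lb), settings,
                               tgrid, ht = lb %in% ht_states)
      notes <<- c(notes, out$notes)
      out
    })
    if (protocol == "vg_int") {
      chi <- Reduce(`+`, lapply(chis, `[[`, "chi"))
      intensity <- .chi_to_intensity(chi, tgrid, omega_grid, gamma, e0,
                                     omega_f)
    } else {
      parts <- lapply(chis, function(x) {
        .chi_to_intensity(x$chi, tgrid, omega_grid, gamma, e0, omega_f)
      })
      intensity <- Reduce(`+`, parts)
    }
  }
  spec <- structure(list(
    omega_ev = omega_grid,
    mode_index = seq_len(nmodes(model)),
    omega_f_ev = omega_f,
    shift_cm1 = omega_f * .CM1_PER_EV,
    scale = 1,
    intensity = intensity,
    protocol = protocol,
    gamma_ev = gamma,
    bright = bright,
    notes = notes,
    prefactor = "omega_I * (omega_I - omega_f)^3, global constant 1 (a.u.)"
  ), class = "vrr_spectrum")
  if (scale != 1) spec <- scale_raman_axis(spec, scale) else spec
}

#' @export
print.vrr_spectrum <- function(x, ...) {
  cat(sprintf(
    "vRR spectrum (%s): %d modes, omega_I in [%.3f, %.3f] eV (%d points), gamma = %g eV\n",
    x$protocol, length(x$mode_index), min(x$omega_ev), max(x$omega_ev),
    length(x$omega_ev), x$gamma_ev))
  if (x$scale != 1) cat(sprintf("  Raman axis scaled by %g\n", x$scale))
  invisible(x)
}

#' Raman excitation profile of one mode
#'
#' A 1D cut of the 2D signal at fixed Raman shift: the intensity of mode
#' `f`'s fundamental as a function of the excitation energy. No additional
#' broadening is applied.
#'
#' @param spec a `vrr_spectrum`.
#' @param f mode index.
#' @return data.frame with `omega_ev` and `intensity`.
#' @export
excitation_profile <- function(spec, f) {
  if (!f %in% spec$mode_index) stop("unknown mode ", f, call. = FALSE)
  data.frame(omega_ev = spec$omega_ev, intensity = spec$intensity[f, ])
}

#' 1D vRR spectrum at a fixed excitation energy
#'
#' Section of the 2D signal at `omega_I`: sticks at the (scaled) mode
#' positions with heights `I^{f0}(omega_I)`, convolved along the Raman
#' shift with a normalized Gaussian of the given HWHM. Off-grid requests
#' snap to the nearest grid point with a warning (interpolating the
#' underlying complex amplitudes would scramble their phases).
#'
#' @param spec a `vrr_spectrum`.
#' @param omega_I excitation energy (eV).
#' @param conv_hwhm_cm1 Gaussian half-width at half-maximum of the
#'   Raman-shift convolution (cm-1, default 15).
#' @param grid_step_cm1 output grid spacing.
#' @return data.frame with `raman_shift_cm1` and `intensity`; the
#'   excitation energy actually used is in attribute `omega_ev`.
#' @export
spectrum_section <- function(spec, omega_I, conv_hwhm_cm1 = 15,
                             grid_step_cm1 = 1) {
  iw <- which.min(abs(spec$omega_ev - omega_I))
  if (abs(spec$omega_ev[iw] - omega_I) > 1e-9) {
    warning("omega_I = ", omega_I, " eV is off-grid; snapping to ",
            spec$omega_ev[iw], " eV")
  }
  sd <- conv_hwhm_cm1 / sqrt(2 * log(2))
  grid <- seq(0, max(spec$shift_cm1) + 8 * sd, by = grid_step_cm1)
  intensity <- rep(0, length(grid))
  for (f in spec$mode_index) {
    intensity <- intensity + spec$intensity[f, iw] *
      stats::dnorm(grid, mean = spec$shift_cm1[f], sd = sd)
  }
  out <- data.frame(raman_shift_cm1 = grid, intensity = intensity)
  attr(out, "omega_ev") <- spec$omega_ev[iw]
  attr(out, "conv_hwhm_cm1") <- conv_hwhm_cm1
  out
}

#' Scale the reported Raman-shift axis
#'
#' Post hoc multiplication of the reported band positions (e.g. by the
#' common empirical harmonic-frequency correction 0.96); the dynamics and
#' the intensities are untouched.
#'
#' @param spec a `vrr_spectrum`.
#' @param factor scaling factor in (0, 1.2].
#' @return the rescaled `vrr_spectrum`.
#' @export
scale_raman_axis <- function(spec, factor) {
  stopifnot(factor > 0, factor <= 1.2)
  spec$shift_cm1 <- spec$shift_cm1 * factor
  spec$scale <- spec$scale * factor
  spec
}

#' Map an experimental excitation energy to the computed energy scale
#'
#' Computed spectra are typically shifted with respect to experiment; to
#' reproduce the experimental resonance conditions the excitation used in
#' the computation is offset by the difference of the absorption maxima:
#' `omega_comp = omega_exp + (abs_max_calc - abs_max_exp)`.
#'
#' @param omega_exp experimental excitation energy (eV).
#' @param abs_max_calc,abs_max_exp positions of the calculated and
#'   experimental absorption maxima (eV).
#' @return excitation energy to use in the computation (eV).
#' @export
match_excitation <- function(omega_exp, abs_max_calc, abs_max_exp) {
  omega_exp + (abs_max_calc - abs_max_exp)
}
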
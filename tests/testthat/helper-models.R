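# Shared fixtures and independent oracles for the test suite. The oracle
# Hamiltonian is assembled element-by-element from first principles
# (explicit <n|q|n'> products over modes), deliberately sharing no code
# with build_hamiltonian().

# <n1|q|n2> for a single harmonic mode, q = (a + a^dag)/sqrt(2)
q_element <- function(n1, n2) {
  if (n1 == n2 + 1) sqrt((n2 + 1) / 2)
  else if (n1 == n2 - 1) sqrt(n2 / 2)
  else 0
}

oracle_hamiltonian <- function(model, basis) {
  d <- basis$dim
  nvib <- basis$nvib
  occ <- basis$occ
  omega <- model$modes$omega
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    ki <- (i - 1) %/% nvib + 1L
    vi <- occ[(i - 1) %% nvib + 1L, ]
    for (j in seq_len(d)) {
      kj <- (j - 1) %/% nvib + 1L
      vj <- occ[(j - 1) %% nvib + 1L, ]
      lam <- if (ki == kj) model$states[[ki]]$gradient
             else vibraman:::coupling_lambda(model, ki, kj)
      val <- 0
      if (ki == kj && all(vi == vj)) {
        val <- model$states[[ki]]$energy + sum((vi + 0.5) * omega)
      }
      diffs <- which(vi != vj)
      if (length(diffs) == 1L) {
        val <- val + lam[diffs] * q_element(vi[diffs], vj[diffs])
      }
      H[i, j] <- val
    }
  }
  H
}

# uniformly random proper rotation matrix
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_dipoles <- function(model, R) {
  for (lb in state_labels(model)) {
    model$states[[lb]]$dipole <- as.vector(R %*% model$states[[lb]]$dipole)
  }
  model
}

# two bright states with parallel dipoles and overlapping bands: the
# canonical destructive-interference construction
interference_model <- function() {
  omega <- 1300 / vibraman:::.CM1_PER_EV
  lam <- omega * sqrt(2 * 0.3)
  lvc_model(omega, list(
    lvc_state("A", 4.7, lam, c(1, 0, 0)),
    lvc_state("B", 5.3, lam, c(0.8, 0, 0))
  ))
}

# fast settings for unit tests (coarse but internally consistent grids)
fast_settings <- function(...) {
  spectrum_settings(gamma_ev = 0.08, dt = 0.1, tmax = 200, n_tot = 8,
                    omega_step_ev = 0.05, ...)
}

# full width at half maximum with linear interpolation of the crossings
interp_fwhm <- function(x, y) {
  pk <- which.max(y)
  half <- y[pk] / 2
  cross <- function(i1, i2) {
    x[i1] + (half - y[i1]) * (x[i2] - x[i1]) / (y[i2] - y[i1])
  }
  il <- max(which(y[1:pk] < half))
  ir <- pk - 1 + min(which(y[pk:length(y)] < half))
  cross(ir - 1, ir) - cross(il, il + 1)
}

expect_rel_equal <- function(got, want, tol) {
  denom <- max(abs(want))
  expect_lt(max(abs(got - want)) / denom, tol)
}
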
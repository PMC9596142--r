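test_that("single bright uncoupled state: all three protocols coincide", {
  m <- fixture_displaced(S = 0.5)
  s <- spectrum_settings(gamma_ev = 0.06, dt = 0.05, tmax = 250, n_tot = 20,
                         omega_step_ev = 0.05)
  lvc <- compute_vrr(m, "lvc", settings = s)
  vgi <- compute_vrr(m, "vg_int", settings = s)
  vgs <- compute_vrr(m, "vg_sum", settings = s)
  # Int and Sum are one-term sums of the same tensor: identical
  expect_identical(vgi$intensity, vgs$intensity)
  # the LVC propagation agrees to basis-convergence level
  expect_rel_equal(lvc$intensity, vgi$intensity, 1e-10)
})

test_that("LVC collapses onto VG-Int when the couplings vanish", {
  m <- fixture_conical(coupling = 0)
  s <- fast_settings()
  s$vg_route <- "numerical"
  lvc <- compute_vrr(m, "lvc", settings = s)
  vgi <- compute_vrr(m, "vg_int", settings = s)
  expect_rel_equal(lvc$intensity, vgi$intensity, 1e-10)
  # with couplings on the protocols genuinely differ
  mc <- fixture_conical(coupling = 0.08)
  lvc_c <- compute_vrr(mc, "lvc", settings = s)
  vgi_c <- compute_vrr(mc, "vg_int", settings = s)
  expect_gt(max(abs(lvc_c$intensity - vgi_c$intensity)) /
              max(vgi_c$intensity), 1e-3)
})

test_that("rotating every dipole leaves all observables unchanged", {
  set.seed(33)
  m <- fixture_conical(0.08)
  R <- random_rotation()
  mr <- rotate_dipoles(m, R)
  s <- fast_settings()
  for (protocol in c("lvc", "vg_int", "vg_sum")) {
    i1 <- compute_vrr(m, protocol, settings = s)$intensity
    i2 <- compute_vrr(mr, protocol, settings = s)$intensity
    expect_rel_equal(i2, i1, 1e-10)
  }
  a1 <- absorption_spectrum(m, "lvc", 0.08, s)$intensity
  a2 <- absorption_spectrum(mr, "lvc", 0.08, s)$intensity
  expect_rel_equal(a2, a1, 1e-10)
})

test_that("A'' fundamentals activate only through the interstate coupling", {
  s <- spectrum_settings(gamma_ev = 0.06, dt = 0.1, tmax = 250, n_tot = 6,
                         omega_step_ev = 0.05)
  off <- compute_vrr(fixture_cs(coupling_a2 = 0), "lvc", settings = s)
  expect_lt(max(off$intensity[3, ]), 1e-14 * max(off$intensity))

  on <- compute_vrr(fixture_cs(coupling_a2 = 0.08), "lvc", settings = s)
  expect_gt(max(on$intensity[3, ]), 1e-6 * max(on$intensity))

  # the activated intensity flows through the dark state's dipole
  mute <- compute_vrr(fixture_cs(coupling_a2 = 0.08,
                                 dark_dipole = c(0, 0, 0)),
                      "lvc", settings = s)
  expect_lt(max(mute$intensity[3, ]), 1e-14 * max(mute$intensity))
})

test_that("destructive interference: VG-Int dips below VG-Sum in the valley", {
  m <- interference_model()
  s <- spectrum_settings(gamma_ev = 0.12, dt = 0.05, tmax = 250, n_tot = 14,
                         omega_step_ev = 0.02)
  vgi <- compute_vrr(m, "vg_int", settings = s)
  vgs <- compute_vrr(m, "vg_sum", settings = s)
  valley <- which(vgi$omega_ev > 4.85 & vgi$omega_ev < 5.1)
  expect_true(all(vgi$intensity[1, valley] < vgs$intensity[1, valley]))

  # cross-check the Int spectrum against the sum-over-states oracle
  b <- enumerate_basis(1, basis_spec(14), 2)
  om <- vgi$omega_ev
  sos <- sum_over_states_alpha(m, b, om, 0.12, f = 1)
  inv <- vibraman:::.invariants_grid(sos)
  want <- om * (om - m$modes$omega)^3 *
    (45 * inv$a2 + 7 * inv$g2 + 5 * inv$d2) / 45
  expect_rel_equal(vgi$intensity[1, ], want, 1e-3)
})

test_that("absorption: broadened sticks, sum rule, eigenvalue positions", {
  # undisplaced single state: one Gaussian at E_v with the requested HWHM
  m <- lvc_model(c(0.12, 0.2),
                 list(lvc_state("A", 4.5, c(0, 0), c(1, 1, 0))))
  s <- spectrum_settings(gamma_ev = 0.04, dt = 0.05, tmax = 250,
                         n_tot = 6, omega_step_ev = 0.002)
  for (hw in c(0.04, 0.12)) {
    ab <- absorption_spectrum(m, "lvc", hwhm_ev = hw, settings = s)
    expect_true(all(ab$intensity >= 0))
    expect_equal(abs_peak(ab), 4.5, tolerance = 1e-3)
    fwhm <- interp_fwhm(ab$omega_ev, ab$intensity)
    expect_equal(fwhm, 2 * hw, tolerance = 0.02 * 2 * hw)
  }

  # t = 0 sum rule: integral of I/omega = pi * sum |mu_k|^2
  m2 <- fixture_conical(0.08)
  s2 <- spectrum_settings(gamma_ev = 0.04, dt = 0.05, tmax = 250,
                          n_tot = 8, omega_step_ev = 0.005,
                          omega_pad_ev = 1.5)
  ab2 <- absorption_spectrum(m2, "lvc", hwhm_ev = 0.05, settings = s2)
  integral <- sum(ab2$intensity / ab2$omega_ev) * 0.005
  mu <- vibraman:::dipole_matrix(m2)
  expect_equal(integral, pi * sum(mu^2), tolerance = 1e-3 * pi * sum(mu^2))

  # coupled fixture: peaks sit on vibronic eigenvalues
  s3 <- spectrum_settings(gamma_ev = 0.04, dt = 0.05, tmax = 250,
                          n_tot = 10, omega_step_ev = 0.002)
  ab3 <- absorption_spectrum(m2, "lvc", hwhm_ev = 0.02, settings = s3)
  b <- enumerate_basis(2, basis_spec(10), 2)
  h <- build_hamiltonian(m2, b)
  sticks <- eigen(h$mat, symmetric = TRUE, only.values = TRUE)$values -
    zpe(m2)
  pk <- ab3$omega_ev[which.max(ab3$intensity)]
  expect_lt(min(abs(pk - sticks)), 0.004)

  expect_error(absorption_spectrum(m2, "lvc", hwhm_ev = 0), "HWHM")
})

test_that("absorption protocols collapse without couplings", {
  m <- fixture_conical(coupling = 0)
  s <- fast_settings()
  a_lvc <- absorption_spectrum(m, "lvc", 0.08, s)
  s$vg_route <- "numerical"
  a_vgs <- absorption_spectrum(m, "vg_sum", 0.08, s)
  expect_rel_equal(a_vgs$intensity, a_lvc$intensity, 1e-10)
})
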
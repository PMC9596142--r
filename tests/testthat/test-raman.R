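test_that("tensor composition limits", {
  tg <- seq(0, 10, by = 0.5)
  nt <- length(tg)
  fake_corr <- function(scale) {
    list(tgrid = tg,
         C0 = matrix(scale * exp(-1i * 4 * tg), 1, nt),
         Cf = array(scale * exp(-1i * 4.1 * tg), c(1, 1, nt)))
  }
  mu <- matrix(c(0.3, -1, 2), 3, 1)
  ct <- compose_tensor_correlation(list("1" = fake_corr(1)), mu, 1L)
  # single state: rank-1 tensor mu mu^T C(t) at every time
  for (it in c(1L, nt)) {
    expect_equal(ct$chi[, , 1, it],
                 outer(mu[, 1], mu[, 1]) * exp(-1i * 4.1 * tg[it]),
                 tolerance = 1e-14)
  }
  ct0 <- compose_tensor_correlation(list("1" = fake_corr(1)),
                                    matrix(0, 3, 1), 1L)
  expect_true(all(ct0$chi == 0) && all(ct0$chi0 == 0))
  expect_error(compose_tensor_correlation(list("1" = fake_corr(1)), mu, 1:2),
               "missing cross-correlations")
})

test_that("two uncoupled states compose additively (k = m survives)", {
  m <- fixture_conical(coupling = 0)
  b <- enumerate_basis(2, basis_spec(8), 2)
  h <- build_hamiltonian(m, b)
  tg <- seq(0, 60, by = 0.5)
  mu <- vibraman:::dipole_matrix(m)
  corrs <- stats::setNames(lapply(1:2, function(mm) {
    vibraman:::.cross_correlations_eigen(h, mm, tg)
  }), c("1", "2"))
  full <- compose_tensor_correlation(corrs, mu, 1:2, zpe_ev = zpe(m))
  diag_only <- compose_tensor_correlation(corrs, mu, 1:2,
                                          diagonal_only = TRUE,
                                          zpe_ev = zpe(m))
  expect_lt(max(Mod(full$chi - diag_only$chi)), 1e-13)
  # and the diagonal sum is the sum of single-state tensors
  single <- lapply(1:2, function(mm) {
    compose_tensor_correlation(corrs[mm], mu, mm, zpe_ev = zpe(m))
  })
  expect_lt(max(Mod(full$chi - (single[[1]]$chi + single[[2]]$chi))), 1e-13)
})

test_that("half-Fourier transform: pole closed form, linearity, convergence", {
  gamma <- 0.1
  E <- 4.0
  make_ct <- function(dt, fun) {
    tg <- seq(0, 250, by = dt)
    structure(list(tgrid = tg,
                   chi = array(rep(fun(tg), each = 9), c(3, 3, 1, length(tg))),
                   chi0 = array(complex(1), c(3, 3, length(tg))),
                   zpe_ev = 0), class = "corr_tensor")
  }
  om <- seq(3.5, 4.5, by = 0.01)
  pol <- half_fourier_alpha(make_ct(0.01, function(t) exp(-1i * E * t)),
                            om, gamma)
  want <- 1i / (gamma - 1i * (om - E))
  expect_lt(max(Mod(pol$alpha[1, 1, 1, ] - want)) / max(Mod(want)), 1e-6)
  expect_equal(pol$alpha[1, 1, 1, which.min(abs(om - 4))], 1i / gamma,
               tolerance = 1e-5)

  # linearity
  f1 <- function(t) exp(-1i * 3.8 * t)
  f2 <- function(t) 0.5 * exp(-1i * 4.2 * t)
  a12 <- half_fourier_alpha(make_ct(0.05, function(t) f1(t) + f2(t)), om,
                            gamma)$alpha
  a1 <- half_fourier_alpha(make_ct(0.05, f1), om, gamma)$alpha
  a2 <- half_fourier_alpha(make_ct(0.05, f2), om, gamma)$alpha
  expect_lt(max(Mod(a12 - (a1 + a2))), 1e-12)

  # halving dt barely moves the result
  ah <- half_fourier_alpha(make_ct(0.01, f1), om, gamma)$alpha
  aq <- half_fourier_alpha(make_ct(0.005, f1), om, gamma)$alpha
  expect_lt(max(Mod(ah - aq)) / max(Mod(aq)), 1e-6)

  expect_error(half_fourier_alpha(make_ct(0.05, f1), om, gamma = 0),
               "gamma must be > 0")
  expect_error(half_fourier_alpha(make_ct(0.05, f1), c(4, 4, 5), gamma),
               "strictly increasing")
  ct_short <- make_ct(0.05, f1)
  short <- which(ct_short$tgrid <= 30)
  ct_short$tgrid <- ct_short$tgrid[short]
  ct_short$chi <- ct_short$chi[, , , short, drop = FALSE]
  expect_warning(half_fourier_alpha(ct_short, om, gamma), "too short")
})

test_that("rotational invariants: pinned values and rotation invariance", {
  iso <- rotational_invariants(diag(3) * (2 + 1i))
  expect_equal(iso$a, 2 + 1i)
  expect_equal(iso$g2, 0)
  expect_equal(iso$d2, 0)

  anti <- matrix(0, 3, 3)
  anti[1, 2] <- 1; anti[2, 1] <- -1
  ia <- rotational_invariants(anti + 0i)
  expect_equal(ia$a, 0 + 0i)
  expect_equal(ia$g2, 0)
  expect_equal(ia$d2, 3)

  set.seed(101)
  for (rep in 1:5) {
    alpha <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
    R <- random_rotation()
    i1 <- rotational_invariants(alpha)
    i2 <- rotational_invariants(t(R) %*% alpha %*% R)
    expect_equal(Mod(i1$a), Mod(i2$a), tolerance = 1e-10)
    expect_equal(i1$g2, i2$g2, tolerance = 1e-10)
    expect_equal(i1$d2, i2$d2, tolerance = 1e-10)
  }
})

test_that("intensity formula: pinned normalization and quadratic scaling", {
  zero <- rotational_invariants(matrix(0i, 3, 3))
  expect_equal(vrr_intensity(zero, 2, 0.1), 0)

  one <- rotational_invariants(diag(3) + 0i)
  expect_equal(vrr_intensity(one, 2, 0), 16)

  set.seed(7)
  alpha <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
  c_ <- 2.3 - 0.7i
  i1 <- vrr_intensity(rotational_invariants(alpha), 5, 0.2)
  i2 <- vrr_intensity(rotational_invariants(c_ * alpha), 5, 0.2)
  expect_equal(i2, Mod(c_)^2 * i1, tolerance = 1e-12)

  expect_error(vrr_intensity(one, 0.1, 0.2), "omega_I > omega_f")
})

test_that("profiles and sections are consistent views of the 2D map", {
  m <- fixture_three_mode()
  spec <- compute_vrr(m, "vg_int", settings = fast_settings())

  prof <- excitation_profile(spec, 2)
  expect_equal(prof$intensity, spec$intensity[2, ])
  expect_error(excitation_profile(spec, 9), "unknown mode")

  # undisplaced, uncoupled mode: identically zero profile
  m0 <- fixture_three_mode()
  m0$states$S1$gradient[1] <- 0
  spec0 <- compute_vrr(m0, "vg_int", settings = fast_settings())
  expect_true(all(excitation_profile(spec0, 1)$intensity == 0))

  iw <- which.min(abs(spec$omega_ev - 4.8))
  sec <- spectrum_section(spec, spec$omega_ev[iw], conv_hwhm_cm1 = 15)
  # integral preserved: kernel is a normalized density
  integral <- sum(sec$intensity) * diff(sec$raman_shift_cm1[1:2])
  expect_equal(integral, sum(spec$intensity[, iw]), tolerance = 1e-10)
  expect_warning(spectrum_section(spec, 4.8001), "snapping")
})

test_that("section convolution width and merging behaviour", {
  # single active mode: one Gaussian of the requested HWHM
  m <- fixture_displaced()
  spec <- compute_vrr(m, "vg_int", settings = fast_settings())
  iw <- which.min(abs(spec$omega_ev - 4.5))
  sec <- spectrum_section(spec, spec$omega_ev[iw], conv_hwhm_cm1 = 15,
                          grid_step_cm1 = 0.1)
  pk <- which.max(sec$intensity)
  half <- sec$intensity[pk] / 2
  above <- range(which(sec$intensity >= half))
  fwhm <- diff(sec$raman_shift_cm1[above])
  expect_equal(fwhm, 30, tolerance = 0.02 * 30)
  expect_equal(sec$raman_shift_cm1[pk], spec$shift_cm1[1], tolerance = 0.2)

  # two sticks 5 cm-1 apart merge into a single-maximum band: compute the
  # expected curve directly from the kernel sum
  sd <- 15 / sqrt(2 * log(2))
  grid <- seq(900, 1100, by = 0.1)
  two <- dnorm(grid, 1000, sd) + dnorm(grid, 1005, sd)
  local_max <- which(diff(sign(diff(two))) == -2) + 1
  expect_length(local_max, 1L)
})

test_that("Raman-axis scaling touches positions only", {
  m <- fixture_three_mode()
  spec <- compute_vrr(m, "vg_int", settings = fast_settings())
  expect_identical(scale_raman_axis(spec, 1), spec)
  scaled <- scale_raman_axis(spec, 0.96)
  expect_equal(scaled$shift_cm1, spec$shift_cm1 * 0.96)
  expect_identical(scaled$intensity, spec$intensity)
  expect_error(scale_raman_axis(spec, 1.5), "factor")

  # a round-number check: 1000 cm-1 reports as 960
  m1 <- lvc_model(1000, list(lvc_state("S1", 4, 0.05, c(1, 0, 0))),
                  omega_unit = "cm-1")
  s1 <- compute_vrr(m1, "vg_int", settings = fast_settings(), scale = 0.96)
  expect_equal(s1$shift_cm1, 960, tolerance = 1e-9)
})

test_that("excitation matching against the absorption maximum", {
  expect_equal(match_excitation(5.0, 4.8, 4.8), 5.0)
  expect_equal(match_excitation(convert(233, "nm", "eV"), 5.1, 4.6),
               convert(233, "nm", "eV") + 0.5)

  # parabolic refinement of the absorption argmax approaches the fine-grid
  # maximum
  m <- fixture_displaced()
  s_coarse <- fast_settings(); s_coarse$omega_step_ev <- 0.02
  s_fine <- fast_settings(); s_fine$omega_step_ev <- 0.001
  pk_c <- abs_peak(absorption_spectrum(m, "lvc", 0.08, s_coarse))
  pk_f <- abs_peak(absorption_spectrum(m, "lvc", 0.08, s_fine))
  expect_lt(abs(pk_c - pk_f), 0.02)
})

test_that("single-mode excitation profile peaks at a vibronic line", {
  m <- fixture_displaced(S = 0.5, energy = 4.5)
  s <- spectrum_settings(gamma_ev = 0.04, dt = 0.05, tmax = 350,
                         n_tot = 16, omega_step_ev = 0.005)
  spec <- compute_vrr(m, "vg_int", settings = s)
  prof <- excitation_profile(spec, 1)
  omega <- m$modes$omega
  e00 <- 4.5 - 0.5 * omega # adiabatic 0-0 line
  lines <- e00 + omega * (0:4)
  peak <- prof$omega_ev[which.max(prof$intensity)]
  expect_lt(min(abs(peak - lines)), 0.04)
})
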
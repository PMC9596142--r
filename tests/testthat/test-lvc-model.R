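test_that("validate_model reports invariant violations without raising", {
  good <- fixture_conical()
  expect_identical(validate_model(good), character(0))

  bad <- lvc_model(c(0.1, 0.15), list(
    lvc_state("S1", 4.5, c(0.1, 0.1, 0.1)) # gradient too long
  ))
  v <- validate_model(bad)
  expect_length(v, 1L)
  expect_match(v, "state S1.*length 3, expected 2")

  dup <- lvc_model(0.1, list(
    lvc_state("A", 4, 0.01), lvc_state("B", 5, 0.01)
  ), list(lvc_coupling("A", "B", 0.01), lvc_coupling("B", "A", 0.02)))
  expect_match(validate_model(dup), "duplicate unordered pair",
               all = FALSE)

  neg <- lvc_model(c(-0.1), list(lvc_state("S1", 4, 0)))
  expect_match(validate_model(neg), "omega must be > 0", all = FALSE)
})

test_that("symmetry_audit enforces the two-irrep selection rules", {
  # allowed pattern: A' state displaced along A' modes only
  expect_identical(symmetry_audit(fixture_cs()), character(0))

  # A'-A'' coupling with a component on an A' mode
  m <- fixture_cs()
  m$couplings[[1]]$lam <- c(0.05, 0, 0.08)
  w <- symmetry_audit(m)
  expect_length(w, 1L)
  expect_match(w, "coupling \\(pipi1, npi\\).*mode 1")

  # A'-A' coupling on an A'' mode
  m2 <- fixture_cs()
  m2$couplings[[2]]$lam <- c(0, 0, 0.05)
  expect_match(symmetry_audit(m2), "coupling \\(pipi1, pipi2\\).*mode 3",
               all = FALSE)

  # gradient on a non-totally-symmetric mode
  m3 <- fixture_cs()
  m3$states$pipi1$gradient[3] <- 0.01
  expect_match(symmetry_audit(m3), "state pipi1.*mode 3", all = FALSE)

  m4 <- fixture_cs()
  m4$modes$symmetry[1] <- "B2"
  expect_error(symmetry_audit(m4), "accepted labels")
})

test_that("huang_rhys matches its closed form", {
  m <- fixture_displaced(S = 0.5)
  expect_equal(huang_rhys(m, "S1"), 0.5, tolerance = 1e-12)

  m0 <- lvc_model(0.1, list(lvc_state("S1", 4, 0)))
  expect_identical(huang_rhys(m0, "S1"), 0)

  # lambda = omega = 0.1 eV -> S = 0.5 exactly
  m1 <- lvc_model(0.1, list(lvc_state("S1", 4, 0.1)))
  expect_equal(huang_rhys(m1, "S1"), 0.5)

  rm <- random_model(4, 2, seed = 11)
  for (lb in state_labels(rm)) {
    want <- (rm$states[[lb]]$gradient / rm$modes$omega)^2 / 2
    expect_equal(huang_rhys(rm, lb), want, tolerance = 1e-14)
  }
  expect_error(huang_rhys(m, "nope"), "unknown state label")
})

test_that("apply_state_shift shifts only the listed energies", {
  m <- fixture_cs()
  expect_identical(apply_state_shift(m, "pipi1", 0), m)

  shifted <- apply_state_shift(m, c("npi", "pipi2"), -0.3)
  expect_equal(shifted$states$npi$energy, m$states$npi$energy - 0.3)
  expect_equal(shifted$states$pipi2$energy, m$states$pipi2$energy - 0.3)
  expect_identical(shifted$states$pipi1, m$states$pipi1)
  expect_identical(shifted$modes, m$modes)
  expect_identical(shifted$couplings, m$couplings)

  back <- apply_state_shift(shifted, c("npi", "pipi2"), 0.3)
  for (lb in state_labels(m)) {
    expect_equal(back$states[[lb]]$energy, m$states[[lb]]$energy,
                 tolerance = 1e-15)
  }
  expect_error(apply_state_shift(m, "ghost", 0.1), "unknown state label")
})

test_that("random_model is deterministic and respects its ranges", {
  f1 <- tempfile(); f2 <- tempfile()
  write_lvc_model(random_model(3, 2, seed = 42), f1)
  write_lvc_model(random_model(3, 2, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))

  m1 <- random_model(3, 2, seed = 1)
  m2 <- random_model(3, 2, seed = 2)
  expect_false(identical(m1, m2))

  flat <- random_model(3, 2, seed = 5, ranges = list(lam_ev = c(0, 0)))
  expect_true(all(vibraman:::gradient_matrix(flat) == 0))
  expect_true(all(vapply(flat$couplings, function(cp) all(cp$lam == 0),
                         logical(1))))

  for (seed in 1:5) {
    expect_identical(validate_model(random_model(3, 3, seed = seed)),
                     character(0))
  }
  expect_error(random_model(2, 2, seed = 1,
                            ranges = list(energy_ev = c(5, 4))),
               "invalid range")
})

test_that("JSON round trip preserves every numeric field", {
  m <- random_model(3, 3, seed = 9, coupling_fraction = 0.7)
  f <- tempfile(fileext = ".json")
  write_lvc_model(m, f)
  back <- read_lvc_model(f)
  expect_equal(back$modes$omega, m$modes$omega, tolerance = 1e-15)
  expect_identical(back$modes$symmetry, m$modes$symmetry)
  for (lb in state_labels(m)) {
    expect_equal(back$states[[lb]], m$states[[lb]], tolerance = 1e-15)
  }
  expect_equal(back$couplings, m$couplings, tolerance = 1e-15)
  expect_equal(zpe(back), zpe(m), tolerance = 1e-15)
})

test_that("model files with unknown or missing keys are rejected", {
  f <- tempfile(fileext = ".json")
  write_lvc_model(fixture_displaced(), f)
  obj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  obj$surprise <- 1
  jsonlite::write_json(obj, f, auto_unbox = TRUE)
  expect_error(read_lvc_model(f), "unknown key")

  obj$surprise <- NULL
  obj$states[[1]]$energy_ev <- NULL
  jsonlite::write_json(obj, f, auto_unbox = TRUE)
  expect_error(read_lvc_model(f), "missing key")

  expect_error(read_lvc_model(tempfile()), "not found")
})

test_that("zpe is recomputed from the mode list", {
  m <- fixture_three_mode()
  expect_equal(zpe(m), sum(m$modes$omega) / 2)
  m$modes$omega[1] <- m$modes$omega[1] * 2
  expect_equal(zpe(m), sum(m$modes$omega) / 2)
})
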
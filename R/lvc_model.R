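# Linear vibronic coupling (LVC) models.
#
# A model consists of nmodes ground-state normal modes (shared by every
# diabatic electronic state), nstates excited diabatic states, and at most
# one coupling vector per unordered pair of states:
#
#   V_g    = sum_j omega_j q_j^2 / 2
#   V_i    = E_i + sum_j (omega_j q_j^2 / 2 + lambda_ii,j q_j)
#   V_ij   = sum_j lambda_ij,j q_j            (i != j)
#
# in dimensionless normal coordinates q with hbar = 1 and everything in eV.
# The excited-state minimum along mode j sits at q_j = -lambda_j / omega_j
# and the Huang-Rhys factor is S_j = lambda_j^2 / (2 omega_j^2).

#' Construct an excited diabatic state specification
#'
#' @param label unique state name.
#' @param energy vertical excitation energy at the ground-state equilibrium
#'   geometry (eV).
#' @param gradient numeric vector of intrastate energy gradients
#'   `lambda_ii` over modes (eV per dimensionless coordinate).
#' @param dipole length-3 transition dipole from the ground state
#'   (Franck-Condon constant vector, arbitrary consistent units).
#' @param symmetry irrep label (free text, e.g. `"A'"` or `"A''"`).
#' @return an object of class `lvc_state`.
#' @export
lvc_state <- function(label, energy, gradient, dipole = c(0, 0, 0),
                      symmetry = "A'") {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(energy), length(energy) == 1L,
            is.numeric(gradient), is.numeric(dipole))
  structure(list(label = label, symmetry = symmetry,
                 energy = as.numeric(energy),
                 gradient = as.numeric(gradient),
                 dipole = as.numeric(dipole)),
            class = "lvc_state")
}

#' Construct an interstate coupling specification
#'
#' Couplings are stored once per unordered pair; Hermiticity of the
#' potential matrix is structural (`lambda_ij = lambda_ji` by construction).
#'
#' @param bra,ket state labels (unordered pair, must differ).
#' @param lam numeric vector of coupling gradients over modes (eV).
#' @return an object of class `lvc_coupling`.
#' @export
lvc_coupling <- function(bra, ket, lam) {
  stopifnot(is.character(bra), is.character(ket), is.numeric(lam))
  structure(list(bra = bra, ket = ket, lam = as.numeric(lam)),
            class = "lvc_coupling")
}

#' Construct a linear vibronic coupling model
#'
#' Minimal type checks only: structural invariants (dimension consistency,
#' uniqueness) are reported by [validate_model()], which allows deliberately
#' ill-formed models to be built and inspected.
#'
#' @param omega ground-state harmonic frequencies, one per mode.
#' @param states list of [lvc_state()] objects.
#' @param couplings list of [lvc_coupling()] objects.
#' @param mode_symmetry character vector of mode irrep labels
#'   (default all `"A'"`).
#' @param omega_unit `"eV"` (internal) or `"cm-1"` (file convention).
#' @return an object of class `lvc_model`.
#' @export
lvc_model <- function(omega, states, couplings = list(),
                      mode_symmetry = NULL, omega_unit = "eV") {
  stopifnot(is.numeric(omega), is.list(states), is.list(couplings))
  if (inherits(states, "lvc_state")) states <- list(states)
  if (inherits(couplings, "lvc_coupling")) couplings <- list(couplings)
  omega <- as.numeric(convert(omega, omega_unit, "eV"))
  if (is.null(mode_symmetry)) mode_symmetry <- rep("A'", length(omega))
  modes <- data.frame(index = seq_along(omega), omega = omega,
                      symmetry = as.character(mode_symmetry),
                      stringsAsFactors = FALSE)
  labels <- vapply(states, function(s) s$label, character(1))
  names(states) <- labels
  structure(list(modes = modes, states = states, couplings = couplings),
            class = "lvc_model")
}

#' @export
print.lvc_model <- function(x, ...) {
  cat(sprintf("LVC model: %d mode(s), %d state(s), %d coupling vector(s)\n",
              nmodes(x), nstates(x), length(x$couplings)))
  cat(sprintf("  zero-point energy E_g0 = %.6f eV\n", zpe(x)))
  for (s in x$states) {
    cat(sprintf("  state %-10s %-4s E = %.4f eV  |mu| = %.4f\n",
                s$label, s$symmetry, s$energy, sqrt(sum(s$dipole^2))))
  }
  invisible(x)
}

#' Number of modes / states of an LVC model
#' @param model an `lvc_model`.
#' @return integer count.
#' @export
nmodes <- function(model) nrow(model$modes)

#' @rdname nmodes
#' @export
nstates <- function(model) length(model$states)

#' @rdname nmodes
#' @export
state_labels <- function(model) names(model$states)

#' Ground-state vibrational zero-point energy
#'
#' `E_g0 = sum_j omega_j / 2`, recomputed on access (never stored).
#'
#' @param model an `lvc_model`.
#' @return scalar energy in eV.
#' @export
zpe <- function(model) sum(model$modes$omega) / 2

# 3 x nstates matrix of transition dipoles, columns ordered as states
dipole_matrix <- function(model) {
  matrix(vapply(model$states, function(s) s$dipole, numeric(3)),
         nrow = 3, dimnames = list(NULL, state_labels(model)))
}

# nmodes x nstates matrix of intrastate gradients
gradient_matrix <- function(model) {
  matrix(vapply(model$states, function(s) s$gradient,
                numeric(nmodes(model))),
         nrow = nmodes(model))
}

# coupling vector between two states (by label or index); zeros if absent
coupling_lambda <- function(model, i, j) {
  labs <- state_labels(model)
  if (is.numeric(i)) i <- labs[i]
  if (is.numeric(j)) j <- labs[j]
  for (cp in model$couplings) {
    if ((cp$bra == i && cp$ket == j) || (cp$bra == j && cp$ket == i)) {
      return(cp$lam)
    }
  }
  numeric(nmodes(model))
}

#' Validate the structural invariants of an LVC model
#'
#' Reports violations rather than raising, so that malformed inputs can be
#' diagnosed in bulk (the CLI `validate` subcommand prints this list).
#'
#' @param model an `lvc_model`.
#' @return character vector of violations; empty when the model is
#'   well-formed.
#' @export
validate_model <- function(model) {
  v <- character(0)
  nm <- nmodes(model)
  if (nm < 1L) v <- c(v, "model has no modes")
  if (any(model$modes$omega <= 0)) {
    v <- c(v, sprintf("mode %d: omega must be > 0",
                      model$modes$index[model$modes$omega <= 0]))
  }
  if (!identical(as.integer(model$modes$index), seq_len(nm))) {
    v <- c(v, "mode indices must be unique and contiguous starting at 1")
  }
  labs <- vapply(model$states, function(s) s$label, character(1))
  if (anyDuplicated(labs)) {
    v <- c(v, paste0("duplicate state label: ",
                     paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  }
  for (s in model$states) {
    if (!is.finite(s$energy) || s$energy <= 0) {
      v <- c(v, sprintf("state %s: energy must be > 0", s$label))
    }
    if (length(s$gradient) != nm) {
      v <- c(v, sprintf("state %s: gradient has length %d, expected %d",
                        s$label, length(s$gradient), nm))
    }
    if (length(s$dipole) != 3L) {
      v <- c(v, sprintf("state %s: dipole has length %d, expected 3",
                        s$label, length(s$dipole)))
    }
  }
  seen <- character(0)
  for (cp in model$couplings) {
    if (!(cp$bra %in% labs)) {
      v <- c(v, sprintf("coupling references unknown state '%s'", cp$bra))
    }
    if (!(cp$ket %in% labs)) {
      v <- c(v, sprintf("coupling references unknown state '%s'", cp$ket))
    }
    if (identical(cp$bra, cp$ket)) {
      v <- c(v, sprintf("coupling (%s, %s): bra and ket must differ",
                        cp$bra, cp$ket))
    }
    if (length(cp$lam) != nm) {
      v <- c(v, sprintf("coupling (%s, %s): lambda has length %d, expected %d",
                        cp$bra, cp$ket, length(cp$lam), nm))
    }
    key <- paste(sort(c(cp$bra, cp$ket)), collapse = "\r")
    if (key %in% seen) {
      v <- c(v, sprintf("duplicate unordered pair (%s, %s)", cp$bra, cp$ket))
    }
    seen <- c(seen, key)
  }
  v
}

.stop_if_invalid <- function(model) {
  v <- validate_model(model)
  if (length(v)) {
    stop("invalid LVC model:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  invisible(model)
}

#' Audit symmetry selection rules of an LVC model
#'
#' For a two-irrep point group (e.g. Cs with irreps A' and A''), intrastate
#' gradients may only have nonzero components on totally symmetric modes,
#' and the coupling between states of irreps `Gi` and `Gj` may only involve
#' modes of irrep `Gi (x) Gj`. Violations are returned as warnings; they are
#' physically inconsistent parametrizations, not hard errors.
#'
#' @param model an `lvc_model` whose modes and states all carry irrep labels.
#' @param totally_symmetric_label label of the totally symmetric irrep
#'   (default `"A'"`).
#' @return character vector of warnings; empty when all selection rules hold.
#' @export
symmetry_audit <- function(model, totally_symmetric_label = "A'") {
  labs <- unique(c(model$modes$symmetry,
                   vapply(model$states, function(s) s$symmetry, character(1)),
                   totally_symmetric_label))
  if (length(labs) > 2L) {
    stop("more than two irrep labels found (", paste(labs, collapse = ", "),
         "); accepted labels are the totally symmetric one ('",
         totally_symmetric_label, "') plus exactly one other", call. = FALSE)
  }
  ts <- totally_symmetric_label
  other <- setdiff(labs, ts)
  prod_irrep <- function(a, b) if (identical(a, b)) ts else other
  warnings <- character(0)
  msym <- model$modes$symmetry
  for (s in model$states) {
    bad <- which(s$gradient != 0 & msym != ts)
    for (j in bad) {
      warnings <- c(warnings, sprintf(
        "state %s: gradient has nonzero component on non-totally-symmetric mode %d (%s)",
        s$label, j, msym[j]))
    }
  }
  for (cp in model$couplings) {
    gi <- model$states[[cp$bra]]$symmetry
    gj <- model$states[[cp$ket]]$symmetry
    expected <- prod_irrep(gi, gj)
    bad <- which(cp$lam != 0 & msym != expected)
    for (j in bad) {
      warnings <- c(warnings, sprintf(
        "coupling (%s, %s): nonzero component on mode %d (%s), expected irrep %s",
        cp$bra, cp$ket, j, msym[j], expected))
    }
  }
  warnings
}

#' Huang-Rhys factors of one excited state
#'
#' `S_j = lambda_j^2 / (2 omega_j^2)`, the dimensionless squared
#' displacement / 2 of the excited-state minimum along each mode. Ranks the
#' Franck-Condon (and hence resonance-Raman) activity of the modes.
#'
#' @param model an `lvc_model`.
#' @param state_label which state's intrastate gradient to use.
#' @return numeric vector `S_j` over modes.
#' @export
huang_rhys <- function(model, state_label) {
  s <- model$states[[state_label]]
  if (is.null(s)) {
    stop("unknown state label '", state_label, "'; available: ",
         paste(state_labels(model), collapse = ", "), call. = FALSE)
  }
  (s$gradient / model$modes$omega)^2 / 2
}

#' Shift the vertical energies of selected states
#'
#' Returns a new model in which `energy <- energy + delta` for the listed
#' states only; every other field is untouched. Used e.g. to red-shift
#' selected higher-lying states before recomputing spectra.
#'
#' @param model an `lvc_model`.
#' @param labels character vector of state labels to shift.
#' @param delta energy shift in eV (negative = red shift).
#' @return the shifted `lvc_model`.
#' @export
apply_state_shift <- function(model, labels, delta) {
  unknown <- setdiff(labels, state_labels(model))
  if (length(unknown)) {
    stop("unknown state label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (lb in labels) {
    model$states[[lb]]$energy <- model$states[[lb]]$energy + delta
  }
  model
}

# Run code with a deterministic RNG stream, restoring the caller's state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random LVC model (seeded fixture generator)
#'
#' Deterministic for a fixed seed: uses R's default Mersenne-Twister stream
#' with a fixed draw order (frequencies, then per state energy / gradient /
#' dipole, then per unordered pair a keep-decision and a coupling vector).
#' All magnitudes are uniform within `ranges`; gradient, dipole and coupling
#' components get independent random signs.
#'
#' @param nmodes,nstates model size (each at least 1).
#' @param seed integer RNG seed.
#' @param ranges list with elements `omega_cm1`, `energy_ev`, `lam_ev`,
#'   `dipole`, each a `c(min, max)` pair for the component magnitudes.
#' @param coupling_fraction probability that a given unordered pair carries
#'   a nonzero coupling vector (remaining pairs are zeroed).
#' @return an `lvc_model` satisfying all structural invariants.
#' @export
random_model <- function(nmodes, nstates, seed,
                         ranges = list(), coupling_fraction = 1) {
  stopifnot(nmodes >= 1L, nstates >= 1L)
  def <- list(omega_cm1 = c(400, 1800), energy_ev = c(4, 6.5),
              lam_ev = c(0, 0.12), dipole = c(0, 1))
  ranges <- utils::modifyList(def, ranges)
  for (nm in names(def)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2]) {
      stop("invalid range for ", nm, ": min must not exceed max",
           call. = FALSE)
    }
  }
  .with_seed(seed, {
    omega <- sort(stats::runif(nmodes, ranges$omega_cm1[1],
                               ranges$omega_cm1[2])) / .CM1_PER_EV
    rsign <- function(n) ifelse(stats::runif(n) < 0.5, -1, 1)
    states <- vector("list", nstates)
    for (i in seq_len(nstates)) {
      energy <- stats::runif(1, ranges$energy_ev[1], ranges$energy_ev[2])
      grad <- stats::runif(nmodes, ranges$lam_ev[1], ranges$lam_ev[2]) *
        rsign(nmodes)
      dip <- stats::runif(3, ranges$dipole[1], ranges$dipole[2]) * rsign(3)
      states[[i]] <- lvc_state(sprintf("S%d", i), energy, grad, dip)
    }
    couplings <- list()
    if (nstates > 1L) {
      for (i in seq_len(nstates - 1L)) {
        for (j in seq(i + 1L, nstates)) {
          keep <- stats::runif(1) < coupling_fraction
          lam <- stats::runif(nmodes, ranges$lam_ev[1], ranges$lam_ev[2]) *
            rsign(nmodes)
          if (!keep) lam <- numeric(nmodes)
          couplings[[length(couplings) + 1L]] <-
            lvc_coupling(sprintf("S%d", i), sprintf("S%d", j), lam)
        }
      }
    }
    lvc_model(omega, states, couplings)
  })
}
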
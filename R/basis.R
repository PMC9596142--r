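# Truncated harmonic-oscillator product basis, replicated per diabatic
# electronic state. Ordering is pinned (state-major, then graded
# lexicographic in the occupation vector) so that stored regression
# baselines remain stable.

#' Basis truncation specification
#'
#' @param n_tot total-quanta cap: occupation vectors satisfy
#'   `sum(n) <= n_tot`.
#' @param n_max per-mode cap (scalar recycled or vector); `Inf` means
#'   limited by `n_tot` only.
#' @return an object of class `basis_spec`.
#' @export
basis_spec <- function(n_tot, n_max = Inf) {
  stopifnot(n_tot >= 0, all(n_max >= 1 | n_tot == 0))
  structure(list(n_tot = as.integer(n_tot), n_max = n_max),
            class = "basis_spec")
}

# Occupation vectors with sum == g, n_j <= n_max_j, reverse-lexicographic
# (leading mode descending), as integer matrix rows.
.compositions <- function(g, n_max) {
  k <- length(n_max)
  if (k == 1L) {
    if (g <= n_max[1]) return(matrix(as.integer(g), 1L, 1L))
    return(matrix(integer(0), 0L, 1L))
  }
  rows <- list()
  for (n1 in seq(min(g, n_max[1]), 0L)) {
    rest <- .compositions(g - n1, n_max[-1])
    if (nrow(rest)) {
      rows[[length(rows) + 1L]] <- cbind(as.integer(n1), rest,
                                         deparse.level = 0)
    }
  }
  if (length(rows)) do.call(rbind, rows) else matrix(integer(0), 0L, k)
}

#' Enumerate the vibronic product basis
#'
#' Elements are pairs (electronic state, occupation vector `n`) with
#' `sum(n) <= n_tot` and `n_j <= n_max_j`; the identical vibrational basis
#' is replicated for each electronic state. Global element index is
#' `(state - 1) * nvib + vib_index` with vibrational states ordered by
#' total quanta, then reverse-lexicographically.
#'
#' @param nmodes number of modes.
#' @param spec a [basis_spec()].
#' @param nstates number of electronic states.
#' @param cap hard cap on the total dimension (default 2e5).
#' @return an object of class `vibronic_basis`.
#' @export
enumerate_basis <- function(nmodes, spec, nstates, cap = 2e5) {
  stopifnot(inherits(spec, "basis_spec"), nmodes >= 1L, nstates >= 1L)
  n_max <- rep_len(spec$n_max, nmodes)
  n_max <- pmin(n_max, spec$n_tot)
  grades <- lapply(0:spec$n_tot, .compositions, n_max = n_max)
  occ <- do.call(rbind, grades)
  nvib <- nrow(occ)
  nstates <- as.integer(nstates)
  dim_total <- nvib * nstates
  if (dim_total > cap) {
    stop("basis dimension ", dim_total, " exceeds the hard cap ", cap,
         "; reduce n_tot/n_max or raise `cap`", call. = FALSE)
  }
  keys <- apply(occ, 1L, paste, collapse = ",")
  lookup <- stats::setNames(seq_len(nvib), keys)
  # raise[v, j] = vib index of occ[v, ] + e_j, NA if outside the basis
  raise <- matrix(NA_integer_, nvib, nmodes)
  lower <- matrix(NA_integer_, nvib, nmodes)
  for (j in seq_len(nmodes)) {
    up <- occ
    up[, j] <- up[, j] + 1L
    raise[, j] <- unname(lookup[apply(up, 1L, paste, collapse = ",")])
    ok <- which(!is.na(raise[, j]))
    lower[raise[ok, j], j] <- ok
  }
  structure(list(occ = occ, nvib = nvib, nmodes = nmodes,
                 nstates = nstates, dim = dim_total,
                 n_tot = spec$n_tot, n_max = n_max,
                 lookup = lookup, raise = raise, lower = lower),
            class = "vibronic_basis")
}

#' @export
print.vibronic_basis <- function(x, ...) {
  cat(sprintf(
    "vibronic basis: %d modes, %d states, %d vib x %d = %d elements (N_tot = %d)\n",
    x$nmodes, x$nstates, x$nvib, x$nstates, x$dim, x$n_tot))
  invisible(x)
}

#' Global index of a basis element
#'
#' @param basis a `vibronic_basis`.
#' @param state electronic state index (1-based).
#' @param occ occupation vector (length nmodes).
#' @return integer index into the amplitude vector, or an error if the
#'   element is not in the basis.
#' @export
basis_index <- function(basis, state, occ) {
  stopifnot(state >= 1L, state <= basis$nstates)
  v <- basis$lookup[paste(as.integer(occ), collapse = ",")]
  if (is.na(v)) {
    stop("occupation (", paste(occ, collapse = ","),
         ") is not in the basis", call. = FALSE)
  }
  (as.integer(state) - 1L) * basis$nvib + unname(v)
}

# vib index of |0> and of the fundamentals |0 + 1_f>
.vib_ground <- function(basis) unname(basis$lookup[paste(rep(0L, basis$nmodes),
                                                         collapse = ",")])
.vib_fundamental <- function(basis, f) {
  occ <- rep(0L, basis$nmodes)
  occ[f] <- 1L
  idx <- basis$lookup[paste(occ, collapse = ",")]
  if (is.na(idx)) {
    stop("basis lacks the fundamental |0 + 1_", f,
         ">; increase n_tot/n_max", call. = FALSE)
  }
  unname(idx)
}

#' Initial wavepacket after vertical excitation
#'
#' The ground vibrational state placed on diabatic state `state`:
#' `|Psi(0)> = |d_state; 0>`.
#'
#' @param basis a `vibronic_basis`.
#' @param state electronic state index.
#' @return an object of class `wavepacket` (complex amplitude vector plus
#'   basis reference).
#' @export
initial_wavepacket <- function(basis, state) {
  amp <- complex(basis$dim)
  amp[basis_index(basis, state, rep(0L, basis$nmodes))] <- 1 + 0i
  structure(list(basis = basis, amp = amp), class = "wavepacket")
}
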
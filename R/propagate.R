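# Wavepacket propagation psi(t) = exp(-i H t) psi(0).
#
# Two routes: a cached eigendecomposition (exact to machine precision,
# the default up to dimension 4000) and a Lanczos/Krylov exponential
# action with adaptive substepping for larger problems or cross-checks.

.check_tgrid <- function(tgrid) {
  if (length(tgrid) < 1L || abs(tgrid[1]) > 1e-12) {
    stop("time grid must start at 0", call. = FALSE)
  }
  if (length(tgrid) > 1L) {
    dt <- diff(tgrid)
    if (any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1))) {
      stop("time grid must be uniform", call. = FALSE)
    }
  }
  invisible(tgrid)
}

#' Propagate a wavepacket on an LVC Hamiltonian
#'
#' Computes `psi(t) = exp(-i H t) psi(0)` on a uniform time grid starting
#' at 0. The eigendecomposition route is exact (used for dimensions up to
#' 4000); the Krylov route applies a Lanczos approximation of the matrix
#' exponential per step with target per-step error `tol`, halving the
#' internal substep until the error estimate passes.
#'
#' @param h an `lvc_hamiltonian`.
#' @param psi0 a `wavepacket` (see [initial_wavepacket()]) or a complex
#'   amplitude vector; should be normalized.
#' @param tgrid uniform time grid in hbar/eV, starting at 0.
#' @param method `"auto"` (eigen below dimension 4000, Krylov above),
#'   `"eigen"`, or `"krylov"`.
#' @param tol per-step error tolerance for the Krylov route.
#' @return an object of class `wavepacket_trajectory` holding the complex
#'   amplitude matrix (dim x ntimes), the grid, and per-time norms.
#' @export
propagate <- function(h, psi0, tgrid, method = c("auto", "eigen", "krylov"),
                      tol = 1e-9) {
  method <- match.arg(method)
  .check_tgrid(tgrid)
  amp0 <- if (inherits(psi0, "wavepacket")) psi0$amp else as.complex(psi0)
  stopifnot(length(amp0) == h$dim)
  if (method == "auto") method <- if (h$dim <= 4000) "eigen" else "krylov"
  nt <- length(tgrid)
  if (method == "eigen") {
    eig <- ham_eigen(h)
    c0 <- as.vector(crossprod(eig$vectors, amp0))
    amp <- matrix(complex(1), h$dim, nt)
    chunk <- max(1L, floor(4e6 / h$dim))
    for (start in seq(1L, nt, by = chunk)) {
      idx <- start:min(start + chunk - 1L, nt)
      phases <- exp(outer(eig$values, tgrid[idx],
                          function(e, t) -1i * e * t)) * c0
      amp[, idx] <- eig$vectors %*% phases
    }
  } else {
    amp <- matrix(complex(1), h$dim, nt)
    amp[, 1] <- amp0
    dt <- if (nt > 1L) tgrid[2] - tgrid[1] else 0
    v <- amp0
    for (i in seq_len(nt - 1L)) {
      v <- .krylov_expv(h, v, dt, tol = tol)
      amp[, i + 1L] <- v
    }
  }
  norms <- sqrt(colSums(Mod(amp)^2))
  structure(list(basis = h$basis, tgrid = tgrid, amp = amp, norms = norms,
                 method = method),
            class = "wavepacket_trajectory")
}

#' @export
print.wavepacket_trajectory <- function(x, ...) {
  cat(sprintf(
    "wavepacket trajectory: dim %d, %d time points (t <= %.2f hbar/eV), %s route\n",
    nrow(x$amp), length(x$tgrid), max(x$tgrid), x$method))
  cat(sprintf("  norm drift: %.3e\n", max(abs(x$norms - x$norms[1]))))
  invisible(x)
}

# Lanczos approximation of exp(-i dt H) v with a posteriori error estimate;
# recursively halves the step when the estimate exceeds tol.
.krylov_expv <- function(h, v, dt, tol = 1e-9, m = 30L, depth = 0L) {
  if (dt == 0) return(v)
  if (depth > 30L) {
    stop("Krylov propagation failed to reach tolerance ", tol, call. = FALSE)
  }
  beta <- sqrt(sum(Mod(v)^2))
  if (beta == 0) return(v)
  n <- length(v)
  m <- min(m, n)
  V <- matrix(complex(1), n, m)
  alpha <- numeric(m)
  bet <- numeric(m) # bet[k] couples k and k+1
  V[, 1] <- v / beta
  w <- ham_apply(h, V[, 1])
  alpha[1] <- Re(sum(Conj(V[, 1]) * w))
  w <- w - alpha[1] * V[, 1]
  k <- 1L
  while (k < m) {
    b <- sqrt(sum(Mod(w)^2))
    if (b < 1e-14) break # happy breakdown: Krylov space is invariant
    bet[k] <- b
    V[, k + 1L] <- w / b
    w <- ham_apply(h, V[, k + 1L])
    alpha[k + 1L] <- Re(sum(Conj(V[, k + 1L]) * w))
    w <- w - alpha[k + 1L] * V[, k + 1L] - b * V[, k]
    # one re-orthogonalization pass keeps the basis clean at long steps
    w <- w - V[, 1:(k + 1L)] %*% crossprod(Conj(V[, 1:(k + 1L)]), w)
    k <- k + 1L
  }
  Tm <- diag(alpha[1:k], k, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      Tm[i, i + 1L] <- bet[i]
      Tm[i + 1L, i] <- bet[i]
    }
  }
  et <- eigen(Tm, symmetric = TRUE)
  u <- et$vectors %*% (exp(-1i * dt * et$values) *
                         as.vector(crossprod(et$vectors, c(1, rep(0, k - 1L)))))
  err <- if (k < m) 0 else abs(bet[k - 1L] * dt * abs(u[k]))
  if (err > tol) {
    half <- .krylov_expv(h, v, dt / 2, tol / 2, m, depth + 1L)
    return(.krylov_expv(h, half, dt / 2, tol / 2, m, depth + 1L))
  }
  as.vector(V[, 1:k] %*% u) * beta
}
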
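# Assembly of the LVC Hamiltonian in the truncated vibronic basis.
#
# With q_j = (a_j + a_j^dag)/sqrt(2), the only nonzero q matrix elements
# are <n_j + 1 | q_j | n_j> = sqrt((n_j + 1)/2). Diagonal blocks carry the
# harmonic ladder energies plus the intrastate gradient ladder terms;
# off-diagonal blocks carry the interstate coupling ladder terms only.
# The matrix is assembled exactly symmetric (same double stored in both
# triangles), so Hermiticity holds to the bit.

#' Build the LVC Hamiltonian operator
#'
#' @param model a validated `lvc_model`.
#' @param basis a `vibronic_basis` with matching `nmodes`/`nstates`.
#' @param sparse materialize as a `Matrix::dgCMatrix` instead of a dense
#'   base matrix (useful above a few thousand basis elements).
#' @return an object of class `lvc_hamiltonian`: the matrix, its dimension,
#'   and references to model and basis. Eigendecompositions are cached on
#'   first use.
#' @export
build_hamiltonian <- function(model, basis, sparse = FALSE) {
  .stop_if_invalid(model)
  if (basis$nmodes != nmodes(model) || basis$nstates != nstates(model)) {
    stop("basis dimensions do not match the model (modes ", basis$nmodes,
         "/", nmodes(model), ", states ", basis$nstates, "/",
         nstates(model), ")", call. = FALSE)
  }
  nvib <- basis$nvib
  ns <- basis$nstates
  omega <- model$modes$omega
  energies <- vapply(model$states, function(s) s$energy, numeric(1))
  grads <- gradient_matrix(model) # nmodes x nstates
  # vibrational ladder structure, shared by all blocks:
  # for each mode j, pairs (v, raise[v,j]) with amplitude sqrt((n_j+1)/2)
  lad_i <- integer(0); lad_j <- integer(0); lad_amp <- numeric(0)
  lad_mode <- integer(0)
  for (j in seq_len(basis$nmodes)) {
    ok <- which(!is.na(basis$raise[, j]))
    lad_i <- c(lad_i, ok)
    lad_j <- c(lad_j, basis$raise[ok, j])
    lad_amp <- c(lad_amp, sqrt((basis$occ[ok, j] + 1) / 2))
    lad_mode <- c(lad_mode, rep(j, length(ok)))
  }
  evib <- as.vector(basis$occ %*% omega) + sum(omega) / 2
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  add <- function(i, j, x) {
    keep <- x != 0
    ti <<- c(ti, i[keep]); tj <<- c(tj, j[keep]); tx <<- c(tx, x[keep])
  }
  # diagonal
  for (k in seq_len(ns)) {
    o <- (k - 1L) * nvib
    add(o + seq_len(nvib), o + seq_len(nvib), energies[k] + evib)
  }
  # intrastate gradient ladder terms (upper triangle of each block)
  for (k in seq_len(ns)) {
    o <- (k - 1L) * nvib
    add(o + lad_i, o + lad_j, grads[lad_mode, k] * lad_amp)
  }
  # interstate couplings: block (ki, kj) gets lam_j ladder terms in both
  # vibrational orientations (q is symmetric within the vib space)
  labs <- state_labels(model)
  for (cp in model$couplings) {
    ki <- match(cp$bra, labs); kj <- match(cp$ket, labs)
    if (ki > kj) { tmp <- ki; ki <- kj; kj <- tmp }
    oi <- (ki - 1L) * nvib; oj <- (kj - 1L) * nvib
    val <- cp$lam[lad_mode] * lad_amp
    add(oi + lad_i, oj + lad_j, val)
    add(oi + lad_j, oj + lad_i, val)
  }
  dim_total <- basis$dim
  if (sparse) {
    upper <- ti <= tj
    mat <- Matrix::sparseMatrix(
      i = c(ti[upper], tj[!upper]), j = c(tj[upper], ti[!upper]),
      x = c(tx[upper], tx[!upper]), dims = c(dim_total, dim_total),
      symmetric = TRUE)
  } else {
    mat <- matrix(0, dim_total, dim_total)
    mat[cbind(ti, tj)] <- tx
    lowertri <- ti != tj
    mat[cbind(tj[lowertri], ti[lowertri])] <- tx[lowertri]
  }
  structure(list(mat = mat, dim = dim_total, basis = basis, model = model,
                 sparse = sparse, cache = new.env(parent = emptyenv())),
            class = "lvc_hamiltonian")
}

#' @export
print.lvc_hamiltonian <- function(x, ...) {
  cat(sprintf("LVC Hamiltonian: dimension %d (%s)\n", x$dim,
              if (x$sparse) "sparse" else "dense"))
  invisible(x)
}

# cached symmetric eigendecomposition
ham_eigen <- function(h) {
  if (is.null(h$cache$eig)) {
    mat <- if (h$sparse) as.matrix(h$mat) else h$mat
    if (nrow(mat) > 4000) {
      stop("dimension ", nrow(mat),
           " exceeds the full-diagonalization cap of 4000", call. = FALSE)
    }
    h$cache$eig <- eigen(mat, symmetric = TRUE)
  }
  h$cache$eig
}

ham_apply <- function(h, v) as.vector(h$mat %*% v)
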
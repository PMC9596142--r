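# JSON serialization of LVC models, schema_version "1".
#
# File units follow reporting conventions: frequencies in cm^-1, energies
# and gradients in eV, dipoles in arbitrary consistent units. One model per
# file; unknown keys are rejected so that typos in hand-written model files
# fail loudly.

.SCHEMA_VERSION <- "1"

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(allowed, names(x))
  if (length(missing)) {
    stop("missing key(s) in ", where, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Write an LVC model to a JSON file
#'
#' Numeric fields are written with maximum precision so that a write/read
#' round trip reproduces the model exactly.
#'
#' @param model an `lvc_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lvc_model <- function(model, path) {
  obj <- list(
    schema_version = .SCHEMA_VERSION,
    units = list(omega = "cm-1", energy = "eV", gradient = "eV",
                 dipole = "au"),
    modes = lapply(seq_len(nmodes(model)), function(j) {
      list(index = model$modes$index[j],
           omega_cm1 = model$modes$omega[j] * .CM1_PER_EV,
           symmetry = model$modes$symmetry[j])
    }),
    states = lapply(unname(model$states), function(s) {
      list(label = s$label, symmetry = s$symmetry, energy_ev = s$energy,
           gradient_ev = as.list(s$gradient), dipole = as.list(s$dipole))
    }),
    couplings = lapply(model$couplings, function(cp) {
      list(bra = cp$bra, ket = cp$ket, lambda_ev = as.list(cp$lam))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read an LVC model from a JSON file
#'
#' @param path path to a model file written by [write_lvc_model()] (or
#'   hand-written to the same schema).
#' @return an `lvc_model`.
#' @export
read_lvc_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .check_keys(obj, c("schema_version", "units", "modes", "states",
                     "couplings"), "model file")
  if (!identical(obj$schema_version, .SCHEMA_VERSION)) {
    stop("unsupported schema_version '", obj$schema_version,
         "' (expected '", .SCHEMA_VERSION, "')", call. = FALSE)
  }
  num <- function(x) vapply(x, as.numeric, numeric(1))
  omega_cm1 <- numeric(0)
  msym <- character(0)
  for (m in obj$modes) {
    .check_keys(m, c("index", "omega_cm1", "symmetry"), "mode entry")
    omega_cm1[m$index] <- m$omega_cm1
    msym[m$index] <- m$symmetry
  }
  states <- lapply(obj$states, function(s) {
    .check_keys(s, c("label", "symmetry", "energy_ev", "gradient_ev",
                     "dipole"), paste0("state '", s$label, "'"))
    lvc_state(s$label, s$energy_ev, num(s$gradient_ev), num(s$dipole),
              s$symmetry)
  })
  couplings <- lapply(obj$couplings, function(cp) {
    .check_keys(cp, c("bra", "ket", "lambda_ev"), "coupling entry")
    lvc_coupling(cp$bra, cp$ket, num(cp$lambda_ev))
  })
  lvc_model(omega_cm1, states, couplings, mode_symmetry = msym,
            omega_unit = "cm-1")
}
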
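# Unit conventions. Internally every energy-like quantity (frequencies,
# vertical energies, gradients, couplings, the damping gamma) is in eV,
# hbar = 1, so the natural time unit is hbar/eV; coordinates are
# dimensionless. Files report vibrational frequencies in cm^-1.
#
# The conversion factors are pinned constants (CODATA-derived) so that
# serialized fixtures are bit-stable across platforms.

.CM1_PER_EV <- 8065.543937
.NM_EV <- 1239.841984 # lambda[nm] * E[eV] for a photon
.FS_PER_HBAR_EV <- 0.658211957 # one hbar/eV expressed in femtoseconds

.normalize_unit <- function(u) {
  key <- tolower(gsub("[[:space:]]", "", u))
  out <- switch(key,
    "ev" = "eV",
    "cm-1" = "cm-1",
    "cm1" = "cm-1",
    "nm" = "nm",
    "fs" = "fs",
    "hbar/ev" = "hbar/eV",
    NULL
  )
  if (is.null(out)) {
    stop("unsupported unit '", u,
         "'; supported units: nm, eV, cm-1, fs, hbar/eV", call. = FALSE)
  }
  out
}

.unit_class <- function(u) {
  if (u %in% c("eV", "cm-1", "nm")) "energy" else "time"
}

#' Convert between the spectroscopic units used by the package
#'
#' Energy-like units are `"eV"`, `"cm-1"` and `"nm"` (photon wavelength,
#' a reciprocal scale: `E[eV] = 1239.841984 / lambda[nm]`). Time units are
#' `"fs"` and `"hbar/eV"` (the internal unit, 0.658211957 fs). Conversions
#' across the energy/time divide are rejected.
#'
#' @param value numeric vector to convert.
#' @param from,to unit names (case-insensitive).
#' @return numeric vector in the target unit.
#' @examples
#' convert(233, "nm", "eV")   # excitation at 233 nm, about 5.32 eV
#' convert(1, "eV", "cm-1")   # 8065.543937
#' @export
convert <- function(value, from, to) {
  from <- .normalize_unit(from)
  to <- .normalize_unit(to)
  if (.unit_class(from) != .unit_class(to)) {
    stop("cannot convert '", from, "' to '", to,
         "': incompatible unit classes", call. = FALSE)
  }
  if (from == to) return(value)
  if (.unit_class(from) == "time") {
    return(if (from == "fs") value / .FS_PER_HBAR_EV else value * .FS_PER_HBAR_EV)
  }
  ev <- switch(from,
    "eV" = value,
    "cm-1" = value / .CM1_PER_EV,
    "nm" = .NM_EV / value
  )
  switch(to,
    "eV" = ev,
    "cm-1" = ev * .CM1_PER_EV,
    "nm" = .NM_EV / ev
  )
}
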
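# Plain-text spectrum writers (TSV with '#' header lines) and the run
# manifest. All outputs are deterministic: no timestamps, no RNG.

.write_tsv <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write spectra to TSV files
#'
#' `write_vrr_map_tsv()` writes the 2D signal in long format
#' (omega_I, mode_index, raman_shift, intensity); `write_section_tsv()`
#' and `write_profile_tsv()` write 1D views; `write_abs_tsv()` writes an
#' absorption spectrum.
#'
#' @param spec the spectrum object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vrr_map_tsv <- function(spec, path) {
  df <- data.frame(
    omega_I_eV = rep(spec$omega_ev, each = length(spec$mode_index)),
    mode_index = rep(spec$mode_index, times = length(spec$omega_ev)),
    raman_shift_cm1 = rep(spec$shift_cm1, times = length(spec$omega_ev)),
    intensity_au = as.vector(spec$intensity)
  )
  .write_tsv(df, path, c(
    "# vRR 2D map (long format)",
    sprintf("# protocol: %s  gamma_eV: %g  scale: %g", spec$protocol,
            spec$gamma_ev, spec$scale),
    sprintf("# prefactor: %s", spec$prefactor)))
}

#' @rdname write_vrr_map_tsv
#' @param section a data.frame from [spectrum_section()].
#' @export
write_section_tsv <- function(section, path) {
  df <- data.frame(raman_shift_cm1 = section$raman_shift_cm1,
                   intensity_au = section$intensity)
  .write_tsv(df, path, c(
    sprintf("# omega_I_eV: %.6f", attr(section, "omega_ev")),
    sprintf("# conv_hwhm_cm1: %g", attr(section, "conv_hwhm_cm1"))))
}

#' @rdname write_vrr_map_tsv
#' @param profile a data.frame from [excitation_profile()].
#' @param f mode index (recorded in the header).
#' @export
write_profile_tsv <- function(profile, f, path) {
  df <- data.frame(omega_I_eV = profile$omega_ev,
                   intensity_au = profile$intensity)
  .write_tsv(df, path, sprintf("# Raman excitation profile, mode %d", f))
}

#' @rdname write_vrr_map_tsv
#' @export
write_abs_tsv <- function(spec, path) {
  df <- data.frame(omega_eV = spec$omega_ev, intensity_au = spec$intensity)
  .write_tsv(df, path, c(
    "# absorption spectrum",
    sprintf("# protocol: %s  gaussian_hwhm_eV: %g", spec$protocol,
            spec$hwhm_ev)))
}

# Manifest: every parameter needed to reproduce the run bit-for-bit, plus
# any convergence/truncation warnings collected along the way.
write_manifest <- function(path, command, params, warnings = character(0)) {
  obj <- list(
    tool = "vibraman",
    version = as.character(utils::packageVersion("vibraman")),
    command = command,
    parameters = params,
    warnings = as.list(warnings)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
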
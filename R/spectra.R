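#' Construct a wavelength-resolved spectrum
#'
#' Container for a single spectrum: a fluorescence emission scan, a raw
#' circular-dichroism trace in millidegrees, a Rayleigh-scattering series,
#' or a converted mean-residue-ellipticity spectrum.
#'
#' @param wavelength_nm Strictly increasing numeric vector of wavelengths
#'   in nanometres.
#' @param signal Numeric vector of the same length as `wavelength_nm`.
#' @param signal_kind One of `"fluorescence"`, `"cd_millideg"`,
#'   `"scattering"`, `"mre_deg_cm2_dmol"`.
#' @param label Optional text label carried through analyses.
#' @return An object of class `"specbind_spectrum"`.
#' @export
#' @examples
#' sp <- new_spectrum(250:300, rnorm(51), "cd_millideg")
new_spectrum <- function(wavelength_nm, signal,
                         signal_kind = c("fluorescence", "cd_millideg",
                                         "scattering", "mre_deg_cm2_dmol"),
                         label = "") {
  signal_kind <- match.arg(signal_kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  signal <- as.numeric(signal)
  if (length(wavelength_nm) != length(signal))
    stop_specbind("wavelength and signal must have the same length",
                  "specbind_validation_error")
  if (length(wavelength_nm) < 1L || any(!is.finite(wavelength_nm)))
    stop_specbind("wavelengths must be finite", "specbind_validation_error")
  if (any(diff(wavelength_nm) <= 0))
    stop_specbind("wavelengths must be strictly increasing",
                  "specbind_validation_error")
  structure(
    list(wavelength_nm = wavelength_nm, signal = signal,
         signal_kind = signal_kind, label = as.character(label)),
    class = "specbind_spectrum"
  )
}

#' @export
print.specbind_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.1f-%.1f nm>%s\n",
              x$signal_kind, length(x$signal),
              min(x$wavelength_nm), max(x$wavelength_nm),
              if (nzchar(x$label)) paste0(" ", x$label) else ""))
  invisible(x)
}

#' Construct a fluorescence quench titration series
#'
#' One titration of protein with increasing ligand: added ligand
#' concentrations (mol/L, first entry 0) paired with fluorescence
#' intensities at a fixed emission wavelength. The first intensity is the
#' ligand-free reference F0.
#'
#' @param ligand_conc_M Strictly increasing numeric vector of total added
#'   ligand concentrations in mol/L; the first entry must be 0.
#' @param intensity Positive fluorescence intensities, same length.
#' @param temperature_K Temperature of the series in kelvin.
#' @param protein_conc_M Protein concentration in mol/L.
#' @param label Optional text label.
#' @return An object of class `"titration_series"`.
#' @export
titration_series <- function(ligand_conc_M, intensity, temperature_K = 298,
                             protein_conc_M = 5e-6, label = "") {
  ligand_conc_M <- as.numeric(ligand_conc_M)
  intensity <- as.numeric(intensity)
  if (length(ligand_conc_M) != length(intensity))
    stop_specbind("concentration and intensity must have the same length",
                  "specbind_validation_error")
  if (length(ligand_conc_M) < 2L)
    stop_specbind("a titration needs at least two points",
                  "specbind_validation_error")
  if (ligand_conc_M[1L] != 0)
    stop_specbind("the first concentration must be 0 (the ligand-free F0 point)",
                  "specbind_validation_error")
  if (any(ligand_conc_M < 0))
    stop_specbind("ligand concentrations must be non-negative",
                  "specbind_validation_error")
  if (any(diff(ligand_conc_M) <= 0)) {
    bad <- which(diff(ligand_conc_M) <= 0)[1L] + 1L
    stop_specbind(sprintf(
      "ligand concentrations must be strictly increasing (row %d repeats or decreases)",
      bad), "specbind_validation_error")
  }
  if (any(intensity <= 0)) {
    bad <- which(intensity <= 0)[1L]
    stop_specbind(sprintf("intensity must be positive (row %d is not)", bad),
                  "specbind_validation_error")
  }
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop_specbind("temperature_K must be positive", "specbind_validation_error")
  if (!is.finite(protein_conc_M) || protein_conc_M <= 0)
    stop_specbind("protein_conc_M must be positive", "specbind_validation_error")
  structure(
    list(ligand_conc_M = ligand_conc_M, intensity = intensity,
         temperature_K = as.numeric(temperature_K),
         protein_conc_M = as.numeric(protein_conc_M),
         label = as.character(label)),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration: %d points, [Q] 0-%.3g M, T = %g K, [P] = %.3g M>%s\n",
    length(x$intensity), max(x$ligand_conc_M), x$temperature_K,
    x$protein_conc_M, if (nzchar(x$label)) paste0(" ", x$label) else ""))
  invisible(x)
}

#' Construct a chemical-denaturation profile
#'
#' Denaturant concentrations (mol/L urea) paired with an optical signal,
#' typically fluorescence intensity at 343 nm.
#'
#' @param denaturant_M Non-decreasing numeric vector of denaturant
#'   concentrations in mol/L.
#' @param signal Numeric signal of the same length.
#' @param temperature_K Temperature in kelvin (default 298).
#' @param label Optional text label.
#' @return An object of class `"unfolding_profile"`.
#' @export
unfolding_profile <- function(denaturant_M, signal, temperature_K = 298,
                              label = "") {
  denaturant_M <- as.numeric(denaturant_M)
  signal <- as.numeric(signal)
  if (length(denaturant_M) != length(signal))
    stop_specbind("denaturant and signal must have the same length",
                  "specbind_validation_error")
  if (any(denaturant_M < 0))
    stop_specbind("denaturant concentrations must be non-negative",
                  "specbind_validation_error")
  if (any(diff(denaturant_M) < 0))
    stop_specbind("denaturant concentrations must be non-decreasing",
                  "specbind_validation_error")
  structure(
    list(denaturant_M = denaturant_M, signal = signal,
         temperature_K = as.numeric(temperature_K),
         label = as.character(label)),
    class = "unfolding_profile"
  )
}

#' @export
print.unfolding_profile <- function(x, ...) {
  cat(sprintf("<unfolding profile: %d points, 0-%.3g M, T = %g K>%s\n",
              length(x$signal), max(x$denaturant_M), x$temperature_K,
              if (nzchar(x$label)) paste0(" ", x$label) else ""))
  invisible(x)
}

#' Subtract a background spectrum from a sample spectrum
#'
#' Pointwise subtraction of a free-ligand (background) spectrum from a
#' sample spectrum on an identical wavelength grid. No interpolation is
#' performed: mismatched grids are an error, because silent resampling
#' corrupts ellipticity ratios.
#'
#' @param sample,background `specbind_spectrum` objects on identical grids
#'   with identical `signal_kind`.
#' @return A `specbind_spectrum` with the difference signal; `signal_kind`
#'   is preserved.
#' @export
subtract_background <- function(sample, background) {
  stopifnot(inherits(sample, "specbind_spectrum"),
            inherits(background, "specbind_spectrum"))
  if (length(sample$wavelength_nm) != length(background$wavelength_nm) ||
      any(sample$wavelength_nm != background$wavelength_nm))
    stop_specbind("wavelength grids differ; no interpolation is performed",
                  "specbind_alignment_error")
  if (sample$signal_kind != background$signal_kind)
    stop_specbind("signal kinds differ between sample and background",
                  "specbind_validation_error")
  new_spectrum(sample$wavelength_nm, sample$signal - background$signal,
               sample$signal_kind, label = sample$label)
}
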
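#' van't Hoff analysis of temperature-dependent association constants
#'
#' Ordinary least squares of \eqn{\ln K_a} on \eqn{1/T}:
#' \eqn{\Delta H = -R \cdot slope} and \eqn{\Delta S = R \cdot intercept}.
#' The free energy at each input temperature is reported from
#' \eqn{\Delta G = \Delta H - T \Delta S} (the conventional route for
#' these tables); \eqn{-RT \ln K_a} is also computed and stored as a
#' diagnostic so the two routes can be compared rather than silently
#' blessing one.
#'
#' @param points A data frame (or matrix) with columns `temperature_K` and
#'   `Ka_assoc_per_M`, at two or more distinct temperatures, all `Ka > 0`.
#' @return An object of class `"thermo_result"` with `dH_J_per_mol`,
#'   `dS_J_per_mol_K`, `stderr_dH`, `stderr_dS` (`NA` for an exact
#'   two-point line), `r_squared`, `dG_J_per_mol_at` (named by
#'   temperature), `dG_minus_RTlnKa_at` (diagnostic) and `R_gas`.
#' @export
#' @examples
#' pts <- data.frame(temperature_K = c(293, 298, 303),
#'                   Ka_assoc_per_M = c(6.85e4, 6.02e4, 5.58e4))
#' fit_vant_hoff(pts)
fit_vant_hoff <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("temperature_K", "Ka_assoc_per_M") %in% names(points)))
    stop_specbind("points needs columns temperature_K and Ka_assoc_per_M",
                  "specbind_format_error")
  tk <- points$temperature_K
  ka <- points$Ka_assoc_per_M
  if (length(tk) < 2L)
    stop_specbind("need Ka at >= 2 temperatures", "specbind_insufficient_data")
  if (anyDuplicated(tk))
    stop_specbind("temperatures must be distinct", "specbind_validation_error")
  if (any(ka <= 0) || any(tk <= 0))
    stop_specbind("temperatures and Ka must be positive",
                  "specbind_validation_error")
  ols <- ols_fit(1 / tk, log(ka))
  dh <- -R_GAS * ols$slope
  ds <- R_GAS * ols$intercept
  exact_two_point <- length(tk) == 2L
  dg <- dh - tk * ds
  structure(
    list(dH_J_per_mol = dh, dS_J_per_mol_K = ds,
         stderr_dH = if (exact_two_point) NA_real_ else R_GAS * ols$slope_se,
         stderr_dS = if (exact_two_point) NA_real_ else R_GAS * ols$intercept_se,
         r_squared = ols$r_squared,
         dG_J_per_mol_at = stats::setNames(dg, as.character(tk)),
         dG_minus_RTlnKa_at = stats::setNames(dg - (-R_GAS * tk * log(ka)),
                                              as.character(tk)),
         R_gas = R_GAS),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<van't Hoff fit: dH = %.2f kJ/mol, dS = %.2f J/mol/K, R^2 = %.5f>\n",
              x$dH_J_per_mol / 1000, x$dS_J_per_mol_K, x$r_squared))
  for (tk in names(x$dG_J_per_mol_at))
    cat(sprintf("  dG(%s K) = %.2f kJ/mol (dH - T dS); differs from -RT lnKa by %.2f kJ/mol\n",
                tk, x$dG_J_per_mol_at[[tk]] / 1000,
                x$dG_minus_RTlnKa_at[[tk]] / 1000))
  invisible(x)
}

#' Diffusion-limited association rate (Smoluchowski)
#'
#' \eqn{k_f = 4 \pi r D N_A \times 1000} in M^-1 s^-1, with the encounter
#' radius `r` in metres, the relative diffusion coefficient `D` in m^2/s
#' and the factor 1000 converting m^3 to litres. Defaults are a typical
#' small-molecule diffusion coefficient (1e-5 cm^2/s = 1e-9 m^2/s) and van
#' der Waals radius (0.4 nm), which give approximately 3.0e9 M^-1 s^-1.
#'
#' @param D_m2_per_s Diffusion coefficient in m^2/s (> 0).
#' @param r_m Encounter radius in metres (>= 0).
#' @return The forward rate constant in M^-1 s^-1.
#' @export
diffusion_limited_kf <- function(D_m2_per_s = 1e-9, r_m = 4e-10) {
  stopifnot(D_m2_per_s > 0, r_m >= 0)
  4 * pi * r_m * D_m2_per_s * N_AVOGADRO * 1000
}

#' Residence time of a complex from Ka and the forward rate
#'
#' Under \eqn{K_a = k_f / k_b}, the dissociation rate is
#' \eqn{k_b = k_f / K_a} and the residence time is its reciprocal,
#' \eqn{\tau = 1/k_b = K_a / k_f}.
#'
#' @param Ka_assoc_per_M Association constant in M^-1 (> 0).
#' @param kf_per_M_per_s Forward (association) rate constant in
#'   M^-1 s^-1; defaults to [diffusion_limited_kf()] with `D_m2_per_s` and
#'   `r_m`.
#' @param D_m2_per_s,r_m Passed to [diffusion_limited_kf()] when
#'   `kf_per_M_per_s` is not supplied.
#' @return An object of class `"kinetic_result"` with `kf_per_M_per_s`,
#'   `kb_per_s`, `residence_time_s`, `Ka_assoc_per_M`, `D_m2_per_s`, `r_m`.
#' @export
#' @examples
#' residence_time(6.02e4)$residence_time_s
residence_time <- function(Ka_assoc_per_M,
                           kf_per_M_per_s = diffusion_limited_kf(D_m2_per_s, r_m),
                           D_m2_per_s = 1e-9, r_m = 4e-10) {
  stopifnot(Ka_assoc_per_M > 0, kf_per_M_per_s > 0)
  kb <- kf_per_M_per_s / Ka_assoc_per_M
  structure(
    list(kf_per_M_per_s = kf_per_M_per_s, kb_per_s = kb,
         residence_time_s = 1 / kb, Ka_assoc_per_M = Ka_assoc_per_M,
         D_m2_per_s = D_m2_per_s, r_m = r_m),
    class = "kinetic_result"
  )
}

#' @export
print.kinetic_result <- function(x, ...) {
  cat(sprintf("<kinetics: kf = %.3g M^-1 s^-1, kb = %.3g s^-1, residence time = %.3g s>\n",
              x$kf_per_M_per_s, x$kb_per_s, x$residence_time_s))
  invisible(x)
}
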
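#' Association constant and site number from the double-logarithmic plot
#'
#' Unweighted ordinary least squares of
#' \eqn{\log_{10}[(F_0 - F)/F]} on \eqn{\log_{10}[Q]}: the slope estimates
#' the number of binding sites \eqn{n} and the intercept
#' \eqn{\log_{10} K_a}. Base-10 logarithms are used because the intercept
#' is read directly as \eqn{\log K_a} on a plot drawn in decades. Only
#' points with positive quench (`F < F0`) at `[Q] > 0` enter the fit;
#' excluded points are counted. The quencher concentration is the total
#' added ligand (no free-ligand iteration), and heteroscedasticity of the
#' log transform is deliberately not reweighted, mirroring standard
#' practice for these plots.
#'
#' @param series A [titration_series()]; `intensity[1]` is F0.
#' @return An object of class `"binding_fit"` with fields
#'   `Ka_assoc_per_M`, `log10Ka`, `n_sites`, `stderr_log10Ka`, `stderr_n`,
#'   `r_squared`, `temperature_K`, `n_points_used`, `n_points_excluded`
#'   and `warnings` (flagged when `n_sites` falls outside the (0, 4)
#'   sanity band).
#' @export
#' @examples
#' tr <- quench_truth(Ka_assoc_per_M = 6.02e4, n_sites = 1.03)
#' fit_double_log(generate_quench(tr))$Ka_assoc_per_M
fit_double_log <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  f0 <- series$intensity[1L]
  q <- series$ligand_conc_M[-1L]
  f <- series$intensity[-1L]
  usable <- q > 0 & f < f0
  n_excl <- sum(!usable)
  if (sum(usable) < 3L)
    stop_specbind(sprintf(
      "need >= 3 points with positive quench; %d of %d excluded",
      n_excl, length(q)), "specbind_insufficient_data")
  x <- log10(q[usable])
  y <- log10((f0 - f[usable]) / f[usable])
  ols <- ols_fit(x, y)
  warnings <- character()
  if (ols$slope <= 0 || ols$slope >= 4)
    warnings <- c(warnings, sprintf(
      "fitted site number %.3g outside the (0, 4) sanity band", ols$slope))
  structure(
    list(Ka_assoc_per_M = 10^ols$intercept, log10Ka = ols$intercept,
         n_sites = ols$slope, stderr_log10Ka = ols$intercept_se,
         stderr_n = ols$slope_se, r_squared = ols$r_squared,
         temperature_K = series$temperature_K,
         n_points_used = sum(usable), n_points_excluded = n_excl,
         label = series$label, warnings = warnings),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<double-log binding fit: Ka = %.4g M^-1, n = %.3f +/- %.3f, R^2 = %.5f, T = %g K>\n",
              x$Ka_assoc_per_M, x$n_sites, x$stderr_n, x$r_squared,
              x$temperature_K))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
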
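#' Stern-Volmer analysis of a quench titration
#'
#' Ordinary least squares of \eqn{F_0/F} on the quencher concentration
#' \eqn{[Q]}. The intercept is fitted freely (not pinned at 1) so that
#' baseline errors are exposed rather than hidden; a warning flag is set
#' when the fitted intercept deviates from 1 by more than 0.05. The slope
#' is the Stern-Volmer constant \eqn{K_{sv}} and the bimolecular quenching
#' rate is \eqn{k_q = K_{sv}/\tau_0}.
#'
#' @param series A [titration_series()]; `intensity[1]` is taken as F0.
#' @param tau0_s Unquenched fluorophore lifetime in seconds; the default
#'   5e-9 s is the accepted lifetime of serum albumin.
#' @return An object of class `"quench_fit"` with fields `Ksv_per_M`,
#'   `Ksv_stderr`, `intercept`, `intercept_stderr`, `kq_per_M_per_s`,
#'   `tau0_s`, `r_squared`, `mechanism` (always `"indeterminate"` for a
#'   single series; see [classify_mechanism()]), `temperature_K`,
#'   `protein_conc_M` and a character vector `warnings`.
#' @export
#' @examples
#' tr <- quench_truth(Ka_assoc_per_M = 4.59e4)
#' fit_stern_volmer(generate_quench(tr))$Ksv_per_M
fit_stern_volmer <- function(series, tau0_s = 5e-9) {
  stopifnot(inherits(series, "titration_series"), tau0_s > 0)
  q <- series$ligand_conc_M
  f <- series$intensity
  if (sum(q > 0) < 3L)
    stop_specbind("need at least 3 nonzero-concentration points",
                  "specbind_insufficient_data")
  f0 <- f[1L]
  warnings <- character()
  if (any(f >= f0 * 1.05))
    warnings <- c(warnings,
                  "anti-quench: some intensities exceed F0 by more than 5%")
  ols <- ols_fit(q, f0 / f)
  if (abs(ols$intercept - 1) > 0.05)
    warnings <- c(warnings, sprintf(
      "fitted intercept %.4g deviates from 1 by more than 0.05", ols$intercept))
  if (ols$slope <= 0 || ols$slope < 2 * ols$slope_se)
    warnings <- c(warnings,
                  "no significant quenching: slope not distinguishable from 0")
  structure(
    list(Ksv_per_M = ols$slope, Ksv_stderr = ols$slope_se,
         intercept = ols$intercept, intercept_stderr = ols$intercept_se,
         kq_per_M_per_s = ols$slope / tau0_s, tau0_s = tau0_s,
         r_squared = ols$r_squared, mechanism = "indeterminate",
         temperature_K = series$temperature_K,
         protein_conc_M = series$protein_conc_M,
         label = series$label, warnings = warnings),
    class = "quench_fit"
  )
}

#' @export
print.quench_fit <- function(x, ...) {
  cat(sprintf("<Stern-Volmer fit: Ksv = %.4g +/- %.2g M^-1, kq = %.4g M^-1 s^-1, R^2 = %.5f, T = %g K>\n",
              x$Ksv_per_M, x$Ksv_stderr, x$kq_per_M_per_s, x$r_squared,
              x$temperature_K))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Classify the quenching mechanism from temperature-ordered fits
#'
#' Static quenching (ground-state complex formation) is indicated when
#' every apparent bimolecular quenching rate exceeds the maximum
#' diffusion-collision limit (~1e10 M^-1 s^-1) and the Stern-Volmer
#' constant does not increase with temperature; dynamic (collisional)
#' quenching when every rate is at or below the limit and Ksv does not
#' decrease with temperature. Conflicting evidence yields
#' `"indeterminate"`. Temperature trends are judged on strict ordering of
#' the point estimates: three temperatures cannot power a formal
#' regression-slope test.
#'
#' @param fits A list of [fit_stern_volmer()] results ordered by
#'   temperature (one is enough; more must have distinct temperatures).
#' @param collisional_limit_per_M_per_s Diffusion-collision ceiling for
#'   `kq`, default 1e10 M^-1 s^-1.
#' @return An object of class `"mechanism_call"`: the mechanism
#'   (`"static"`, `"dynamic"` or `"indeterminate"`) plus the decision rule,
#'   the threshold used and the evidence (kq and Ksv by temperature).
#' @export
classify_mechanism <- function(fits, collisional_limit_per_M_per_s = 1e10) {
  if (inherits(fits, "quench_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1L), "quench_fit")))
  temps <- vapply(fits, `[[`, numeric(1L), "temperature_K")
  if (anyDuplicated(temps))
    stop_specbind("fits must be at distinct temperatures",
                  "specbind_validation_error")
  ord <- order(temps)
  temps <- temps[ord]
  ksv <- vapply(fits, `[[`, numeric(1L), "Ksv_per_M")[ord]
  kq <- vapply(fits, `[[`, numeric(1L), "kq_per_M_per_s")[ord]
  non_increasing <- length(ksv) == 1L || all(diff(ksv) <= 0)
  non_decreasing <- length(ksv) == 1L || all(diff(ksv) >= 0)
  mech <- if (all(kq > collisional_limit_per_M_per_s) && non_increasing) {
    "static"
  } else if (all(kq <= collisional_limit_per_M_per_s) && non_decreasing) {
    "dynamic"
  } else {
    "indeterminate"
  }
  structure(
    list(mechanism = mech,
         rule = paste("static: all kq above the collisional limit and Ksv",
                      "non-increasing with T; dynamic: all kq at or below the",
                      "limit and Ksv non-decreasing; otherwise indeterminate"),
         collisional_limit_per_M_per_s = collisional_limit_per_M_per_s,
         temperature_K = temps, Ksv_per_M = ksv, kq_per_M_per_s = kq),
    class = "mechanism_call"
  )
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<quenching mechanism: %s (limit %.3g M^-1 s^-1)>\n",
              x$mechanism, x$collisional_limit_per_M_per_s))
  invisible(x)
}

#' Binding-specificity check across protein concentrations
#'
#' Colloidal aggregates of a small molecule sequester protein, so their
#' apparent affinity drops sharply as protein concentration rises. A
#' specific binder shows nearly constant Ksv across protein
#' concentrations. The check passes when the maximum pairwise relative
#' spread of the Ksv values, `|Ksv_i - Ksv_j| / max(Ksv)`, stays below
#' `max_rel_drop`.
#'
#' @param fits A list of at least two [fit_stern_volmer()] results at
#'   distinct protein concentrations.
#' @param max_rel_drop Tolerated relative spread (default 0.5).
#' @return An object of class `"specificity_report"` with the Ksv
#'   sequence, protein concentrations, the observed maximum relative
#'   spread, and a logical `pass`.
#' @export
specificity_check <- function(fits, max_rel_drop = 0.5) {
  stopifnot(all(vapply(fits, inherits, logical(1L), "quench_fit")))
  if (length(fits) < 2L)
    stop_specbind("need Stern-Volmer fits at >= 2 protein concentrations",
                  "specbind_insufficient_data")
  pc <- vapply(fits, `[[`, numeric(1L), "protein_conc_M")
  if (anyDuplicated(pc))
    stop_specbind("fits must be at distinct protein concentrations",
                  "specbind_validation_error")
  ord <- order(pc)
  pc <- pc[ord]
  ksv <- vapply(fits, `[[`, numeric(1L), "Ksv_per_M")[ord]
  spread <- max(abs(outer(ksv, ksv, "-"))) / max(ksv)
  structure(
    list(pass = spread < max_rel_drop,
         max_rel_spread = spread, max_rel_drop = max_rel_drop,
         protein_conc_M = pc, Ksv_per_M = ksv),
    class = "specificity_report"
  )
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("<specificity: %s (max relative Ksv spread %.3f, limit %.2f)>\n",
              if (x$pass) "PASS" else "FAIL", x$max_rel_spread,
              x$max_rel_drop))
  invisible(x)
}
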
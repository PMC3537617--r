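#' Fit linear state baselines to a denaturation profile
#'
#' Independent ordinary-least-squares lines of signal vs denaturant over
#' the pre-transition (N), intermediate (I) and post-transition (U)
#' regions. Baselines are extrapolated as fitted lines (not plateau
#' constants) into the transition zones, since sloped native baselines are
#' the norm for albumin fluorescence.
#'
#' @param profile An [unfolding_profile()].
#' @param regions Named list of `(min_M, max_M)` denaturant windows `N`,
#'   `I`, `U`; windows must be ordered, non-overlapping, and each contain
#'   at least two data points. The defaults (N: 0-2.25 M, I: 4.75-5.25 M,
#'   U: 8 M and above) encode the landmarks of serum-albumin urea
#'   unfolding — onset near 2.4 M, intermediate plateau near 5 M — on a
#'   0.25 M grid.
#' @return An object of class `"baseline_set"`: the regions plus
#'   `(intercept, slope)` lines `line_N`, `line_I`, `line_U`.
#' @export
fit_baselines <- function(profile,
                          regions = list(N = c(0, 2.25), I = c(4.75, 5.25),
                                         U = c(8, Inf))) {
  stopifnot(inherits(profile, "unfolding_profile"),
            all(c("N", "I", "U") %in% names(regions)))
  rn <- regions$N; ri <- regions$I; ru <- regions$U
  if (!(rn[1L] < rn[2L] && ri[1L] < ri[2L] && ru[1L] < ru[2L]))
    stop_specbind("each region window must have min < max",
                  "specbind_validation_error")
  if (!(rn[2L] < ri[1L] && ri[2L] < ru[1L]))
    stop_specbind("regions must be ordered N < I < U and non-overlapping",
                  "specbind_validation_error")
  u <- profile$denaturant_M
  y <- profile$signal
  lines <- lapply(c(N = "N", I = "I", U = "U"), function(nm) {
    w <- regions[[nm]]
    sel <- u >= w[1L] & u <= w[2L]
    if (sum(sel) < 2L)
      stop_specbind(sprintf(
        "region %s [%g, %g] contains %d point(s); need at least 2",
        nm, w[1L], w[2L], sum(sel)), "specbind_insufficient_data")
    if (stats::var(u[sel]) == 0) c(mean(y[sel]), 0)
    else {
      cf <- stats::coef(stats::lm(y[sel] ~ u[sel]))
      c(unname(cf[1L]), unname(cf[2L]))
    }
  })
  structure(
    list(region_N = rn, region_I = ri, region_U = ru,
         line_N = lines$N, line_I = lines$I, line_U = lines$U),
    class = "baseline_set"
  )
}

#' @export
print.baseline_set <- function(x, ...) {
  cat(sprintf("<baselines: N %.4g + %.4g u | I %.4g + %.4g u | U %.4g + %.4g u>\n",
              x$line_N[1L], x$line_N[2L], x$line_I[1L], x$line_I[2L],
              x$line_U[1L], x$line_U[2L]))
  invisible(x)
}

baseline_at <- function(line, u) line[1L] + line[2L] * u

#' Baseline-normalized state fractions of a two-step unfolding profile
#'
#' Within the first transition range (from the end of the N region to the
#' start of the I region) the intermediate fraction is
#' \eqn{f_I = (y - y_N)/(y_I - y_N)}; within the second transition range
#' (end of I region to start of U region) the unfolded fraction is
#' \eqn{f_U = (y - y_I)/(y_U - y_I)}. The ranges are open intervals:
#' points sitting exactly on a region boundary belong to the baseline
#' regions, not to the transition data. Baseline values are the fitted
#' lines evaluated at each point's denaturant concentration. Fractions
#' outside the plausible reporting band \[-0.05, 1.05\] are flagged (not
#' altered).
#'
#' @param profile An [unfolding_profile()].
#' @param baselines A [fit_baselines()] result.
#' @return An object of class `"state_fractions"`: data frames
#'   `transition1` and `transition2` with columns `denaturant_M`, `f`,
#'   `flagged`, plus the profile temperature.
#' @export
state_fractions <- function(profile, baselines) {
  stopifnot(inherits(profile, "unfolding_profile"),
            inherits(baselines, "baseline_set"))
  u <- profile$denaturant_M
  y <- profile$signal
  one <- function(range_lo, range_hi, line_lo, line_hi) {
    sel <- u > range_lo & u < range_hi
    uu <- u[sel]
    y_lo <- baseline_at(line_lo, uu)
    y_hi <- baseline_at(line_hi, uu)
    denom <- y_hi - y_lo
    if (any(abs(denom) < 1e-12 * pmax(abs(y_lo), 1)))
      stop_specbind("degenerate baselines: state signals coincide in a transition range",
                    "specbind_degenerate_baseline")
    f <- (y[sel] - y_lo) / denom
    data.frame(denaturant_M = uu, f = f, flagged = f < -0.05 | f > 1.05)
  }
  structure(
    list(
      transition1 = one(baselines$region_N[2L], baselines$region_I[1L],
                        baselines$line_N, baselines$line_I),
      transition2 = one(baselines$region_I[2L], baselines$region_U[1L],
                        baselines$line_I, baselines$line_U),
      temperature_K = profile$temperature_K
    ),
    class = "state_fractions"
  )
}

#' Per-point unfolding free energies from state fractions
#'
#' For each usable point, \eqn{\Delta G = -RT \ln(f / (1 - f))}. Only
#' points with `f` inside the band (default \[0.05, 0.95\]) are
#' transformed: the log-ratio diverges at the bounds, and restricting to
#' the transition zone is standard linear-extrapolation practice. The
#' number of excluded points is reported per transition.
#'
#' @param fractions A [state_fractions()] result.
#' @param temperature_K Temperature in kelvin; defaults to the
#'   temperature carried by `fractions`.
#' @param band Inclusive fraction band for the transform.
#' @return An object of class `"per_point_dG"`: data frames `transition1`
#'   and `transition2` with columns `denaturant_M`, `f`, `dG_J_per_mol`,
#'   plus `n_excluded` counts and the temperature.
#' @export
per_point_dG <- function(fractions, temperature_K = NULL,
                         band = c(0.05, 0.95)) {
  stopifnot(inherits(fractions, "state_fractions"))
  tk <- temperature_K %||% fractions$temperature_K
  rt <- R_GAS * tk
  one <- function(df) {
    keep <- df$f >= band[1L] & df$f <= band[2L]
    out <- df[keep, c("denaturant_M", "f")]
    out$dG_J_per_mol <- -rt * log(out$f / (1 - out$f))
    list(points = out, n_excluded = sum(!keep))
  }
  t1 <- one(fractions$transition1)
  t2 <- one(fractions$transition2)
  if (nrow(t1$points) == 0L && nrow(t2$points) == 0L)
    stop_specbind("no fractions inside the transform band",
                  "specbind_insufficient_data")
  structure(
    list(transition1 = t1$points, transition2 = t2$points,
         n_excluded = c(transition1 = t1$n_excluded,
                        transition2 = t2$n_excluded),
         temperature_K = tk, band = band),
    class = "per_point_dG"
  )
}

new_transition_fit <- function(dG, m, stderr_dG, stderr_m, method,
                               transition, r_squared = NA_real_,
                               convergence = NA_character_) {
  structure(
    list(dG_H2O_J_per_mol = dG, m_J_per_mol_per_M = m,
         midpoint_M = dG / m, stderr_dG = stderr_dG, stderr_m = stderr_m,
         r_squared = r_squared, method = method, transition = transition,
         convergence = convergence),
    class = "transition_fit"
  )
}

#' Construct a transition fit from known parameter values
#'
#' Builds a `"transition_fit"` record directly from reported numbers
#' (e.g. a published table) so that stability arithmetic such as
#' [compare_stability()] can be applied to literature values. The
#' denaturant sensitivity `m` may be `NA` when unreported; the midpoint is
#' then `NA` as well.
#'
#' @param dG_H2O_J_per_mol Water-extrapolated free energy in J/mol.
#' @param m_J_per_mol_per_M Denaturant sensitivity in J/mol/M, or `NA`.
#' @param method `"linear_LEM"` or `"nonlinear"`.
#' @param transition `"N_to_I"` or `"I_to_U"`.
#' @param stderr_dG,stderr_m Optional standard errors in the same units.
#' @return An object of class `"transition_fit"`.
#' @export
transition_fit <- function(dG_H2O_J_per_mol, m_J_per_mol_per_M = NA_real_,
                           method = c("linear_LEM", "nonlinear"),
                           transition = c("N_to_I", "I_to_U"),
                           stderr_dG = NA_real_, stderr_m = NA_real_) {
  new_transition_fit(dG_H2O_J_per_mol, m_J_per_mol_per_M, stderr_dG,
                     stderr_m, match.arg(method), match.arg(transition))
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf("<%s %s fit: dG_H2O = %.2f kJ/mol, m = %.2f kJ/mol/M, midpoint = %.2f M>\n",
              x$transition, x$method, x$dG_H2O_J_per_mol / 1000,
              x$m_J_per_mol_per_M / 1000, x$midpoint_M))
  invisible(x)
}

#' Linear extrapolation (LEM) fit of per-point free energies
#'
#' Ordinary least squares of \eqn{\Delta G} on `[urea]`:
#' \eqn{\Delta G^{H_2O}} is the intercept and the denaturant sensitivity
#' `m` is minus the slope (so `m > 0` for a destabilizing denaturant); the
#' transition midpoint is their ratio.
#'
#' @param dG_points A data frame with columns `denaturant_M` and
#'   `dG_J_per_mol` (>= 3 rows), e.g. one transition of a
#'   [per_point_dG()] result.
#' @param transition `"N_to_I"` or `"I_to_U"`, recorded on the fit.
#' @return A `"transition_fit"` with `method = "linear_LEM"`.
#' @export
fit_lem <- function(dG_points, transition = c("N_to_I", "I_to_U")) {
  transition <- match.arg(transition)
  dG_points <- as.data.frame(dG_points)
  if (nrow(dG_points) < 3L)
    stop_specbind(sprintf("need >= 3 free-energy points, have %d",
                          nrow(dG_points)), "specbind_insufficient_data")
  ols <- ols_fit(dG_points$denaturant_M, dG_points$dG_J_per_mol)
  new_transition_fit(ols$intercept, -ols$slope, ols$intercept_se,
                     ols$slope_se, "linear_LEM", transition,
                     r_squared = ols$r_squared, convergence = "OLS")
}

#' Nonlinear two-state fit of fraction-unfolded data
#'
#' Least-squares fit, in fraction space, of the two-state logistic
#' \deqn{f_d([urea]) = \frac{\exp(-( \Delta G^{H_2O} - m [urea])/RT)}
#'   {1 + \exp(-(\Delta G^{H_2O} - m [urea])/RT)}}
#' to baseline-normalized fractions. Fitting fraction space (rather than
#' raw signal) avoids jointly refitting the baselines. Initial values come
#' from a linear-extrapolation fit of the band-transformed points; on
#' non-convergence a small restart grid around that start is tried before
#' failing.
#'
#' @param fraction_points A data frame with columns `denaturant_M` and
#'   `f` (>= 4 rows whose fractions at least partially span (0.1, 0.9)),
#'   e.g. one transition of a [state_fractions()] result.
#' @param temperature_K Temperature in kelvin (default 298).
#' @param transition `"N_to_I"` or `"I_to_U"`.
#' @param start Optional named list `list(dG, m)` (J/mol, J/mol/M)
#'   overriding the LEM-derived start.
#' @return A `"transition_fit"` with `method = "nonlinear"` and a
#'   convergence report.
#' @export
fit_nonlinear <- function(fraction_points, temperature_K = 298,
                          transition = c("N_to_I", "I_to_U"), start = NULL) {
  transition <- match.arg(transition)
  df <- as.data.frame(fraction_points)
  df <- df[is.finite(df$f) & is.finite(df$denaturant_M), , drop = FALSE]
  if (nrow(df) < 4L)
    stop_specbind(sprintf("need >= 4 fraction points, have %d", nrow(df)),
                  "specbind_insufficient_data")
  if (max(df$f) <= 0.1 || min(df$f) >= 0.9)
    stop_specbind("fractions never enter (0.1, 0.9); transition not sampled",
                  "specbind_fit_failure")
  if (diff(range(df$f)) < 1e-6 || diff(range(df$denaturant_M)) == 0)
    stop_specbind("fractions carry no information on the transition slope (non-identifiable)",
                  "specbind_fit_failure")
  rt <- R_GAS * temperature_K
  if (is.null(start)) {
    inb <- df$f >= 0.05 & df$f <= 0.95
    start <- if (sum(inb) >= 3L) {
      dg_pts <- -rt * log(df$f[inb] / (1 - df$f[inb]))
      cf <- stats::coef(stats::lm(dg_pts ~ df$denaturant_M[inb]))
      list(dG = unname(cf[1L]), m = -unname(cf[2L]))
    } else {
      mid <- stats::median(df$denaturant_M)
      list(dG = 4 * rt, m = 4 * rt / mid)
    }
  }
  model <- function(dG, m, u) {
    e <- exp(-(dG - m * u) / rt)
    e / (1 + e)
  }
  try_one <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        f ~ model(dG, m, denaturant_M), data = df,
        start = st,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
  }
  fit <- try_one(start)
  if (is.null(fit)) {
    for (sc_dg in c(0.5, 2, 4)) {
      for (sc_m in c(0.5, 2)) {
        fit <- try_one(list(dG = start$dG * sc_dg, m = start$m * sc_m))
        if (!is.null(fit)) break
      }
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit))
    stop_specbind("nonlinear fraction fit failed to converge after restart grid",
                  "specbind_fit_failure")
  cf <- summary(fit)$coefficients
  if (cf["m", 1L] <= 0)
    stop_specbind("nonlinear fit converged to a non-positive m (non-identifiable data)",
                  "specbind_fit_failure")
  resid <- stats::residuals(fit)
  ss_tot <- sum((df$f - mean(df$f))^2)
  new_transition_fit(unname(cf["dG", 1L]), unname(cf["m", 1L]),
                     unname(cf["dG", 2L]), unname(cf["m", 2L]),
                     "nonlinear", transition,
                     r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot
                                 else NA_real_,
                     convergence = fit$convInfo$stopMessage %||% "converged")
}

#' Ligand-induced stabilization from paired transition fits
#'
#' Sums the water-extrapolated free energies of the two transitions for
#' the apo protein and the ligand complex (obtained with the same
#' regression method) and reports the total stabilization
#' \eqn{\Delta\Delta G^{H_2O} = \Delta G^{H_2O}_{complex} -
#' \Delta G^{H_2O}_{apo}}, together with a per-transition breakdown.
#'
#' @param apo,complex Each a list of two `"transition_fit"` objects (in
#'   order N->I then I->U) sharing one method.
#' @return An object of class `"stability_comparison"` with
#'   `total_dG_H2O_apo`, `total_dG_H2O_complex`, `ddG_H2O_J_per_mol`,
#'   `per_transition_ddG` and the method.
#' @export
compare_stability <- function(apo, complex) {
  check_side <- function(side, nm) {
    if (!(is.list(side) && length(side) == 2L &&
          all(vapply(side, inherits, logical(1L), "transition_fit"))))
      stop_specbind(sprintf("%s must be a list of two transition fits", nm),
                    "specbind_validation_error")
  }
  check_side(apo, "apo"); check_side(complex, "complex")
  methods <- vapply(c(apo, complex), `[[`, character(1L), "method")
  if (length(unique(methods)) != 1L)
    stop_specbind("apo and complex fits must share one regression method",
                  "specbind_validation_error")
  dg_apo <- vapply(apo, `[[`, numeric(1L), "dG_H2O_J_per_mol")
  dg_cpx <- vapply(complex, `[[`, numeric(1L), "dG_H2O_J_per_mol")
  total_apo <- sum(dg_apo)
  total_cpx <- sum(dg_cpx)
  structure(
    list(total_dG_H2O_apo = total_apo, total_dG_H2O_complex = total_cpx,
         ddG_H2O_J_per_mol = total_cpx - total_apo,
         per_transition_ddG = stats::setNames(dg_cpx - dg_apo,
                                              c("N_to_I", "I_to_U")),
         method = methods[1L]),
    class = "stability_comparison"
  )
}

#' @export
print.stability_comparison <- function(x, ...) {
  cat(sprintf("<stability (%s): total apo %.2f, complex %.2f, ddG_H2O = %.2f kJ/mol>\n",
              x$method, x$total_dG_H2O_apo / 1000,
              x$total_dG_H2O_complex / 1000, x$ddG_H2O_J_per_mol / 1000))
  cat(sprintf("  per transition: N->I %+.2f, I->U %+.2f kJ/mol\n",
              x$per_transition_ddG[1L] / 1000, x$per_transition_ddG[2L] / 1000))
  invisible(x)
}

#' Full three-state denaturation analysis of a profile
#'
#' Convenience pipeline: baseline fitting, fraction transforms, per-point
#' free energies, and linear-extrapolation and/or nonlinear transition
#' fits for both steps.
#'
#' @param profile An [unfolding_profile()].
#' @param regions Baseline windows passed to [fit_baselines()].
#' @param temperature_K Temperature for the free-energy transforms;
#'   defaults to the profile's.
#' @param method `"both"` (default), `"linear"` or `"nonlinear"`.
#' @return An object of class `"unfolding_analysis"`: the baselines,
#'   fractions, per-point free energies, and a `fits` list with elements
#'   `linear` and/or `nonlinear`, each holding transition fits `N_to_I`
#'   and `I_to_U`.
#' @export
fit_unfolding <- function(profile,
                          regions = list(N = c(0, 2.25), I = c(4.75, 5.25),
                                         U = c(8, Inf)),
                          temperature_K = NULL,
                          method = c("both", "linear", "nonlinear")) {
  method <- match.arg(method)
  tk <- temperature_K %||% profile$temperature_K
  baselines <- fit_baselines(profile, regions)
  fractions <- state_fractions(profile, baselines)
  dg <- per_point_dG(fractions, temperature_K = tk)
  fits <- list()
  if (method %in% c("both", "linear")) {
    fits$linear <- list(
      N_to_I = fit_lem(dg$transition1, "N_to_I"),
      I_to_U = fit_lem(dg$transition2, "I_to_U")
    )
  }
  if (method %in% c("both", "nonlinear")) {
    fits$nonlinear <- list(
      N_to_I = fit_nonlinear(fractions$transition1, tk, "N_to_I"),
      I_to_U = fit_nonlinear(fractions$transition2, tk, "I_to_U")
    )
  }
  structure(
    list(baselines = baselines, fractions = fractions, per_point_dG = dg,
         fits = fits, temperature_K = tk),
    class = "unfolding_analysis"
  )
}

#' @export
print.unfolding_analysis <- function(x, ...) {
  cat("<three-state unfolding analysis>\n")
  for (m in names(x$fits)) {
    for (tr in names(x$fits[[m]])) {
      ft <- x$fits[[m]][[tr]]
      cat(sprintf("  %s %s: dG_H2O = %.2f kJ/mol, m = %.2f kJ/mol/M, midpoint = %.2f M\n",
                  m, tr, ft$dG_H2O_J_per_mol / 1000,
                  ft$m_J_per_mol_per_M / 1000, ft$midpoint_M))
    }
  }
  invisible(x)
}
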
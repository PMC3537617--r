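#' Ground truth for a synthetic quench titration
#'
#' Parameters of the empirical saturable quench model
#' \eqn{(F_0 - F)/F = K_a [Q]^n}, i.e. \eqn{F = F_0 / (1 + K_a [Q]^n)}.
#' With `n_sites = 1` this reduces exactly to the Stern-Volmer relation
#' \eqn{F_0/F = 1 + K_{sv}[Q]} with \eqn{K_{sv} = K_a}, and for any `n`
#' the double-logarithmic plot \eqn{\log[(F_0-F)/F]} vs \eqn{\log[Q]} is an
#' exact straight line. The generator therefore produces data for which the
#' analysis equations are the true model, isolating estimator correctness
#' from model misfit.
#'
#' @param Ka_assoc_per_M Association constant in M^-1 (> 0).
#' @param n_sites Binding-site number / cooperativity exponent (> 0).
#' @param F0 Ligand-free fluorescence intensity (> 0, arbitrary units).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   intensity noise; must be < 0.2 (larger values are implausible for a
#'   bench fluorimeter and the generator refuses them).
#' @param seed Integer seed making noisy output reproducible.
#' @return An object of class `"quench_truth"`.
#' @export
quench_truth <- function(Ka_assoc_per_M, n_sites = 1, F0 = 1000,
                         noise_cv = 0, seed = 1L) {
  stopifnot(Ka_assoc_per_M > 0, n_sites > 0, F0 > 0, noise_cv >= 0)
  if (noise_cv >= 0.2)
    stop_specbind("noise_cv must be < 0.2", "specbind_validation_error")
  structure(
    list(Ka_assoc_per_M = Ka_assoc_per_M, n_sites = n_sites, F0 = F0,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "quench_truth"
  )
}

#' Generate a synthetic quench titration series
#'
#' Produces intensities \eqn{F = F_0/(1 + K_a [Q]^n)} on the given
#' concentration grid; the first (ligand-free) point is exactly `F0`.
#' Points at `[Q] > 0` are multiplied by unit-mean lognormal noise with the
#' truth's coefficient of variation, under the truth's seed, so output is
#' deterministic given the seed.
#'
#' @param truth A [quench_truth()].
#' @param conc_grid Ligand concentrations in mol/L, starting at 0 and
#'   strictly increasing. Default 0-20 µM in 1 µM steps, the dynamic range
#'   of a 0-20 µL titration of 2.7 mM stock into 3 mL.
#' @param temperature_K,protein_conc_M Metadata stored on the series.
#' @param label Optional label.
#' @return A [titration_series()].
#' @export
generate_quench <- function(truth, conc_grid = seq(0, 20e-6, by = 1e-6),
                            temperature_K = 298, protein_conc_M = 5e-6,
                            label = "") {
  stopifnot(inherits(truth, "quench_truth"))
  if (any(conc_grid < 0))
    stop_specbind("concentrations must be non-negative",
                  "specbind_validation_error")
  if (conc_grid[1L] != 0 || any(diff(conc_grid) <= 0))
    stop_specbind("conc_grid must start at 0 and be strictly increasing",
                  "specbind_validation_error")
  q <- conc_grid[-1L]
  f <- truth$F0 / (1 + truth$Ka_assoc_per_M * q^truth$n_sites)
  f <- f * with_seed(truth$seed, lognormal_factors(length(f), truth$noise_cv))
  titration_series(
    ligand_conc_M = conc_grid,
    intensity = c(truth$F0, f),
    temperature_K = temperature_K, protein_conc_M = protein_conc_M,
    label = label
  )
}

#' Generate titrations across temperatures obeying the van't Hoff relation
#'
#' The association constant at each temperature is
#' \eqn{K_a(T) = \exp(-\Delta H / (R T) + \Delta S / R)}, exact before
#' noise. Each series reuses the base truth's `n_sites`, `F0` and
#' `noise_cv`; per-temperature seeds are derived as `seed + index` so the
#' whole family is reproducible from one seed.
#'
#' @param dH_J_per_mol Binding enthalpy in J/mol.
#' @param dS_J_per_mol_K Binding entropy in J/mol/K.
#' @param temps_K Temperatures in kelvin (all > 0).
#' @param base A [quench_truth()] supplying everything except `Ka`.
#' @param conc_grid Passed to [generate_quench()].
#' @param protein_conc_M Protein concentration stored on each series.
#' @return A list of [titration_series()], one per temperature.
#' @export
generate_temperature_series <- function(dH_J_per_mol, dS_J_per_mol_K, temps_K,
                                        base,
                                        conc_grid = seq(0, 20e-6, by = 1e-6),
                                        protein_conc_M = 5e-6) {
  stopifnot(inherits(base, "quench_truth"), all(temps_K > 0))
  lapply(seq_along(temps_K), function(i) {
    tk <- temps_K[i]
    ka <- exp(-dH_J_per_mol / (R_GAS * tk) + dS_J_per_mol_K / R_GAS)
    tr <- quench_truth(ka, base$n_sites, base$F0, base$noise_cv,
                       base$seed + i)
    generate_quench(tr, conc_grid, temperature_K = tk,
                    protein_conc_M = protein_conc_M,
                    label = sprintf("T=%gK", tk))
  })
}

#' Ground truth for a synthetic three-state denaturation profile
#'
#' Parameters of a two-step unfolding scheme N <-> I <-> U with linear free
#' energy dependence on denaturant for each step
#' (\eqn{\Delta G_i([urea]) = \Delta G_i^{H_2O} - m_i [urea]}) and linear
#' signal baselines for the three states. The midpoint of the first
#' transition (`dG1/m1`) must precede that of the second (`dG2/m2`).
#'
#' @param dG1_J_per_mol,dG2_J_per_mol Water-extrapolated free energies of
#'   the N->I and I->U steps, in J/mol (> 0). Defaults are the apo-protein
#'   nonlinear estimates for serum albumin (17.19 and 15.23 kJ/mol).
#' @param m1_J_per_mol_per_M,m2_J_per_mol_per_M Denaturant sensitivities
#'   in J/mol/M (> 0).
#' @param baselines Named list with elements `N`, `I`, `U`, each a numeric
#'   `(intercept, slope)` pair of signal vs denaturant.
#' @param zone1_M,zone2_M Denaturant windows (min, max) within which the
#'   first and second transitions are rendered by the stepwise signal model
#'   (see [generate_unfolding()]); must be disjoint and ordered.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   signal noise (< 0.2).
#' @param seed Integer seed.
#' @return An object of class `"unfold_truth"`.
#' @export
unfold_truth <- function(dG1_J_per_mol = 17190, m1_J_per_mol_per_M = 3500,
                         dG2_J_per_mol = 15230, m2_J_per_mol_per_M = 2500,
                         baselines = list(N = c(1.0, 0), I = c(0.5, 0),
                                          U = c(0.0, 0)),
                         zone1_M = c(2.25, 4.75), zone2_M = c(5.25, 8.0),
                         noise_cv = 0, seed = 1L) {
  stopifnot(dG1_J_per_mol > 0, dG2_J_per_mol > 0,
            m1_J_per_mol_per_M > 0, m2_J_per_mol_per_M > 0,
            noise_cv >= 0, noise_cv < 0.2,
            all(c("N", "I", "U") %in% names(baselines)),
            length(zone1_M) == 2L, length(zone2_M) == 2L)
  mid1 <- dG1_J_per_mol / m1_J_per_mol_per_M
  mid2 <- dG2_J_per_mol / m2_J_per_mol_per_M
  if (mid1 >= mid2)
    stop_specbind(
      "transition-1 midpoint (dG1/m1) must precede transition-2 midpoint (dG2/m2)",
      "specbind_validation_error")
  if (!(zone1_M[1L] < zone1_M[2L] && zone1_M[2L] <= zone2_M[1L] &&
        zone2_M[1L] < zone2_M[2L]))
    stop_specbind("transition zones must be ordered and non-overlapping",
                  "specbind_validation_error")
  structure(
    list(dG1_J_per_mol = dG1_J_per_mol,
         m1_J_per_mol_per_M = m1_J_per_mol_per_M,
         dG2_J_per_mol = dG2_J_per_mol,
         m2_J_per_mol_per_M = m2_J_per_mol_per_M,
         baselines = baselines, zone1_M = zone1_M, zone2_M = zone2_M,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "unfold_truth"
  )
}

#' Equilibrium state populations of the sequential three-state scheme
#'
#' For N <-> I <-> U with step constants
#' \eqn{K_1 = \exp(-\Delta G_1/RT)}, \eqn{K_2 = \exp(-\Delta G_2/RT)} and
#' \eqn{\Delta G_i = \Delta G_i^{H_2O} - m_i [urea]}, the populations are
#' \eqn{p_N = 1/(1 + K_1 + K_1 K_2)}, \eqn{p_I = K_1 p_N},
#' \eqn{p_U = K_1 K_2 p_N}; they sum to one at every point.
#'
#' @param truth An [unfold_truth()].
#' @param denat_M Denaturant concentrations in mol/L.
#' @param temperature_K Temperature in kelvin.
#' @return A data frame with columns `denaturant_M`, `pN`, `pI`, `pU`.
#' @export
three_state_populations <- function(truth, denat_M, temperature_K = 298) {
  stopifnot(inherits(truth, "unfold_truth"))
  rt <- R_GAS * temperature_K
  k1 <- exp(-(truth$dG1_J_per_mol - truth$m1_J_per_mol_per_M * denat_M) / rt)
  k2 <- exp(-(truth$dG2_J_per_mol - truth$m2_J_per_mol_per_M * denat_M) / rt)
  pn <- 1 / (1 + k1 + k1 * k2)
  data.frame(denaturant_M = denat_M, pN = pn, pI = k1 * pn, pU = k1 * k2 * pn)
}

#' Generate a synthetic three-state denaturation profile
#'
#' Two signal models are available:
#'
#' * `"stepwise"` (default): each transition is rendered as its exact
#'   two-state conversion inside its own denaturant zone
#'   (`zone1_M`, `zone2_M` of the truth), with the pure state baselines
#'   emitted outside the zones. Within zone 1 the signal is
#'   \eqn{y_N + (y_I - y_N) f_1} with \eqn{f_1 = K_1/(1+K_1)}, and within
#'   zone 2 \eqn{y_I + (y_U - y_I) f_2} with \eqn{f_2 = K_2/(1+K_2)}. This
#'   is the model the baseline/fraction analysis of the unfolding module
#'   assumes, so the full pipeline is an exact inverse of this generator —
#'   the same design used for the quench generator, giving every analysis
#'   stage an exactly checkable oracle.
#' * `"sequential"`: the thermodynamically coupled mixture
#'   \eqn{y = p_N y_N + p_I y_I + p_U y_U} with populations from
#'   [three_state_populations()]. This is the physically consistent signal;
#'   note that when transitions overlap, the two-state fraction analysis of
#'   such data is biased (see the package vignette).
#'
#' Multiplicative lognormal noise with the truth's `noise_cv` is applied
#' under the truth's seed. If the grid does not span both midpoints a note
#' is recorded in the profile label (not an error).
#'
#' @param truth An [unfold_truth()].
#' @param denat_grid Denaturant grid in mol/L; default 0-9 M in 0.25 M
#'   steps.
#' @param temperature_K Temperature in kelvin (default 298).
#' @param signal_model `"stepwise"` or `"sequential"`.
#' @return An [unfolding_profile()].
#' @export
generate_unfolding <- function(truth, denat_grid = seq(0, 9, by = 0.25),
                               temperature_K = 298,
                               signal_model = c("stepwise", "sequential")) {
  stopifnot(inherits(truth, "unfold_truth"))
  signal_model <- match.arg(signal_model)
  u <- as.numeric(denat_grid)
  rt <- R_GAS * temperature_K
  bl <- truth$baselines
  y_n <- bl$N[1L] + bl$N[2L] * u
  y_i <- bl$I[1L] + bl$I[2L] * u
  y_u <- bl$U[1L] + bl$U[2L] * u
  if (signal_model == "sequential") {
    p <- three_state_populations(truth, u, temperature_K)
    y <- p$pN * y_n + p$pI * y_i + p$pU * y_u
  } else {
    k1 <- exp(-(truth$dG1_J_per_mol - truth$m1_J_per_mol_per_M * u) / rt)
    k2 <- exp(-(truth$dG2_J_per_mol - truth$m2_J_per_mol_per_M * u) / rt)
    f1 <- ifelse(u <= truth$zone1_M[1L], 0,
                 ifelse(u >= truth$zone1_M[2L], 1, k1 / (1 + k1)))
    f2 <- ifelse(u <= truth$zone2_M[1L], 0,
                 ifelse(u >= truth$zone2_M[2L], 1, k2 / (1 + k2)))
    y <- y_n + (y_i - y_n) * f1 + (y_u - y_i) * f2
  }
  y <- y * with_seed(truth$seed, lognormal_factors(length(y), truth$noise_cv))
  mid1 <- truth$dG1_J_per_mol / truth$m1_J_per_mol_per_M
  mid2 <- truth$dG2_J_per_mol / truth$m2_J_per_mol_per_M
  label <- sprintf("synthetic %s three-state profile", signal_model)
  if (min(u) > mid1 || max(u) < mid2)
    label <- paste0(label, " [warning: grid does not span both midpoints]")
  unfolding_profile(u, y, temperature_K = temperature_K, label = label)
}

#' Generate a synthetic Rayleigh-scattering series
#'
#' Emulates light-scattering monitoring of colloidal aggregate formation:
#' flat low signal below an aggregation threshold and a steep linear rise
#' above it. With `cmc_like_threshold_M = NULL` no aggregation occurs and
#' the expected signal is constant over the grid.
#'
#' @param conc_grid Ligand concentrations in mol/L, starting at 0,
#'   strictly increasing. Default 0-60 µM in 2.5 µM steps.
#' @param cmc_like_threshold_M Aggregation onset concentration in mol/L,
#'   or `NULL` for no aggregation.
#' @param seed Integer seed.
#' @param base_signal Mean scattering signal below threshold.
#' @param rise_factor Signal at the top of the grid relative to
#'   `base_signal` when aggregation occurs.
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @return A [titration_series()] holding the scattering intensities.
#' @export
generate_scattering <- function(conc_grid = seq(0, 60e-6, by = 2.5e-6),
                                cmc_like_threshold_M = NULL, seed = 1L,
                                base_signal = 10, rise_factor = 50,
                                noise_cv = 0.05) {
  if (any(diff(conc_grid) <= 0))
    stop_specbind("conc_grid must be strictly increasing",
                  "specbind_validation_error")
  mu <- rep(base_signal, length(conc_grid))
  if (!is.null(cmc_like_threshold_M)) {
    above <- conc_grid > cmc_like_threshold_M
    span <- max(conc_grid) - cmc_like_threshold_M
    mu[above] <- base_signal +
      (rise_factor - 1) * base_signal *
        (conc_grid[above] - cmc_like_threshold_M) / span
  }
  sig <- mu * with_seed(seed, lognormal_factors(length(mu), noise_cv))
  titration_series(conc_grid, sig, temperature_K = 298, protein_conc_M = 5e-6,
                   label = "synthetic scattering at 350 nm")
}
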
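# Shared fixtures, all generated in code.

# Gas constant as used throughout (J/mol/K).
RGAS <- 8.3145

# Stern-Volmer fits reproducing the published albumin temperature series:
# noiseless titrations generated with Ka equal to each printed Ksv (n = 1).
table1_sv_fits <- function(tau0 = 5e-9) {
  ksv <- c(4.59e4, 4.40e4, 3.74e4)
  temps <- c(293, 298, 303)
  lapply(seq_along(ksv), function(i) {
    s <- generate_quench(quench_truth(ksv[i]), temperature_K = temps[i])
    fit_stern_volmer(s, tau0_s = tau0)
  })
}

# Exact two-state fractions of one unfolding step on a urea grid.
two_state_fractions <- function(dG, m, u, temperature_K = 298) {
  k <- exp(-(dG - m * u) / (RGAS * temperature_K))
  data.frame(denaturant_M = u, f = k / (1 + k))
}

# A small hand-built profile with pure linear plateaus and one midway point
# in each transition gap; exact fractions are knowable by construction.
plateau_profile <- function() {
  u <- c(0, 1, 2, 3, 4.5, 5, 5.5, 6.5, 8, 9)
  y <- c(1, 1, 1, 0.75, 0.5, 0.5, 0.5, 0.35, 0.2, 0.2)
  unfolding_profile(u, y)
}

plateau_regions <- function() list(N = c(0, 2), I = c(4.5, 5.5), U = c(8, 9))
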
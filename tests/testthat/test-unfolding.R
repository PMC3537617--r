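test_that("baseline fitting recovers plateau and sloped state lines", {
  p <- plateau_profile()
  bl <- fit_baselines(p, plateau_regions())
  expect_equal(bl$line_N, c(1, 0), tolerance = 1e-12)
  expect_equal(bl$line_I, c(0.5, 0), tolerance = 1e-12)
  expect_equal(bl$line_U, c(0.2, 0), tolerance = 1e-12)

  # sloped baselines from the generator's pure-state regions
  tr <- unfold_truth(baselines = list(N = c(1.0, -0.01), I = c(0.55, -0.005),
                                      U = c(0.2, 0.002)))
  prof <- generate_unfolding(tr)
  bl2 <- fit_baselines(prof)
  expect_equal(bl2$line_N, c(1.0, -0.01), tolerance = 1e-6)
  expect_equal(bl2$line_I, c(0.55, -0.005), tolerance = 1e-6)
  expect_equal(bl2$line_U, c(0.2, 0.002), tolerance = 1e-6)

  expect_error(fit_baselines(p, list(N = c(0, 5), I = c(4.5, 5.5),
                                     U = c(8, 9))),
               class = "specbind_validation_error")
  err <- expect_error(
    fit_baselines(p, list(N = c(0, 2), I = c(6.9, 7.1), U = c(8, 9))),
    class = "specbind_insufficient_data")
  expect_match(conditionMessage(err), "region I")
})

test_that("state fractions interpolate between baselines", {
  p <- plateau_profile()
  fr <- state_fractions(p, fit_baselines(p, plateau_regions()))
  # u = 3 sits exactly midway between the N and I plateaus
  expect_equal(fr$transition1$f[fr$transition1$denaturant_M == 3], 0.5,
               tolerance = 1e-12)
  # u = 6.5 at signal 0.35 is midway between I (0.5) and U (0.2)
  expect_equal(fr$transition2$f[fr$transition2$denaturant_M == 6.5], 0.5,
               tolerance = 1e-12)

  # a point lying exactly on the native baseline has f = 0
  p2 <- unfolding_profile(c(0, 1, 2, 3, 4.5, 5, 5.5, 6.5, 8, 9),
                          c(1, 1, 1, 1, 0.5, 0.5, 0.5, 0.35, 0.2, 0.2))
  fr2 <- state_fractions(p2, fit_baselines(p2, plateau_regions()))
  expect_equal(fr2$transition1$f[fr2$transition1$denaturant_M == 3], 0,
               tolerance = 1e-12)

  # coincident N and I baselines are degenerate
  p3 <- unfolding_profile(c(0, 1, 2, 3, 4.5, 5, 5.5, 6.5, 8, 9),
                          c(1, 1, 1, 1, 1, 1, 1, 0.6, 0.2, 0.2))
  expect_error(state_fractions(p3, fit_baselines(p3, plateau_regions())),
               class = "specbind_degenerate_baseline")
})

test_that("per-point free energies apply the log-ratio transform in band", {
  fr <- structure(list(
    transition1 = data.frame(denaturant_M = c(3, 3.5, 4, 4.5),
                             f = c(0.5, 0.269, 0.99, 0.03),
                             flagged = rep(FALSE, 4)),
    transition2 = data.frame(denaturant_M = numeric(), f = numeric(),
                             flagged = logical()),
    temperature_K = 298), class = "state_fractions")
  dg <- per_point_dG(fr)
  expect_equal(nrow(dg$transition1), 2)        # 0.99 and 0.03 excluded
  expect_identical(unname(dg$n_excluded["transition1"]), 2L)
  expect_equal(dg$transition1$dG_J_per_mol[1], 0, tolerance = 1e-12)
  # frozen hand evaluation of -R*298*log(0.269/0.731)
  expect_equal(dg$transition1$dG_J_per_mol[2], 2476.983, tolerance = 1e-6)
})

test_that("free-energy transform and the two-state logistic are mutual inverses", {
  rt <- RGAS * 298
  set.seed(99)
  f <- runif(50, 0.05, 0.95)
  dg <- -rt * log(f / (1 - f))
  f_back <- exp(-dg / rt) / (1 + exp(-dg / rt))
  expect_equal(f_back, f, tolerance = 1e-12)
})

test_that("linear extrapolation fit is exact on exact free-energy lines", {
  u <- seq(2.5, 4.5, by = 0.25)
  dg <- 17190 - 3500 * u
  ft <- fit_lem(data.frame(denaturant_M = u, dG_J_per_mol = dg), "N_to_I")
  expect_equal(ft$dG_H2O_J_per_mol, 17190, tolerance = 1e-9)
  expect_equal(ft$m_J_per_mol_per_M, 3500, tolerance = 1e-9)
  expect_equal(ft$midpoint_M, 17190 / 3500, tolerance = 1e-9)
  expect_identical(ft$method, "linear_LEM")

  expect_error(fit_lem(data.frame(denaturant_M = u[1:2],
                                  dG_J_per_mol = dg[1:2])),
               class = "specbind_insufficient_data")
})

test_that("nonlinear fraction fit recovers exact two-state curves", {
  u <- seq(2.5, 7, by = 0.25)
  fr <- two_state_fractions(17190, 3500, u)
  ft <- fit_nonlinear(fr, transition = "N_to_I")
  expect_equal(ft$dG_H2O_J_per_mol, 17190, tolerance = 1e-6)
  expect_equal(ft$m_J_per_mol_per_M, 3500, tolerance = 1e-6)

  # LEM on the transformed points agrees with the nonlinear route
  rt <- RGAS * 298
  inb <- fr$f >= 0.05 & fr$f <= 0.95
  lem <- fit_lem(data.frame(denaturant_M = u[inb],
                            dG_J_per_mol = -rt * log(fr$f[inb] / (1 - fr$f[inb]))))
  expect_equal(lem$dG_H2O_J_per_mol, ft$dG_H2O_J_per_mol, tolerance = 1e-6)

  # uninformative fractions are refused
  flat <- data.frame(denaturant_M = u, f = rep(0.5, length(u)))
  expect_error(fit_nonlinear(flat), class = "specbind_fit_failure")
  low <- data.frame(denaturant_M = u, f = seq(0.01, 0.05, length.out = length(u)))
  expect_error(fit_nonlinear(low), class = "specbind_fit_failure")
})

test_that("full pipeline inverts the stepwise generator for both transitions", {
  tr <- unfold_truth()   # apo truth: 17.19/15.23 kJ/mol, m = 3.5/2.5 kJ/mol/M
  an <- fit_unfolding(generate_unfolding(tr))
  for (m in c("linear", "nonlinear")) {
    expect_equal(an$fits[[m]]$N_to_I$dG_H2O_J_per_mol, 17190,
                 tolerance = 1e-3)
    expect_equal(an$fits[[m]]$N_to_I$m_J_per_mol_per_M, 3500,
                 tolerance = 1e-3)
    expect_equal(an$fits[[m]]$I_to_U$dG_H2O_J_per_mol, 15230,
                 tolerance = 1e-3)
    expect_equal(an$fits[[m]]$I_to_U$m_J_per_mol_per_M, 2500,
                 tolerance = 1e-3)
  }
  # the two regression routes agree on noiseless data
  expect_equal(an$fits$linear$N_to_I$dG_H2O_J_per_mol,
               an$fits$nonlinear$N_to_I$dG_H2O_J_per_mol, tolerance = 1e-6)
  expect_equal(an$fits$linear$I_to_U$dG_H2O_J_per_mol,
               an$fits$nonlinear$I_to_U$dG_H2O_J_per_mol, tolerance = 1e-6)

  # the measured fraction curve crosses one half at the fitted midpoint
  # (transition 2, whose midpoint lies inside its analysis window)
  fr <- an$fractions$transition2
  logit <- log(fr$f / (1 - fr$f))
  u_half <- approx(logit, fr$denaturant_M, xout = 0)$y
  expect_equal(u_half, an$fits$nonlinear$I_to_U$midpoint_M, tolerance = 1e-6)
})

test_that("nonlinear standard errors are calibrated under noise", {
  u <- seq(2.5, 4.5, by = 0.25)
  f0 <- two_state_fractions(17190, 3500, u)$f
  n_rep <- 500
  ok <- logical(n_rep)
  sdlog <- sqrt(log1p(0.01^2))
  for (i in seq_len(n_rep)) {
    set.seed(i)
    f <- f0 * rlnorm(length(f0), -sdlog^2 / 2, sdlog)
    ft <- fit_nonlinear(data.frame(denaturant_M = u, f = f))
    ok[i] <- abs(ft$dG_H2O_J_per_mol - 17190) <= 3 * ft$stderr_dG &&
      abs(ft$m_J_per_mol_per_M - 3500) <= 3 * ft$stderr_m
  }
  expect_gte(mean(ok), 0.95)
})

test_that("stability comparison reproduces published-style arithmetic", {
  mk <- function(dg, tr, method) transition_fit(dg * 1000, method = method,
                                                transition = tr)
  apo_nl <- list(mk(17.19, "N_to_I", "nonlinear"),
                 mk(15.23, "I_to_U", "nonlinear"))
  cpx_nl <- list(mk(19.09, "N_to_I", "nonlinear"),
                 mk(15.32, "I_to_U", "nonlinear"))
  cmp <- compare_stability(apo_nl, cpx_nl)
  expect_equal(cmp$total_dG_H2O_apo / 1000, 32.42, tolerance = 1e-9)
  expect_equal(cmp$total_dG_H2O_complex / 1000, 34.41, tolerance = 1e-9)
  expect_equal(cmp$ddG_H2O_J_per_mol / 1000, 1.99, tolerance = 1e-9)
  expect_equal(cmp$ddG_H2O_J_per_mol,
               cmp$total_dG_H2O_complex - cmp$total_dG_H2O_apo)

  same <- compare_stability(apo_nl, apo_nl)
  expect_equal(same$ddG_H2O_J_per_mol, 0)

  apo_lin <- list(mk(15.72, "N_to_I", "linear_LEM"),
                  mk(9.99, "I_to_U", "linear_LEM"))
  expect_error(compare_stability(apo_lin, cpx_nl),
               class = "specbind_validation_error")
})
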
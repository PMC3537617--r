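test_that("quench generator reproduces the saturable model exactly", {
  ka <- 6.02e4
  tr <- quench_truth(ka, n_sites = 1, F0 = 1000, noise_cv = 0)
  grid <- c(0, 0.5 / ka, 1 / ka, 2 / ka, 4 / ka)
  s <- generate_quench(tr, grid)
  expect_identical(s$intensity[1], 1000)          # F0 exact
  expect_equal(s$intensity[3], 500)               # half-quench at [Q] = 1/Ka

  # with n = 1, F0/F - 1 is exactly linear in [Q] with slope Ka
  q <- s$ligand_conc_M[-1]
  expect_equal((1000 / s$intensity[-1] - 1) / q, rep(ka, 4), tolerance = 1e-12)

  noisy <- quench_truth(ka, noise_cv = 0.05, seed = 42)
  expect_identical(generate_quench(noisy)$intensity,
                   generate_quench(noisy)$intensity)
  other <- quench_truth(ka, noise_cv = 0.05, seed = 43)
  expect_false(identical(generate_quench(noisy)$intensity,
                         generate_quench(other)$intensity))

  expect_error(generate_quench(tr, c(-1e-6, 0, 1e-6)),
               class = "specbind_validation_error")
  expect_error(quench_truth(ka, noise_cv = 0.25),
               class = "specbind_validation_error")
})

test_that("temperature series obey the van't Hoff relation exactly", {
  base <- quench_truth(1, n_sites = 1, F0 = 1000, noise_cv = 0)
  dh <- -15130
  ds <- 40.87
  ss <- generate_temperature_series(dh, ds, c(293, 298, 303), base)
  # hand evaluation of exp(-dH/(R T) + dS/R) at 298 K, frozen
  ka298_expected <- 61201.50
  ka_fitted <- fit_stern_volmer(ss[[2]])$Ksv_per_M   # n = 1: slope = Ka
  expect_equal(ka_fitted, ka298_expected, tolerance = 1e-6)

  # dH = 0: Ka identical at all temperatures
  flat <- generate_temperature_series(0, ds, c(280, 300, 320), base)
  kas <- vapply(flat, function(s) fit_stern_volmer(s)$Ksv_per_M, numeric(1))
  expect_equal(max(kas) - min(kas), 0, tolerance = 1e-6 * kas[1])

  # negative dH with dS = 0: Ka strictly decreasing in T
  dec <- generate_temperature_series(-20000, 0, c(280, 300, 320), base)
  kas2 <- vapply(dec, function(s) fit_stern_volmer(s)$Ksv_per_M, numeric(1))
  expect_true(all(diff(kas2) < 0))
})

test_that("three-state populations are a proper sequential partition", {
  truths <- list(
    unfold_truth(),
    unfold_truth(dG1_J_per_mol = 12000, m1_J_per_mol_per_M = 4000,
                 dG2_J_per_mol = 20000, m2_J_per_mol_per_M = 2600),
    unfold_truth(dG1_J_per_mol = 25000, m1_J_per_mol_per_M = 6000,
                 dG2_J_per_mol = 30000, m2_J_per_mol_per_M = 3500)
  )
  u <- seq(0, 9, by = 0.25)
  for (tr in truths) {
    p <- three_state_populations(tr, u)
    expect_equal(p$pN + p$pI + p$pU, rep(1, length(u)), tolerance = 1e-12)
    expect_true(all(p$pN >= 0 & p$pI >= 0 & p$pU >= 0))
  }

  # folded protein at zero denaturant: both dG >= 15 kJ/mol implies pN > 0.99
  tr <- unfold_truth(dG1_J_per_mol = 15000, m1_J_per_mol_per_M = 3500,
                     dG2_J_per_mol = 15500, m2_J_per_mol_per_M = 2500)
  expect_gt(three_state_populations(tr, 0)$pN, 0.99)

  # at the first midpoint with the second step still strongly uphill,
  # native and intermediate are equally populated
  tr2 <- unfold_truth(dG1_J_per_mol = 17190, m1_J_per_mol_per_M = 3500,
                      dG2_J_per_mol = 30000, m2_J_per_mol_per_M = 2500)
  mid1 <- 17190 / 3500
  p <- three_state_populations(tr2, mid1)
  expect_equal(p$pN, p$pI, tolerance = 1e-3)
  expect_equal(p$pN, 0.5, tolerance = 1e-2)

  # midpoint ordering is enforced
  expect_error(unfold_truth(dG1_J_per_mol = 20000, m1_J_per_mol_per_M = 2000,
                            dG2_J_per_mol = 15000, m2_J_per_mol_per_M = 2500),
               class = "specbind_validation_error")
})

test_that("unfolding generator is monotone, seeded and grid-aware", {
  tr <- unfold_truth()
  p <- generate_unfolding(tr)
  expect_true(all(diff(p$signal) <= 1e-12))   # flat baselines: non-increasing
  ps <- generate_unfolding(tr, signal_model = "sequential")
  expect_true(all(diff(ps$signal) <= 1e-12))

  noisy <- unfold_truth(noise_cv = 0.02, seed = 11)
  expect_identical(generate_unfolding(noisy)$signal,
                   generate_unfolding(noisy)$signal)

  short <- generate_unfolding(tr, denat_grid = seq(0, 3, by = 0.25))
  expect_match(short$label, "does not span")
  expect_no_match(p$label, "does not span")
})

test_that("scattering generator separates aggregating from clean ligands", {
  clean <- generate_scattering(cmc_like_threshold_M = NULL, seed = 5)
  sl <- coef(lm(clean$intensity ~ clean$ligand_conc_M))[2]
  # slope contributes negligibly relative to the base signal over the grid
  expect_lt(abs(sl) * max(clean$ligand_conc_M), 0.2 * mean(clean$intensity))

  agg <- generate_scattering(cmc_like_threshold_M = 30e-6, seed = 5)
  below <- agg$intensity[agg$ligand_conc_M <= 30e-6]
  above <- agg$intensity[agg$ligand_conc_M > 35e-6]
  expect_true(all(above > mean(below) + 5 * sd(below)))

  expect_identical(generate_scattering(cmc_like_threshold_M = 30e-6, seed = 5)$intensity,
                   agg$intensity)
})
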
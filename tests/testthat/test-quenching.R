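test_that("Stern-Volmer fit recovers noiseless synthetic data exactly", {
  s <- generate_quench(quench_truth(4.59e4))
  f <- fit_stern_volmer(s)
  expect_equal(f$Ksv_per_M, 4.59e4, tolerance = 1e-6)
  expect_equal(f$intercept, 1, tolerance = 1e-9)
  expect_gte(f$r_squared, 1 - 1e-12)
  expect_length(f$warnings, 0)

  # kq * tau0 == Ksv identity across a spread of fits and lifetimes
  for (ka in c(1e3, 4.4e4, 2e6)) {
    for (tau0 in c(1e-9, 5e-9)) {
      ft <- fit_stern_volmer(generate_quench(quench_truth(ka)), tau0_s = tau0)
      expect_equal(ft$kq_per_M_per_s * ft$tau0_s, ft$Ksv_per_M,
                   tolerance = 1e-12)
    }
  }
})

test_that("quenching rate follows from Ksv and the fluorescence lifetime", {
  f <- fit_stern_volmer(generate_quench(quench_truth(4.40e4)), tau0_s = 5e-9)
  expect_equal(f$kq_per_M_per_s, 8.80e12, tolerance = 1e-9)
})

test_that("degenerate titrations are flagged or refused", {
  const <- titration_series(c(0, 1e-6, 2e-6, 3e-6), rep(1000, 4))
  f <- fit_stern_volmer(const)
  expect_equal(f$Ksv_per_M, 0, tolerance = 1e-9)
  expect_true(any(grepl("no significant quenching", f$warnings)))

  short <- titration_series(c(0, 1e-6, 2e-6), c(1000, 950, 900))
  expect_error(fit_stern_volmer(short), class = "specbind_insufficient_data")

  anti <- titration_series(c(0, 1e-6, 2e-6, 3e-6), c(1000, 1100, 1200, 1300))
  expect_true(any(grepl("anti-quench", fit_stern_volmer(anti)$warnings)))
})

test_that("mechanism classification follows kq magnitude and Ksv(T) trend", {
  # complex formation: kq far above the collisional limit, Ksv falling with T
  fits <- table1_sv_fits()
  call <- classify_mechanism(fits)
  expect_identical(call$mechanism, "static")
  expect_true(all(call$kq_per_M_per_s > 1e10))
  expect_true(all(diff(call$Ksv_per_M) < 0))

  # collisional quenching: kq below the limit, Ksv rising with T
  dyn <- lapply(seq_along(c(293, 298, 303)), function(i) {
    s <- generate_quench(quench_truth(c(30, 40, 50)[i]),
                         temperature_K = c(293, 298, 303)[i])
    fit_stern_volmer(s, tau0_s = 5e-9)
  })
  expect_identical(classify_mechanism(dyn)$mechanism, "dynamic")

  # conflicting evidence: large kq but Ksv rising with T
  conf <- lapply(seq_along(c(293, 298, 303)), function(i) {
    s <- generate_quench(quench_truth(c(3.7e4, 4.4e4, 4.6e4)[i]),
                         temperature_K = c(293, 298, 303)[i])
    fit_stern_volmer(s)
  })
  expect_identical(classify_mechanism(conf)$mechanism, "indeterminate")

  dup <- fits
  dup[[2]]$temperature_K <- 293
  expect_error(classify_mechanism(dup), class = "specbind_validation_error")
})

test_that("specificity check distinguishes specific binding from colloids", {
  mk <- function(ka, pc) fit_stern_volmer(
    generate_quench(quench_truth(ka), protein_conc_M = pc))
  # near-constant Ksv across protein concentrations: specific binding
  spec3 <- list(mk(4.59e4, 3e-6), mk(4.11e4, 6e-6), mk(4.03e4, 12e-6))
  rep1 <- specificity_check(spec3)
  expect_true(rep1$pass)
  expect_equal(rep1$max_rel_spread, (4.59e4 - 4.03e4) / 4.59e4,
               tolerance = 1e-6)

  # Ksv halving with each doubling of protein: colloid signature
  coll <- list(mk(4e4, 3e-6), mk(2e4, 6e-6), mk(1e4, 12e-6))
  expect_false(specificity_check(coll)$pass)

  expect_error(specificity_check(list(mk(4e4, 3e-6))),
               class = "specbind_insufficient_data")
})

test_that("Ksv estimator is unbiased and its intervals calibrated under noise", {
  truth <- 4.40e4
  n_rep <- 1000
  est <- numeric(n_rep)
  cover <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    s <- generate_quench(quench_truth(truth, noise_cv = 0.01, seed = i))
    f <- fit_stern_volmer(s)
    est[i] <- f$Ksv_per_M
    tq <- qt(0.975, length(s$intensity) - 2)
    cover[i] <- abs(f$Ksv_per_M - truth) <= tq * f$Ksv_stderr
  }
  expect_lt(abs(mean(est) - truth) / truth, 0.01)
  expect_gte(mean(cover), 0.92)
})
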
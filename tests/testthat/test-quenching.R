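test_that("quenching partition matches the worked example and closes", {
  q <- quenching_partition(0.2, 0.4, 1.0)
  expect_equal(q$y_ii, 0.5)
  expect_equal(q$y_npq, 0.3)
  expect_equal(q$y_no, 0.2)
  # fully closed reaction centers, no quenching
  q2 <- quenching_partition(1, 1, 1)
  expect_equal(q2$y_ii, 0)
  expect_equal(q2$y_npq, 0)
  expect_equal(q2$y_no, 1)
  expect_error(quenching_partition(0.5, 0.4, 1.0), "inconsistent")
  expect_error(quenching_partition(0.2, 1.1, 1.0), "inconsistent")
})

test_that("closure Y(II)+Y(NPQ)+Y(NO)=1 holds for random valid records", {
  rec <- random_quenching_records(2000, seed = 3)
  q <- quenching_partition(rec$f, rec$fm_prime, rec$fm)
  expect_lt(max(abs(q$y_ii + q$y_npq + q$y_no - 1)), 1e-9)
  expect_true(all(q$y_ii >= 0 & q$y_ii <= 1))
  expect_true(all(q$y_npq >= 0 & q$y_npq <= 1))
  expect_true(all(q$y_no >= 0 & q$y_no <= 1))
})

test_that("Fv/Fm follows its definition and rejects degenerates", {
  expect_equal(fv_fm(500, 2500), 0.8)
  expect_equal(fv_fm(1e-9, 1), 1, tolerance = 1e-6)
  expect_error(fv_fm(2500, 2500), "degenerate")
})

test_that("ETR is the four-factor product and is linear in its inputs", {
  expect_equal(electron_transport_rate(0.5, 100), 21)
  expect_equal(electron_transport_rate(0.7, 0), 0)
  expect_equal(electron_transport_rate(0.68, 231), 0.68 * 231 * 0.42,
               tolerance = 1e-12)
  expect_equal(electron_transport_rate(0.68, 231), 65.9736)
  # linearity in both arguments
  expect_equal(electron_transport_rate(0.4, 200),
               2 * electron_transport_rate(0.2, 200))
  expect_equal(electron_transport_rate(0.4, 200),
               2 * electron_transport_rate(0.4, 100))
  expect_error(electron_transport_rate(1.2, 100), "Y\\(II\\)")
})

test_that("RLC fits recover the generating parameters exactly without noise", {
  for (pars in list(c(0.2, 40), c(0.3, 60), c(0.35, 90))) {
    rl <- simulate_rlc(pars[1], pars[2])
    ft <- fit_rlc(rl$ppfd, rl$etr)
    expect_lt(abs(ft$alpha - pars[1]) / pars[1], 1e-3)
    expect_lt(abs(ft$retrmax - pars[2]) / pars[2], 1e-3)
    expect_equal(ft$ek, ft$retrmax / ft$alpha, tolerance = 1e-9)
    expect_true(ft$converged)
  }
})

test_that("RLC fits are invariant to the order of the irradiance steps", {
  rl <- simulate_rlc(0.3, 60, noise_sd = 1, seed = 8)
  ft1 <- fit_rlc(rl$ppfd, rl$etr)
  set.seed(99)
  perm <- sample(nrow(rl))
  ft2 <- fit_rlc(rl$ppfd[perm], rl$etr[perm])
  expect_equal(ft1$alpha, ft2$alpha, tolerance = 1e-9)
  expect_equal(ft1$retrmax, ft2$retrmax, tolerance = 1e-9)
})

test_that("far below saturation the fitted initial slope tracks the data slope", {
  I <- c(0, 2, 4, 6, 8, 10)
  etr <- 0.25 * I  # essentially linear regime
  ft <- fit_rlc(I, etr)
  expect_equal(ft$alpha, 0.25, tolerance = 0.01)
})

test_that("RLC fit guards reject unusable curves", {
  expect_error(fit_rlc(c(0, 10, 20), c(0, 1, 2)), "5 distinct")
  expect_error(fit_rlc(c(10, 20, 30, 40, 50), 1:5), "zero-irradiance")
  expect_error(fit_rlc(c(0, 10, 20, 30, 40), rep(0, 5)), "degenerate")
})

test_that("noisy RLC recovery keeps median relative error within 5%", {
  errs <- matrix(NA_real_, 60, 2)
  for (i in 1:60) {
    rl <- simulate_rlc(0.3, 60, noise_sd = 0.02 * 60, seed = 1e4 + i)
    ft <- fit_rlc(rl$ppfd, rl$etr)
    errs[i, ] <- c(abs(ft$alpha - 0.3) / 0.3, abs(ft$retrmax - 60) / 60)
  }
  expect_lte(stats::median(errs[, 1]), 0.05)
  expect_lte(stats::median(errs[, 2]), 0.05)
})
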
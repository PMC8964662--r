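test_that("noiseless surveys are interpolated exactly by the translog fit", {
  for (truth in list(c(0.5, 0, 0.33, 0), c(0.5, -0.2, 0.33, 0.02))) {
    s <- simulate_survey(200, truth = truth, noise_sd = 0, seed = 7)
    fit <- suppressWarnings(fit_happiness(s))  # perfect-fit lm note
    expect_equal(fit$beta1, truth[1], tolerance = 1e-8)
    expect_equal(fit$beta2, truth[2], tolerance = 1e-8)
    expect_equal(fit$beta3, truth[3], tolerance = 1e-8)
    expect_equal(fit$beta4, truth[4], tolerance = 1e-8)
  }
})

test_that("degenerate designs are rejected", {
  s <- simulate_survey(50, c(0.5, 0, 0.33, 0), seed = 1)
  s$H <- 0.7
  expect_error(fit_happiness(s), "singular design")
  s2 <- simulate_survey(5, c(0.5, 0, 0.33, 0), seed = 1)
  expect_error(fit_happiness(s2), "at least 10")
})

test_that("elasticity estimators evaluate their closed forms", {
  s <- simulate_survey(100, c(0.5, -0.2, 0.33, 0), noise_sd = 0, seed = 3)
  fit <- suppressWarnings(fit_happiness(s))
  expect_equal(omega_hat(1, fit), 0.5, tolerance = 1e-8)
  expect_equal(omega_hat(exp(-1), fit), 0.7, tolerance = 1e-8)
  expect_equal(epsilon_omega_hat(1, fit), -0.4, tolerance = 1e-8)
  expect_equal(epsilon_omega_hat(exp(-1), fit), -0.2 / 0.7, tolerance = 1e-8)
  expect_equal(r_star_hat(1, fit), 1 - 0.5 + 0.4, tolerance = 1e-8)

  # beta1 small and beta2 negative pushes r* above 1
  s2 <- simulate_survey(100, c(0.1, -0.2, 0.33, 0), noise_sd = 0, seed = 3)
  fit2 <- suppressWarnings(fit_happiness(s2))
  expect_equal(r_star_hat(1, fit2), 2.9, tolerance = 1e-7)

  # CRRA: everything constant in H
  s3 <- simulate_survey(100, c(0.5, 0, 0.33, 0), noise_sd = 0, seed = 3)
  fit3 <- suppressWarnings(fit_happiness(s3))
  hgrid <- c(0.2, 0.5, 1)
  expect_equal(omega_hat(hgrid, fit3), rep(0.5, 3), tolerance = 1e-8)
  expect_equal(epsilon_omega_hat(hgrid, fit3), rep(0, 3), tolerance = 1e-8)
})

test_that("r* identity 1 - omega - epsilon^omega holds for any fit", {
  s <- simulate_survey(500, c(0.6, -0.15, 0.3, 0.01), noise_sd = 0.2,
                       seed = 11)
  fit <- fit_happiness(s)
  for (h in c(0.1, 0.3, 0.6, 1)) {
    expect_equal(r_star_hat(h, fit),
                 1 - suppressWarnings(omega_hat(h, fit)) -
                   epsilon_omega_hat(h, fit),
                 tolerance = 1e-14)
  }
})

test_that("the intercept changes no slope-derived quantity on clean data", {
  s <- simulate_survey(300, c(0.5, -0.2, 0.33, 0, 1.7), noise_sd = 0,
                       seed = 5)  # nonzero true intercept
  f1 <- suppressWarnings(fit_happiness(s, include_intercept = TRUE))
  f0 <- fit_happiness(s, include_intercept = FALSE)
  expect_equal(omega_hat(0.8, f1), 0.5 - 0.2 * log(0.8), tolerance = 1e-8)
  # dropping the intercept on intercept-shifted data biases the fit
  expect_gt(max(abs(c(f0$beta1, f0$beta2, f0$beta3, f0$beta4) -
                      c(0.5, -0.2, 0.33, 0))), 1e-3)
  # and on intercept-free data the two fits agree on every estimator
  s2 <- simulate_survey(300, c(0.5, -0.2, 0.33, 0), noise_sd = 0, seed = 5)
  g1 <- suppressWarnings(fit_happiness(s2, include_intercept = TRUE))
  g0 <- suppressWarnings(fit_happiness(s2, include_intercept = FALSE))
  for (h in c(0.3, 1)) {
    expect_equal(omega_hat(h, g1), omega_hat(h, g0), tolerance = 1e-7)
    expect_equal(r_star_hat(h, g1), r_star_hat(h, g0), tolerance = 1e-7)
  }
})

test_that("simulated surveys are deterministic given the seed", {
  a <- simulate_survey(100, c(0.5, -0.2, 0.33, 0), seed = 99)
  b <- simulate_survey(100, c(0.5, -0.2, 0.33, 0), seed = 99)
  expect_identical(a, b)
})

test_that("coefficients and r* are recovered within 3 SE at n = 10^4", {
  truth <- c(0.5, -0.2, 0.33, 0)
  s <- simulate_survey(1e4, truth, noise_sd = 0.1, seed = 2024)
  fit <- fit_happiness(s)
  expect_lt(abs(fit$beta2 - truth[2]) / fit$coef_se["beta2"], 3)
  rec <- recover_full_prefs(1, fit)
  expect_lt(abs(rec$prefs$omega_h - 0.5) / rec$se["omega_h"], 3)
  expect_lt(abs(rec$prefs$r_star - 0.9) / rec$se["r_star"], 3)
})

test_that("estimator error shrinks with sample size", {
  truth <- c(0.5, -0.2, 0.33, 0)
  err <- sapply(c(100, 1000, 10000), function(n) {
    mean(sapply(1:8, function(rep) {
      s <- simulate_survey(n, truth, noise_sd = 0.1, seed = 1000 + rep)
      fit <- fit_happiness(s)
      abs(r_star_hat(1, fit) - 0.9)
    }))
  })
  expect_true(all(diff(err) < 0))
})

test_that("posture classification matches the generating utility", {
  crra <- simulate_survey(1e4, c(0.5, 0, 0.33, 0), noise_sd = 0.1, seed = 8)
  drra <- simulate_survey(1e4, c(0.5, -0.2, 0.33, 0), noise_sd = 0.1,
                          seed = 8)
  irra <- simulate_survey(1e4, c(0.5, 0.2, 0.33, 0), noise_sd = 0.1,
                          seed = 8)
  expect_identical(classify_posture(fit_happiness(crra)), "CRRA")
  expect_identical(classify_posture(fit_happiness(drra)), "DRRA")
  expect_identical(classify_posture(fit_happiness(irra)), "IRRA")
  # a DRRA HARA utility (eta < 0) also classifies as DRRA through the
  # translog approximation
  hs <- simulate_survey(1e4, hara_params(0.5, eta = -0.2), noise_sd = 0.1,
                        seed = 8)
  expect_identical(classify_posture(fit_happiness(hs)), "DRRA")
})

test_that("full preference recovery chains to gamma and the HARA shift", {
  s <- simulate_survey(200, c(0.5, 0, 0.33, 0), noise_sd = 0, seed = 13)
  fit <- suppressWarnings(fit_happiness(s))
  rec <- recover_full_prefs(1, fit)
  expect_equal(rec$gamma, 0.5, tolerance = 1e-7)
  expect_equal(rec$prefs$pi_star, 1.5, tolerance = 1e-6)
  expect_equal(rec$hara$eta, 0, tolerance = 1e-6)

  # DRRA simulation recovers gamma within 0.05 of truth at n = 10^4
  s2 <- simulate_survey(1e4, c(0.5, -0.2, 0.33, 0), noise_sd = 0.1,
                        seed = 21)
  rec2 <- recover_full_prefs(1, fit_happiness(s2))
  expect_lt(abs(rec2$gamma - 0.5 / 1.4), 0.05)

  # negative estimates are reported, not clamped
  s3 <- simulate_survey(100, c(-0.2, 0, 0.33, 0), noise_sd = 0, seed = 13)
  fit3 <- suppressWarnings(fit_happiness(s3))
  expect_error(recover_full_prefs(1, fit3), "must both be positive")
})

test_that("consumption-side elasticity mirrors the QoL estimator", {
  s <- simulate_survey(200, c(0.5, -0.2, 0.4, -0.01), noise_sd = 0, seed = 6)
  fit <- suppressWarnings(fit_happiness(s))
  expect_equal(omega_c_hat(exp(10), fit), 0.4 - 0.01 * 10, tolerance = 1e-7)
  expect_error(omega_c_hat(-1, fit), "strictly positive")
})
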
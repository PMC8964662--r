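test_that("GRA-QALY and TVMI arithmetic", {
  expect_equal(gra_qaly(0, 2, 0.5, 0.9, 0, 1), 0)
  expect_equal(gra_qaly(0, 1, 0.5, 0.9, 0.2, 1), 0.5 * 0.9 * 0.2)
  expect_equal(gra_qaly(0.1, 2, 0.5, 0.9, 0.2, 1.025), 0.29225)
  expect_equal(tvmi(75000, 0.29225), 21918.75)
  expect_equal(tvmi(75000, 0), 0)
  expect_error(gra_qaly(0.3, 2, 0.5, 0.9, 0.2, 1), "p1 \\+ mu_p")
})

test_that("static decision adopts at the boundary and handles dominance", {
  dec <- igracer_static(21918.75, 0.29225, 75000)
  expect_true(dec$adopt)
  expect_equal(dec$ratio, 75000)
  expect_false(igracer_static(21918.76, 0.29225, 75000)$adopt)
  expect_true(igracer_static(0, 0.1, 75000)$adopt)
  # zero benefit: decision by cost sign
  expect_warning(d0 <- igracer_static(1000, 0, 75000), "dominance")
  expect_false(d0$adopt)
  expect_true(is.na(d0$ratio))
  expect_warning(d1 <- igracer_static(-1000, 0, 75000), "dominance")
  expect_true(d1$adopt)
})

test_that("survival paths accumulate and absorb at zero", {
  expect_equal(survival_path(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(survival_path(c(0.9, 0.8)), c(0.9, 0.72))
  expect_equal(survival_path(c(0.9, 0, 0.8)), c(0.9, 0, 0))
  expect_error(survival_path(c(0.9, 1.1)), "\\[0, 1\\]")
})

make_periods <- function(n = 6, seed = 1, stationary = FALSE) {
  set.seed(seed)
  draw <- function(lo, hi) if (stationary) rep(runif(1, lo, hi), n) else
    runif(n, lo, hi)
  period_params(mu_b = draw(0.05, 0.3), epsilon = draw(0.9, 1.1),
                delta = draw(1, 2.5), R = draw(1, 3),
                mu_p = draw(0, 0.05), p = draw(0.8, 0.99),
                delta_c = draw(5000, 20000), phi = 0.4, beta = 0.97,
                delta_c0 = 10000)
}

test_that("cost-only scenarios price to discounted costs", {
  per <- period_params(mu_b = 0, delta = 0, mu_p = 0, p = c(0.9, 0.8),
                       delta_c = c(1000, 2000), phi = 0.5, beta = 0.95,
                       delta_c0 = 500)
  expected <- -(500 + 0.95 * 1 * 0.9 * 1000 + 0.95^2 * 0.9 * 0.8 * 2000)
  expect_equal(as.numeric(nmb_dynamic(per, 150000, 0.5)), expected)
})

test_that("dynamic and stationary net monetary benefit coincide", {
  for (seed in 1:5) {
    per <- make_periods(n = 8, seed = seed, stationary = TRUE)
    nd <- as.numeric(nmb_dynamic(per, 150000, 0.5))
    kg <- k_grace(150000, 0.5, per$R[1])
    ns <- nmb_stationary(kg, per$mu_p[1], per$delta[1], per$phi, per$p[1],
                         per$mu_b[1], per$epsilon[1], per$delta_c[1],
                         per$delta_c0, n_periods = 8, beta = per$beta)
    expect_equal(nd, ns, tolerance = 1e-10)
  }
  # undiscounted, certain survival: horizon factor is N
  per1 <- period_params(mu_b = 0.1, delta = 1.5, R = 1, mu_p = 0.02,
                        p = 1, delta_c = 0, phi = 0.5, beta = 1)
  kg <- k_grace(150000, 0.5, 1)
  expect_equal(nmb_stationary(kg, 0.02, 1.5, 0.5, 1, 0.1, 1, 0, 0,
                              n_periods = 5, beta = 1),
               5 * as.numeric(nmb_dynamic(per1, 150000, 0.5)))
})

test_that("single-period dynamics reduce to the discounted static rule", {
  per <- period_params(mu_b = 0.2, epsilon = 1.05, delta = 1.8, R = 1.4,
                       mu_p = 0.05, p = 0.9, delta_c = 10000, phi = 0.4,
                       beta = 0.97, delta_c0 = 0)
  gq <- gra_qaly(0.05, 1.8, 0.4, 0.9, 0.2, 1.05)
  kg <- k_grace(150000, 0.5, 1.4)
  expect_equal(as.numeric(nmb_dynamic(per, 150000, 0.5)),
               0.97 * (kg * gq - 0.9 * 10000), tolerance = 1e-12)
  dd <- igracer_dynamic(per, 150000, 0.5, j = 1)
  expect_equal(dd$ratio, 0.97 * 0.9 * 10000 / (0.97 * gq), tolerance = 1e-12)
  expect_equal(dd$threshold, kg)
})

test_that("the adopt decision is invariant to the normalization period", {
  for (seed in 1:4) {
    per <- make_periods(n = 6, seed = seed)
    res <- lapply(1:6, function(j)
      igracer_dynamic(per, 150000, 0.5, d_star = 0.1, psi = 0.45, j = j))
    adopts <- vapply(res, `[[`, logical(1), "adopt")
    expect_length(unique(adopts), 1L)
    # ratio and threshold both scale with R_j, leaving the margin fixed
    margins <- vapply(res, function(x) x$ratio / x$threshold, numeric(1))
    expect_equal(max(margins) - min(margins), 0, tolerance = 1e-12)
  }
})

test_that("the ratio rule and the net-benefit sign agree", {
  for (seed in 1:6) {
    per <- make_periods(n = 5, seed = seed * 11)
    nmb <- as.numeric(nmb_dynamic(per, 150000, 0.5))
    dec <- igracer_dynamic(per, 150000, 0.5)
    expect_identical(dec$adopt, nmb >= 0)
  }
})

test_that("stationary inputs reproduce the geometric-series decision rule", {
  per <- make_periods(n = 7, seed = 3, stationary = TRUE)
  dec <- igracer_dynamic(per, 150000, 0.5, j = 1)
  bp <- per$beta * per$p[1]
  horizon <- per$beta * (1 - bp^7) / (1 - bp)
  gain <- per$mu_p[1] * per$delta[1] +
    per$phi * per$p[1] * per$mu_b[1] * per$epsilon[1]
  lhs <- (per$delta_c0 + per$delta_c[1] * sum(bp^(1:7))) / (gain * horizon)
  expect_equal(dec$ratio, lhs, tolerance = 1e-10)
  expect_identical(dec$adopt, lhs <= dec$threshold)
})

test_that("net benefit moves with gains and against costs", {
  base <- make_periods(n = 4, seed = 9)
  bump <- function(field, amount) {
    per <- base
    per[[field]] <- per[[field]] + amount
    per
  }
  n0 <- as.numeric(nmb_dynamic(base, 150000, 0.5))
  expect_gt(as.numeric(nmb_dynamic(bump("mu_b", 0.05), 150000, 0.5)), n0)
  expect_gt(as.numeric(nmb_dynamic(bump("mu_p", 0.005), 150000, 0.5)), n0)
  expect_lt(as.numeric(nmb_dynamic(bump("delta_c", 1000), 150000, 0.5)), n0)
})

test_that("discount conversion and input validation", {
  expect_equal(discount_factor(0.03), 1 / 1.03)
  expect_equal(discount_factor(0), 1)
  expect_error(period_params(mu_b = c(0.1, 0.2), delta = c(1, 2, 3),
                             mu_p = 0, p = 1, phi = 0.5),
               "length 1 or the common horizon")
  expect_error(period_params(mu_b = 0.1, delta = 1, mu_p = 0, p = 1.2,
                             phi = 0.5), "\\[0, 1\\]")
})
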
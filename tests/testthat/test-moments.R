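test_that("arm moments follow the population convention", {
  m <- arm_moments(c(0.5, 0.5, 0.5))
  expect_equal(m$variance, 0)
  expect_equal(m$skewness, 0)
  expect_true(is.na(m$excess_kurtosis))
  expect_equal(arm_moments(c(0, 1))$variance, 0.25)
  expect_equal(arm_moments(c(0, 1), estimator = "unbiased")$variance, 0.5)
  expect_error(arm_moments(0.5), "at least 2")
  expect_error(arm_moments(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("sample moments approach the analytic Beta moments", {
  a <- 2; b <- 5
  set.seed(42)
  x <- rbeta(2e5, a, b)
  m <- arm_moments(x)
  mu <- a / (a + b)
  v <- a * b / ((a + b)^2 * (a + b + 1))
  g1 <- 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
  expect_equal(m$mean, mu, tolerance = 2e-3)
  expect_equal(m$variance, v, tolerance = 2e-2)
  expect_equal(m$third_central, g1 * v^1.5, tolerance = 5e-2)
})

test_that("outcome contrasts derive gains and loss fractions", {
  set.seed(7)
  x <- rbeta(100, 5, 5)
  same <- outcome_contrast(x, x)
  expect_equal(same$mu_b, 0)
  expect_equal(same$delta_var, 0)
  expect_equal(same$loss$ell_star, same$loss$t_star)

  treat <- rep(0.75, 10); ctrl <- rep(0.5, 10)
  oc <- outcome_contrast(treat, ctrl)
  expect_equal(oc$loss$ell_star, 0.5)
  expect_equal(oc$loss$t_star, 0.25)
  expect_equal(oc$mu_b, 0.25)
  # complete cure: t* = 0
  cure <- outcome_contrast(rep(1, 10), ctrl)
  expect_equal(cure$loss$t_star, 0)
})

test_that("certainty-equivalence ratio prices variance and skewness", {
  p <- crra_prefs(0.5)
  expect_equal(epsilon_ratio(moment_contrast(0.1, 0.5), p), 1)
  expect_equal(epsilon_ratio(moment_contrast(0.1, 0.5, delta_var = -0.01), p),
               1.05)
  expect_equal(epsilon_ratio(moment_contrast(0.1, 0.5, delta_skew = 0.001),
                             p), 1.005)
  expect_error(epsilon_ratio(moment_contrast(0, 0.5), p), "mu_b = 0")
  # decreasing in the variance contrast, increasing in the skewness contrast
  eps_v <- sapply(c(-0.01, 0, 0.01), function(dv)
    epsilon_ratio(moment_contrast(0.1, 0.5, delta_var = dv), p))
  expect_true(all(diff(eps_v) < 0))
  eps_s <- sapply(c(-0.001, 0, 0.001), function(ds)
    epsilon_ratio(moment_contrast(0.1, 0.5, delta_skew = ds), p))
  expect_true(all(diff(eps_s) > 0))
})

test_that("utility-share series match exact CRRA ratios", {
  p <- crra_prefs(0.5)
  expect_equal(rho_sick(0, p), 1)
  expect_equal(rho_sick(0.25, p), 0.86621, tolerance = 1e-5)
  expect_equal(crra_utility_ratio(0.25, 0.5), 0.86603, tolerance = 1e-5)
  expect_equal(rho_well(0, p), 1)
  expect_equal(rho_well(0.2, p), 0.8945, tolerance = 1e-4)
  # risk-neutral: linear utility gives 1 - t*
  expect_equal(rho_sick(0.3, crra_prefs(0)), 0.7)
  for (r in c(0.25, 0.5, 0.9)) {
    for (x in c(0.1, 0.2, 0.3)) {
      expect_lt(abs(rho_sick(x, crra_prefs(r)) - crra_utility_ratio(x, r)),
                1e-2)
      expect_lt(abs(rho_well(x, crra_prefs(r)) - crra_utility_ratio(x, r)),
                1e-2)
    }
  }
  # sick state no better than well state whenever t* >= d*
  expect_lte(rho_sick(0.3, p), rho_well(0.1, p))
})

test_that("the overall share is the illness-probability mixture", {
  expect_equal(rho_total(1, 0.8, 1), 0.8)
  expect_equal(rho_total(0, 0.8, 1), 1)
  expect_equal(rho_total(0.5, 0.8, 1), 0.9)
  expect_error(rho_total(1.2, 0.8, 1), "\\[0, 1\\]")
})

test_that("the substitution rate satisfies omega R delta = rho H0", {
  expect_equal(mrs_delta(1, omega_h = 0.5, R = 1), 2)
  set.seed(31)
  for (i in 1:50) {
    rho <- runif(1, 0.5, 1); om <- runif(1, 0.2, 1)
    rr <- runif(1, 1, 4); h0 <- runif(1, 0.6, 1)
    d <- mrs_delta(rho, om, rr, h0)
    expect_equal(om * rr * d, rho * h0, tolerance = 1e-12)
  }
})

test_that("the exact substitution rate agrees with the reformulation", {
  prm <- hara_params(0.5)  # CRRA, r* = 0.5
  h0 <- 1; phi <- 0.4; t_star <- 0.2; d_star <- 0.1
  mu_h <- h0 * (1 - 0.35)
  # degenerate outcome: treated QoL is a point mass
  d_ex <- delta_exact(prm, phi, treated = h0 * (1 - t_star),
                      well = h0 * (1 - d_star), mu_h = mu_h)
  # exact rho and exact R reproduce it identically
  rho_ex <- (phi * hara_value(h0 * (1 - t_star), prm) +
               (1 - phi) * hara_value(h0 * (1 - d_star), prm)) /
    hara_value(h0, prm)
  om <- hara_prefs_at(h0, prm)$omega_h
  r_ex <- severity_ratio_exact(loss_profile(0.35, 0.2, 0.1), prm)
  expect_equal(mrs_delta(rho_ex, om, r_ex, h0), d_ex, tolerance = 1e-12)
  # and the series route lands within its truncation error
  p <- hara_prefs_at(h0, prm)
  rho_series <- rho_total(phi, rho_sick(t_star, p), rho_well(d_star, p))
  expect_equal(mrs_delta(rho_series, om, severity_ratio_crra(0.35, 0.5), h0),
               d_ex, tolerance = 1e-2)

  # phi = 0, well state at baseline: delta = H0 / omega_h
  expect_equal(delta_exact(prm, 0, treated = 0.5, well = 1, mu_h = 1),
               1 / om, tolerance = 1e-12)
})

test_that("Monte Carlo and quadrature substitution rates agree", {
  prm <- hara_params(0.4, eta = 0.1)
  shp <- list(shape1 = 8, shape2 = 3)
  dq <- delta_exact(prm, 0.6, treated = shp, well = 0.9, mu_h = 0.6)
  set.seed(17)
  draws <- rbeta(2e5, shp$shape1, shp$shape2)
  dm <- delta_exact(prm, 0.6, treated = draws, well = 0.9, mu_h = 0.6)
  w <- hara_value(draws, prm)
  mc_se <- 0.6 * sd(w) / sqrt(length(draws)) / hara_marginal(0.6, prm)
  expect_lt(abs(dm - dq), 3 * mc_se)
})

test_that("the two total-value forms are one identity", {
  set.seed(5)
  for (i in 1:200) {
    k <- runif(1, 5e4, 3e5); om <- runif(1, 0.2, 1)
    rr <- runif(1, 1, 5); h0 <- runif(1, 0.5, 1)
    rho <- runif(1, 0.4, 1); phi <- runif(1)
    p1 <- runif(1); mu_p <- runif(1, 0, 1 - p1)
    mu_b <- runif(1, 0, 0.3); eps <- runif(1, 0.8, 1.2)
    d_star <- runif(1, 0, 0.3); psi <- runif(1, 0.3, 1)
    delta <- mrs_delta(rho, om, rr, h0)
    kg <- k_grace(k, om, rr, h0, d_star, psi)
    v1 <- tvmi(kg, gra_qaly(mu_p, delta, phi, p1, mu_b, eps))
    v2 <- tvmi_alt(k, mu_p, rho, phi, p1, om, rr, mu_b, eps, h0, d_star, psi)
    expect_equal(v1, v2, tolerance = 1e-12)
  }
})
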
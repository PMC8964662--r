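#' Fit the translog happiness regression
#'
#' Ordinary least squares fit of
#' \deqn{\ln(Happy) = \beta_1\ln H + \tfrac12\beta_2(\ln H)^2
#'   + \beta_3\ln C + \tfrac12\beta_4(\ln C)^2 (+ \beta_5\ln H\ln C)
#'   + \epsilon,}
#' the second-order (translog) approximation of utility in QoL and
#' consumption.  An intercept is included by default: happiness scales are
#' arbitrary and every downstream quantity depends only on slopes, so the
#' intercept protects against scale-induced bias without changing any
#' estimator.  The optional interaction term `beta5` can be fitted but is
#' excluded from all estimator formulas.
#'
#' @param survey A data frame with strictly positive columns `happy`, `H`
#'   (QoL in (0, 1\]) and `C` (annual consumption); see [read_survey()] for
#'   the ordinal-score mapping.
#' @param include_intercept Include an intercept (default `TRUE`).
#' @param interaction Also fit the `ln(H) * ln(C)` interaction (default
#'   `FALSE`); reported but never used by the estimators.
#' @return An object of class `happiness_fit` holding the coefficients
#'   `beta1`--`beta4` (plus `intercept`/`beta5` when fitted), their
#'   standard errors, the coefficient covariance (for delta-method
#'   propagation), `sigma` and `n`.
#' @examples
#' s <- simulate_survey(200, truth = c(0.5, -0.2, 0.33, 0), noise_sd = 0.1,
#'                      seed = 1)
#' fit_happiness(s)
#' @export
fit_happiness <- function(survey, include_intercept = TRUE,
                          interaction = FALSE) {
  stopifnot(is.data.frame(survey))
  need <- c("happy", "H", "C")
  if (!all(need %in% names(survey))) {
    stop("`survey` must have columns happy, H, C", call. = FALSE)
  }
  if (nrow(survey) < 10L) {
    stop("at least 10 survey rows are required", call. = FALSE)
  }
  with(survey, {
    if (anyNA(happy) || anyNA(H) || anyNA(C)) {
      stop("survey contains missing values", call. = FALSE)
    }
    if (any(happy <= 0) || any(C <= 0) || any(H <= 0) || any(H > 1)) {
      stop("require happy > 0, C > 0 and H in (0, 1]", call. = FALSE)
    }
  })
  d <- data.frame(y = log(survey$happy),
                  x1 = log(survey$H),
                  x2 = 0.5 * log(survey$H)^2,
                  x3 = log(survey$C),
                  x4 = 0.5 * log(survey$C)^2)
  if (stats::sd(d$x1) == 0 || stats::sd(d$x3) == 0) {
    stop("singular design: H or C is constant across rows", call. = FALSE)
  }
  if (interaction) d$x5 <- log(survey$H) * log(survey$C)
  form <- if (include_intercept) y ~ . else y ~ . + 0
  fit <- stats::lm(form, data = d)
  if (anyNA(stats::coef(fit))) {
    stop("singular design: collinear regressors in the translog fit",
         call. = FALSE)
  }
  sm <- summary(fit)
  cf <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  map <- c(x1 = "beta1", x2 = "beta2", x3 = "beta3", x4 = "beta4",
           x5 = "beta5", `(Intercept)` = "intercept")
  names(cf) <- map[names(cf)]
  names(se) <- map[names(se)]
  vc <- stats::vcov(fit)
  dimnames(vc) <- list(map[rownames(vc)], map[colnames(vc)])
  structure(list(beta1 = unname(cf["beta1"]), beta2 = unname(cf["beta2"]),
                 beta3 = unname(cf["beta3"]), beta4 = unname(cf["beta4"]),
                 beta5 = if (interaction) unname(cf["beta5"]) else NULL,
                 intercept = if (include_intercept) unname(cf["intercept"])
                             else NULL,
                 coef = cf, coef_se = se, vcov = vc,
                 sigma = sm$sigma, n = nrow(survey),
                 include_intercept = include_intercept,
                 interaction = interaction),
            class = "happiness_fit")
}

#' @export
print.happiness_fit <- function(x, ...) {
  cat(sprintf("Translog happiness fit (n = %d%s)\n", x$n,
              if (x$include_intercept) ", with intercept" else ""))
  tab <- rbind(estimate = x$coef, se = x$coef_se)
  print(round(tab, 4))
  cat(sprintf("  posture by sign of beta2: %s\n", classify_posture(x)))
  invisible(x)
}

#' Estimated elasticity of utility with respect to QoL
#'
#' \eqn{\hat\omega_H(H) = \hat\beta_1 + \hat\beta_2\ln H}.  Constant in `H`
#' under CRRA (`beta2 = 0`).
#'
#' @param h QoL level(s) in (0, 1\]; vectorized.
#' @param fit A [fit_happiness()] result.
#' @return The elasticity estimate(s); a warning is issued outside (0, 1\].
#' @examples
#' \dontrun{omega_hat(1, fit)  # = beta1}
#' @export
omega_hat <- function(h, fit) {
  stopifnot(inherits(fit, "happiness_fit"), is.numeric(h))
  if (any(h <= 0) || any(h > 1)) {
    stop("`h` must lie in (0, 1]", call. = FALSE)
  }
  out <- fit$beta1 + fit$beta2 * log(h)
  if (any(out <= 0) || any(out > 1)) {
    warning("estimated omega_h outside (0, 1] at some H", call. = FALSE)
  }
  out
}

#' Estimated elasticity of the QoL elasticity
#'
#' \eqn{\hat\epsilon^\omega(H) = \hat\beta_2 /
#'   (\hat\beta_1 + \hat\beta_2\ln H)}: how fast \eqn{\omega_H} itself
#' changes with `H`.  Zero for all `H` under CRRA.
#'
#' @inheritParams omega_hat
#' @return The elasticity-of-elasticity estimate(s).
#' @export
epsilon_omega_hat <- function(h, fit) {
  stopifnot(inherits(fit, "happiness_fit"), is.numeric(h))
  if (any(h <= 0) || any(h > 1)) {
    stop("`h` must lie in (0, 1]", call. = FALSE)
  }
  den <- fit$beta1 + fit$beta2 * log(h)
  if (any(abs(den) < 1e-12)) {
    stop("omega_hat vanishes at some H: epsilon^omega undefined",
         call. = FALSE)
  }
  fit$beta2 / den
}

#' Estimated relative risk aversion over QoL
#'
#' \eqn{\hat r^*(H) = 1 - \hat\omega_H(H) - \hat\epsilon^\omega(H)}.  Under
#' CRRA this is \eqn{1 - \omega_H}; with `beta2 < 0` (DRRA) it can exceed
#' \eqn{1 - \hat\omega_H} and even 1.
#'
#' @inheritParams omega_hat
#' @return The risk-aversion estimate(s).
#' @export
r_star_hat <- function(h, fit) {
  1 - omega_hat_quiet(h, fit) - epsilon_omega_hat(h, fit)
}

# omega_hat without the range warning, for internal chaining
omega_hat_quiet <- function(h, fit) {
  suppressWarnings(omega_hat(h, fit))
}

#' Estimated elasticity of utility with respect to consumption
#'
#' Mirror of [omega_hat()] on the consumption side:
#' \eqn{\hat\omega_C(C) = \hat\beta_3 + \hat\beta_4\ln C}.
#'
#' @param consumption Consumption level(s), `> 0`.
#' @param fit A [fit_happiness()] result.
#' @return The consumption-elasticity estimate(s).
#' @export
omega_c_hat <- function(consumption, fit) {
  stopifnot(inherits(fit, "happiness_fit"), is.numeric(consumption))
  if (any(consumption <= 0)) {
    stop("`consumption` must be strictly positive", call. = FALSE)
  }
  fit$beta3 + fit$beta4 * log(consumption)
}

#' Classify the risk posture implied by a happiness fit
#'
#' The sign of \eqn{\beta_2} classifies relative risk aversion as
#' decreasing (`beta2 < 0`, DRRA), constant (CRRA) or increasing
#' (`beta2 > 0`, IRRA).  Because a fitted \eqn{\hat\beta_2} is never
#' exactly zero, CRRA is declared when \eqn{\hat\beta_2} is statistically
#' indistinguishable from zero at the given level.
#'
#' @param fit A [fit_happiness()] result.
#' @param level Two-sided significance level for the CRRA zone
#'   (default 0.01).
#' @return One of `"DRRA"`, `"CRRA"`, `"IRRA"`.
#' @export
classify_posture <- function(fit, level = 0.01) {
  stopifnot(inherits(fit, "happiness_fit"))
  z <- fit$beta2 / fit$coef_se["beta2"]
  crit <- stats::qnorm(1 - level / 2)
  if (!is.finite(z) || abs(z) <= crit) "CRRA"
  else if (fit$beta2 < 0) "DRRA"
  else "IRRA"
}

#' Recover the full preference bundle from a happiness fit
#'
#' Chains the estimators: \eqn{\hat\omega_H(H)} and \eqn{\hat r^*(H)} from
#' the fitted slopes, curvature \eqn{\gamma = \hat\omega_H/(\hat r^* +
#' \hat\omega_H)}, and the higher-order parameters from the HARA ladder.
#' Also returns the implied HARA parameters (the shift solves
#' \eqn{r^* = (1-\gamma)H/(H+\eta)}) and delta-method standard errors for
#' \eqn{\hat\omega_H} and \eqn{\hat r^*}.
#'
#' @param h QoL level at which to evaluate the bundle, in (0, 1\].
#' @param fit A [fit_happiness()] result.
#' @return A list with `prefs` (a [risk_prefs()] bundle at `h`), `hara`
#'   (a [hara_params()] object), `gamma` and `se` (named vector with
#'   delta-method standard errors of `omega_h` and `r_star`).
#' @export
recover_full_prefs <- function(h, fit) {
  stopifnot(is.numeric(h), length(h) == 1L)
  om <- omega_hat_quiet(h, fit)
  rs <- r_star_hat(h, fit)
  if (om <= 0 || rs <= 0) {
    stop(sprintf(paste0("cannot recover preferences: omega_hat = %.4g, ",
                        "r_star_hat = %.4g must both be positive at H = %g"),
                 om, rs, h), call. = FALSE)
  }
  g <- gamma_from_elasticity(om, rs)
  prefs <- suppressWarnings(
    risk_prefs(omega_h = om, r_star = rs,
               pi_star = higher_order_pref(2, g, rs),
               tau_star = higher_order_pref(3, g, rs),
               eval_h = h, crra = abs(fit$beta2) < 1e-12)
  )
  eta <- h * (1 - g) / rs - h
  list(prefs = prefs, hara = hara_params(g, eta), gamma = g,
       se = prefs_se(h, fit))
}

# delta-method standard errors of omega_hat(h) and r_star_hat(h)
prefs_se <- function(h, fit) {
  x <- log(h)
  vc <- fit$vcov[c("beta1", "beta2"), c("beta1", "beta2")]
  g_omega <- c(1, x)
  om <- fit$beta1 + fit$beta2 * x
  # r = 1 - (b1 + b2 x) - b2/(b1 + b2 x)
  g_r <- c(-1 + fit$beta2 / om^2,
           -x - 1 / om + fit$beta2 * x / om^2)
  c(omega_h = sqrt(drop(g_omega %*% vc %*% g_omega)),
    r_star = sqrt(drop(g_r %*% vc %*% g_r)))
}

#' Simulate a happiness survey from a known utility
#'
#' Draws QoL from a Beta distribution on (0, 1\] and consumption from a
#' lognormal, then sets \eqn{\ln(Happy)} from the translog model at the
#' true coefficients (or at the exact log-utility of a HARA truth) plus
#' Gaussian noise.  Deterministic given `seed`; used for parameter-recovery
#' and posture-classification experiments.
#'
#' @param n Number of respondents, `>= 1`.
#' @param truth Either a numeric vector `c(beta1, beta2, beta3, beta4)` of
#'   translog coefficients (optionally named, with optional `intercept`),
#'   or a [hara_params()] object, in which case
#'   \eqn{\ln(Happy) = \ln W(H) + \beta_3\ln C} with `beta3 = 1/3`.
#' @param noise_sd Standard deviation of the Gaussian noise on
#'   \eqn{\ln(Happy)}, `>= 0`; default 0.1.
#' @param seed Optional integer seed.
#' @param h_shape Beta shape parameters for the QoL draw; default
#'   `c(2, 2)`.
#' @param c_meanlog,c_sdlog Lognormal parameters for consumption; defaults
#'   `log(50000)` and 0.5.
#' @return A data frame with columns `happy`, `H`, `C` (all positive).
#' @examples
#' s <- simulate_survey(100, truth = c(0.5, 0, 0.33, 0), seed = 42)
#' @export
simulate_survey <- function(n, truth, noise_sd = 0.1, seed = NULL,
                            h_shape = c(2, 2), c_meanlog = log(50000),
                            c_sdlog = 0.5) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(noise_sd), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (any(h_shape <= 0) || c_sdlog < 0) {
    stop("invalid distribution parameters for H or C", call. = FALSE)
  }
  h <- stats::rbeta(n, h_shape[1], h_shape[2])
  h <- pmax(h, 1e-6)  # keep strictly inside (0, 1]
  cons <- stats::rlnorm(n, c_meanlog, c_sdlog)
  if (inherits(truth, "hara_params")) {
    if (truth$eta < 0) h <- pmax(h, -truth$eta + 1e-4)  # keep W(H) > 0
    ln_happy <- log(hara_value(h, truth)) + (1 / 3) * log(cons)
  } else {
    stopifnot(is.numeric(truth), length(truth) >= 4L)
    b <- truth
    if (is.null(names(b))) {
      names(b) <- c("beta1", "beta2", "beta3", "beta4",
                    "intercept")[seq_along(b)]
    }
    icpt <- if ("intercept" %in% names(b)) b[["intercept"]] else 0
    ln_happy <- icpt + b[["beta1"]] * log(h) +
      0.5 * b[["beta2"]] * log(h)^2 +
      b[["beta3"]] * log(cons) + 0.5 * b[["beta4"]] * log(cons)^2
  }
  if (noise_sd > 0) ln_happy <- ln_happy + stats::rnorm(n, 0, noise_sd)
  data.frame(happy = exp(ln_happy), H = h, C = cons)
}
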
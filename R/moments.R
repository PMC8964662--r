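#' Central moments of a trial arm's QoL outcomes
#'
#' Computes the mean, variance, third central moment (skewness times
#' \eqn{\sigma^3}) and fourth-moment excess (excess kurtosis) of a vector
#' of patient-level QoL outcomes.  Population (1/n) central moments are the
#' default, matching the definition of the moment contrasts as plain
#' differences of arm moments; an unbiased-variance option is provided for
#' practice.
#'
#' @param x Numeric vector of QoL outcomes, each in \[0, 1\], length >= 2.
#' @param estimator `"population"` (default) or `"unbiased"`; affects the
#'   variance only (third and fourth moments always use 1/n weights).
#' @return A list with `n`, `mean`, `variance`, `third_central`, `skewness`
#'   (\eqn{\gamma_1}) and `excess_kurtosis` (`NA` for degenerate samples).
#' @examples
#' arm_moments(c(0, 1))$variance   # 0.25 (population convention)
#' @export
arm_moments <- function(x, estimator = c("population", "unbiased")) {
  estimator <- match.arg(estimator)
  stopifnot(is.numeric(x))
  if (length(x) < 2L) {
    stop("at least 2 outcomes per arm are required", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("QoL outcomes must be non-missing and lie in [0, 1]", call. = FALSE)
  }
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  variance <- if (estimator == "unbiased") m2 * n / (n - 1) else m2
  list(n = n,
       mean = m,
       variance = variance,
       third_central = m3,
       skewness = if (m2 > 0) m3 / m2^1.5 else 0,
       excess_kurtosis = if (m2 > 0) m4 / m2^2 - 3 else NA_real_)
}

#' Moment contrast between treatment and control arms
#'
#' Converts patient-level QoL outcomes from a two-arm comparison into the
#' moment contrasts used by the GRACE valuation: the mean incremental gain
#' \eqn{\mu_B}, the variance difference \eqn{\Delta\sigma^2_H}, the
#' third-central-moment (skewness) difference
#' \eqn{\Delta[\gamma_1\sigma^3_H]} and the excess-kurtosis difference
#' (informational only — it enters no valuation formula).  Also derives the
#' loss profile: \eqn{\ell^* = (H_0 - \bar H_C)/H_0} and
#' \eqn{t^* = (H_0 - \bar H_T)/H_0}.
#'
#' @param treat,ctrl Numeric vectors of QoL outcomes for the treatment and
#'   control arms.
#' @param h0 Baseline QoL in (0, 1\]; default 1.
#' @param d_star Permanent-disability loss for the loss profile; default 0.
#' @param estimator Moment convention, see [arm_moments()].
#' @return An object of class `outcome_contrast`; its `loss` element is the
#'   derived [loss_profile()].
#' @examples
#' set.seed(1)
#' oc <- outcome_contrast(treat = rbeta(50, 6, 2), ctrl = rbeta(50, 4, 4))
#' oc$mu_b
#' @export
outcome_contrast <- function(treat, ctrl, h0 = 1, d_star = 0,
                             estimator = c("population", "unbiased")) {
  estimator <- match.arg(estimator)
  mt <- arm_moments(treat, estimator)
  mc <- arm_moments(ctrl, estimator)
  loss <- loss_profile(ell_star = (h0 - mc$mean) / h0,
                       t_star = (h0 - mt$mean) / h0,
                       d_star = d_star, h0 = h0)
  new_outcome_contrast(mu_b = mt$mean - mc$mean,
                       mu_h = mc$mean,
                       delta_var = mt$variance - mc$variance,
                       delta_skew = mt$third_central - mc$third_central,
                       delta_kurt = mt$excess_kurtosis - mc$excess_kurtosis,
                       n_treat = mt$n, n_ctrl = mc$n, loss = loss)
}

#' Moment contrast from summary statistics
#'
#' Builds an `outcome_contrast` directly from published summary moments
#' rather than patient-level data.
#'
#' @param mu_b Mean incremental QoL gain (treatment minus control).
#' @param mu_h Mean untreated sick-state QoL, in (0, 1\].
#' @param delta_var Treatment-minus-control variance difference; default 0.
#' @param delta_skew Treatment-minus-control difference of third central
#'   moments; default 0.
#' @param delta_kurt Optional excess-kurtosis difference (informational).
#' @param n_treat,n_ctrl Optional arm sizes.
#' @param loss Optional [loss_profile()].
#' @return An object of class `outcome_contrast`.
#' @export
moment_contrast <- function(mu_b, mu_h, delta_var = 0, delta_skew = 0,
                            delta_kurt = NA_real_, n_treat = NA_integer_,
                            n_ctrl = NA_integer_, loss = NULL) {
  new_outcome_contrast(mu_b, mu_h, delta_var, delta_skew, delta_kurt,
                       n_treat, n_ctrl, loss)
}

new_outcome_contrast <- function(mu_b, mu_h, delta_var, delta_skew,
                                 delta_kurt, n_treat, n_ctrl, loss) {
  stopifnot(is.numeric(mu_b), is.numeric(mu_h))
  if (!is.finite(mu_h) || mu_h <= 0 || mu_h > 1) {
    stop("`mu_h` must lie in (0, 1]", call. = FALSE)
  }
  if (mu_b < -mu_h) {
    stop("`mu_b` below -mu_h implies negative treated QoL", call. = FALSE)
  }
  structure(list(mu_b = mu_b, mu_h = mu_h, delta_var = delta_var,
                 delta_skew = delta_skew, delta_kurt = delta_kurt,
                 n_treat = n_treat, n_ctrl = n_ctrl, loss = loss),
            class = "outcome_contrast")
}

#' @export
print.outcome_contrast <- function(x, ...) {
  cat("QoL outcome contrast (treatment - control)\n")
  cat(sprintf("  mu_B = %.4g  mu_H = %.4g\n", x$mu_b, x$mu_h))
  cat(sprintf("  delta variance = %.4g  delta skewness (3rd central) = %.4g\n",
              x$delta_var, x$delta_skew))
  if (!is.na(x$delta_kurt)) {
    cat(sprintf("  delta excess kurtosis = %.4g (informational)\n",
                x$delta_kurt))
  }
  if (!is.null(x$loss)) {
    cat(sprintf("  ell* = %.4g  t* = %.4g  d* = %.4g  (H0 = %g)\n",
                x$loss$ell_star, x$loss$t_star, x$loss$d_star, x$loss$h0))
  }
  invisible(x)
}

#' Certainty-equivalence ratio
#'
#' Converts average QoL gains into certainty-equivalent gains using the
#' variance and skewness contrasts:
#' \deqn{\epsilon = 1 + \frac{1}{\mu_B}\left[
#'   -\tfrac12 r^* \frac{\Delta\sigma^2_H}{\mu_H}
#'   + \tfrac16 \pi^* r^* \frac{\Delta[\gamma_1\sigma^3_H]}{\mu_H^2}
#'   \right].}
#' \eqn{\epsilon = 1} when variance and skewness do not differ across arms;
#' variance reductions and positive-skewness increases raise it.  The
#' kurtosis contrast is carried for information but enters no term.
#' Preferences are evaluated at the untreated sick-state mean \eqn{\mu_H}.
#'
#' @param contrast An [outcome_contrast()] or [moment_contrast()].
#' @param prefs A [risk_prefs()] bundle (non-CRRA bundles should be
#'   evaluated at `mu_h`; a mismatch triggers a warning).
#' @return The certainty-equivalence ratio \eqn{\epsilon}.
#' @examples
#' epsilon_ratio(moment_contrast(mu_b = 0.1, mu_h = 0.5, delta_var = -0.01),
#'               crra_prefs(0.5))   # 1.05
#' @export
epsilon_ratio <- function(contrast, prefs) {
  stopifnot(inherits(contrast, "outcome_contrast"),
            inherits(prefs, "risk_prefs"))
  if (contrast$mu_b == 0) {
    stop("epsilon is undefined at mu_b = 0; value variance effects through ",
         "the product mu_b * epsilon in the valuation, which remains finite",
         call. = FALSE)
  }
  if (!prefs$crra && !is.na(prefs$eval_h) &&
      abs(prefs$eval_h - contrast$mu_h) > 1e-6) {
    warning("non-CRRA preferences evaluated at H = ", prefs$eval_h,
            " but mu_h = ", contrast$mu_h,
            "; re-evaluate the bundle at mu_h", call. = FALSE)
  }
  r <- prefs$r_star; p <- prefs$pi_star
  adj <- -0.5 * r * contrast$delta_var / contrast$mu_h +
    (1 / 6) * p * r * contrast$delta_skew / contrast$mu_h^2
  1 + adj / contrast$mu_b
}

# shared Taylor series for the period-1 utility share 1 - omega*(x + ...)
rho_series <- function(x, prefs, order) {
  order <- check_order(order)
  r <- prefs$r_star; p <- prefs$pi_star
  s <- x
  if (order >= 2) s <- s + 0.5 * r * x^2
  if (order >= 3) s <- s + (1 / 6) * r * p * x^3
  rho <- 1 - prefs$omega_h * s
  if (any(rho <= 0)) {
    warning("computed rho <= 0: the Taylor expansion is outside its range ",
            "of validity for these losses", call. = FALSE)
  }
  rho
}

#' Sick-state share of period-1 utility
#'
#' \deqn{\rho_S = 1 - \omega_H\left[t^* + \tfrac12 r^* t^{*2}
#'   + \tfrac16 r^*\pi^* t^{*3}\right],}
#' the treated sick-state expected QoL utility relative to baseline
#' utility.  Health losses are discounted by the elasticity
#' \eqn{\omega_H}, reflecting diminishing returns to QoL.  Preferences are
#' evaluated at baseline QoL.
#'
#' @param t_star Treated relative QoL loss in \[0, 1).
#' @param prefs A [risk_prefs()] bundle.
#' @param order Truncation order, 1 to 3 (default 3).
#' @return The ratio \eqn{\rho_S} in (0, 1\].
#' @examples
#' rho_sick(0.25, crra_prefs(0.5))   # 0.86621 (exact CRRA: 0.86603)
#' @export
rho_sick <- function(t_star, prefs, order = 3) {
  stopifnot(inherits(prefs, "risk_prefs"), is.numeric(t_star))
  if (any(t_star < 0) || any(t_star >= 1)) {
    stop("`t_star` must lie in [0, 1)", call. = FALSE)
  }
  rho_series(t_star, prefs, order)
}

#' Well-state share of period-1 utility
#'
#' \deqn{\rho_W = 1 - \omega_H\left[d^* + \tfrac12 r^* d^{*2}
#'   + \tfrac16 r^*\pi^* d^{*3}\right],}
#' the well-state QoL utility (baseline less any permanent disability)
#' relative to baseline utility; equals 1 when `d_star = 0`.  Identical in
#' form to \eqn{1 - d^*\psi} with \eqn{\psi} the disability ratio.
#'
#' @param d_star Permanent-disability relative loss in \[0, 1).
#' @inheritParams rho_sick
#' @return The ratio \eqn{\rho_W} in (0, 1\].
#' @export
rho_well <- function(d_star, prefs, order = 3) {
  stopifnot(inherits(prefs, "risk_prefs"), is.numeric(d_star))
  if (any(d_star < 0) || any(d_star >= 1)) {
    stop("`d_star` must lie in [0, 1)", call. = FALSE)
  }
  rho_series(d_star, prefs, order)
}

#' Overall period-1 utility share
#'
#' The illness-probability-weighted combination
#' \eqn{\rho = \phi\rho_S + (1-\phi)\rho_W}.
#'
#' @param phi Probability of acute illness in period 1, in \[0, 1\].
#' @param rho_s,rho_w Sick- and well-state shares.
#' @return The combined ratio \eqn{\rho}.
#' @export
rho_total <- function(phi, rho_s, rho_w) {
  stopifnot(is.numeric(phi), is.numeric(rho_s), is.numeric(rho_w))
  if (any(phi < 0) || any(phi > 1)) {
    stop("`phi` must lie in [0, 1]", call. = FALSE)
  }
  phi * rho_s + (1 - phi) * rho_w
}

#' Marginal rate of substitution between life expectancy and QoL
#'
#' \deqn{\delta = \frac{\rho H_0}{\omega_H R},}
#' the QoL-equivalent value of a marginal survival gain.  This closed form
#' removes the need for disease-by-disease estimation of the substitution
#' rate: \eqn{\rho} comes from trial moments and risk preferences alone.
#'
#' @param rho Period-1 utility share from [rho_total()].
#' @param omega_h Elasticity of utility with respect to QoL.
#' @param R Disease-severity ratio.
#' @param h0 Baseline QoL; default 1.
#' @return The substitution rate \eqn{\delta}.
#' @examples
#' mrs_delta(1, omega_h = 0.5, R = 1)   # 2
#' @export
mrs_delta <- function(rho, omega_h, R, h0 = 1) {
  stopifnot(is.numeric(rho), is.numeric(omega_h), is.numeric(R),
            is.numeric(h0))
  if (any(omega_h * R <= 0)) {
    stop("require omega_h * R > 0", call. = FALSE)
  }
  rho * h0 / (omega_h * R)
}

#' Exact marginal rate of substitution by expectation
#'
#' Evaluates the defining ratio
#' \deqn{\delta = \frac{\phi\,E[W(H_{1S}+B)] + (1-\phi)\,W(H_{1W})}
#'   {W'(\mu_H)}}
#' directly for a HARA utility, taking the treated sick-state outcome
#' distribution either as a sample (Monte Carlo) or as a Beta law
#' (adaptive quadrature).  Serves as the oracle for [mrs_delta()].
#'
#' @param utility A [hara_params()] object.
#' @param phi Probability of acute illness in period 1.
#' @param treated Either a numeric vector of treated sick-state QoL
#'   outcomes (a degenerate scalar is allowed) or a
#'   `list(shape1 =, shape2 =)` describing a Beta distribution on (0, 1).
#' @param well Non-stochastic well-state QoL \eqn{H_{1W}}.
#' @param mu_h Mean untreated sick-state QoL at which the marginal utility
#'   denominator is evaluated.
#' @return The substitution rate \eqn{\delta}.
#' @export
delta_exact <- function(utility, phi, treated, well, mu_h) {
  stopifnot(inherits(utility, "hara_params"),
            is.numeric(phi), length(phi) == 1L, phi >= 0, phi <= 1)
  ew <- if (is.numeric(treated)) {
    mean(hara_value(treated, utility))
  } else if (is.list(treated) && all(c("shape1", "shape2") %in% names(treated))) {
    q <- stats::integrate(function(h) {
      stats::dbeta(h, treated$shape1, treated$shape2) * hara_value(h, utility)
    }, lower = 0, upper = 1, rel.tol = 1e-10)
    if (q$message != "OK") {
      stop("quadrature for E[W(H1S + B)] failed: ", q$message, call. = FALSE)
    }
    q$value
  } else {
    stop("`treated` must be a numeric vector or list(shape1=, shape2=)",
         call. = FALSE)
  }
  v <- phi * ew + (1 - phi) * hara_value(well, utility)
  v / hara_marginal(mu_h, utility)
}
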
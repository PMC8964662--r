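#' Economic context for cost-effectiveness thresholds
#'
#' Holds annual consumption and the elasticity of utility with respect to
#' consumption, from which the traditional cost-effectiveness threshold
#' \eqn{K = C/\omega_C} follows.
#'
#' @param consumption Annual consumption `C` (currency), `> 0`.
#' @param omega_c Elasticity of utility with respect to consumption,
#'   strictly in (0, 1).
#' @return An object of class `econ_context` with derived threshold `k`.
#' @examples
#' econ_context(50000, 1/3)   # K = 150,000
#' @export
econ_context <- function(consumption, omega_c) {
  stopifnot(is.numeric(consumption), length(consumption) == 1L,
            is.numeric(omega_c), length(omega_c) == 1L)
  if (!is.finite(consumption) || consumption <= 0) {
    stop("`consumption` must be strictly positive", call. = FALSE)
  }
  if (!is.finite(omega_c) || omega_c <= 0 || omega_c >= 1) {
    stop("`omega_c` must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(consumption = consumption, omega_c = omega_c,
                 k = consumption / omega_c),
            class = "econ_context")
}

#' Relative QoL loss profile
#'
#' Records the relative QoL losses that drive severity and disability
#' adjustments: `ell_star` (untreated loss, including disability), `t_star`
#' (treated loss, including disability) and `d_star` (permanent-disability
#' loss alone), all relative to baseline QoL `h0`.  The losses must be
#' ordered `0 <= d_star <= t_star <= ell_star < 1`: treatment cannot leave
#' patients worse off than no treatment, and the treated loss includes the
#' disability loss.
#'
#' @param ell_star Untreated relative QoL loss in \[0, 1).
#' @param t_star Treated relative QoL loss in \[0, 1); defaults to
#'   `ell_star` (no treatment effect).
#' @param d_star Permanent-disability relative loss in \[0, 1); default 0.
#' @param h0 Baseline QoL in (0, 1\]; default 1.
#' @return An object of class `loss_profile` with derived fields `mu_h`
#'   (mean untreated sick-state QoL) and `h0d` (baseline QoL with
#'   disability).
#' @examples
#' loss_profile(ell_star = 0.5, t_star = 0.25)
#' @export
loss_profile <- function(ell_star, t_star = ell_star, d_star = 0, h0 = 1) {
  stopifnot(is.numeric(ell_star), is.numeric(t_star), is.numeric(d_star),
            is.numeric(h0))
  if (h0 <= 0 || h0 > 1) stop("`h0` must lie in (0, 1]", call. = FALSE)
  for (nm in c("ell_star", "t_star", "d_star")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v >= 1) {
      stop(sprintf("`%s` must lie in [0, 1)", nm), call. = FALSE)
    }
  }
  if (!(d_star <= t_star && t_star <= ell_star)) {
    stop("losses must satisfy 0 <= d_star <= t_star <= ell_star < 1",
         call. = FALSE)
  }
  structure(list(ell_star = ell_star, t_star = t_star, d_star = d_star,
                 h0 = h0, mu_h = h0 * (1 - ell_star), h0d = h0 * (1 - d_star)),
            class = "loss_profile")
}

#' Disease-severity ratio under CRRA utility
#'
#' The exact marginal-utility ratio \eqn{R = W'(\mu_H)/W'(H_0)} for CRRA
#' utility, which reduces to the closed form
#' \eqn{R = (1 - \ell^*)^{-r^*}}.  `R >= 1`, rising with both untreated
#' severity and risk aversion; `R = 1` for risk-neutral consumers
#' (traditional CEA).
#'
#' @param ell_star Untreated relative QoL loss in \[0, 1); vectorized.
#' @param r_star Relative risk aversion, `>= 0`; vectorized.
#' @return The severity ratio `R`.
#' @examples
#' severity_ratio_crra(0.7, 1)     # 3.33
#' severity_ratio_crra(0.5, 0.5)   # 1.41
#' @export
severity_ratio_crra <- function(ell_star, r_star) {
  stopifnot(is.numeric(ell_star), is.numeric(r_star))
  if (any(ell_star < 0) || any(ell_star > 1)) {
    stop("`ell_star` must lie in [0, 1)", call. = FALSE)
  }
  if (any(r_star < 0)) stop("`r_star` must be non-negative", call. = FALSE)
  if (any(ell_star == 1 & r_star > 0)) {
    stop("R is unbounded at ell_star = 1 with r_star > 0", call. = FALSE)
  }
  (1 - ell_star)^(-r_star)
}

#' Disease-severity ratio by Taylor expansion
#'
#' Series form of the severity ratio for general (possibly non-CRRA)
#' preferences:
#' \deqn{R \approx 1 + r^*\ell^* + \tfrac12 r^*\pi^*\ell^{*2}
#'   + \tfrac16 r^*\pi^*\tau^*\ell^{*3},}
#' truncated at `order`.  The truncation error grows quickly with severity;
#' a warning is issued for `ell_star > 0.5`, where the series can fall well
#' short of the exact ratio.
#'
#' @param ell_star Untreated relative QoL loss in \[0, 1).
#' @param prefs A [risk_prefs()] bundle (evaluated at the sick-state QoL
#'   for non-CRRA preferences).
#' @param order Truncation order, 1 to 3 (default 3).
#' @return The approximated severity ratio.
#' @examples
#' severity_ratio_taylor(0.1, crra_prefs(0.5))   # 1.0541 (exact: 1.05409)
#' @export
severity_ratio_taylor <- function(ell_star, prefs, order = 3) {
  stopifnot(inherits(prefs, "risk_prefs"), is.numeric(ell_star))
  if (any(ell_star < 0) || any(ell_star >= 1)) {
    stop("`ell_star` must lie in [0, 1)", call. = FALSE)
  }
  order <- check_order(order)
  if (order >= 2 && is.null(prefs$pi_star)) {
    stop("`pi_star` required for order >= 2", call. = FALSE)
  }
  if (order == 3 && is.null(prefs$tau_star)) {
    stop("`tau_star` required for order 3", call. = FALSE)
  }
  if (any(ell_star > 0.5)) {
    warning("Taylor severity ratio is unreliable for ell_star > 0.5; ",
            "prefer the exact form where available", call. = FALSE)
  }
  r <- prefs$r_star; p <- prefs$pi_star; tau <- prefs$tau_star
  out <- 1 + r * ell_star
  if (order >= 2) out <- out + 0.5 * r * p * ell_star^2
  if (order >= 3) out <- out + (1 / 6) * r * p * tau * ell_star^3
  out
}

#' Exact disease-severity ratio for HARA utility
#'
#' The exact marginal-utility ratio \eqn{R = W'(\mu_H)/W'(H_0)} with
#' \eqn{\mu_H = H_0(1-\ell^*)}, for any simplified HARA utility.  Serves as
#' the oracle against which the Taylor form is checked; reduces to
#' [severity_ratio_crra()] when `eta = 0`.
#'
#' @param loss A [loss_profile()].
#' @param utility A [hara_params()] object.
#' @return The exact severity ratio.
#' @export
severity_ratio_exact <- function(loss, utility) {
  stopifnot(inherits(loss, "loss_profile"), inherits(utility, "hara_params"))
  hara_marginal(loss$mu_h, utility) / hara_marginal(loss$h0, utility)
}

#' Severity-ratio grid
#'
#' Regenerates the CRRA severity-multiplier grid over untreated-loss and
#' risk-aversion values.
#'
#' @param ell_star Untreated-loss grid (rows).
#' @param r_star Risk-aversion grid (columns).
#' @return A matrix of severity ratios.
#' @export
severity_table <- function(ell_star = c(0, 0.1, 0.3, 0.5, 0.7, 0.9),
                           r_star = c(0, 0.25, 0.5, 0.75, 1)) {
  out <- outer(ell_star, r_star, severity_ratio_crra)
  dimnames(out) <- list(paste0("ell=", ell_star), paste0("r=", r_star))
  out
}

#' Disability ratio (series form)
#'
#' The disability ratio \eqn{\psi} satisfies
#' \eqn{W(H_{0d})/W(H_0) = 1 - d^*\psi} and has the expansion
#' \deqn{\psi = \omega_H\left(1 + \tfrac12 r^* d^*
#'   + \tfrac16 r^*\pi^* d^{*2}\right).}
#' Under weak risk aversion \eqn{0 < \psi \le 1}: \eqn{\psi = 1} for
#' risk-neutral consumers and \eqn{\psi < 1} under strict risk aversion.
#' Preferences should be evaluated at baseline QoL `h0`.
#'
#' @param d_star Permanent-disability relative loss in \[0, 1).
#' @param prefs A [risk_prefs()] bundle evaluated at baseline QoL.
#' @param order Truncation order, 1 to 3 (default 3).
#' @return The disability ratio.
#' @examples
#' disability_ratio(0.2, crra_prefs(0.5))   # 0.5275
#' @export
disability_ratio <- function(d_star, prefs, order = 3) {
  stopifnot(inherits(prefs, "risk_prefs"), is.numeric(d_star))
  if (any(d_star < 0) || any(d_star >= 1)) {
    stop("`d_star` must lie in [0, 1)", call. = FALSE)
  }
  order <- check_order(order)
  r <- prefs$r_star; p <- prefs$pi_star
  fac <- 1
  if (order >= 2) fac <- fac + 0.5 * r * d_star
  if (order >= 3) fac <- fac + (1 / 6) * r * p * d_star^2
  psi <- prefs$omega_h * fac
  if (any(psi > 1 + 1e-12)) {
    warning("computed psi > 1, violating the weak-risk-aversion bound; ",
            "check that the preference inputs are mutually consistent",
            call. = FALSE)
  }
  psi
}

#' Exact disability ratio for HARA utility
#'
#' Computes \eqn{\psi} from its defining relation
#' \eqn{W(H_{0d})/W(H_0) = 1 - d^*\psi}, i.e. as the ratio of the average
#' slope of `W` between \eqn{H_{0d}} and \eqn{H_0} to the average slope
#' between 0 and \eqn{H_0}.  The slope-ratio reading requires the
#' convention \eqn{W(0) = 0}, which holds for the simplified HARA family
#' only when `eta >= 0`; `eta < 0` is rejected.
#'
#' @param d_star Permanent-disability relative loss in (0, 1).
#' @param h0 Baseline QoL in (0, 1\].
#' @param utility A [hara_params()] object with `eta >= 0`.
#' @return The exact disability ratio.
#' @examples
#' disability_ratio_exact(0.2, 1, hara_params(0.5))   # 0.52786
#' @export
disability_ratio_exact <- function(d_star, h0 = 1, utility) {
  stopifnot(inherits(utility, "hara_params"),
            is.numeric(d_star), length(d_star) == 1L)
  if (utility$eta < 0) {
    stop("the exact disability ratio presumes W(0) = 0, which fails for ",
         "eta < 0; no closed form is available in that regime",
         call. = FALSE)
  }
  if (d_star <= 0 || d_star >= 1) {
    stop("`d_star` must lie strictly in (0, 1); the d* -> 0 limit is ",
         "omega_h at h0", call. = FALSE)
  }
  h0d <- h0 * (1 - d_star)
  w0 <- hara_value(h0, utility)
  wd <- hara_value(h0d, utility)
  ((w0 - wd) / (h0 - h0d)) / (w0 / h0)
}

#' Traditional cost-effectiveness threshold
#'
#' \eqn{K = C/\omega_C}, the willingness to pay per QALY under traditional
#' CEA.
#'
#' @param econ An [econ_context()].
#' @return The threshold `K` (currency per QALY).
#' @examples
#' k_traditional(econ_context(50000, 1/3))   # 150,000
#' @export
k_traditional <- function(econ) {
  stopifnot(inherits(econ, "econ_context"))
  econ$k
}

#' Severity- and disability-adjusted willingness-to-pay threshold
#'
#' The GRACE threshold
#' \deqn{K_{GRACE} = \frac{K\,\omega_H\,R}{H_0\,(1 - d^*\psi)},}
#' the willingness to pay per generalized risk-adjusted QALY.  With
#' `omega_h = 1`, `R = 1`, `d_star = 0` and `h0 = 1` it reduces to the
#' traditional threshold `k`.
#'
#' @param k Traditional threshold (currency per QALY).
#' @param omega_h Elasticity of utility with respect to QoL.
#' @param R Disease-severity ratio.
#' @param h0 Baseline QoL; default 1.
#' @param d_star Permanent-disability loss; default 0.
#' @param psi Disability ratio; default 1 (irrelevant when `d_star = 0`).
#' @return The threshold (currency per GRA-QALY).
#' @examples
#' k_grace(150000, omega_h = 0.5, R = 1)   # 75,000
#' @export
k_grace <- function(k, omega_h, R, h0 = 1, d_star = 0, psi = 1) {
  stopifnot(is.numeric(k), is.numeric(omega_h), is.numeric(R),
            is.numeric(h0), is.numeric(d_star), is.numeric(psi))
  denom <- 1 - d_star * psi
  if (any(denom <= 0)) {
    stop("require 1 - d_star * psi > 0 for a well-defined threshold",
         call. = FALSE)
  }
  k * omega_h * R / (h0 * denom)
}

#' Does disability leave willingness to pay for life extension unchanged?
#'
#' Under CRRA utility, permanent disability weakly increases the WTP for
#' life-extension if and only if
#' \eqn{\partial t^*/\partial d^* \le (1 - t^*)/(1 - d^*)}.  The condition
#' always holds for curative therapies (`t_star = d_star` with unit
#' sensitivity); for imperfect therapies it is non-trivial.
#'
#' @param t_star Treated relative QoL loss in \[0, 1).
#' @param d_star Permanent-disability loss in \[0, 1).
#' @param dt_dd Sensitivity \eqn{\partial t^*/\partial d^*} (user-supplied;
#'   no estimator is provided).
#' @return A list with `satisfied` (logical), `margin`
#'   (`(1 - t*)/(1 - d*) - dt_dd`; non-negative iff satisfied) and `bound`.
#' @examples
#' disability_le_condition(0.5, 0.2, 0.5)   # satisfied, margin 0.125
#' @export
disability_le_condition <- function(t_star, d_star, dt_dd) {
  stopifnot(is.numeric(t_star), is.numeric(d_star), is.numeric(dt_dd))
  if (any(t_star < 0) || any(t_star >= 1) || any(d_star < 0) ||
      any(d_star >= 1)) {
    stop("`t_star` and `d_star` must lie in [0, 1)", call. = FALSE)
  }
  bound <- (1 - t_star) / (1 - d_star)
  margin <- bound - dt_dd
  list(satisfied = margin >= 0, margin = margin, bound = bound)
}

# shared validation of Taylor truncation orders
check_order <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || !(order %in% 1:3)) {
    stop("`order` must be 1, 2 or 3", call. = FALSE)
  }
  as.integer(order)
}
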
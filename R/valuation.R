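#' Generalized risk-adjusted QALY gain
#'
#' \deqn{\mathrm{GRA\text{-}QALY} = \mu_p\delta + \phi p_1 \mu_B \epsilon:}
#' survival gains valued at the substitution rate \eqn{\delta} plus
#' certainty-equivalent QoL gains.
#'
#' @param mu_p Expected gain in survival probability from treatment.
#' @param delta Marginal rate of substitution between life expectancy and
#'   QoL, from [mrs_delta()].
#' @param phi Probability of acute illness in period 1.
#' @param p1 Probability of survival into period 1.
#' @param mu_b Mean incremental QoL gain.
#' @param epsilon Certainty-equivalence ratio; default 1.
#' @return The GRA-QALY gain (QoL-equivalent units).
#' @examples
#' gra_qaly(0.1, 2, 0.5, 0.9, 0.2, 1.025)   # 0.29225
#' @export
gra_qaly <- function(mu_p, delta, phi, p1, mu_b, epsilon = 1) {
  stopifnot(is.numeric(mu_p), is.numeric(delta), is.numeric(phi),
            is.numeric(p1), is.numeric(mu_b), is.numeric(epsilon))
  if (any(phi < 0) || any(phi > 1) || any(p1 < 0) || any(p1 > 1)) {
    stop("`phi` and `p1` must lie in [0, 1]", call. = FALSE)
  }
  if (any(p1 + mu_p > 1 + 1e-12) || any(p1 + mu_p < 0)) {
    stop("post-gain survival p1 + mu_p must lie in [0, 1]", call. = FALSE)
  }
  mu_p * delta + phi * p1 * mu_b * epsilon
}

#' Total value of a medical intervention
#'
#' The monetary value of an intervention: the severity- and
#' disability-adjusted threshold times the GRA-QALY gain.
#'
#' @param k_grace Threshold from [k_grace()] (currency per GRA-QALY).
#' @param gra_qaly GRA-QALY gain from [gra_qaly()].
#' @return Monetary value (input currency units).
#' @export
tvmi <- function(k_grace, gra_qaly) {
  stopifnot(is.numeric(k_grace), is.numeric(gra_qaly))
  k_grace * gra_qaly
}

#' Total value of a medical intervention, substitution-free form
#'
#' Equivalent formulation that prices the survival gain through the
#' period-1 utility share \eqn{\rho} instead of \eqn{\delta}:
#' \deqn{\mathrm{TVMI} = \frac{K\left[\mu_p\rho H_0
#'   + \phi p_1 \omega_H R \mu_B \epsilon\right]}{H_0(1 - d^*\psi)}.}
#' Agrees with [tvmi()] exactly because \eqn{\omega_H R \delta = \rho H_0}.
#'
#' @param k Traditional threshold `K`.
#' @param mu_p Expected survival-probability gain.
#' @param rho Period-1 utility share.
#' @param phi Illness probability.
#' @param p1 Survival probability into period 1.
#' @param omega_h Elasticity of utility with respect to QoL.
#' @param R Disease-severity ratio.
#' @param mu_b Mean incremental QoL gain.
#' @param epsilon Certainty-equivalence ratio; default 1.
#' @param h0 Baseline QoL; default 1.
#' @param d_star Permanent-disability loss; default 0.
#' @param psi Disability ratio; default 1.
#' @return Monetary value (input currency units).
#' @export
tvmi_alt <- function(k, mu_p, rho, phi, p1, omega_h, R, mu_b, epsilon = 1,
                     h0 = 1, d_star = 0, psi = 1) {
  denom <- h0 * (1 - d_star * psi)
  if (any(denom <= 0)) {
    stop("require H0 * (1 - d_star * psi) > 0", call. = FALSE)
  }
  k * (mu_p * rho * h0 + phi * p1 * omega_h * R * mu_b * epsilon) / denom
}

#' Static cost-effectiveness decision
#'
#' The incremental generalized risk-adjusted cost-effectiveness ratio
#' \eqn{\Delta C / \mathrm{GRA\text{-}QALY}} and the adopt decision
#' (adopt iff the ratio does not exceed the threshold, with adoption at
#' equality).  With a non-positive GRA-QALY gain the ratio is not reported
#' (its sign is ambiguous); the decision falls back to the sign of the net
#' monetary benefit, which reproduces the dominance guidance: at zero
#' benefit, adopt iff the incremental cost is negative.
#'
#' @param delta_c Incremental cost (currency).
#' @param gra_qaly GRA-QALY gain.
#' @param k_grace Threshold (currency per GRA-QALY).
#' @return A list with `ratio` (`NA` under dominance), `threshold`, `nmb`
#'   (net monetary benefit `k_grace * gra_qaly - delta_c`), `adopt` and
#'   `dominance` (logical: was the decision made without a ratio).
#' @examples
#' igracer_static(21918.75, 0.29225, 75000)$adopt   # TRUE (boundary)
#' @export
igracer_static <- function(delta_c, gra_qaly, k_grace) {
  stopifnot(is.numeric(delta_c), is.numeric(gra_qaly), is.numeric(k_grace))
  nmb <- k_grace * gra_qaly - delta_c
  if (gra_qaly > 0) {
    ratio <- delta_c / gra_qaly
    list(ratio = ratio, threshold = k_grace, nmb = nmb,
         adopt = ratio <= k_grace, dominance = FALSE)
  } else {
    warning("non-positive GRA-QALY gain: no finite cost-effectiveness ",
            "ratio; deciding by dominance (negative incremental cost ",
            "adopts, positive rejects)", call. = FALSE)
    list(ratio = NA_real_, threshold = k_grace, nmb = nmb,
         adopt = nmb >= 0, dominance = TRUE)
  }
}

#' Cumulative survival path
#'
#' Cumulative post-treatment survival \eqn{\Pi_n = \prod_{k\le n} p_k}
#' (with \eqn{\Pi_0 = 1} implicit).
#'
#' @param p Vector of per-period survival probabilities, each in \[0, 1\].
#' @return Vector \eqn{(\Pi_1, \ldots, \Pi_N)}, nonincreasing.
#' @examples
#' survival_path(c(0.9, 0.8))   # 0.90 0.72
#' @export
survival_path <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0) || any(p > 1)) {
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  cumprod(p)
}

#' Per-period parameters for multi-period valuation
#'
#' Collects the period-by-period inputs of the dynamic net monetary
#' benefit: QoL gains, certainty-equivalence and substitution rates,
#' severity ratios, survival gains and levels, and incremental costs, plus
#' the scalars shared across periods (illness probability `phi`, one-period
#' discount factor `beta`, and the period-zero cost).  Scalar inputs are
#' recycled to the common horizon length.
#'
#' @param mu_b Mean incremental QoL gain per period.
#' @param epsilon Certainty-equivalence ratio per period; default 1.
#' @param delta Substitution rate per period.
#' @param R Disease-severity ratio per period; default 1.
#' @param mu_p Survival-probability gain per period.
#' @param p Post-treatment survival probability per period.
#' @param delta_c Incremental cost per period; default 0.
#' @param phi Illness probability (constant across periods).
#' @param beta One-period discount factor in (0, 1\]; default 1.  Use
#'   [discount_factor()] to convert an annual rate.
#' @param delta_c0 Period-zero incremental cost; default 0.
#' @return An object of class `period_params` with horizon `n_periods`.
#' @export
period_params <- function(mu_b, epsilon = 1, delta, R = 1, mu_p, p,
                          delta_c = 0, phi, beta = 1, delta_c0 = 0) {
  arrays <- list(mu_b = mu_b, epsilon = epsilon, delta = delta, R = R,
                 mu_p = mu_p, p = p, delta_c = delta_c)
  lens <- lengths(arrays)
  n <- max(lens)
  if (!all(lens == 1L | lens == n)) {
    stop("per-period inputs must have length 1 or the common horizon ",
         "length ", n, call. = FALSE)
  }
  arrays <- lapply(arrays, rep_len, n)
  stopifnot(is.numeric(phi), length(phi) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(delta_c0), length(delta_c0) == 1L)
  if (phi < 0 || phi > 1) stop("`phi` must lie in [0, 1]", call. = FALSE)
  if (beta <= 0 || beta > 1) stop("`beta` must lie in (0, 1]", call. = FALSE)
  if (any(arrays$p < 0) || any(arrays$p > 1)) {
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(c(arrays, list(phi = phi, beta = beta, delta_c0 = delta_c0,
                           n_periods = n)),
            class = "period_params")
}

#' Convert an annual discount rate to a one-period factor
#'
#' @param rate Annual discount rate (e.g. 0.03).
#' @return The discount factor \eqn{\beta = 1/(1+rate)}.
#' @export
discount_factor <- function(rate) {
  stopifnot(is.numeric(rate), all(rate > -1))
  1 / (1 + rate)
}

# discounted per-period building blocks shared by the dynamic NMB and ratio
period_components <- function(periods) {
  n <- seq_len(periods$n_periods)
  pi_prev <- c(1, survival_path(periods$p))[n]     # Pi_{n-1}
  disc <- periods$beta^n * pi_prev
  gain <- periods$mu_p * periods$delta +
    periods$phi * periods$p * periods$mu_b * periods$epsilon
  cost <- periods$p * periods$delta_c
  list(disc = disc, gain = gain, cost = cost)
}

#' Multi-period net monetary benefit
#'
#' Net monetary benefit in period-zero currency:
#' \deqn{\mathrm{NMB}_0 = \sum_{n=1}^N \beta^n \Pi_{n-1}\left\{
#'   \frac{K\omega_H R_n}{H_0(1-d^*\psi)}
#'   \left[\mu_{pn}\delta_n + \phi p_n \mu_{Bn}\epsilon_n\right]
#'   - p_n\Delta C_n\right\} - \Delta C_0.}
#'
#' @param periods A [period_params()] object.
#' @param k Traditional threshold `K`.
#' @param omega_h Elasticity of utility with respect to QoL.
#' @param h0 Baseline QoL; default 1.
#' @param d_star Permanent-disability loss; default 0.
#' @param psi Disability ratio; default 1.
#' @return The net monetary benefit (scalar, currency), with the per-period
#'   discounted contributions attached as attribute `"periods"`.
#' @export
nmb_dynamic <- function(periods, k, omega_h, h0 = 1, d_star = 0, psi = 1) {
  stopifnot(inherits(periods, "period_params"))
  kg <- k_grace(k, omega_h, periods$R, h0 = h0, d_star = d_star, psi = psi)
  comp <- period_components(periods)
  contrib <- comp$disc * (kg * comp$gain - comp$cost)
  out <- sum(contrib) - periods$delta_c0
  attr(out, "periods") <- data.frame(period = seq_along(contrib),
                                     contribution = contrib)
  out
}

#' Net monetary benefit under stationary outcomes
#'
#' Geometric-series form when the QoL outcome distribution, survival and
#' costs repeat every period:
#' \deqn{\mathrm{NMB} = \beta\frac{1-(\beta p)^N}{1-\beta p}\,
#'   K_{GRACE}\left[\mu_p\delta + \phi p \mu_B\epsilon\right]
#'   - \left[\Delta C_0 + \sum_{n=1}^N (\beta p)^n \Delta C_n\right].}
#' At \eqn{\beta p = 1} the horizon factor takes its limit \eqn{N\beta}.
#' Identical to [nmb_dynamic()] with constant per-period arrays.
#'
#' @param k_grace Threshold from [k_grace()].
#' @param mu_p,delta,phi,p,mu_b,epsilon Stationary per-period parameters.
#' @param delta_c Constant per-period incremental cost; default 0.
#' @param delta_c0 Period-zero incremental cost; default 0.
#' @param n_periods Horizon `N >= 1`.
#' @param beta One-period discount factor in (0, 1\]; default 1.
#' @return The net monetary benefit (currency).
#' @export
nmb_stationary <- function(k_grace, mu_p, delta, phi, p, mu_b, epsilon = 1,
                           delta_c = 0, delta_c0 = 0, n_periods, beta = 1) {
  stopifnot(is.numeric(n_periods), length(n_periods) == 1L, n_periods >= 1,
            n_periods == round(n_periods))
  if (beta <= 0 || beta > 1) stop("`beta` must lie in (0, 1]", call. = FALSE)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  bp <- beta * p
  horizon <- if (abs(1 - bp) < 1e-12) beta * n_periods else
    beta * (1 - bp^n_periods) / (1 - bp)
  value <- horizon * k_grace * (mu_p * delta + phi * p * mu_b * epsilon)
  costs <- delta_c0 + delta_c * sum(bp^seq_len(n_periods))
  value - costs
}

#' Multi-period cost-effectiveness decision
#'
#' The dynamic incremental generalized risk-adjusted cost-effectiveness
#' ratio: discounted incremental costs over discounted GRA-QALY gains, with
#' the severity profile normalized to period `j`, compared against the
#' threshold \eqn{K R_j \omega_H / (H_0(1-\psi d^*))}.  The adopt decision
#' is invariant to the choice of `j` (both sides scale with \eqn{R_j}) and
#' agrees with the sign of [nmb_dynamic()].  With a non-positive
#' denominator the ratio is suppressed and the decision falls back to the
#' net-monetary-benefit sign, as in [igracer_static()].
#'
#' @inheritParams nmb_dynamic
#' @param j Normalization period in `1..N`; default 1.
#' @return A list with `ratio`, `threshold`, `nmb`, `adopt`, `dominance`
#'   and `j`.
#' @export
igracer_dynamic <- function(periods, k, omega_h, h0 = 1, d_star = 0,
                            psi = 1, j = 1) {
  stopifnot(inherits(periods, "period_params"))
  if (!(j %in% seq_len(periods$n_periods))) {
    stop("`j` must be a period index in 1..N", call. = FALSE)
  }
  r_j <- periods$R[j]
  if (r_j <= 0) stop("R_j must be strictly positive", call. = FALSE)
  comp <- period_components(periods)
  num <- periods$delta_c0 + sum(comp$disc * comp$cost)
  den <- sum(comp$disc * (periods$R / r_j) * comp$gain)
  threshold <- k_grace(k, omega_h, r_j, h0 = h0, d_star = d_star, psi = psi)
  nmb <- as.numeric(nmb_dynamic(periods, k, omega_h, h0 = h0,
                                d_star = d_star, psi = psi))
  if (den > 0) {
    ratio <- num / den
    list(ratio = ratio, threshold = threshold, nmb = nmb,
         adopt = ratio <= threshold, dominance = FALSE, j = j)
  } else {
    warning("non-positive discounted GRA-QALY denominator: deciding by ",
            "dominance (net monetary benefit sign)", call. = FALSE)
    list(ratio = NA_real_, threshold = threshold, nmb = nmb,
         adopt = nmb >= 0, dominance = TRUE, j = j)
  }
}
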
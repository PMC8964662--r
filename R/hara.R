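#' Simplified HARA utility parameters
#'
#' Constructs the parameter pair of the simplified hyperbolic absolute risk
#' aversion (HARA) utility over health-related quality of life (QoL),
#' \deqn{W(H) = \frac{1-\gamma}{\gamma} (H + \eta)^\gamma,}
#' with the scale constant fixed so that the family is indexed by curvature
#' `gamma` and shift `eta` alone.  `eta = 0` gives constant relative risk
#' aversion (CRRA); `eta > 0` gives increasing relative risk aversion (IRRA)
#' and `eta < 0` decreasing relative risk aversion (DRRA).
#'
#' @param gamma Curvature parameter, strictly in (0, 1).
#' @param eta Shift parameter in QoL units; may be negative.  The utility is
#'   defined only where `H + eta >= 0`.
#' @return An object of class `hara_params`.
#' @examples
#' crra <- hara_params(gamma = 0.5)       # CRRA with r* = 0.5
#' drra <- hara_params(0.5, eta = -0.25)  # DRRA
#' @seealso [hara_value()], [hara_prefs_at()]
#' @export
hara_params <- function(gamma, eta = 0) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L,
            is.numeric(eta), length(eta) == 1L, is.finite(eta))
  if (!is.finite(gamma) || gamma <= 0 || gamma >= 1) {
    stop("`gamma` must lie strictly in (0, 1); the risk-neutral and ",
         "logarithmic boundaries are not members of this family ",
         "(use crra_prefs() for the risk-neutral preference bundle)",
         call. = FALSE)
  }
  structure(list(gamma = gamma, eta = eta), class = "hara_params")
}

#' @export
print.hara_params <- function(x, ...) {
  cat(sprintf("Simplified HARA utility: gamma = %g, eta = %g (%s)\n",
              x$gamma, x$eta,
              if (x$eta == 0) "CRRA" else if (x$eta > 0) "IRRA" else "DRRA"))
  invisible(x)
}

#' Evaluate simplified HARA utility
#'
#' Computes \eqn{W(H) = ((1-\gamma)/\gamma)(H+\eta)^\gamma}, with the
#' boundary convention \eqn{W(H) = 0} when \eqn{H + \eta = 0}.
#'
#' @param h QoL level(s) in \[0, 1\]; vectorized.
#' @param params A [hara_params()] object.
#' @return Utility value(s), dimensionless.
#' @examples
#' hara_value(1, hara_params(0.5))     # 1
#' hara_value(0.25, hara_params(0.5))  # 0.5
#' @export
hara_value <- function(h, params) {
  stopifnot(inherits(params, "hara_params"), is.numeric(h))
  z <- h + params$eta
  if (any(z < 0)) {
    stop("HARA utility undefined: H + eta < 0 for some inputs", call. = FALSE)
  }
  g <- params$gamma
  out <- ((1 - g) / g) * z^g
  out[z == 0] <- 0
  out
}

#' Marginal simplified HARA utility
#'
#' Computes \eqn{W'(H) = (1-\gamma)(H+\eta)^{\gamma-1}}, the marginal utility
#' of QoL.  Used by the exact severity ratio and the exact marginal rate of
#' substitution.
#'
#' @inheritParams hara_value
#' @return Marginal utility value(s).
#' @export
hara_marginal <- function(h, params) {
  stopifnot(inherits(params, "hara_params"), is.numeric(h))
  z <- h + params$eta
  if (any(z <= 0)) {
    stop("marginal HARA utility undefined: H + eta <= 0 for some inputs",
         call. = FALSE)
  }
  (1 - params$gamma) * z^(params$gamma - 1)
}

#' Relative risk-preference bundle
#'
#' Bundles the relative risk-preference parameters over QoL used throughout
#' the GRACE framework: the elasticity of utility with respect to QoL
#' (`omega_h`), relative risk aversion (`r_star`), relative prudence
#' (`pi_star`), and optionally relative temperance (`tau_star`), together
#' with the QoL level at which they are evaluated.  When `pi_star` (or
#' `tau_star`) is omitted and `r_star > 0`, the missing higher-order
#' parameters are completed through the HARA relations
#' \eqn{\zeta_j^* = ((j-\gamma)/(1-\gamma)) r^*} with
#' \eqn{\gamma = \omega_H/(r^* + \omega_H)}; under CRRA these reduce to
#' \eqn{\pi^* = 1 + r^*} and \eqn{\tau^* = 2 + r^*}.
#'
#' @param omega_h Elasticity of utility with respect to QoL, in (0, 1\].
#'   Values above 1 (possible under DRRA utility) trigger a warning, not an
#'   error.
#' @param r_star Relative risk aversion, `>= 0`.
#' @param pi_star Relative prudence, `>= 0`; completed from HARA if `NULL`.
#' @param tau_star Relative temperance, `>= 0`; completed from HARA if `NULL`.
#' @param eval_h QoL level at which the parameters are evaluated (`NA` if
#'   not tied to a level, e.g. under CRRA where they are constant).
#' @param crra Logical; `TRUE` if the bundle comes from a CRRA utility.  If
#'   `NULL`, inferred from `omega_h + r_star == 1` (within 1e-8).
#' @return An object of class `risk_prefs`.
#' @examples
#' risk_prefs(omega_h = 0.5, r_star = 0.5)   # CRRA: pi* = 1.5, tau* = 2.5
#' @export
risk_prefs <- function(omega_h, r_star, pi_star = NULL, tau_star = NULL,
                       eval_h = NA_real_, crra = NULL) {
  stopifnot(is.numeric(omega_h), length(omega_h) == 1L,
            is.numeric(r_star), length(r_star) == 1L)
  if (!is.finite(omega_h) || omega_h <= 0) {
    stop("`omega_h` must be strictly positive", call. = FALSE)
  }
  if (omega_h > 1) {
    warning("`omega_h` exceeds 1; this lies outside the usual (0, 1] range ",
            "and can arise only for strongly DRRA utility", call. = FALSE)
  }
  if (!is.finite(r_star) || r_star < 0) {
    stop("`r_star` must be non-negative", call. = FALSE)
  }
  if (is.null(crra)) crra <- abs(omega_h + r_star - 1) < 1e-8
  if (is.null(pi_star)) {
    pi_star <- if (r_star > 0) {
      higher_order_pref(2, gamma_from_elasticity(omega_h, r_star), r_star)
    } else {
      1 + r_star  # risk-neutral limit: CRRA ladder (inert wherever multiplied by r*)
    }
  }
  if (is.null(tau_star)) {
    tau_star <- if (r_star > 0) {
      higher_order_pref(3, gamma_from_elasticity(omega_h, r_star), r_star)
    } else {
      2 + r_star
    }
  }
  if (pi_star < 0 || tau_star < 0) {
    stop("`pi_star` and `tau_star` must be non-negative", call. = FALSE)
  }
  structure(list(omega_h = omega_h, r_star = r_star, pi_star = pi_star,
                 tau_star = tau_star, eval_h = eval_h, crra = isTRUE(crra)),
            class = "risk_prefs")
}

#' @export
print.risk_prefs <- function(x, ...) {
  cat("Relative risk preferences over QoL",
      if (x$crra) "(CRRA)" else "(non-CRRA)", "\n")
  cat(sprintf("  omega_h = %.4g, r* = %.4g, pi* = %.4g, tau* = %.4g\n",
              x$omega_h, x$r_star, x$pi_star, x$tau_star))
  if (!is.na(x$eval_h)) cat(sprintf("  evaluated at H = %.4g\n", x$eval_h))
  invisible(x)
}

#' Risk-preference parameters of a HARA utility at a QoL level
#'
#' Evaluates the closed-form relative risk-preference parameters of the
#' simplified HARA utility at QoL level `h`:
#' \eqn{r^* = (1-\gamma) H/Z}, \eqn{\omega_H = \gamma H/Z},
#' \eqn{\pi^* = (2-\gamma) H/Z}, \eqn{\tau^* = (3-\gamma) H/Z}, with
#' \eqn{Z = H + \eta}.  Under CRRA (`eta = 0`) the parameters are constant in
#' `h`.
#'
#' @param h QoL level, strictly positive, with `h + eta > 0`.
#' @param params A [hara_params()] object.
#' @return A [risk_prefs()] bundle evaluated at `h`.
#' @examples
#' hara_prefs_at(0.5, hara_params(0.5))              # CRRA: r* = 0.5
#' hara_prefs_at(0.5, hara_params(0.5, eta = -0.25)) # DRRA: r* = 1
#' @export
hara_prefs_at <- function(h, params) {
  stopifnot(inherits(params, "hara_params"),
            is.numeric(h), length(h) == 1L)
  z <- h + params$eta
  if (h <= 0 || z <= 0) {
    stop("risk preferences undefined: require H > 0 and H + eta > 0",
         call. = FALSE)
  }
  g <- params$gamma
  hz <- h / z
  suppressWarnings(  # omega_h > 1 is legitimate here for eta < 0
    risk_prefs(omega_h = g * hz, r_star = (1 - g) * hz,
               pi_star = (2 - g) * hz, tau_star = (3 - g) * hz,
               eval_h = h, crra = params$eta == 0)
  )
}

#' Recover HARA curvature from elasticity and risk aversion
#'
#' Inverts the HARA relations \eqn{r^*/\omega_H = (1-\gamma)/\gamma} to give
#' \eqn{\gamma = \omega_H / (r^* + \omega_H)}, which lies strictly in (0, 1)
#' for positive inputs.
#'
#' @param omega_h Elasticity of utility with respect to QoL, `> 0`.
#' @param r_star Relative risk aversion, `> 0`.
#' @return The curvature `gamma`.
#' @examples
#' gamma_from_elasticity(0.5, 0.5)   # 0.5
#' @export
gamma_from_elasticity <- function(omega_h, r_star) {
  stopifnot(is.numeric(omega_h), is.numeric(r_star))
  if (any(omega_h <= 0) || any(r_star <= 0)) {
    stop("`omega_h` and `r_star` must both be strictly positive to recover ",
         "`gamma`", call. = FALSE)
  }
  omega_h / (r_star + omega_h)
}

#' Recover HARA curvature from discrete-choice estimates
#'
#' Given relative risk aversion and relative prudence (e.g. estimated by
#' discrete choice experiments), recovers the HARA curvature
#' \eqn{\gamma = (\pi^* - 2 r^*) / (\pi^* - r^*)}.
#'
#' @param r_star Relative risk aversion, `> 0`.
#' @param pi_star Relative prudence, must exceed `r_star`.
#' @return The curvature `gamma`.  A value of exactly 0 (when
#'   `pi_star = 2 * r_star`) sits on the logarithmic boundary of the family
#'   and is returned with a warning; negative values indicate a pair outside
#'   the HARA family and error.
#' @examples
#' gamma_from_dce(0.5, 1.5)   # 0.5 (CRRA-consistent pair)
#' @export
gamma_from_dce <- function(r_star, pi_star) {
  stopifnot(is.numeric(r_star), length(r_star) == 1L,
            is.numeric(pi_star), length(pi_star) == 1L)
  if (!(r_star > 0) || pi_star <= r_star) {
    stop("require pi_star > r_star > 0 to recover `gamma`", call. = FALSE)
  }
  g <- (pi_star - 2 * r_star) / (pi_star - r_star)
  if (g < 0) {
    stop("(r_star, pi_star) imply gamma < 0, outside the simplified HARA ",
         "family", call. = FALSE)
  }
  if (g == 0) {
    warning("recovered gamma = 0 lies on the (non-strict) boundary of the ",
            "family", call. = FALSE)
  }
  g
}

#' j-th order relative risk-preference parameter under HARA
#'
#' Computes \eqn{\zeta_j^* = ((j - \gamma)/(1 - \gamma)) r^*}.  The first
#' three orders are relative risk aversion (`j = 1`), relative prudence
#' (`j = 2`), and relative temperance (`j = 3`).
#'
#' @param j Order, integer `>= 1`.
#' @param gamma HARA curvature in \[0, 1).
#' @param r_star Relative risk aversion, `>= 0`.
#' @return The parameter \eqn{\zeta_j^*}.
#' @examples
#' higher_order_pref(2, 0.5, 0.5)   # relative prudence 1.5
#' @export
higher_order_pref <- function(j, gamma, r_star) {
  stopifnot(is.numeric(j), is.numeric(gamma), is.numeric(r_star))
  if (any(j < 1) || any(j != round(j))) {
    stop("`j` must be an integer >= 1", call. = FALSE)
  }
  if (any(gamma < 0) || any(gamma >= 1)) {
    stop("`gamma` must lie in [0, 1); the relation degenerates at gamma = 1",
         call. = FALSE)
  }
  if (any(r_star < 0)) stop("`r_star` must be non-negative", call. = FALSE)
  ((j - gamma) / (1 - gamma)) * r_star
}

#' CRRA risk-preference bundle
#'
#' Builds the full preference bundle implied by constant relative risk
#' aversion: \eqn{\omega_H = 1 - r^*}, \eqn{\pi^* = 1 + r^*},
#' \eqn{\tau^* = 2 + r^*} (generally \eqn{\zeta_j^* = (j - 1) + r^*}).
#'
#' @param r_star Relative risk aversion in \[0, 1).  Values `>= 1` are
#'   rejected because CRRA ties `omega_h = 1 - r_star`, which must remain
#'   positive.
#' @return A [risk_prefs()] bundle with `crra = TRUE`.
#' @examples
#' crra_prefs(0.5)   # omega_h = 0.5, pi* = 1.5, tau* = 2.5
#' crra_prefs(0)     # risk-neutral: omega_h = 1 (traditional CEA)
#' @export
crra_prefs <- function(r_star) {
  stopifnot(is.numeric(r_star), length(r_star) == 1L)
  if (!is.finite(r_star) || r_star < 0) {
    stop("`r_star` must be non-negative", call. = FALSE)
  }
  if (r_star >= 1) {
    stop("CRRA ties omega_h = 1 - r_star, so `r_star` must be < 1 for a ",
         "valid elasticity; use hara_params() with eta < 0 for r* >= 1",
         call. = FALSE)
  }
  risk_prefs(omega_h = 1 - r_star, r_star = r_star,
             pi_star = 1 + r_star, tau_star = 2 + r_star,
             eval_h = NA_real_, crra = TRUE)
}

#' Relative bias of CRRA-based higher-order preference estimates
#'
#' When the true utility is HARA with curvature `gamma` but CRRA is
#' (incorrectly) assumed, the higher-order parameters
#' \eqn{\zeta_j^*} are estimated with relative bias
#' \deqn{(1-\gamma)\,\frac{1 + (j-1)/r^*}{j - \gamma} - 1,}
#' which at \eqn{r^* = 1} reduces to \eqn{j(1-\gamma)/(j-\gamma) - 1}.  The
#' bias is zero at `gamma = 0` (where CRRA is correctly specified) and grows
#' in magnitude with `gamma`.
#'
#' @param j Order of the preference parameter, integer `>= 2`.
#' @param gamma True HARA curvature in \[0, 1).
#' @param r_star Relative risk aversion, `> 0` (default 1).
#' @return Relative bias as a (typically negative) fraction.
#' @examples
#' crra_misspecification_bias(2, 0.5)   # -1/3: prudence understated by 33%
#' @export
crra_misspecification_bias <- function(j, gamma, r_star = 1) {
  stopifnot(is.numeric(j), is.numeric(gamma), is.numeric(r_star))
  if (any(j < 2) || any(j != round(j))) {
    stop("`j` must be an integer >= 2 (bias is defined for higher-order ",
         "parameters)", call. = FALSE)
  }
  if (any(gamma < 0) || any(gamma >= 1)) {
    stop("`gamma` must lie in [0, 1)", call. = FALSE)
  }
  if (any(r_star <= 0)) {
    stop("`r_star` must be strictly positive", call. = FALSE)
  }
  (1 - gamma) * (1 + (j - 1) / r_star) / (j - gamma) - 1
}

#' Grid of CRRA-misspecification biases
#'
#' Evaluates [crra_misspecification_bias()] over a grid of curvatures and
#' orders, reproducing the published bias table at `r_star = 1`.
#'
#' @param gamma Curvature grid (columns).
#' @param j Order grid (rows).
#' @param r_star Relative risk aversion at which biases are evaluated.
#' @return A matrix of bias fractions with orders in rows and curvatures in
#'   columns.
#' @export
crra_bias_table <- function(gamma = c(0, 0.2, 0.4, 0.5, 0.6, 0.8),
                            j = 2:6, r_star = 1) {
  out <- outer(j, gamma, function(jj, gg) {
    crra_misspecification_bias(jj, gg, r_star)
  })
  dimnames(out) <- list(paste0("zeta", j), paste0("gamma=", gamma))
  out
}
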
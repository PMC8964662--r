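#' Read a happiness survey from CSV
#'
#' Expects a header `happy,H,C`.  Ordinal happiness scores whose minimum is
#' not positive are shifted so the minimum score maps to 1 (the logarithm
#' requires strict positivity and happiness scales are arbitrary); a
#' message reports the shift.
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns `happy`, `H`, `C` suitable for
#'   [fit_happiness()].
#' @export
read_survey <- function(path) {
  d <- utils::read.csv(path)
  need <- c("happy", "H", "C")
  if (!all(need %in% names(d))) {
    stop("survey CSV must have header happy,H,C", call. = FALSE)
  }
  d <- d[need]
  if (anyNA(d)) stop("survey contains missing values", call. = FALSE)
  if (min(d$happy) <= 0) {
    shift <- 1 - min(d$happy)
    message("shifting happiness scores by ", shift,
            " so the minimum maps to 1")
    d$happy <- d$happy + shift
  }
  if (any(d$H <= 0) || any(d$H > 1)) {
    stop("column H must lie in (0, 1]", call. = FALSE)
  }
  if (any(d$C <= 0)) stop("column C must be strictly positive", call. = FALSE)
  d
}

#' Read trial-arm QoL outcomes from CSV
#'
#' Expects a header `arm,H` with `arm` in `{treatment, control}` and `H`
#' in \[0, 1\].
#'
#' @param path Path to a CSV file.
#' @return A list with numeric vectors `treat` and `ctrl`.
#' @export
read_outcomes <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("arm", "H") %in% names(d))) {
    stop("outcomes CSV must have header arm,H", call. = FALSE)
  }
  if (!all(d$arm %in% c("treatment", "control"))) {
    stop("column arm must be 'treatment' or 'control'", call. = FALSE)
  }
  list(treat = d$H[d$arm == "treatment"],
       ctrl = d$H[d$arm == "control"])
}

#' Load and validate a scenario configuration
#'
#' Reads a JSON scenario and validates it into the canonical nested form
#' with sections `econ` (`C`, `omega_C`), `prefs` (either
#' `{omega_h, r_star[, pi_star, tau_star]}` or `{gamma, eta}`), `disease`
#' (`phi`, `ell_star`, `d_star`, `H0`), `treatment` (`mu_b` or an
#' `outcomes` CSV path, plus `t_star`, `mu_p`, `p1` or a per-period `p`
#' array, `delta_var`, `delta_skew`, `delta_c`, `delta_c0`) and `options`
#' (`taylor_order`, `beta`, `N`, `normalization_period`, `seed`).  A flat
#' key set (as used by the thresholds command) is lifted into sections.
#' Defaults: `H0 = 1`, `d_star = 0`, `taylor_order = 3`, `beta = 1`,
#' `N = 1`.
#'
#' @param path Path to a JSON file (or a list already parsed from one).
#' @return A validated scenario list of class `grace_scenario`.
#' @export
load_scenario <- function(path) {
  cfg <- if (is.list(path)) path else jsonlite::fromJSON(path)
  flat_keys <- c(C = "econ", omega_C = "econ",
                 omega_h = "prefs", omega_H = "prefs", r_star = "prefs",
                 pi_star = "prefs", tau_star = "prefs", gamma = "prefs",
                 eta = "prefs",
                 phi = "disease", ell_star = "disease", d_star = "disease",
                 H0 = "disease",
                 mu_b = "treatment", t_star = "treatment",
                 mu_p = "treatment", p1 = "treatment", p = "treatment",
                 delta_var = "treatment", delta_skew = "treatment",
                 mu_h = "treatment", epsilon = "treatment",
                 outcomes = "treatment", delta_c = "treatment",
                 delta_c0 = "treatment",
                 taylor_order = "options", beta = "options", N = "options",
                 normalization_period = "options", seed = "options")
  if (!any(c("econ", "prefs") %in% names(cfg))) {
    lifted <- list()
    for (key in intersect(names(cfg), names(flat_keys))) {
      sec <- flat_keys[[key]]
      lifted[[sec]][[key]] <- cfg[[key]]
    }
    cfg <- lifted
  }
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("scenario field `%s`: %s", field, msg), call. = FALSE)
  }
  num1 <- function(sec, field, lo = -Inf, hi = Inf, default = NULL,
                   open_lo = FALSE, open_hi = FALSE) {
    v <- cfg[[sec]][[field]]
    if (is.null(v)) {
      if (is.null(default)) fail(paste(sec, field, sep = "."), "is required")
      return(default)
    }
    path <- paste(sec, field, sep = ".")
    if (!is.numeric(v)) fail(path, "must be numeric")
    bad <- v < lo | v > hi | (open_lo & v == lo) | (open_hi & v == hi)
    if (any(!is.finite(v)) || any(bad)) {
      fail(path, sprintf("must lie in %s%g, %g%s",
                         if (open_lo) "(" else "[", lo, hi,
                         if (open_hi) ")" else "]"))
    }
    v
  }
  # normalize alternative capitalizations used in flat configs
  if (!is.null(cfg$prefs$omega_H) && is.null(cfg$prefs$omega_h)) {
    cfg$prefs$omega_h <- cfg$prefs$omega_H
  }
  out <- list()
  out$econ <- list(C = num1("econ", "C", lo = 0, open_lo = TRUE),
                   omega_C = num1("econ", "omega_C", 0, 1, open_lo = TRUE,
                                  open_hi = TRUE))
  has_hara <- !is.null(cfg$prefs$gamma) || !is.null(cfg$prefs$eta)
  has_direct <- !is.null(cfg$prefs$omega_h) || !is.null(cfg$prefs$r_star)
  if (has_hara && has_direct) {
    fail("prefs", paste("exactly one parameterization allowed:",
                        "{omega_h, r_star} or {gamma, eta}"))
  }
  if (!has_hara && !has_direct) fail("prefs", "is required")
  out$prefs <- if (has_hara) {
    list(gamma = num1("prefs", "gamma", 0, 1, open_lo = TRUE,
                      open_hi = TRUE),
         eta = num1("prefs", "eta", default = 0))
  } else {
    list(omega_h = num1("prefs", "omega_h", 0, 1, open_lo = TRUE),
         r_star = num1("prefs", "r_star", 0),
         pi_star = cfg$prefs$pi_star, tau_star = cfg$prefs$tau_star)
  }
  out$disease <- list(
    phi = num1("disease", "phi", 0, 1),
    ell_star = num1("disease", "ell_star", 0, 1, open_hi = TRUE),
    d_star = num1("disease", "d_star", 0, 1, open_hi = TRUE, default = 0),
    H0 = num1("disease", "H0", 0, 1, open_lo = TRUE, default = 1))
  tr <- cfg$treatment
  if (is.null(tr)) fail("treatment", "is required")
  has_outcomes <- !is.null(tr$outcomes)
  has_moments <- !is.null(tr$mu_b)
  if (has_outcomes == has_moments) {
    fail("treatment", paste("exactly one of `mu_b` (summary moments) or",
                            "`outcomes` (CSV path) must be present"))
  }
  out$treatment <- list(
    outcomes = tr$outcomes,
    mu_b = tr$mu_b,
    t_star = if (is.null(tr$t_star)) NULL else
      num1("treatment", "t_star", 0, 1, open_hi = TRUE),
    mu_p = num1("treatment", "mu_p", default = 0),
    p1 = num1("treatment", "p1", 0, 1, default = 1),
    p = tr$p,
    delta_var = num1("treatment", "delta_var", default = 0),
    delta_skew = num1("treatment", "delta_skew", default = 0),
    mu_h = tr$mu_h,
    epsilon = tr$epsilon,
    delta_c = num1("treatment", "delta_c", default = 0),
    delta_c0 = num1("treatment", "delta_c0", default = 0))
  out$options <- list(
    taylor_order = num1("options", "taylor_order", 1, 3, default = 3),
    beta = num1("options", "beta", 0, 1, open_lo = TRUE, default = 1),
    N = num1("options", "N", 1, Inf, default = 1),
    normalization_period = num1("options", "normalization_period", 1, Inf,
                                default = 1),
    seed = cfg$options$seed)
  structure(out, class = "grace_scenario")
}

#' Run the full GRACE pipeline on a scenario
#'
#' Orchestrates the whole chain: preference resolution, severity ratio
#' `R`, disability ratio `psi`, outcome moments and the
#' certainty-equivalence ratio `epsilon`, utility shares `rho`, the
#' substitution rate `delta`, thresholds, and the static (and, for
#' multi-period scenarios, dynamic) value and decision rules.
#'
#' @param config A scenario from [load_scenario()] (or a path / list
#'   accepted by it).
#' @return An object of class `grace_report` with elements `inputs`
#'   (the resolved scenario), `derived` (every intermediate quantity:
#'   `k`, `omega_h`, `r_star`, `pi_star`, `tau_star`, `gamma`, `R`, `psi`,
#'   `epsilon`, `rho_s`, `rho_w`, `rho`, `delta`, `k_grace`, `gra_qaly`,
#'   `tvmi`, `nmb`, `igracer`, `threshold`, `adopt`), `warnings`, `seed`
#'   and `version`.
#' @examples
#' cfg <- list(
#'   econ = list(C = 50000, omega_C = 1/3),
#'   prefs = list(omega_h = 0.5, r_star = 0.5),
#'   disease = list(phi = 0.5, ell_star = 0.5),
#'   treatment = list(mu_b = 0.2, t_star = 0.25, mu_p = 0.1, p1 = 0.9,
#'                    delta_c = 20000))
#' run_pipeline(cfg)
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "grace_scenario")) config else
    load_scenario(config)
  warns <- character()
  report <- withCallingHandlers(
    run_pipeline_impl(cfg),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  report$warnings <- warns
  report
}

run_pipeline_impl <- function(cfg) {
  h0 <- cfg$disease$H0
  d_star <- cfg$disease$d_star
  phi <- cfg$disease$phi
  order <- cfg$options$taylor_order
  mu_h_default <- h0 * (1 - cfg$disease$ell_star)

  # stage 1: preferences -----------------------------------------------
  if (!is.null(cfg$prefs$gamma)) {
    hara <- hara_params(cfg$prefs$gamma, cfg$prefs$eta)
    prefs_h0 <- hara_prefs_at(h0, hara)
    prefs_sick <- hara_prefs_at(mu_h_default, hara)
    gamma <- cfg$prefs$gamma
  } else {
    prefs_h0 <- risk_prefs(cfg$prefs$omega_h, cfg$prefs$r_star,
                           pi_star = cfg$prefs$pi_star,
                           tau_star = cfg$prefs$tau_star, eval_h = h0)
    prefs_sick <- prefs_h0  # single bundle accepted (exact under CRRA)
    if (!prefs_h0$crra) {
      warning("non-CRRA preference bundle supplied as scalars is used at ",
              "both H0 and mu_H; supply {gamma, eta} to re-evaluate by ",
              "health state", call. = FALSE)
    }
    gamma <- if (prefs_h0$r_star > 0) {
      gamma_from_elasticity(prefs_h0$omega_h, prefs_h0$r_star)
    } else NA_real_
  }
  crra <- prefs_h0$crra

  # stage 2: traditional threshold -------------------------------------
  econ <- econ_context(cfg$econ$C, cfg$econ$omega_C)
  k <- k_traditional(econ)

  # stage 3: outcome moments and epsilon -------------------------------
  tr <- cfg$treatment
  if (!is.null(tr$outcomes)) {
    arms <- read_outcomes(tr$outcomes)
    contrast <- outcome_contrast(arms$treat, arms$ctrl, h0 = h0,
                                 d_star = d_star)
    ell_star <- contrast$loss$ell_star
    t_star <- contrast$loss$t_star
    mu_h <- contrast$mu_h
  } else {
    ell_star <- cfg$disease$ell_star
    t_star <- if (!is.null(tr$t_star)) tr$t_star else ell_star
    mu_h <- if (!is.null(tr$mu_h)) tr$mu_h else mu_h_default
    contrast <- moment_contrast(mu_b = tr$mu_b, mu_h = mu_h,
                                delta_var = tr$delta_var,
                                delta_skew = tr$delta_skew)
  }
  epsilon <- if (!is.null(tr$epsilon)) tr$epsilon else
    epsilon_ratio(contrast, prefs_sick)

  # stage 4: severity and disability adjustments ------------------------
  R <- if (crra) severity_ratio_crra(ell_star, prefs_sick$r_star) else
    severity_ratio_taylor(ell_star, prefs_sick, order = order)
  psi <- disability_ratio(d_star, prefs_h0, order = order)
  kg <- k_grace(k, prefs_h0$omega_h, R, h0 = h0, d_star = d_star, psi = psi)

  # stage 5: utility shares and the substitution rate -------------------
  rho_s <- rho_sick(t_star, prefs_h0, order = order)
  rho_w <- rho_well(d_star, prefs_h0, order = order)
  rho <- rho_total(phi, rho_s, rho_w)
  delta <- mrs_delta(rho, prefs_h0$omega_h, R, h0 = h0)

  # stage 6: valuation and decision -------------------------------------
  n_per <- cfg$options$N
  p_vec <- if (!is.null(tr$p)) tr$p else tr$p1
  gq <- gra_qaly(tr$mu_p[1], delta[1], phi, p_vec[1], contrast$mu_b[1],
                 epsilon[1])
  value <- tvmi(kg[1], gq)
  static_cost <- tr$delta_c0 + sum(tr$delta_c)
  dec <- igracer_static(static_cost, gq, kg[1])

  dynamic <- NULL
  if (n_per > 1 || length(p_vec) > 1) {
    periods <- period_params(mu_b = contrast$mu_b, epsilon = epsilon,
                             delta = delta, R = R, mu_p = tr$mu_p,
                             p = rep_len(p_vec, max(n_per, length(p_vec))),
                             delta_c = tr$delta_c, phi = phi,
                             beta = cfg$options$beta,
                             delta_c0 = tr$delta_c0)
    nmb <- as.numeric(nmb_dynamic(periods, k, prefs_h0$omega_h, h0 = h0,
                                  d_star = d_star, psi = psi))
    dyn_dec <- igracer_dynamic(periods, k, prefs_h0$omega_h, h0 = h0,
                               d_star = d_star, psi = psi,
                               j = cfg$options$normalization_period)
    dynamic <- list(nmb = nmb, igracer = dyn_dec$ratio,
                    threshold = dyn_dec$threshold, adopt = dyn_dec$adopt,
                    n_periods = periods$n_periods)
  }

  structure(list(
    inputs = cfg,
    derived = list(
      k = k, omega_h = prefs_h0$omega_h, r_star = prefs_h0$r_star,
      pi_star = prefs_h0$pi_star, tau_star = prefs_h0$tau_star,
      gamma = gamma, crra = crra,
      ell_star = ell_star, t_star = t_star, d_star = d_star,
      mu_h = mu_h[1], mu_b = contrast$mu_b,
      delta_var = contrast$delta_var, delta_skew = contrast$delta_skew,
      delta_kurt = contrast$delta_kurt,
      R = R, psi = psi, epsilon = epsilon,
      rho_s = rho_s, rho_w = rho_w, rho = rho, delta = delta,
      k_grace = kg, gra_qaly = gq, tvmi = value,
      nmb = dec$nmb, igracer = dec$ratio, threshold = dec$threshold,
      adopt = dec$adopt, dominance = dec$dominance),
    dynamic = dynamic,
    warnings = character(),
    seed = cfg$options$seed,
    version = as.character(utils::packageVersion("gracecea"))),
    class = "grace_report")
}

#' @export
print.grace_report <- function(x, ...) {
  d <- x$derived
  cat("GRACE valuation report\n")
  cat(sprintf("  thresholds:  K = %s, K_GRACE = %s per GRA-QALY\n",
              format(d$k, big.mark = ","),
              format(signif(d$k_grace[1], 6), big.mark = ",")))
  cat(sprintf(
    "  adjustments: R = %.4g  psi = %.4g  epsilon = %.4g  delta = %.4g\n",
    d$R[1], d$psi, d$epsilon[1], d$delta[1]))
  cat(sprintf("  GRA-QALY gain = %.5g   TVMI = %s\n", d$gra_qaly,
              format(signif(d$tvmi, 6), big.mark = ",")))
  cat(sprintf("  IGRACER = %s vs threshold %s -> %s\n",
              if (is.na(d$igracer)) "(dominance)" else
                format(signif(d$igracer, 6), big.mark = ","),
              format(signif(d$threshold, 6), big.mark = ","),
              if (d$adopt) "ADOPT" else "REJECT"))
  if (!is.null(x$dynamic)) {
    cat(sprintf("  dynamic (%d periods): NMB = %s -> %s\n",
                x$dynamic$n_periods,
                format(signif(x$dynamic$nmb, 6), big.mark = ","),
                if (x$dynamic$adopt) "ADOPT" else "REJECT"))
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Generate deterministic synthetic fixtures
#'
#' Writes reproducible synthetic inputs for the pipeline: two-arm trial
#' outcomes drawn from Beta distributions matched to requested means and
#' variances, a happiness survey from a known translog truth, or a
#' multi-period scenario JSON.  A manifest JSON recording the generator
#' parameters and seed accompanies every fixture.
#'
#' @param kind One of `"trial_arms"`, `"happiness_survey"`,
#'   `"dynamic_scenario"`.
#' @param params A named list of generator parameters.  For `trial_arms`:
#'   `n`, `mean_t`, `var_t`, `mean_c`, `var_c`.  For `happiness_survey`:
#'   passed to [simulate_survey()] (`n`, `truth`, `noise_sd`, ...).  For
#'   `dynamic_scenario`: a scenario list written as JSON (defaults filled
#'   by [load_scenario()]).
#' @param seed Integer seed; required for the stochastic kinds.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the files written.
#' @export
generate_fixture <- function(kind = c("trial_arms", "happiness_survey",
                                      "dynamic_scenario"),
                             params, seed = NULL, dir = ".") {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (kind == "trial_arms") {
    stopifnot(all(c("n", "mean_t", "var_t", "mean_c", "var_c") %in%
                    names(params)))
    set.seed(seed)
    st <- beta_from_moments(params$mean_t, params$var_t)
    sc <- beta_from_moments(params$mean_c, params$var_c)
    d <- data.frame(
      arm = rep(c("treatment", "control"), each = params$n),
      H = c(stats::rbeta(params$n, st$shape1, st$shape2),
            stats::rbeta(params$n, sc$shape1, sc$shape2)))
    paths <- file.path(dir, "trial_arms.csv")
    utils::write.csv(d, paths, row.names = FALSE)
  } else if (kind == "happiness_survey") {
    args <- params
    args$seed <- seed
    d <- do.call(simulate_survey, args)
    paths <- file.path(dir, "happiness_survey.csv")
    utils::write.csv(d, paths, row.names = FALSE)
  } else {
    cfg <- load_scenario(params)
    paths <- file.path(dir, "dynamic_scenario.json")
    jsonlite::write_json(unclass(cfg), paths, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  manifest <- file.path(dir, paste0(kind, "_manifest.json"))
  jsonlite::write_json(
    list(kind = kind, seed = seed,
         params = rapply(params, unclass, how = "replace")),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE, null = "null")
  invisible(c(paths, manifest))
}

#' Match a Beta distribution to a mean and variance
#'
#' Solves for the Beta shape parameters with the requested first two
#' moments.  Feasible only when `variance < mean * (1 - mean)`.
#'
#' @param mean Target mean in (0, 1).
#' @param variance Target variance, `> 0`.
#' @return A list with `shape1` and `shape2`.
#' @export
beta_from_moments <- function(mean, variance) {
  stopifnot(is.numeric(mean), is.numeric(variance))
  if (mean <= 0 || mean >= 1) stop("`mean` must lie in (0, 1)", call. = FALSE)
  if (variance <= 0 || variance >= mean * (1 - mean)) {
    stop(sprintf(paste0("no Beta distribution has mean %g and variance %g ",
                        "(need 0 < variance < %g)"),
                 mean, variance, mean * (1 - mean)), call. = FALSE)
  }
  nu <- mean * (1 - mean) / variance - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}
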
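---
title: "Generalized risk-adjusted cost-effectiveness: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized risk-adjusted cost-effectiveness: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gracecea)
```

## The model

Traditional cost-effectiveness analysis (CEA) treats a quality-adjusted
life-year (QALY) as equally valuable wherever it accrues: utility is linear
in health-related quality of life (QoL), so a 0.1 QoL gain is worth the same
to a patient at QoL 0.9 as to one at QoL 0.2. Generalized risk-adjusted
cost-effectiveness (GRACE) relaxes exactly this restriction. Period utility
is multiplicative, $U(C)\,W(H)$, with consumption $C$ and a QoL index
$H \in (0, 1]$, and $W$ is increasing and strictly concave. Three
consequences follow:

1. **Severity raises willingness to pay.** The marginal utility of QoL is
   higher in worse health states, so the threshold per QALY grows with
   untreated severity (and with pre-existing permanent disability).
2. **Outcome uncertainty matters.** Risk-averse patients value reductions
   in the variance of treatment outcomes and increases in their positive
   skewness, beyond the mean gain.
3. **The life-extension/QoL trade-off varies with health.** People in
   worse health trade remaining life expectancy for QoL at a different
   rate than the healthy, contradicting "a QALY is a QALY".

The package implements the full chain: preference parameters, adjusted
thresholds, moment-based adjustments, and static plus multi-period decision
rules.

### Utility and risk preferences

We use the simplified hyperbolic absolute risk aversion (HARA) family

$$W(H) = \frac{1-\gamma}{\gamma}\,Z^{\gamma}, \qquad Z = H + \eta,
  \qquad \gamma \in (0,1),$$

with $W(H) = 0$ at $Z = 0$. The scale constant of the general HARA family
is fixed (rescaling adds no generality on a $[0,1]$ QoL domain), so the
family is indexed by curvature $\gamma$ and shift $\eta$ alone. Closed
forms follow for the relative risk-preference ladder at any $H$:

$$r^* = (1-\gamma)\frac{H}{Z},\quad
  \omega_H = \gamma\frac{H}{Z},\quad
  \zeta_j^* = \frac{j-\gamma}{1-\gamma}\,r^*,$$

where $\omega_H$ is the elasticity of utility with respect to QoL, $r^*$
relative risk aversion, and $\zeta_2^* = \pi^*$ (prudence),
$\zeta_3^* = \tau^*$ (temperance). $\eta = 0$ gives constant relative risk
aversion (CRRA) with $r^* = 1-\gamma$; $\eta < 0$ gives decreasing relative
risk aversion and permits $r^* > 1$; $\eta > 0$ gives increasing relative
risk aversion. Because $H/Z$ cancels in the ratio $r^*/\omega_H$, the
curvature is identified from any one evaluation point:
$\gamma = \omega_H/(r^* + \omega_H)$, and a discrete-choice pair
$(r^*, \pi^*)$ identifies it as $\gamma = (\pi^*-2r^*)/(\pi^*-r^*)$.

`crra_misspecification_bias()` quantifies what is lost by assuming CRRA
when the truth is HARA: higher-order parameters are understated by
$(1-\gamma)(1+(j-1)/r^*)/(j-\gamma) - 1$, up to roughly $-77\%$ at
$\gamma = 0.8$ for $\zeta_6^*$. The bias matters most when outcome
distributions are strongly non-normal, because that is when prudence and
temperance carry weight.

```{r}
round(100 * crra_bias_table())
```

### Estimating preferences from happiness surveys

Discrete choice experiments can estimate $(r^*, \pi^*)$ directly, and the
package accepts those as numeric inputs. As a cheaper alternative,
`fit_happiness()` estimates the translog regression

$$\ln(\mathit{Happy}) = \beta_1 \ln H + \tfrac12\beta_2 (\ln H)^2
  + \beta_3 \ln C + \tfrac12\beta_4 (\ln C)^2 + \varepsilon$$

by ordinary least squares, a second-order approximation of any smooth
utility. The estimators are then

$$\hat\omega_H(H) = \hat\beta_1 + \hat\beta_2\ln H,\qquad
  \hat\epsilon^{\omega}(H) = \frac{\hat\beta_2}{\hat\omega_H(H)},\qquad
  \hat r^*(H) = 1 - \hat\omega_H(H) - \hat\epsilon^{\omega}(H),$$

and the sign of $\beta_2$ classifies the risk posture (negative: DRRA,
zero: CRRA, positive: IRRA). Design choices worth stating:

* **Intercept.** The regression is specified without an intercept, but the
  package includes one by default: happiness scales are arbitrary, every
  downstream quantity depends only on slopes, and the intercept absorbs
  scale shifts that would otherwise bias them. On data generated without a
  level shift the two fits agree on every estimator (tested).
* **Ordinal scores.** Logs require positivity; `read_survey()` shifts an
  ordinal scale so its minimum maps to 1.
* **Posture classification.** A fitted $\hat\beta_2$ is never exactly
  zero, so `classify_posture()` declares CRRA when $\hat\beta_2$ is
  statistically indistinguishable from zero, using a two-sided test at the
  1% level. A 5% level would leave the correct-classification rate for
  CRRA truths at 95% by construction; 1% keeps it near 99% while leaving
  genuinely curved alternatives (which have enormous $t$-statistics at
  survey scale) unaffected.
* **Interaction and ordered models.** The $\ln H \ln C$ interaction can be
  fitted (`interaction = TRUE`) but is excluded from the estimators, which
  are derived under the interaction-free specification. Ordered-response
  models are out of scope; the translog OLS form is the specification.
* **Uncertainty.** Standard errors for $\hat\omega_H$ and $\hat r^*$ are
  propagated from the coefficient covariance by the delta method
  (`recover_full_prefs()$se`); this propagation is an extension beyond the
  point estimators.

`simulate_survey()` generates surveys from known truths — a coefficient
vector, or a HARA utility evaluated exactly — with $H \sim$ Beta(2, 2)
(a unimodal QoL distribution on the unit interval; the simulator's default,
a modelling choice, as no canonical survey distribution for $H$ exists) and
lognormal consumption centred near \$50{,}000. Recovery is tested at
$n = 10^4$ with noise 0.1 on the log scale.

### Severity, disability, and thresholds

With consumption elasticity $\omega_C$, the traditional threshold is
$K = C/\omega_C$. GRACE scales it by the QoL elasticity, the
disease-severity ratio $R = W'(\mu_H)/W'(H_0)$, and a disability
correction:

$$K_{GRACE} = \frac{K\,\omega_H\,R}{H_0\,(1 - d^*\psi)},$$

where $\mu_H = H_0(1-\ell^*)$ is mean untreated sick-state QoL, $d^*$ the
permanent-disability loss, and the disability ratio $\psi$ solves
$W(H_{0d})/W(H_0) = 1 - d^*\psi$. Under CRRA, $R = (1-\ell^*)^{-r^*}$
exactly (`severity_ratio_crra()`); for general preferences the package
uses the truncated expansion
$R \approx 1 + r^*\ell^* + \tfrac12 r^*\pi^*\ell^{*2} +
\tfrac16 r^*\pi^*\tau^*\ell^{*3}$. The default path is the exact CRRA form
whenever the preference bundle is CRRA, and the series otherwise — the
series is a third-order object and falls badly short at extreme severity
(1.98 vs 3.16 at $\ell^* = 0.9$, $r^* = 0.5$), so a warning fires for
$\ell^* > 0.5$. $\psi$ has the expansion
$\omega_H(1 + \tfrac12 r^*d^* + \tfrac16 r^*\pi^*d^{*2})$, with
$\psi = 1$ for risk-neutral consumers and $\psi < 1$ under strict risk
aversion, so $1 - d^*\psi > 0$ and the threshold is well defined; its
exact counterpart is the slope ratio
$[(W(H_0)-W(H_{0d}))/(H_0-H_{0d})]\,/\,[W(H_0)/H_0]$, which presumes
$W(0)=0$ and is therefore restricted to $\eta \ge 0$ — for $\eta < 0$ no
closed form exists and the package raises an error rather than guessing.

Evaluation points matter away from CRRA: $\psi$ and $\omega_H$ are defined
at baseline $H_0$ while $R$'s preferences belong at $\mu_H$. Preference
bundles therefore carry their evaluation point (`eval_h`), the pipeline
evaluates HARA-parameterized preferences at each point, and a scalar
non-CRRA bundle used at both points triggers a warning.

Disability never lowers the threshold for QoL gains; whether it also
preserves willingness to pay for life extension depends on
$\partial t^*/\partial d^* \le (1-t^*)/(1-d^*)$
(`disability_le_condition()`; always satisfied for curative therapies).
The sensitivity $\partial t^*/\partial d^*$ is accepted as a user-supplied
scalar — no estimator for it exists.

### From trial arms to adjustments

`outcome_contrast()` reduces two-arm patient-level QoL data to the moment
contrasts: mean gain $\mu_B$, variance difference $\Delta\sigma^2_H$,
third-central-moment difference $\Delta[\gamma_1\sigma^3_H]$, and an
excess-kurtosis difference. Population (1/n) central moments are the
default because the contrasts are defined as plain moment differences; an
unbiased-variance option exists for practice. The skewness contrast is
read as a difference of per-arm third central moments (each arm's
$\gamma_1\sigma^3$), not a pooled-scale quantity. The kurtosis contrast is
computed and reported as informational only: no valuation term uses it,
the fourth-order term of the certainty-equivalence expansion being
unstated.

The certainty-equivalence ratio converts mean gains to certainty
equivalents:

$$\epsilon = 1 + \frac{1}{\mu_B}\left[-\tfrac12 r^*
  \frac{\Delta\sigma^2_H}{\mu_H} + \tfrac16 \pi^* r^*
  \frac{\Delta[\gamma_1\sigma^3_H]}{\mu_H^2}\right],$$

with preferences evaluated at $\mu_H$ (the control-arm mean, matching the
definition of the untreated sick state). At $\mu_B = 0$, $\epsilon$ is
undefined and the package raises an error rather than returning $\pm\infty$:
the valuation only ever needs the product $\mu_B\epsilon$, which stays
finite, and callers valuing pure variance effects should work at the level
of that product.

The substitution rate between life expectancy and QoL needs no
disease-specific study. With the period-1 utility shares

$$\rho_S = 1 - \omega_H\!\left[t^* + \tfrac12 r^*t^{*2}
  + \tfrac16 r^*\pi^*t^{*3}\right],\quad
  \rho_W = 1 - \omega_H\!\left[d^* + \tfrac12 r^*d^{*2}
  + \tfrac16 r^*\pi^*d^{*3}\right],$$

and $\rho = \phi\rho_S + (1-\phi)\rho_W$, the marginal rate of
substitution is $\delta = \rho H_0/(\omega_H R)$. The identity
$\omega_H R \delta = \rho H_0$ makes the two total-value forms
(`tvmi()` via $\delta$, `tvmi_alt()` via $\rho$) algebraically equal, which
the tests verify to machine precision on randomized inputs, and
`delta_exact()` (quadrature or Monte Carlo over the treated outcome
distribution) provides the expectation-based oracle. Note $\rho_W$ and
$1 - d^*\psi$ are the same series — a cross-check the tests exploit.

### Decision rules

The generalized risk-adjusted QALY gain is
$\mu_p\delta + \phi p_1 \mu_B \epsilon$; the value of an intervention is
$K_{GRACE}$ times that; and the static rule adopts when
$\Delta C / \mathrm{GRA\text{-}QALY} \le K_{GRACE}$, with adoption at
equality. Multi-period assessments discount with a one-period factor
$\beta$ (supplied directly, or via `discount_factor(rate)`) and cumulative
survival $\Pi_n = \prod_{k\le n} p_k$:

$$\mathrm{NMB}_0 = \sum_{n=1}^N \beta^n \Pi_{n-1}\left\{
  \frac{K\omega_H R_n}{H_0(1-d^*\psi)}
  \left[\mu_{pn}\delta_n + \phi p_n \mu_{Bn}\epsilon_n\right]
  - p_n\Delta C_n\right\} - \Delta C_0.$$

The matching ratio rule normalizes the severity profile to a reference
period $j$ (default 1, overridable); the adopt decision is invariant to
$j$ because numerator-free $R_j$ scales ratio and threshold alike. Under
stationary outcomes both collapse to a geometric-series form with horizon
factor $\beta(1-(\beta p)^N)/(1-\beta p)$, taken as $N\beta$ in the
$\beta p = 1$ limit. Modelling assumptions inherited from the framework:
$\phi$, $d^*$ and $\psi$ are constant across periods (the dynamic
formulation never indexes them by $n$), and time-varying disability is
not supported.

Two edge rules are deliberate. Adoption at equality uses "$\le$"
throughout, matching the decision rules' weak inequality. And when the
GRA-QALY denominator is non-positive, the ratio's sign is ambiguous
(the classic ICER-quadrant problem), so the functions suppress the ratio,
warn, and decide by the sign of the net monetary benefit — which
reproduces the natural dominance guidance (at zero benefit: adopt iff
costs are negative) and keeps the ratio and NMB formulations consistent
by construction.

## Synthetic data: what it emulates and what it does not

The package ships no data; `generate_fixture()` builds all inputs in code.

* **Trial arms** are Beta draws matched to requested means and variances
  (`beta_from_moments()`; infeasible requests — variance at or above
  $m(1-m)$ — are errors). Skewness then follows from the Beta shape, which
  is realistic for bounded QoL indices: arms with mean near 1 are left
  skewed. Defaults used in tests (control mean 0.5, treatment mean 0.75,
  variances 0.02 and 0.01) mirror the worked severity example
  ($\ell^* = 0.5$, $t^* = 0.25$) with a variance-reducing treatment.
* **Happiness surveys** are generated from the exact translog model (or
  exact HARA log-utility), so the estimators are consistent by
  construction and recovery experiments test estimation error only.

Real data differ in ways the generators do not emulate: ordinal happiness
scales with few categories and ceiling effects, measurement error in $H$
and $C$, sampling designs, correlated errors, and trial outcomes that are
mixtures (e.g. point mass at full recovery). Passing recovery tests
therefore demonstrates the estimators' correctness under their own
assumptions, not robustness to survey psychometrics — the latter is out of
scope.

## Numerical choices and problem sizes

* Taylor truncation order defaults to 3 everywhere and is capped there:
  the published expansions stop at the temperance term, and the kurtosis
  continuation is unstated.
* Severity series warn at $\ell^* > 0.5$; utility-share series warn if
  they fall to zero or below (outside the expansion's validity).
* Quadrature uses `stats::integrate` at `rel.tol = 1e-10`; identities are
  tested at $10^{-12}$ relative (closed forms) and $10^{-10}$
  (dynamic/stationary equivalence).
* Finite-difference oracles (central differences, $h = 10^{-6}$ for first,
  $10^{-4}$ for second derivatives) live in the test suite only.
* Test and acceptance problem sizes, chosen so the whole suite runs in
  seconds while leaving Monte Carlo error far below the tolerances:
  surveys at $n = 10^4$ with 100 classification replicates; identity
  checks at 1,000 random draws; moment oracles at $2\times10^5$ draws.

## Known limitations

* Non-CRRA preferences supplied as bare scalars cannot be re-evaluated at
  other health states; supply $(\gamma, \eta)$ to get state-specific
  bundles. The CRRA case is exact either way.
* The exact disability-ratio oracle requires $\eta \ge 0$; the series form
  is the only route for DRRA utilities.
* $r^* \ge 1$ regimes (possible with $\eta < 0$) expose prudence and
  temperance without clamping; no published bound exists for them there.
* Currency is an opaque label; no conversion or inflation handling.
* Probabilistic sensitivity analysis and state-transition engines are out
  of scope — per-period parameter arrays are accepted from any upstream
  model.
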
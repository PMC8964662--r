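# Numerical-differentiation oracles for the HARA closed forms.  These stay
# in the test suite: they check the algebra by brute force and never stand
# behind the public surface.

num_deriv <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

num_deriv2 <- function(f, x, h = 1e-4) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

num_deriv3 <- function(f, x, h = 1e-3) {
  (f(x + 2 * h) - 2 * f(x + h) + 2 * f(x - h) - f(x - 2 * h)) / (2 * h^3)
}

# relative risk aversion / prudence at h by finite differences of W
num_r_star <- function(h, params) {
  w <- function(x) hara_value(x, params)
  -num_deriv2(w, h) / num_deriv(w, h) * h
}

num_pi_star <- function(h, params) {
  w <- function(x) hara_value(x, params)
  -num_deriv3(w, h) / num_deriv2(w, h) * h
}

# exact CRRA utility ratio W(h0 * (1 - x)) / W(h0); W = const * H^gamma
crra_utility_ratio <- function(x, r_star) {
  (1 - x)^(1 - r_star)
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
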
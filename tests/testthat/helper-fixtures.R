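# Shared fixtures: the default parameter set and a cheap no-lysis set used
# where only logistic growth matters.

ref_params <- function() params_preset("fitted_means")

logistic_params <- function(gamma0 = 1.57, rho_s = 0.33) {
  model_params(gamma0 = gamma0, rho_s = rho_s, alpha0 = 0, K = 3.29,
               n = 4.46, beta0 = 6.1, k = 19, m = 1, delta = 0.1)
}

# closed-form logistic growth at carrying capacity rho_s
logistic_closed_form <- function(t, x0, gamma0, rho_s) {
  rho_s * x0 * exp(gamma0 * t) / (rho_s + x0 * (exp(gamma0 * t) - 1))
}

no_noise <- function(seed = NULL) noise_model(0, 0, 0, seed = seed)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
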
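# shared fixtures: the "monkey-like" generative parameter sets used across
# the suite, and small cached simulations (built once per test run)

monkey_params <- function(variant = "reset", reset_threshold0 = 0.3,
                          theta_pref = 1, alpha = 0.3, kappa_basis = 2,
                          pref_color_bias = 0.05, ...) {
  agent_params(variant, alpha = alpha, kappa_basis = kappa_basis,
               reset_threshold0 = reset_threshold0, volatility = 0.02,
               location_bias = c(0, 0.1, -0.1, 0.05),
               size_bias = c(0.1, -0.05),
               pref_color_bias = pref_color_bias,
               theta_pref = theta_pref,
               prev_color_bias = 0.05, ...)
}

# independent power-series oracle for the modified Bessel function I0
i0_series <- function(kappa, k_max = 30L) {
  k <- 0:k_max
  sum(((kappa / 2)^(2 * k)) / (factorial(k))^2)
}

# memoised medium session used by several neural-module tests
cached_session <- local({
  ses <- NULL
  function(n_trials = 900L, seed = 601L) {
    if (is.null(ses)) {
      set.seed(seed)
      ses <<- simulate_trials(monkey_params(), n_trials)
    }
    ses
  }
})
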
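#' Agent parameter sets
#'
#' Constructs the parameter list for one of the behavioral model variants:
#'
#' * `"reset"` — Q-learning over color with N von Mises radial basis
#'   functions, reward-prediction-error updates, and a reset of the weights
#'   when |RPE| exceeds a dynamic threshold (12 free parameters).
#' * `"no_reset"` — same without the reset mechanism (10 parameters).
#' * `"dual_alpha"` — reset model with separate learning rates for positive
#'   and negative RPEs (13 parameters).
#' * `"wslf"` / `"wsls"` — win-stay-lose-forget / win-stay-lose-shift
#'   baselines: the remembered template is simply the previously rewarded
#'   color; on a below-threshold reward it is forgotten (values flat) or
#'   shifted to the opposite color (8 parameters).
#'
#' The softmax temperature `beta_softmax` is fixed at 0.3 and is never
#' fitted. One of the four location biases is pinned at 0 because the
#' softmax is invariant to a common shift of all option values.
#'
#' @param variant One of `"reset"`, `"no_reset"`, `"dual_alpha"`, `"wslf"`,
#'   `"wsls"`.
#' @param alpha Learning rate in `[0, 1]`.
#' @param kappa_basis Concentration of the radial basis functions
#'   (`10^rho`, `rho` in `[-2.5, 2.5]`). Smaller values generalize more.
#' @param n_basis Number of basis functions N (default 6); centers equally
#'   spaced with the first at 0.
#' @param beta_softmax Softmax temperature (fixed 0.3).
#' @param reset_threshold0 Asymptotic |RPE| threshold for a reset (drops).
#' @param volatility Rate (1/trials) at which the reset threshold decays
#'   back to `reset_threshold0` after a reset; smaller values penalize
#'   consecutive resets more.
#' @param beta_reset Slope of the reset sigmoid (1e4: resets are all or
#'   none).
#' @param location_bias Numeric length 4, value-units added per location;
#'   the first entry is pinned to 0.
#' @param size_bias Numeric length 2: bias when the stimulus is smaller
#'   (`[1]`) or bigger (`[2]`) than standard.
#' @param pref_color_bias Gain (value units per radian of proximity) on
#'   `pi - |d(theta, theta_pref)|`.
#' @param theta_pref Preferred color, radians.
#' @param prev_color_bias Gain on proximity to the previously chosen color.
#' @param alpha_neg Learning rate for negative RPEs (`dual_alpha` only).
#' @param reward_threshold WSLF/WSLS stay/forget threshold, drops.
#' @param wsl_gain Gain on template proximity for WSLF/WSLS; fixed at 1
#'   (not fitted), the temperature sets the scale.
#' @return An object of class `agent_params` (a named list) with an
#'   `n_params` attribute giving the number of free parameters.
#' @export
agent_params <- function(variant = c("reset", "no_reset", "dual_alpha",
                                     "wslf", "wsls"),
                         alpha = 0.3, kappa_basis = 2, n_basis = 6L,
                         beta_softmax = 0.3,
                         reset_threshold0 = 0.5, volatility = 0.02,
                         beta_reset = 1e4,
                         location_bias = c(0, 0, 0, 0),
                         size_bias = c(0, 0),
                         pref_color_bias = 0, theta_pref = 0,
                         prev_color_bias = 0,
                         alpha_neg = NULL,
                         reward_threshold = 2,
                         wsl_gain = 1) {
  variant <- match.arg(variant)
  stopifnot(n_basis >= 3L, beta_reset > 0, alpha >= 0, kappa_basis >= 0,
            length(location_bias) == 4L, length(size_bias) == 2L,
            beta_softmax > 0)
  if (location_bias[1] != 0) {
    stop("location_bias[1] is pinned at 0 (softmax shift invariance)",
         call. = FALSE)
  }
  if (variant == "dual_alpha" && is.null(alpha_neg)) alpha_neg <- alpha
  p <- structure(
    list(variant = variant, alpha = alpha, kappa_basis = kappa_basis,
         n_basis = as.integer(n_basis), beta_softmax = beta_softmax,
         reset_threshold0 = reset_threshold0, volatility = volatility,
         beta_reset = beta_reset, location_bias = location_bias,
         size_bias = size_bias, pref_color_bias = pref_color_bias,
         theta_pref = canonical_angle(theta_pref),
         prev_color_bias = prev_color_bias, alpha_neg = alpha_neg,
         reward_threshold = reward_threshold, wsl_gain = wsl_gain),
    class = "agent_params")
  attr(p, "n_params") <- switch(variant,
    no_reset = 10L, reset = 12L, dual_alpha = 13L, wslf = 8L, wsls = 8L)
  p
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params> variant:", x$variant,
      " (", attr(x, "n_params"), "free parameters )\n")
  cat("  alpha =", x$alpha, " kappa_basis =", x$kappa_basis,
      " n_basis =", x$n_basis, " beta =", x$beta_softmax, "\n")
  if (x$variant %in% c("reset", "dual_alpha")) {
    cat("  reset_threshold0 =", x$reset_threshold0,
        " volatility =", x$volatility, "\n")
  }
  if (x$variant %in% c("wslf", "wsls")) {
    cat("  reward_threshold =", x$reward_threshold, "\n")
  }
  invisible(x)
}

# equally spaced basis centers, first at 0
basis_centers <- function(n_basis) {
  canonical_angle(2 * pi * (seq_len(n_basis) - 1L) / n_basis)
}

# basis activations x_i(theta): von Mises densities at the centers.
# theta may be a vector; returns length(theta) x n_basis matrix.
basis_activation <- function(theta, params) {
  mu <- basis_centers(params$n_basis)
  outer(theta, mu, function(th, m) {
    von_mises_density(th, m, params$kappa_basis)
  })
}

#' Initialize agent state
#'
#' Weights start at 0 (flat value function); the reset clock starts at 1,
#' so the reset threshold starts high and decays toward its asymptote —
#' fresh zero weights are already a "reset" state.
#'
#' @param params An [agent_params()] object.
#' @return An `agent_state` list: `weights`, `trials_since_reset`,
#'   `prev_chosen`, `wsl_template` (WSLF/WSLS remembered color or `NA`),
#'   `last_rpe`.
#' @export
agent_init <- function(params) {
  structure(
    list(weights = rep(0, params$n_basis),
         trials_since_reset = 1L,
         prev_chosen = NA_real_,
         wsl_template = NA_real_,
         last_rpe = NA_real_),
    class = "agent_state")
}

#' Expected value function over colors
#'
#' `v(theta) = sum_i w_i x_i(theta)` — the linear function-approximation
#' value of each color (before any choice biases). For WSLF/WSLS agents the
#' "value" is the proximity `pi - |d(theta, remembered)|` to the remembered
#' template (0 everywhere when forgotten).
#'
#' @param state An [agent_init()] state.
#' @param params An [agent_params()] object.
#' @param theta Colors at which to evaluate, radians.
#' @return Numeric vector of values, same length as `theta`.
#' @export
value_function <- function(state, params, theta) {
  if (params$variant %in% c("wslf", "wsls")) {
    if (is.na(state$wsl_template)) return(rep(0, length(theta)))
    return(params$wsl_gain *
             (pi - abs(angular_distance(theta, state$wsl_template))))
  }
  drop(basis_activation(theta, params) %*% state$weights)
}

#' Expected value of each option including choice biases
#'
#' Adds to `v(theta)` the location bias of the occupied slot, the size bias
#' if the stimulus was displayed smaller/bigger, and proximity biases to a
#' preferred color and to the previously chosen color (the latter is 0 on
#' the first trial of a session, and is never used by WSLF/WSLS).
#'
#' @inheritParams value_function
#' @param colors Colors of the (usually 3) options, radians.
#' @param locations Integer slots 1–4 of each option.
#' @param sizes Integer per option: 0 standard, 1 smaller, 2 bigger.
#' @return Numeric vector of expected values, one per option.
#' @export
expected_value <- function(state, params, colors, locations,
                           sizes = rep(0L, length(colors))) {
  ev <- value_function(state, params, colors) +
    params$location_bias[locations] +
    ifelse(sizes > 0L, params$size_bias[pmax(sizes, 1L)], 0) +
    params$pref_color_bias *
      (pi - abs(angular_distance(colors, params$theta_pref)))
  if (!(params$variant %in% c("wslf", "wsls")) &&
      !is.na(state$prev_chosen)) {
    ev <- ev + params$prev_color_bias *
      (pi - abs(angular_distance(colors, state$prev_chosen)))
  }
  ev
}

#' Softmax choice probabilities
#'
#' `P(j) = exp(EV_j / beta) / sum_i exp(EV_i / beta)`; computed with the
#' max subtracted for numerical stability, so it is exactly invariant to
#' adding a constant to all values.
#'
#' @param ev Numeric vector of option values.
#' @param beta Softmax temperature, `> 0`.
#' @return Probabilities summing to 1.
#' @export
choice_probabilities <- function(ev, beta = 0.3) {
  if (any(!is.finite(ev))) stop("non-finite option values", call. = FALSE)
  stopifnot(beta > 0)
  z <- exp((ev - max(ev)) / beta)
  z / sum(z)
}

#' One learning update after an outcome
#'
#' Computes the reward prediction error `RPE = R - v(chosen)`, the reset
#' fraction `k = plogis(beta_reset * (|RPE| - threshold))` with
#' `threshold = reset_threshold0 / tanh(volatility * trials_since_reset)`,
#' and the weight update
#' `w' = (1 - k) * (w + alpha * RPE * x(chosen)) + k * R * x(chosen)`.
#' The `no_reset` variant forces `k = 0`; `dual_alpha` uses `alpha_neg`
#' when RPE is negative. WSLF/WSLS agents instead apply their stay /
#' forget / shift rule. The reset clock resets to 1 when `k` rounds to 1.
#'
#' @inheritParams value_function
#' @param chosen Chosen color, radians.
#' @param reward Received reward, drops (`>= 0`).
#' @return A list: `state` (updated), `rpe`, `reset` (logical),
#'   `k_reset` (the continuous fraction).
#' @export
agent_update <- function(state, params, chosen, reward) {
  stopifnot(reward >= 0)
  chosen <- canonical_angle(chosen)
  if (params$variant %in% c("wslf", "wsls")) {
    if (reward >= params$reward_threshold) {
      state$wsl_template <- chosen
    } else if (params$variant == "wslf") {
      state$wsl_template <- NA_real_
    } else {
      state$wsl_template <- canonical_angle(chosen + pi)
    }
    state$prev_chosen <- chosen
    state$last_rpe <- NA_real_
    return(list(state = state, rpe = NA_real_, reset = FALSE, k_reset = 0))
  }
  x <- drop(basis_activation(chosen, params))
  rpe <- reward - sum(state$weights * x)
  if (params$variant == "no_reset") {
    k <- 0
  } else {
    thr <- params$reset_threshold0 /
      tanh(params$volatility * state$trials_since_reset)
    k <- stats::plogis(params$beta_reset * (abs(rpe) - thr))
  }
  a <- params$alpha
  if (params$variant == "dual_alpha" && rpe < 0) a <- params$alpha_neg
  state$weights <- (1 - k) * (state$weights + a * rpe * x) +
    k * reward * x
  reset <- k >= 0.5
  state$trials_since_reset <-
    if (reset) 1L else state$trials_since_reset + 1L
  state$prev_chosen <- chosen
  state$last_rpe <- rpe
  list(state = state, rpe = rpe, reset = reset, k_reset = k)
}

#' Estimated attentional template
#'
#' The color with the highest value on the wheel grid (argmax of
#' `v(theta)`); ties are broken by the lowest grid index, so an all-zero
#' value function returns the first wheel color.
#'
#' @inheritParams value_function
#' @param wheel Wheel grid from [color_wheel()].
#' @return A single angle in `[-pi, pi)`.
#' @export
estimated_template <- function(state, params, wheel = color_wheel()) {
  wheel[which.max(value_function(state, params, wheel))]
}

#' Entropy of the value function
#'
#' The value function is shifted to be strictly positive
#' (`V - min(V) + 1/n_colors`), normalized to a density over the circle by
#' a Riemann sum on the wheel grid, and its differential entropy
#' `-sum(P log P) dtheta` returned in nats. A flat value function gives
#' `log(2*pi)`; the entropy is invariant to adding a constant to `v` and
#' falls as the value function concentrates.
#'
#' @inheritParams estimated_template
#' @return Entropy in nats.
#' @export
value_entropy <- function(state, params, wheel = color_wheel()) {
  v <- value_function(state, params, wheel)
  n <- length(wheel)
  dth <- 2 * pi / n
  p <- v - min(v) + 1 / n
  p <- p / sum(p * dth)
  -sum(p * log(p)) * dth
}
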
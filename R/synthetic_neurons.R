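#' Latent model variables of a session
#'
#' Replays the model on a recorded session and returns the full latent
#' value function per trial — the regressor source for the neural encoding
#' analyses and the synthetic-population generator.
#'
#' @param params An [agent_params()] object (the generative or fitted
#'   parameters).
#' @param session A `session_record`.
#' @param wheel Wheel grid.
#' @return A list: `est_template` (per-trial argmax color), `values`
#'   (trial x wheel-color matrix of `v(theta, t)` *after* the trial's
#'   update), `mean_value`, `rpe`, `reset`, `entropy`, `chosen_color`.
#' @export
latent_values <- function(params, session, wheel = color_wheel()) {
  tr <- negative_log_likelihood(params, session, traces = TRUE)
  b <- basis_activation(wheel, params)          # n_colors x n_basis
  values <- tr$weight_traj %*% t(b)             # trials x n_colors
  list(est_template = tr$est_template, values = values,
       mean_value = rowMeans(values), rpe = tr$rpe, reset = tr$reset,
       entropy = tr$entropy, chosen_color = session$chosen_color)
}

#' Time base of a synthetic recording
#'
#' Bin centers of `n_bins` windows of `bin_ms` milliseconds, the first
#' starting at `start_ms` relative to target onset. The default covers
#' -600 to +600 ms in 200-ms bins.
#'
#' @param n_bins,bin_ms,start_ms Bin count, width (ms) and first edge (ms).
#' @return Numeric vector of bin-center times in ms.
#' @export
time_bins <- function(n_bins = 6L, bin_ms = 200, start_ms = -600) {
  start_ms + bin_ms / 2 + bin_ms * (seq_len(n_bins) - 1L)
}

#' Build a table of synthetic neuron specifications
#'
#' Each neuron carries a ground-truth encoding model mirroring the
#' single-neuron analyses:
#' `template` (von Mises tuning to the trial's estimated template),
#' `expected_value` (tuned integral of the value function),
#' `mean_value` (linear in the mean value), `chosen_color` (tuning to the
#' chosen color), `value_at_location` / `choice_at_location`
#' (location-specific stimulus value / choice indicator), or `untuned`.
#'
#' @param n Number of neurons.
#' @param mix Named numeric of mixture weights over encoding types
#'   (normalized internally). Defaults echo typical tuned proportions
#'   (~30% template, ~25% expected value).
#' @param gain Modulation gain (rate units per regressor unit).
#' @param baseline Baseline rate.
#' @param noise `"gaussian"` or `"poisson"`.
#' @param sigma Gaussian noise SD (z-scored rate units).
#' @param kappa_range Tuning concentrations drawn log-uniform as `10^rho`,
#'   `rho` uniform in this range.
#' @param latency,width First modulated bin (1-based) and number of
#'   modulated bins; recycled across neurons.
#' @param n_bins Number of time bins the population will be generated for.
#' @return A tibble with one row per neuron: `neuron`, `encoding`,
#'   `theta0`, `kappa_tune`, `gain`, `baseline`, `noise`, `sigma`,
#'   `latency`, `width`, `location`, `hemisphere`.
#' @export
neuron_specs <- function(n = 150L,
                         mix = c(template = 0.30, expected_value = 0.25,
                                 mean_value = 0.10, chosen_color = 0.15,
                                 untuned = 0.20),
                         gain = 2, baseline = 5, noise = "gaussian",
                         sigma = 1, kappa_range = c(-0.3, 0.7),
                         latency = 3L, width = 4L, n_bins = 6L) {
  mix <- mix / sum(mix)
  enc <- sample(names(mix), n, replace = TRUE, prob = mix)
  tibble::tibble(
    neuron = seq_len(n),
    encoding = enc,
    theta0 = stats::runif(n, -pi, pi),
    kappa_tune = 10^stats::runif(n, kappa_range[1], kappa_range[2]),
    gain = rep_len(gain, n),
    baseline = rep_len(baseline, n),
    noise = rep_len(noise, n),
    sigma = rep_len(sigma, n),
    latency = pmin(rep_len(as.integer(latency), n), n_bins),
    width = rep_len(as.integer(width), n),
    location = sample(4L, n, replace = TRUE),
    hemisphere = sample(c("L", "R"), n, replace = TRUE))
}

# per-trial regressor implied by one neuron's encoding spec
spec_regressor <- function(spec, session, lat, wheel) {
  n <- nrow(session)
  switch(spec$encoding,
    template = von_mises_density(lat$est_template, spec$theta0,
                                 spec$kappa_tune),
    expected_value = {
      w <- von_mises_density(wheel, spec$theta0, spec$kappa_tune)
      drop(lat$values %*% w) * (2 * pi / length(wheel))
    },
    mean_value = lat$mean_value,
    chosen_color = von_mises_density(session$chosen_color, spec$theta0,
                                     spec$kappa_tune),
    value_at_location = {
      value_at_loc(session, lat, spec$location, wheel)
    },
    choice_at_location = {
      locs <- cbind(session$loc1, session$loc2, session$loc3)
      as.numeric(locs[cbind(seq_len(n), session$chosen_idx)] ==
                   spec$location)
    },
    untuned = rep(0, n),
    stop("unknown encoding type: ", spec$encoding))
}

# value of the stimulus displayed at a location (0 when unoccupied)
value_at_loc <- function(session, lat, location, wheel = color_wheel()) {
  n <- nrow(session)
  locs <- cbind(session$loc1, session$loc2, session$loc3)
  cols <- cbind(session$color1, session$color2, session$color3)
  out <- numeric(n)
  hit <- locs == location
  any_hit <- rowSums(hit) > 0L
  j <- max.col(hit, ties.method = "first")
  ci <- wheel_index(cols[cbind(seq_len(n), j)], length(wheel))
  out[any_hit] <- lat$values[cbind(seq_len(n), ci)][any_hit]
  out
}

#' Generate a synthetic population recording
#'
#' Produces a trial x neuron x time-bin firing-rate array in which each
#' neuron follows its ground-truth encoding model
#' (`rate = baseline + gain * regressor` within the neuron's modulated
#' bins) plus Gaussian or Poisson noise. Latent regressors come from
#' replaying `params` on the session.
#'
#' @param session A `session_record` with recorded choices and rewards.
#' @param specs A [neuron_specs()] tibble.
#' @param params Agent parameters used to reconstruct latent values
#'   (defaults to the generative parameters attached to the session).
#' @param n_bins Number of 200-ms bins ([time_bins()]).
#' @param wheel Wheel grid.
#' @return A `population_recording`: list with `rates`
#'   (trial x neuron x bin array), `trials` (the session tibble), `specs`,
#'   `time` (bin centers, ms), `regressors` (trial x neuron matrix of the
#'   noiseless ground-truth regressor).
#' @export
generate_population <- function(session, specs,
                                params = attr(session, "agent_params"),
                                n_bins = 6L, wheel = color_wheel()) {
  if (is.null(params)) {
    stop("no agent params attached to session; pass `params`",
         call. = FALSE)
  }
  lat <- latent_values(params, session, wheel)
  n <- nrow(session); m <- nrow(specs)
  rates <- array(0, dim = c(n, m, n_bins))
  reg <- matrix(0, n, m)
  for (i in seq_len(m)) {
    sp <- specs[i, ]
    r <- spec_regressor(sp, session, lat, wheel)
    reg[, i] <- r
    bins_on <- seq.int(sp$latency,
                       min(sp$latency + sp$width - 1L, n_bins))
    for (b in seq_len(n_bins)) {
      mu <- sp$baseline + if (b %in% bins_on) sp$gain * r else 0
      rates[, i, b] <- if (sp$noise == "poisson") {
        stats::rpois(n, pmax(mu, 0))
      } else {
        mu + stats::rnorm(n, 0, sp$sigma)
      }
    }
  }
  structure(list(rates = rates, trials = session, specs = specs,
                 time = time_bins(n_bins), regressors = reg),
            class = "population_recording")
}

#' @export
print.population_recording <- function(x, ...) {
  d <- dim(x$rates)
  cat("<population_recording>", d[1], "trials x", d[2], "neurons x",
      d[3], "time bins\n")
  cat("  encodings:",
      paste(names(table(x$specs$encoding)),
            table(x$specs$encoding), collapse = ", "), "\n")
  invisible(x)
}

#' Long-format view of a population recording
#'
#' @param x A `population_recording`.
#' @param ... Unused.
#' @return A tibble: `trial`, `neuron`, `time_ms`, `rate`.
#' @export
tidy.population_recording <- function(x, ...) {
  d <- dim(x$rates)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    neuron = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time_ms = rep(x$time, each = d[1] * d[2]),
    rate = as.vector(x$rates))
}

#' Hemifield value-coding fixture with a local-to-global lag
#'
#' Generates a population in which neurons first code the value of the
#' chosen (and unchosen) stimulus only within their receptive-field
#' location ("local" stage), and `lag_bins` later the same loadings also
#' code chosen value regardless of location ("global" stage). Because the
#' local and global stages share per-neuron loadings, the disattenuated
#' local-to-global alignment becomes detectable exactly when the global
#' stage switches on; with `lag_bins = 0` the two are aligned from the
#' first coding bin. Ipsilateral coding is scaled by `ipsi_gain` (0 keeps
#' value coding strictly contralateral).
#'
#' @param session A `session_record`.
#' @param n_neurons Neurons per population.
#' @param params Agent parameters for the latent values.
#' @param n_bins Number of time bins.
#' @param onset_bin First bin (1-based) of local value coding.
#' @param lag_bins Bins between local onset and global onset.
#' @param gain,unchosen_gain Loading scale for chosen / highest-unchosen
#'   value coding.
#' @param ipsi_gain Multiplier on loadings of ipsilateral-RF neurons.
#' @param sigma Gaussian noise SD.
#' @param baseline Baseline rate.
#' @return A `population_recording` whose `specs` carry `rf_location` and
#'   `hemisphere`; loadings in the `loadings` element.
#' @export
generate_hemifield_value_population <- function(session, n_neurons = 120L,
    params = attr(session, "agent_params"), n_bins = 6L, onset_bin = 3L,
    lag_bins = 2L, gain = 1.5, unchosen_gain = 1, ipsi_gain = 1,
    sigma = 0.5, baseline = 5) {
  lat <- latent_values(params, session)
  n <- nrow(session)
  locs <- cbind(session$loc1, session$loc2, session$loc3)
  chosen_loc <- locs[cbind(seq_len(n), session$chosen_idx)]
  chosen_val <- lat$values[cbind(seq_len(n),
                                 wheel_index(session$chosen_color))]
  # highest-value unchosen stimulus and its location, per trial
  unch_val <- numeric(n); unch_loc <- integer(n)
  cols <- cbind(session$color1, session$color2, session$color3)
  for (j in 1:3) {
    v <- lat$values[cbind(seq_len(n), wheel_index(cols[, j]))]
    take <- j != session$chosen_idx & v > unch_val
    unch_val[take] <- v[take]; unch_loc[take] <- locs[take, j]
  }
  # single left-hemisphere population: right-screen locations 1 (45 deg)
  # and 4 (315 deg) are contralateral, 2 and 3 ipsilateral
  rf_loc <- sample(4L, n_neurons, replace = TRUE)
  hemi <- rep("L", n_neurons)
  contra <- rf_loc %in% c(1L, 4L)
  # before the lag the local code is a within-hemifield contrast (+w at
  # the RF location, -w at the paired location), so it cancels in the
  # location-agnostic global regression; at the lag the loadings rotate
  # onto the shared global axis
  pair_of <- c(4L, 3L, 2L, 1L)
  w_local <- stats::rnorm(n_neurons, 0, gain)
  w_global <- stats::rnorm(n_neurons, 0, gain)
  u <- stats::rnorm(n_neurons, 0, unchosen_gain)
  scale_i <- ifelse(contra, 1, ipsi_gain)
  rates <- array(0, dim = c(n, n_neurons, n_bins))
  global_on <- onset_bin + lag_bins
  for (i in seq_len(n_neurons)) {
    local_ch <- (chosen_loc == rf_loc[i]) * chosen_val
    local_ch_pair <- (chosen_loc == pair_of[rf_loc[i]]) * chosen_val
    local_un <- (unch_loc == rf_loc[i]) * unch_val
    for (b in seq_len(n_bins)) {
      mu <- baseline
      if (b >= onset_bin && b < global_on) {
        mu <- mu + scale_i[i] *
          (w_local[i] * (local_ch - local_ch_pair) + u[i] * local_un)
      }
      if (b >= global_on) {
        mu <- mu + scale_i[i] *
          (w_global[i] * local_ch + u[i] * local_un) +
          w_global[i] * chosen_val
      }
      rates[, i, b] <- mu + stats::rnorm(n, 0, sigma)
    }
  }
  w <- w_global
  specs <- tibble::tibble(neuron = seq_len(n_neurons),
                          encoding = "hemifield_value",
                          rf_location = rf_loc, hemisphere = hemi,
                          gain = w, unchosen_gain = u,
                          baseline = baseline, sigma = sigma)
  structure(list(rates = rates, trials = session, specs = specs,
                 time = time_bins(n_bins),
                 loadings = list(chosen = w, unchosen = u),
                 onset_bin = onset_bin, lag_bins = lag_bins),
            class = "population_recording")
}

#' Plot the latent value function over trials
#'
#' Heatmap of `v(theta, t)` across a session with the estimated template
#' and the true template overlaid — the standard picture of template
#' drift and resets during learning.
#'
#' @param session A `session_record`.
#' @param params Agent parameters (default: the attached generative or
#'   fitted ones).
#' @param trials Optional trial-range subset.
#' @return A ggplot object.
#' @export
plot_value_trace <- function(session,
                             params = attr(session, "agent_params"),
                             trials = NULL) {
  lat <- latent_values(params, session)
  wheel <- color_wheel(ncol(lat$values))
  keep <- trials %||% seq_len(nrow(session))
  df <- tidyr::expand_grid(trial = keep, color = wheel)
  df$value <- as.vector(t(lat$values[keep, , drop = FALSE]))
  overlay <- tibble::tibble(trial = keep,
                            est = lat$est_template[keep],
                            true = session$template[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$color,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = overlay, inherit.aes = FALSE,
                        ggplot2::aes(x = .data$trial, y = .data$est),
                        size = 0.3, colour = "white") +
    ggplot2::geom_line(data = overlay, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$trial, y = .data$true),
                       colour = "red", linetype = "dashed") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Trial", y = "Color (rad)", fill = "v") +
    ggplot2::theme_minimal()
}
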
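#' Block specification for the task
#'
#' The hidden template color is fixed within a block. A block ends (and the
#' template switches, uncued) once the subject has chosen the best target
#' (the stimulus closest to the true template) on at least
#' `criterion_frac` of the last `criterion_window` trials, the block has at
#' least `min_trials` trials, — or once `max_trials` is reached.
#'
#' @param criterion_frac Fraction of best choices required (0.85 by
#'   default, the stricter of the two animals' 0.80/0.85 settings).
#' @param criterion_window Rolling window in trials (30).
#' @param min_trials Minimum attempted trials per block (35).
#' @param max_trials Hard cap on block length.
#' @param r_max Maximum reward scale in drops (6 = fixed scheme). Set
#'   `r_max_increment > 0` for the escalating scheme (base + increment per
#'   completed block).
#' @param r_max_increment Drops added to `r_max` per completed block (0).
#' @param kappa_reward Concentration of the reward profile (2.5).
#' @param size_change_prob Probability that one stimulus is displayed
#'   bigger or smaller (0.05; 0.20 for the other animal's scheme).
#' @return A `block_spec` list.
#' @export
block_spec <- function(criterion_frac = 0.85, criterion_window = 30L,
                       min_trials = 35L, max_trials = 400L,
                       r_max = 6L, r_max_increment = 0L,
                       kappa_reward = 2.5, size_change_prob = 0.05) {
  stopifnot(criterion_frac > 0, criterion_frac <= 1, min_trials >= 1L,
            max_trials >= min_trials, r_max >= 0)
  structure(list(criterion_frac = criterion_frac,
                 criterion_window = as.integer(criterion_window),
                 min_trials = as.integer(min_trials),
                 max_trials = as.integer(max_trials),
                 r_max = as.integer(r_max),
                 r_max_increment = as.integer(r_max_increment),
                 kappa_reward = kappa_reward,
                 size_change_prob = size_change_prob),
            class = "block_spec")
}

#' Sample the stimuli of one trial
#'
#' Draws 3 colors from the wheel by rejection until all pairwise circular
#' distances are at least `min_separation` (pi/6 in the task), and 3
#' distinct locations uniformly from the 4 slots. With probability
#' `size_change_prob` one stimulus is marked bigger or smaller.
#'
#' @param min_separation Minimum pairwise color distance, radians.
#' @param wheel Wheel grid from [color_wheel()].
#' @param size_change_prob Probability of a size perturbation.
#' @return A one-row tibble: `color1..3`, `loc1..3`, `size_stim` (0 =
#'   none, else option index), `size_type` (0 none, 1 smaller, 2 bigger).
#' @export
sample_trial <- function(min_separation = pi / 6, wheel = color_wheel(),
                         size_change_prob = 0) {
  if (3 * min_separation >= 2 * pi) {
    stop("infeasible separation: 3 colors cannot be that far apart",
         call. = FALSE)
  }
  repeat {
    colors <- sample(wheel, 3L, replace = FALSE)
    d <- abs(angular_distance(colors[c(1, 1, 2)], colors[c(2, 3, 3)]))
    if (all(d >= min_separation)) break
  }
  locs <- sample(4L, 3L)
  size_stim <- 0L; size_type <- 0L
  if (stats::runif(1) < size_change_prob) {
    size_stim <- sample(3L, 1L)
    size_type <- sample(2L, 1L)
  }
  tibble::tibble(color1 = colors[1], color2 = colors[2],
                 color3 = colors[3],
                 loc1 = locs[1], loc2 = locs[2], loc3 = locs[3],
                 size_stim = size_stim, size_type = size_type)
}

#' Sample a new template color
#'
#' Uniform over the wheel, with colors within `window` of recent templates
#' down-weighted by `weight` so a session covers the wheel broadly. If the
#' whole wheel is penalized to weight 0 the draw falls back to uniform.
#'
#' @param history Angles of templates already used this session.
#' @param wheel Wheel grid.
#' @param window Penalization half-width, radians (pi/4).
#' @param weight Relative sampling weight inside the window (0.2).
#' @return A single angle.
#' @export
sample_template <- function(history = numeric(), wheel = color_wheel(),
                            window = pi / 4, weight = 0.2) {
  w <- rep(1, length(wheel))
  for (h in history) {
    w[abs(angular_distance(wheel, h)) < window] <- weight
  }
  if (all(w <= 0)) w <- rep(1, length(wheel))
  sample(wheel, 1L, prob = w)
}

#' Simulate a session of the template-learning task
#'
#' Runs `n_blocks` blocks of the task with a learning agent: on each trial,
#' stimuli are sampled, the agent chooses by softmax over its expected
#' values, reward is delivered from the von Mises profile around the hidden
#' template, and the agent updates. The template switches (uncued) when the
#' rolling best-choice criterion is met ([block_spec()]).
#'
#' Set `choose` to override the agent's policy, e.g.
#' `choose = function(ev, best) best` yields an oracle that always takes
#' the best target.
#'
#' @param params An [agent_params()] object.
#' @param n_blocks Number of blocks to simulate.
#' @param spec A [block_spec()].
#' @param wheel Wheel grid.
#' @param min_separation Minimum pairwise stimulus color distance.
#' @param latents If `TRUE` (default), record the model's latent traces
#'   (estimated template, RPE, resets, value entropy) per trial.
#' @param choose Optional `function(ev, best_idx)` returning the chosen
#'   option index 1–3; default samples from the softmax.
#' @param templates Optional vector of template colors to use per block
#'   (bypasses [sample_template()]).
#' @param n_trials Optional total-trial cap: blocks keep running (up to
#'   `n_blocks`) until this many trials have been recorded, and the
#'   session is cut there.
#' @return A `session_record` tibble, one row per trial: `block`, `trial`,
#'   `trial_in_block`, `template`, `color1..3`, `loc1..3`, `size_stim`,
#'   `size_type`, `chosen_idx`, `chosen_color`, `reward`, `best_idx`,
#'   `best_chosen`, and latent columns `est_template`, `rpe`, `reset`,
#'   `entropy` when `latents = TRUE`. The [agent_params()] used, the
#'   [block_spec()] and the final agent state are attached as attributes.
#' @export
run_session <- function(params, n_blocks = 10L, spec = block_spec(),
                        wheel = color_wheel(), min_separation = pi / 6,
                        latents = TRUE, choose = NULL,
                        templates = NULL, n_trials = NULL) {
  state <- agent_init(params)
  blocks <- list()
  history <- numeric()
  trial_global <- 0L
  b <- 0L
  mt <- spec$max_trials
  win <- spec$criterion_window
  while (b < n_blocks &&
         (is.null(n_trials) || trial_global < n_trials)) {
    b <- b + 1L
    template <- if (!is.null(templates)) {
      canonical_angle(templates[b])
    } else {
      sample_template(history, wheel)
    }
    history <- c(history, template)
    r_max <- spec$r_max + spec$r_max_increment * (b - 1L)
    # preallocated per-block storage (tibble built once per block)
    col_m <- matrix(0, mt, 3L); loc_m <- matrix(0L, mt, 3L)
    size_stim <- integer(mt); size_type <- integer(mt)
    chosen_idx <- integer(mt); reward_v <- numeric(mt)
    best_idx_v <- integer(mt); best_v <- logical(mt)
    n_done <- 0L
    for (t in seq_len(mt)) {
      trial_global <- trial_global + 1L
      # rejection-sample 3 wheel colors with pairwise separation
      repeat {
        colors <- wheel[sample.int(length(wheel), 3L)]
        d <- abs(angular_distance(colors[c(1, 1, 2)], colors[c(2, 3, 3)]))
        if (all(d >= min_separation)) break
      }
      locs <- sample.int(4L, 3L)
      sizes <- integer(3L)
      if (spec$size_change_prob > 0 &&
          stats::runif(1) < spec$size_change_prob) {
        size_stim[t] <- sample.int(3L, 1L)
        size_type[t] <- sample.int(2L, 1L)
        sizes[size_stim[t]] <- size_type[t]
      }
      ev <- expected_value(state, params, colors, locs, sizes)
      # best target = closest to the true template; ties -> lowest index
      best_idx <- which.min(abs(angular_distance(colors, template)))
      j <- if (is.null(choose)) {
        sample(3L, 1L, prob = choice_probabilities(ev, params$beta_softmax))
      } else {
        choose(ev, best_idx)
      }
      reward <- reward_function(colors[j], template,
                                kappa = spec$kappa_reward, r_max = r_max)
      upd <- agent_update(state, params, colors[j], reward)
      state <- upd$state
      col_m[t, ] <- colors; loc_m[t, ] <- locs
      chosen_idx[t] <- j; reward_v[t] <- reward
      best_idx_v[t] <- best_idx; best_v[t] <- j == best_idx
      n_done <- t
      # criterion: >= frac best choices over the last `window` trials,
      # never before `window` choices exist, nor before min_trials
      if (!is.null(n_trials) && trial_global >= n_trials) break
      if (t >= spec$min_trials && t >= win &&
          sum(best_v[(t - win + 1L):t]) >= spec$criterion_frac * win) {
        break
      }
    }
    s <- seq_len(n_done)
    blocks[[b]] <- tibble::tibble(
      block = b, trial = trial_global - n_done + s, trial_in_block = s,
      template = template,
      color1 = col_m[s, 1], color2 = col_m[s, 2], color3 = col_m[s, 3],
      loc1 = loc_m[s, 1], loc2 = loc_m[s, 2], loc3 = loc_m[s, 3],
      size_stim = size_stim[s], size_type = size_type[s],
      chosen_idx = chosen_idx[s],
      chosen_color = col_m[cbind(s, chosen_idx[s])],
      reward = reward_v[s], best_idx = best_idx_v[s], best_chosen = best_v[s])
  }
  out <- dplyr::bind_rows(blocks)
  attr(out, "wheel_size") <- length(wheel)
  if (latents) {
    tr <- negative_log_likelihood(params, out, traces = TRUE)
    out$est_template <- tr$est_template
    out$rpe <- tr$rpe
    out$reset <- tr$reset
    out$entropy <- tr$entropy
  }
  attr(out, "agent_params") <- params
  attr(out, "block_spec") <- spec
  attr(out, "final_state") <- state
  class(out) <- c("session_record", class(out))
  out
}

#' Write / read a session record as CSV + JSON sidecar
#'
#' The CSV holds one row per trial; the sidecar stores the agent
#' parameters, block spec and wheel size so a session round-trips.
#'
#' @param session A `session_record` tibble from [run_session()].
#' @param path CSV path; the sidecar is written at `paste0(path, ".json")`.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   the session tibble with config attributes restored.
#' @export
write_session <- function(session, path) {
  utils::write.csv(as.data.frame(session), path, row.names = FALSE)
  side <- list(
    agent_params = unclass(attr(session, "agent_params")),
    block_spec = unclass(attr(session, "block_spec")),
    wheel_size = attr(session, "wheel_size"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    ap <- side$agent_params
    attr(out, "agent_params") <- agent_params(
      variant = ap$variant, alpha = ap$alpha,
      kappa_basis = ap$kappa_basis, n_basis = ap$n_basis,
      beta_softmax = ap$beta_softmax,
      reset_threshold0 = ap$reset_threshold0, volatility = ap$volatility,
      beta_reset = ap$beta_reset, location_bias = ap$location_bias,
      size_bias = ap$size_bias, pref_color_bias = ap$pref_color_bias,
      theta_pref = ap$theta_pref, prev_color_bias = ap$prev_color_bias,
      alpha_neg = ap$alpha_neg, reward_threshold = ap$reward_threshold,
      wsl_gain = ap$wsl_gain)
    bs <- side$block_spec
    attr(out, "block_spec") <- do.call(block_spec, bs)
    attr(out, "wheel_size") <- side$wheel_size
  }
  class(out) <- c("session_record", class(out))
  out
}

#' Learning curve around template switches
#'
#' Probability of choosing the best target as a function of trial position
#' within the block, pooled across blocks — the behavioral signature of
#' template learning.
#'
#' @param session A `session_record`.
#' @param max_trial Truncate at this within-block trial.
#' @return A tibble: `trial_in_block`, `p_best`, `n_blocks`.
#' @export
learning_curve <- function(session, max_trial = 60L) {
  session |>
    dplyr::filter(.data$trial_in_block <= max_trial) |>
    dplyr::group_by(trial_in_block = .data$trial_in_block) |>
    dplyr::summarise(p_best = mean(.data$best_chosen),
                     n_blocks = dplyr::n(), .groups = "drop")
}

#' Plot a session's learning curve
#'
#' @param session A `session_record`.
#' @param max_trial Truncate at this within-block trial.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(session, max_trial = 60L) {
  lc <- learning_curve(session, max_trial)
  ggplot2::ggplot(lc, ggplot2::aes(x = .data$trial_in_block,
                                   y = .data$p_best)) +
    ggplot2::geom_hline(yintercept = 1 / 3, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Trial in block", y = "P(best target chosen)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
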
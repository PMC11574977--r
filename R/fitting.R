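#' @useDynLib templateRL, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

# session tibble -> integer/double arrays for the C++ forward pass
session_arrays <- function(session, n_colors = NULL) {
  if (is.null(n_colors)) n_colors <- attr(session, "wheel_size") %||% 100L
  col <- cbind(session$color1, session$color2, session$color3)
  idx <- matrix(wheel_index(col, n_colors) - 1L, ncol = 3L)
  loc <- cbind(session$loc1, session$loc2, session$loc3) - 1L
  sz <- matrix(0L, nrow(session), 3L)
  pick <- which(session$size_stim > 0L)
  sz[cbind(pick, session$size_stim[pick])] <- session$size_type[pick]
  list(idx = idx, loc = loc, sizes = sz,
       chosen = as.integer(session$chosen_idx) - 1L,
       reward = as.numeric(session$reward),
       colors = col, n_colors = as.integer(n_colors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

variant_code <- function(variant) {
  switch(variant, no_reset = 0L, reset = 1L, dual_alpha = 2L,
         stop("no C++ forward pass for variant ", variant))
}

# agent_params -> 14-slot natural-unit vector for the C++ forward pass
par14 <- function(p) {
  c(p$alpha, p$kappa_basis, p$reset_threshold0, p$volatility,
    p$location_bias, p$size_bias, p$pref_color_bias, p$theta_pref,
    p$prev_color_bias, p$alpha_neg %||% p$alpha)
}

#' Negative log likelihood of a session under a model
#'
#' Forward-simulates the latent learning state deterministically given the
#' recorded choices and rewards and accumulates `-log P(chosen)` under the
#' softmax policy. With `traces = TRUE` the per-trial latent traces
#' (estimated template, RPE, reset flags, value-function entropy) are
#' returned as well.
#'
#' @param params An [agent_params()] object.
#' @param session A `session_record` tibble ([run_session()] or
#'   [read_session()]).
#' @param traces Return per-trial latent traces.
#' @return With `traces = FALSE`, a single NLL in nats. Otherwise a list
#'   with `nll`, `loglik`, `est_template`, `rpe`, `reset`, `entropy`,
#'   `mean_lik` (the geometric-mean per-trial likelihood `exp(-NLL/n)`).
#' @export
negative_log_likelihood <- function(params, session, traces = FALSE) {
  arr <- session_arrays(session)
  if (params$variant %in% c("wslf", "wsls")) {
    return(nll_wsl(params, arr, traces))
  }
  res <- forward_pass_cpp(par14(params), variant_code(params$variant),
                          params$n_basis, arr$n_colors,
                          params$beta_softmax, params$beta_reset,
                          arr$idx, arr$loc, arr$sizes, arr$chosen,
                          arr$reward, traces)
  if (!traces) return(res$nll)
  res$mean_lik <- exp(-res$nll / length(arr$chosen))
  res
}

# vectorized forward pass for the win-stay-lose-forget / -shift baselines;
# the remembered template after trial t depends only on trial t, so no
# sequential loop over parameters is needed
nll_wsl <- function(params, arr, traces = FALSE) {
  n <- length(arr$chosen)
  chosen_color <- arr$colors[cbind(seq_len(n), arr$chosen + 1L)]
  win <- arr$reward >= params$reward_threshold
  tmpl <- c(NA_real_, ifelse(win[-n], chosen_color[-n],
                             if (params$variant == "wsls") {
                               canonical_angle(chosen_color[-n] + pi)
                             } else NA_real_))
  ev <- matrix(0, n, 3L)
  for (j in 1:3) {
    prox <- pi - abs(angular_distance(arr$colors[, j],
                                      ifelse(is.na(tmpl), 0, tmpl)))
    ev[, j] <- ifelse(is.na(tmpl), 0, params$wsl_gain * prox) +
      params$location_bias[arr$loc[, j] + 1L] +
      ifelse(arr$sizes[, j] > 0L,
             params$size_bias[pmax(arr$sizes[, j], 1L)], 0) +
      params$pref_color_bias *
        (pi - abs(angular_distance(arr$colors[, j], params$theta_pref)))
  }
  s <- ev / params$beta_softmax
  m <- apply(s, 1L, max)
  logp <- s[cbind(seq_len(n), arr$chosen + 1L)] - m -
    log(rowSums(exp(s - m)))
  nll <- -sum(logp)
  if (!traces) return(nll)
  list(nll = nll, loglik = logp,
       est_template = ifelse(is.na(tmpl), NA_real_, tmpl),
       rpe = rep(NA_real_, n), reset = rep(FALSE, n),
       entropy = rep(NA_real_, n), mean_lik = exp(-nll / n))
}

# --- free-parameter packing ------------------------------------------------

# fitted-parameter layout per variant (kappa fitted as rho = log10 kappa)
free_param_names <- function(variant) {
  biases <- c("loc_bias2", "loc_bias3", "loc_bias4", "size_bias_small",
              "size_bias_big", "pref_color_bias", "theta_pref")
  switch(variant,
    no_reset = c("alpha", "rho", biases, "prev_color_bias"),
    reset = c("alpha", "rho", "reset_threshold0", "volatility", biases,
              "prev_color_bias"),
    dual_alpha = c("alpha", "alpha_neg", "rho", "reset_threshold0",
                   "volatility", biases, "prev_color_bias"),
    wslf = c("reward_threshold", biases),
    wsls = c("reward_threshold", biases))
}

# lower/upper fit bounds and the (narrower) multi-start sampling range
param_box <- function(variant) {
  nm <- free_param_names(variant)
  lo <- c(alpha = 0, alpha_neg = 0, rho = -2.5, reset_threshold0 = 0,
          volatility = 1e-3, reward_threshold = 0,
          loc_bias2 = -10, loc_bias3 = -10, loc_bias4 = -10,
          size_bias_small = -10, size_bias_big = -10,
          pref_color_bias = -10, theta_pref = -pi,
          prev_color_bias = -10)[nm]
  hi <- c(alpha = 1, alpha_neg = 1, rho = 2.5, reset_threshold0 = 5,
          volatility = 1, reward_threshold = 6,
          loc_bias2 = 10, loc_bias3 = 10, loc_bias4 = 10,
          size_bias_small = 10, size_bias_big = 10,
          pref_color_bias = 10, theta_pref = pi,
          prev_color_bias = 10)[nm]
  slo <- c(alpha = 0.05, alpha_neg = 0.05, rho = -1, reset_threshold0 = 0.1,
           volatility = 0.02, reward_threshold = 0.5,
           loc_bias2 = -0.5, loc_bias3 = -0.5, loc_bias4 = -0.5,
           size_bias_small = -0.5, size_bias_big = -0.5,
           pref_color_bias = -0.5, theta_pref = -pi,
           prev_color_bias = -0.5)[nm]
  shi <- c(alpha = 0.8, alpha_neg = 0.8, rho = 1, reset_threshold0 = 1.5,
           volatility = 0.5, reward_threshold = 4,
           loc_bias2 = 0.5, loc_bias3 = 0.5, loc_bias4 = 0.5,
           size_bias_small = 0.5, size_bias_big = 0.5,
           pref_color_bias = 0.5, theta_pref = pi,
           prev_color_bias = 0.5)[nm]
  list(names = nm, lower = lo, upper = hi, start_lo = slo, start_hi = shi)
}

pack_params <- function(p) {
  v <- c(alpha = p$alpha, alpha_neg = p$alpha_neg %||% p$alpha,
         rho = log10(max(p$kappa_basis, 10^-2.5)),
         reset_threshold0 = p$reset_threshold0,
         volatility = p$volatility,
         reward_threshold = p$reward_threshold,
         loc_bias2 = p$location_bias[2], loc_bias3 = p$location_bias[3],
         loc_bias4 = p$location_bias[4],
         size_bias_small = p$size_bias[1], size_bias_big = p$size_bias[2],
         pref_color_bias = p$pref_color_bias, theta_pref = p$theta_pref,
         prev_color_bias = p$prev_color_bias)
  unname(v[free_param_names(p$variant)])
}

unpack_params <- function(x, variant, n_basis = 6L, beta_softmax = 0.3,
                          beta_reset = 1e4) {
  v <- stats::setNames(x, free_param_names(variant))
  g <- function(nm, default = 0) if (nm %in% names(v)) unname(v[nm]) else default
  agent_params(
    variant = variant,
    alpha = g("alpha"), alpha_neg = g("alpha_neg", NULL),
    kappa_basis = 10^g("rho"),
    n_basis = n_basis, beta_softmax = beta_softmax,
    reset_threshold0 = g("reset_threshold0", 0.5),
    volatility = g("volatility", 0.1), beta_reset = beta_reset,
    location_bias = c(0, g("loc_bias2"), g("loc_bias3"), g("loc_bias4")),
    size_bias = c(g("size_bias_small"), g("size_bias_big")),
    pref_color_bias = g("pref_color_bias"),
    theta_pref = g("theta_pref"),
    prev_color_bias = g("prev_color_bias"),
    reward_threshold = g("reward_threshold", 2))
}

# --- fitting ---------------------------------------------------------------

# fast packed-vector -> 14-slot C++ parameter vector (hot path: no
# agent_params() construction or validation per likelihood evaluation)
packed_to_par14 <- function(variant) {
  switch(variant,
    no_reset = function(x) c(x[1], 10^x[2], 0, 1, 0, x[3], x[4], x[5],
                             x[6], x[7], x[8], x[9], x[10], x[1]),
    reset = function(x) c(x[1], 10^x[2], x[3], x[4], 0, x[5], x[6], x[7],
                          x[8], x[9], x[10], x[11], x[12], x[1]),
    dual_alpha = function(x) c(x[1], 10^x[3], x[4], x[5], 0, x[6], x[7],
                               x[8], x[9], x[10], x[11], x[12], x[13],
                               x[2]))
}

# coarse screen grid over the sharp "dynamics" parameters (learning rate,
# basis concentration, reset threshold/volatility or stay threshold); the
# bias parameters enter the option values linearly and are left at 0 here
dynamics_grid <- function(variant) {
  alpha <- c(0.05, 0.1, 0.2, 0.3, 0.45, 0.65)
  rho <- c(-0.8, -0.4, -0.1, 0.15, 0.4, 0.7, 1.1)
  switch(variant,
    no_reset = tidyr::expand_grid(alpha = alpha, rho = rho),
    reset = ,
    dual_alpha = tidyr::expand_grid(alpha = alpha, rho = rho,
                                    thr = c(0.2, 0.35, 0.55, 0.9, 1.5, 4.5),
                                    vol = c(0.008, 0.02, 0.06, 0.2)),
    wslf = ,
    wsls = tibble::tibble(thr = c(0.5, 1, 1.5, 2, 2.5, 3, 3.5)))
}

# grid row -> full packed start vector (biases 0, theta_pref 0)
grid_to_start <- function(g, variant) {
  nm <- free_param_names(variant)
  x <- stats::setNames(rep(0, length(nm)), nm)
  if ("alpha" %in% names(g)) x["alpha"] <- g$alpha
  if ("alpha_neg" %in% nm) x["alpha_neg"] <- g$alpha
  if ("rho" %in% names(g)) x["rho"] <- g$rho
  if ("thr" %in% names(g)) {
    if ("reset_threshold0" %in% nm) x["reset_threshold0"] <- g$thr
    if ("reward_threshold" %in% nm) x["reward_threshold"] <- g$thr
  }
  if ("vol" %in% names(g)) x["volatility"] <- g$vol
  unname(x)
}

#' Fit a behavioral model to a session by maximum likelihood
#'
#' Multi-start bounded maximum likelihood. The likelihood is extremely
#' sharp in the learning-dynamics parameters (learning rate, basis
#' concentration, reset threshold and volatility) because small changes
#' compound over the whole latent trajectory, while the bias parameters
#' enter the option values linearly and are well behaved. The optimizer
#' therefore (1) screens a coarse grid over the dynamics parameters with
#' biases at 0 and re-ranks the leading cells after profiling the biases
#' at fixed dynamics, (2) runs bounded BFGS, a Nelder-Mead pass on a
#' sinusoidal bound transform (the reset threshold makes the surface
#' piecewise constant in places), and a final BFGS polish from each
#' candidate (top profiled cells, Latin-hypercube draws, and any warm
#' starts), with a second simplex round for the three leading candidates,
#' (3) refines the best solution by coordinate scans over each dynamics
#' parameter (plus a joint threshold-volatility grid), and (4) refines the
#' preferred-color parameters by a dedicated circular scan, since their
#' shallow contribution can strand gradient descent in a local optimum of
#' `theta_pref`. The softmax temperature is fixed at 0.3 and is never
#' fitted. BIC is `n_params * log(n_trials) + 2 * NLL`.
#'
#' @param session A `session_record` tibble.
#' @param variant Model variant (see [agent_params()]).
#' @param n_basis Number of radial basis functions (default 6).
#' @param n_starts Number of polished starts (default 20: the best 18
#'   profiled grid cells plus 2 Latin-hypercube draws).
#' @param maxit_nm Nelder-Mead evaluation budget per start.
#' @param maxit_polish BFGS iteration budget per gradient stage.
#' @param extra_starts List of [agent_params()] (or packed numeric
#'   vectors) used as additional warm starts, e.g. a fitted nested model.
#' @param beta_softmax Fixed softmax temperature.
#' @param screen Run the grid screen/profiling stage (default). With
#'   `FALSE`, only `extra_starts` are used — the economical path for very
#'   long sessions warm-started from a fit to their leading trials.
#' @param verbose Print per-start progress.
#' @return A `template_fit` object: `params` (fitted [agent_params()]),
#'   `neg_log_lik`, `bic`, `n_trials`, `n_params`, `n_starts`,
#'   `converged`, `mean_lik`, `loglik` (per trial), `traces` (tibble of
#'   latent traces under the fitted parameters), `starts` (per-start NLL
#'   table). Supports [tidy()] and [glance()].
#' @export
fit_session <- function(session, variant = "reset", n_basis = 6L,
                        n_starts = 20L, maxit_nm = 400L,
                        maxit_polish = 60L, extra_starts = list(),
                        beta_softmax = 0.3, screen = TRUE,
                        verbose = FALSE) {
  stopifnot(nrow(session) >= 50L)
  if (nrow(session) < 200L) {
    warning("fewer than ~200 trials; parameters may not be identifiable")
  }
  arr <- session_arrays(session)
  box <- param_box(variant)
  k <- length(box$names)

  obj <- if (variant %in% c("wslf", "wsls")) {
    function(x) nll_wsl(unpack_params(x, variant, n_basis, beta_softmax),
                        arr)
  } else {
    vc <- variant_code(variant)
    map14 <- packed_to_par14(variant)
    function(x) {
      forward_pass_cpp(map14(x), vc, n_basis, arr$n_colors, beta_softmax,
                       1e4, arr$idx, arr$loc, arr$sizes,
                       arr$chosen, arr$reward, FALSE)$nll
    }
  }

  # sinusoidal transform keeps Nelder-Mead inside the box
  to_z <- function(x) asin(pmin(pmax(2 * (x - box$lower) /
                                       (box$upper - box$lower) - 1,
                                     -1), 1))
  to_x <- function(z) box$lower +
    (box$upper - box$lower) * (sin(z) + 1) / 2
  obj_z <- function(z) obj(to_x(z))

  # stage 1: coarse dynamics screen (biases 0), then re-rank the top
  # cells after profiling the well-behaved bias parameters at fixed
  # dynamics — the dynamics basin quality is only visible once the
  # biases stop absorbing misfit. With screen = FALSE only the provided
  # warm starts are used (e.g. a fit to a leading subset of a very long
  # session).
  dyn_nm <- intersect(c("alpha", "alpha_neg", "rho", "reset_threshold0",
                        "volatility", "reward_threshold"), box$names)
  if (screen) {
    grid <- dynamics_grid(variant)
    gstart <- t(vapply(seq_len(nrow(grid)),
                       function(i) grid_to_start(grid[i, ], variant),
                       numeric(k)))
    gnll <- apply(gstart, 1L, obj)
    bias_ix <- which(!box$names %in% dyn_nm)
    n_prof <- min(18L, nrow(gstart))
    top <- order(gnll)[seq_len(n_prof)]
    prof <- vapply(top, function(i) {
      x0 <- gstart[i, ]
      r <- tryCatch(
        stats::optim(x0[bias_ix],
                     function(b) { x0[bias_ix] <- b; obj(x0) },
                     method = "L-BFGS-B", lower = box$lower[bias_ix],
                     upper = box$upper[bias_ix],
                     control = list(maxit = 12L)),
        error = function(e) list(value = gnll[i], par = x0[bias_ix]))
      gstart[i, bias_ix] <<- r$par
      r$value
    }, numeric(1))
    n_grid <- min(max(n_starts - 2L, 1L), n_prof)
    n_lhs <- max(n_starts - n_grid, 0L)
    starts <- gstart[top[order(prof)][seq_len(n_grid)], , drop = FALSE]
    if (n_lhs > 0L) starts <- rbind(starts, lhs_starts(n_lhs, box))
  } else {
    if (!length(extra_starts)) {
      stop("screen = FALSE needs at least one warm start", call. = FALSE)
    }
    starts <- matrix(numeric(0), 0L, k)
  }
  for (es in extra_starts) {
    xs <- if (inherits(es, "agent_params")) pack_params(es) else es
    if (length(xs) == k) starts <- rbind(starts, pmin(pmax(xs, box$lower),
                                                      box$upper))
  }

  # stage 2: BFGS -> Nelder-Mead -> BFGS from each start
  lbfgsb <- function(x0, maxit) {
    tryCatch(stats::optim(x0, obj, method = "L-BFGS-B", lower = box$lower,
                          upper = box$upper,
                          control = list(maxit = maxit)),
             error = function(e) list(par = x0, value = obj(x0),
                                      convergence = 52L))
  }
  best <- NULL
  start_tbl <- vector("list", nrow(starts))
  cands <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    r1 <- lbfgsb(starts[s, ], maxit_polish)
    nm <- stats::optim(to_z(r1$par), obj_z, method = "Nelder-Mead",
                       control = list(maxit = maxit_nm))
    x2 <- to_x(nm$par)
    r3 <- if (nm$value < r1$value) lbfgsb(x2, maxit_polish) else r1
    cand <- if (r3$value <= min(r1$value, nm$value)) {
      list(par = r3$par, value = r3$value, converged = r3$convergence == 0)
    } else if (nm$value < r1$value) {
      list(par = x2, value = nm$value, converged = nm$convergence == 0)
    } else {
      list(par = r1$par, value = r1$value, converged = r1$convergence == 0)
    }
    start_tbl[[s]] <- tibble::tibble(start = s, nll = cand$value,
                                     converged = cand$converged)
    if (is.null(best) || cand$value < best$value) best <- cand
    if (verbose) message("start ", s, ": NLL = ", round(cand$value, 2))
    cands[[s]] <- cand
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("all optimization starts failed", call. = FALSE)
  }

  # a second simplex round for the leading candidates: the surface has
  # several near-tied basins and one pass often stalls between them
  lead <- order(vapply(cands, `[[`, numeric(1), "value"))
  for (s in lead[seq_len(min(3L, length(lead)))]) {
    nm2 <- stats::optim(to_z(cands[[s]]$par), obj_z,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit_nm))
    r2 <- lbfgsb(to_x(nm2$par), maxit_polish)
    v <- min(nm2$value, r2$value)
    if (v < best$value) {
      best <- if (r2$value <= nm2$value) {
        list(par = r2$par, value = r2$value,
             converged = r2$convergence == 0)
      } else {
        list(par = to_x(nm2$par), value = nm2$value,
             converged = nm2$convergence == 0)
      }
    }
  }

  # stage 2b: coordinate refinement of the sharp dynamics parameters.
  # 1-D scans (and a joint threshold x volatility scan) escape wrong
  # basins that gradient steps and the simplex cannot leave, at a few
  # hundred likelihood evaluations
  dyn <- intersect(c("alpha", "alpha_neg", "rho", "reset_threshold0",
                     "volatility", "reward_threshold"), box$names)
  for (round in 1:2) {
    for (nm_j in dyn) {
      j <- match(nm_j, box$names)
      grid_j <- seq(box$lower[j], box$upper[j], length.out = 25L)
      vals <- vapply(grid_j, function(g) {
        x <- best$par; x[j] <- g; obj(x)
      }, numeric(1))
      if (min(vals) < best$value) {
        x <- best$par; x[j] <- grid_j[which.min(vals)]
        best <- list(par = x, value = min(vals),
                     converged = best$converged)
      }
    }
    if (all(c("reset_threshold0", "volatility") %in% box$names)) {
      jt <- match("reset_threshold0", box$names)
      jv <- match("volatility", box$names)
      g2 <- tidyr::expand_grid(
        thr = seq(0.05, 2, length.out = 12L),
        vol = c(0.004, 0.008, 0.015, 0.03, 0.06, 0.12, 0.3))
      vals <- vapply(seq_len(nrow(g2)), function(i) {
        x <- best$par; x[jt] <- g2$thr[i]; x[jv] <- g2$vol[i]; obj(x)
      }, numeric(1))
      if (min(vals) < best$value) {
        x <- best$par
        x[jt] <- g2$thr[which.min(vals)]
        x[jv] <- g2$vol[which.min(vals)]
        best <- list(par = x, value = min(vals),
                     converged = best$converged)
      }
    }
    r <- lbfgsb(best$par, maxit_polish)
    if (r$value < best$value) {
      best <- list(par = r$par, value = r$value,
                   converged = r$convergence == 0)
    }
  }

  # stage 3: circular refinement of the preferred-color parameters, whose
  # shallow likelihood contribution admits local optima in theta_pref
  ip <- match(c("pref_color_bias", "theta_pref"), free_param_names(variant))
  if (!anyNA(ip)) {
    for (tp in seq(-pi, pi, length.out = 13L)[-13L]) {
      x0 <- best$par
      x0[ip[2]] <- tp
      sub <- function(y) { x0[ip] <- y; obj(x0) }
      r <- tryCatch(stats::optim(x0[ip], sub, method = "L-BFGS-B",
                                 lower = box$lower[ip],
                                 upper = box$upper[ip],
                                 control = list(maxit = 25L)),
                    error = function(e) NULL)
      if (!is.null(r) && r$value < best$value) {
        x0[ip] <- r$par
        best <- list(par = x0, value = r$value, converged = best$converged)
      }
    }
    r <- lbfgsb(best$par, maxit_polish)
    if (r$value < best$value) {
      best <- list(par = r$par, value = r$value,
                   converged = r$convergence == 0)
    }
    # canonical form: (b, mu) and (-b, mu + pi) give identical likelihoods
    # (proximities differ by a constant, which the softmax ignores), so
    # report the non-negative-gain representative
    if (best$par[ip[1]] < 0) {
      best$par[ip[1]] <- -best$par[ip[1]]
      best$par[ip[2]] <- canonical_angle(best$par[ip[2]] + pi)
    }
  }

  pars <- unpack_params(best$par, variant, n_basis, beta_softmax)
  tr <- negative_log_likelihood(pars, session, traces = TRUE)
  n <- nrow(session)
  np <- attr(pars, "n_params")
  structure(list(
    params = pars, variant = variant, n_basis = n_basis,
    neg_log_lik = best$value, bic = np * log(n) + 2 * best$value,
    n_trials = n, n_params = np, n_starts = nrow(starts),
    converged = best$converged, mean_lik = tr$mean_lik,
    loglik = tr$loglik,
    traces = tibble::tibble(trial = seq_len(n),
                            est_template = tr$est_template,
                            rpe = tr$rpe, reset = tr$reset,
                            entropy = tr$entropy),
    starts = dplyr::bind_rows(start_tbl)),
    class = "template_fit")
}

lhs_starts <- function(n_starts, box) {
  k <- length(box$names)
  u <- lhs::randomLHS(n_starts, k)
  sweep(sweep(u, 2L, box$start_hi - box$start_lo, "*"), 2L,
        box$start_lo, "+")
}

#' @export
print.template_fit <- function(x, ...) {
  cat("<template_fit>", x$variant, "model,", x$n_basis, "basis functions\n")
  cat("  NLL =", round(x$neg_log_lik, 2), " BIC =", round(x$bic, 2),
      " mean per-trial likelihood =", round(x$mean_lik, 3), "\n")
  cat("  n_trials =", x$n_trials, " n_params =", x$n_params,
      " converged =", x$converged, "\n")
  invisible(x)
}

#' Tidy a fitted behavioral model
#'
#' @param x A `template_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`.
#' @export
tidy.template_fit <- function(x, ...) {
  tibble::tibble(term = free_param_names(x$variant),
                 estimate = pack_params(x$params))
}

#' One-row summary of a fitted behavioral model
#'
#' @param x A `template_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `variant`, `n_basis`, `n_params`, `n_trials`,
#'   `neg_log_lik`, `bic`, `mean_lik`, `converged`.
#' @export
glance.template_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant, n_basis = x$n_basis,
                 n_params = x$n_params, n_trials = x$n_trials,
                 neg_log_lik = x$neg_log_lik, bic = x$bic,
                 mean_lik = x$mean_lik, converged = x$converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Compare model variants by BIC
#'
#' Fits each candidate (variant, n_basis) pair to the session and tabulates
#' BIC and the difference to the best candidate. Nested pairs warm-start
#' each other: the fitted No Reset solution seeds a Reset start with a high
#' threshold (so the richer model can always match its nested special
#' case), and vice versa.
#'
#' @param session A `session_record`.
#' @param variants Character vector of variants to fit.
#' @param n_basis_list Basis counts to fit (recycled against variants via
#'   crossing).
#' @param ... Passed to [fit_session()].
#' @return A tibble sorted by BIC: `variant`, `n_basis`, `n_params`,
#'   `neg_log_lik`, `bic`, `delta_bic`, `winner`; fitted objects in the
#'   `fits` attribute.
#' @export
compare_models <- function(session, variants = c("no_reset", "reset"),
                           n_basis_list = 6L, ...) {
  stopifnot(length(variants) * length(n_basis_list) >= 1L)
  grid <- tidyr::expand_grid(variant = variants, n_basis = n_basis_list)
  fits <- list()
  for (i in seq_len(nrow(grid))) {
    v <- grid$variant[i]; nb <- grid$n_basis[i]
    extra <- list()
    for (f in fits) {
      if (f$n_basis == nb) extra <- c(extra, warm_starts(f, v))
    }
    fits[[i]] <- fit_session(session, variant = v, n_basis = nb,
                             extra_starts = extra, ...)
  }
  out <- dplyr::bind_rows(lapply(fits, glance)) |>
    dplyr::mutate(delta_bic = .data$bic - min(.data$bic),
                  winner = .data$bic == min(.data$bic)) |>
    dplyr::arrange(.data$bic)
  attr(out, "fits") <- fits
  out
}

# warm starts for variant `to` derived from a fitted model `from`
warm_starts <- function(from, to) {
  p <- from$params
  if (from$variant == to) return(list(p))
  mk <- function(...) {
    q <- p
    dots <- list(...)
    for (nm in names(dots)) q[[nm]] <- dots[[nm]]
    do.call(agent_params, c(list(variant = to),
                            q[setdiff(names(q), "variant")]))
  }
  if (to %in% c("reset", "dual_alpha") &&
      from$variant %in% c("no_reset", "reset")) {
    # high threshold ~ never reset: richer model matches the nested fit
    return(list(mk(reset_threshold0 = 4.5, volatility = 0.5), mk()))
  }
  if (to == "no_reset" && from$variant %in% c("reset", "dual_alpha")) {
    return(list(mk()))
  }
  if (to %in% c("wslf", "wsls")) return(list())
  list(mk())
}

#' Sweep the number of radial basis functions
#'
#' Fits one variant at each basis count and reports BIC; used to check
#' that model complexity plateaus (in the task this happens by N = 6).
#' The packed parameter vector does not reference the basis count, so
#' each fit is warm-started from every previous count's solution.
#'
#' @param session A `session_record`.
#' @param n_basis_list Basis counts (default 3:8).
#' @param variant Model variant.
#' @param ... Passed to [fit_session()].
#' @return Tibble: `n_basis`, `neg_log_lik`, `bic`, `delta_bic`.
#' @export
basis_sweep <- function(session, n_basis_list = 3:8, variant = "reset",
                        ...) {
  fits <- list()
  warm <- list()
  for (nb in n_basis_list) {
    f <- fit_session(session, variant = variant, n_basis = nb,
                     extra_starts = warm, ...)
    fits[[length(fits) + 1L]] <- f
    warm <- c(warm, list(pack_params(f$params)))
  }
  dplyr::bind_rows(lapply(fits, glance)) |>
    dplyr::mutate(delta_bic = .data$bic - min(.data$bic))
}

#' Generate-and-refit recovery experiment
#'
#' Simulates choice sequences from known generative parameters, refits one
#' or more candidate variants to each, and reports model identification
#' (BIC margins), the circular correlation between generative and
#' recovered trial-wise estimated templates, and parameter recovery errors
#' (including the absolute circular error of the preferred color).
#'
#' @param generative List of [agent_params()] to generate from (one
#'   sequence each), or a single `agent_params` with `n_sequences`.
#' @param n_sequences Sequences per generative parameter set.
#' @param n_trials Approximate sequence length (blocks run until this many
#'   trials have accumulated).
#' @param fit_variants Variants to refit to every sequence.
#' @param spec A [block_spec()].
#' @param ... Passed to [fit_session()].
#' @return A `recovery_report` tibble with one row per (sequence, fitted
#'   variant): BIC, `delta_bic_vs_generative`, `template_circ_corr`,
#'   `theta_pref_error`, `alpha_error`, `kappa_error`; fitted objects in
#'   the `fits` attribute.
#' @export
recovery_experiment <- function(generative, n_sequences = 1L,
                                n_trials = 3000L,
                                fit_variants = NULL, spec = block_spec(),
                                ...) {
  if (inherits(generative, "agent_params")) {
    generative <- rep(list(generative), n_sequences)
  }
  rows <- list()
  fits <- list()
  for (i in seq_along(generative)) {
    gp <- generative[[i]]
    ses <- simulate_trials(gp, n_trials, spec)
    gen_tr <- negative_log_likelihood(gp, ses, traces = TRUE)
    fv <- fit_variants %||% gp$variant
    cmp <- compare_models(ses, variants = fv, ...)
    cf <- attr(cmp, "fits")
    gen_bic <- cmp$bic[cmp$variant == gp$variant][1]
    for (f in cf) {
      same <- f$variant == gp$variant
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sequence = i, generative_variant = gp$variant,
        fitted_variant = f$variant, n_trials = f$n_trials,
        bic = f$bic,
        delta_bic_vs_generative = f$bic - gen_bic,
        template_circ_corr = if (same) {
          circular_correlation(gen_tr$est_template, f$traces$est_template)
        } else NA_real_,
        theta_pref_error = if (same) {
          abs(angular_distance(f$params$theta_pref, gp$theta_pref))
        } else NA_real_,
        alpha_error = if (same) f$params$alpha - gp$alpha else NA_real_,
        kappa_error = if (same) {
          f$params$kappa_basis - gp$kappa_basis
        } else NA_real_)
      fits[[length(fits) + 1L]] <- f
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  class(out) <- c("recovery_report", class(out))
  out
}

#' Simulate until a target number of trials
#'
#' Runs whole blocks of the task until at least `n_trials` trials have
#' accumulated, then truncates to exactly `n_trials`.
#'
#' @inheritParams run_session
#' @param n_trials Target trial count.
#' @return A `session_record` with `n_trials` rows.
#' @export
simulate_trials <- function(params, n_trials = 3000L, spec = block_spec(),
                            ...) {
  run_session(params, n_blocks = Inf, spec = spec, n_trials = n_trials,
              ...)
}
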
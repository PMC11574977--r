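#' Regressor traces for the single-neuron encoding models
#'
#' Bundles the per-trial latent traces the four encoding models regress
#' firing rates on: the estimated template, the full value function (for
#' the tuned value integral), its mean, and the chosen color.
#'
#' @param session A `session_record`.
#' @param params Agent parameters (default: attached generative ones).
#' @param wheel Wheel grid.
#' @return A list of traces: `template` (angles), `values`
#'   (trial x color matrix), `mean_value`, `chosen_color` (angles).
#' @export
encoding_traces <- function(session,
                            params = attr(session, "agent_params"),
                            wheel = color_wheel()) {
  lat <- latent_values(params, session, wheel)
  list(template = lat$est_template, values = lat$values,
       mean_value = lat$mean_value, chosen_color = session$chosen_color,
       wheel = wheel)
}

# regressor for a circular-tuning model at (theta0, kappa)
tuning_regressor <- function(trace, model, theta0, kappa, wheel) {
  switch(model,
    template = von_mises_density(trace$template, theta0, kappa),
    chosen_color = von_mises_density(trace$chosen_color, theta0, kappa),
    expected_value = {
      w <- von_mises_density(wheel, theta0, kappa)
      drop(trace$values %*% w) * (2 * pi / length(wheel))
    },
    stop("not a tuned model: ", model))
}

# profiled least squares: given the regressor, (beta0, beta) are the OLS
# solution; returns SSE and the coefficients
ols2 <- function(y, x) {
  vx <- stats::var(x)
  if (!is.finite(vx) || vx < 1e-12) {
    b <- 0
  } else {
    b <- stats::cov(x, y) / vx
  }
  b <- pmin(pmax(b, -10), 10)
  b0 <- pmin(pmax(mean(y) - b * mean(x), -10), 10)
  e <- y - b0 - b * x
  list(sse = sum(e^2), beta0 = b0, beta = b)
}

#' Fit one encoding model to one neuron
#'
#' Fits one of the four single-neuron models by cross-validated
#' constrained least squares:
#' * `template`: `FR = b0 + b * vm(estimated_template; theta0, kappa)`
#' * `expected_value`: `FR = b0 + b * integral(v(theta) *
#'   vm(theta; theta0, kappa) dtheta)` (Riemann sum on the wheel grid)
#' * `mean_value`: `FR = b0 + b * mean(v)` (linear; the `kappa -> 0`
#'   limit of the expected-value model)
#' * `chosen_color`: `FR = b0 + b * vm(chosen_color; theta0, kappa)`
#'
#' Constraints: `b0, b` in `[-10, 10]`, `kappa = 10^rho` with `rho` in
#' `[-2.5, 2.5]`. For each fold the tuned models profile `(b0, b)` by
#' least squares over a `theta0 x rho` grid and polish the best cell with
#' bounded BFGS; validation R-squared is `1 - SSE/SST` on the withheld
#' fold (negative allowed). Folds are random trials, seeded, and shared
#' across the four models of a neuron.
#'
#' @param rates Numeric vector of one neuron's (z-scored) rates, one per
#'   trial.
#' @param trace An [encoding_traces()] list.
#' @param model `"template"`, `"expected_value"`, `"mean_value"` or
#'   `"chosen_color"`.
#' @param folds Number of cross-validation folds (10).
#' @param fold_id Optional integer vector of precomputed fold labels.
#' @param grid_theta,grid_rho Coarse-grid resolution for the profiled
#'   search.
#' @return A `tuning_fit` list: `model`, `beta0`, `beta`, `theta0`,
#'   `kappa`, `r2_folds`, `mean_r2`, `significant` (mean R-squared > 0).
#' @export
fit_tuning_model <- function(rates, trace, model, folds = 10L,
                             fold_id = NULL, grid_theta = 8L,
                             grid_rho = 5L) {
  n <- length(rates)
  stopifnot(n == length(trace$template))
  if (is.null(fold_id)) fold_id <- make_folds(n, folds)
  folds <- max(fold_id)
  wheel <- trace$wheel
  r2 <- numeric(folds)
  coefs <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr_i <- fold_id != f
    y <- rates[tr_i]
    if (model == "mean_value") {
      o <- ols2(y, trace$mean_value[tr_i])
      fit <- list(theta0 = NA_real_, rho = NA_real_, o = o)
    } else {
      sub <- lapply(trace[c("template", "chosen_color")], function(z) z[tr_i])
      sub$values <- trace$values[tr_i, , drop = FALSE]
      sub$mean_value <- trace$mean_value[tr_i]
      sub$wheel <- wheel
      sse_at <- function(th, rho) {
        x <- tuning_regressor(sub, model, th, 10^rho, wheel)
        ols2(y, x)$sse
      }
      g <- tidyr::expand_grid(
        th = seq(-pi, pi, length.out = grid_theta + 1L)[-1L],
        rho = seq(-1, 1.5, length.out = grid_rho))
      g$sse <- mapply(sse_at, g$th, g$rho)
      b <- g[which.min(g$sse), ]
      opt <- tryCatch(
        stats::optim(c(b$th, b$rho),
                     function(p) sse_at(p[1], p[2]),
                     method = "L-BFGS-B", lower = c(-2 * pi, -2.5),
                     upper = c(2 * pi, 2.5),
                     control = list(maxit = 40L)),
        error = function(e) list(par = c(b$th, b$rho), value = b$sse))
      x <- tuning_regressor(sub, model, opt$par[1], 10^opt$par[2], wheel)
      fit <- list(theta0 = canonical_angle(opt$par[1]), rho = opt$par[2],
                  o = ols2(y, x))
    }
    # validation R^2
    va <- !tr_i
    xv <- if (model == "mean_value") {
      trace$mean_value[va]
    } else {
      subv <- list(template = trace$template[va],
                   chosen_color = trace$chosen_color[va],
                   values = trace$values[va, , drop = FALSE],
                   wheel = wheel)
      tuning_regressor(subv, model, fit$theta0 %||% 0,
                       10^(fit$rho %||% 0), wheel)
    }
    yv <- rates[va]
    pred <- fit$o$beta0 + fit$o$beta * xv
    sst <- sum((yv - mean(yv))^2)
    r2[f] <- if (sst > 0) 1 - sum((yv - pred)^2) / sst else NA_real_
    coefs[[f]] <- fit
  }
  best <- coefs[[which.max(r2)]]
  structure(list(model = model, beta0 = best$o$beta0, beta = best$o$beta,
                 theta0 = best$theta0,
                 kappa = if (is.na(best$rho)) NA_real_ else 10^best$rho,
                 r2_folds = r2, mean_r2 = mean(r2, na.rm = TRUE),
                 significant = mean(r2, na.rm = TRUE) > 0),
            class = "tuning_fit")
}

make_folds <- function(n, folds) {
  sample(rep_len(seq_len(folds), n))
}

#' Select the winning encoding model for a neuron
#'
#' Mutually exclusive selection: a neuron is sensitive to a factor if the
#' model's mean validation R-squared is positive; among significant
#' models the winner has the highest mean R-squared; with none, `NA`.
#'
#' @param fits A list of `tuning_fit` objects fitted on identical folds.
#' @return The winning model name, or `NA_character_`.
#' @export
select_model <- function(fits) {
  r2 <- vapply(fits, function(f) f$mean_r2, numeric(1))
  if (all(r2 <= 0, na.rm = TRUE)) return(NA_character_)
  vapply(fits, function(f) f$model, character(1))[which.max(r2)]
}

#' Fit and select encoding models across a population
#'
#' Fits the four competing models to every neuron (identical folds within
#' a neuron), selects winners, and returns a per-neuron table. Rates are
#' averaged over `window_bins` and z-scored.
#'
#' @param pop A `population_recording`.
#' @param trace An [encoding_traces()] list (defaults to traces from the
#'   generative parameters attached to the session).
#' @param window_bins Time bins averaged into the analysis window
#'   (default: all).
#' @param folds Cross-validation folds.
#' @param models Model set to compete.
#' @param ... Passed to [fit_tuning_model()].
#' @return A tibble: `neuron`, `winner`, one `r2_<model>` column per
#'   model, `theta0`, `kappa` (of the winner when tuned).
#' @export
encode_population <- function(pop, trace = NULL, window_bins = NULL,
                              folds = 10L,
                              models = c("template", "expected_value",
                                         "mean_value", "chosen_color"),
                              ...) {
  if (is.null(trace)) trace <- encoding_traces(pop$trials)
  d <- dim(pop$rates)
  if (is.null(window_bins)) window_bins <- seq_len(d[3])
  x <- apply(pop$rates[, , window_bins, drop = FALSE], c(1, 2), mean)
  x <- scale(x)
  rows <- vector("list", d[2])
  for (i in seq_len(d[2])) {
    fid <- make_folds(d[1], folds)
    fits <- lapply(models, function(m) {
      fit_tuning_model(x[, i], trace, m, fold_id = fid, ...)
    })
    win <- select_model(fits)
    r2 <- stats::setNames(vapply(fits, function(f) f$mean_r2, numeric(1)),
                          paste0("r2_", models))
    wf <- if (!is.na(win)) fits[[match(win, models)]] else NULL
    rows[[i]] <- tibble::tibble(
      neuron = i, winner = win, !!!as.list(r2),
      theta0 = if (!is.null(wf)) wf$theta0 else NA_real_,
      kappa = if (!is.null(wf)) wf$kappa else NA_real_)
  }
  dplyr::bind_rows(rows)
}

#' Permutation test for the proportion of tuned neurons
#'
#' Compares the observed proportion of neurons won by each model against
#' a null built by shuffling the trial labels of the regressor traces and
#' re-running the fit/selection pipeline.
#'
#' @param pop A `population_recording`.
#' @param trace An [encoding_traces()] list.
#' @param n_shuffles Number of trace-relabeling shuffles.
#' @param ... Passed to [encode_population()] (e.g. `folds`).
#' @return A tibble per model: `model`, `prop_observed`, `null_mean`,
#'   `p` (one-sided permutation p-value, `(1 + #null >= obs) /
#'   (1 + n_shuffles)`).
#' @export
population_proportion_test <- function(pop, trace = NULL,
                                       n_shuffles = 500L, ...) {
  if (is.null(trace)) trace <- encoding_traces(pop$trials)
  models <- c("template", "expected_value", "mean_value", "chosen_color")
  prop_of <- function(tb) {
    vapply(models, function(m) mean(tb$winner %in% m), numeric(1))
  }
  obs <- prop_of(encode_population(pop, trace, ...))
  n <- length(trace$template)
  null <- matrix(0, n_shuffles, length(models))
  for (s in seq_len(n_shuffles)) {
    perm <- sample.int(n)
    tr_s <- list(template = trace$template[perm],
                 values = trace$values[perm, , drop = FALSE],
                 mean_value = trace$mean_value[perm],
                 chosen_color = trace$chosen_color[perm],
                 wheel = trace$wheel)
    null[s, ] <- prop_of(encode_population(pop, tr_s, ...))
  }
  tibble::tibble(
    model = models, prop_observed = obs,
    null_mean = colMeans(null),
    p = (1 + colSums(sweep(null, 2, obs, ">="))) / (1 + n_shuffles))
}
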
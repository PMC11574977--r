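#' Trial-level value regressors for the population GLMs
#'
#' Derives, from the latent model values, the regressors of the "global"
#' GLM (reward, chosen value, highest unchosen value — current and
#' previous trial — and mean value) and of the per-location "local" GLM
#' (chosen indicator, value-if-chosen, value-if-unchosen at one screen
#' location).
#'
#' @param session A `session_record`.
#' @param params Agent parameters for the latent values.
#' @param wheel Wheel grid.
#' @return A list: `global` (trial x regressor matrix) and `local`
#'   (list of 4 trial x regressor matrices, one per location).
#' @export
value_regressors <- function(session,
                             params = attr(session, "agent_params"),
                             wheel = color_wheel()) {
  lat <- latent_values(params, session, wheel)
  n <- nrow(session)
  cols <- cbind(session$color1, session$color2, session$color3)
  locs <- cbind(session$loc1, session$loc2, session$loc3)
  vals <- matrix(0, n, 3L)
  for (j in 1:3) {
    vals[, j] <- lat$values[cbind(seq_len(n), wheel_index(cols[, j],
                                                          length(wheel)))]
  }
  ch <- cbind(seq_len(n), session$chosen_idx)
  chosen_val <- vals[ch]
  vmask <- vals; vmask[ch] <- -Inf
  unchosen_val <- apply(vmask, 1L, max)
  lag1 <- function(x) c(NA, x[-n])
  glob <- cbind(reward = session$reward,
                chosen_value = chosen_val,
                unchosen_value = unchosen_val,
                prev_reward = lag1(session$reward),
                prev_chosen_value = lag1(chosen_val),
                prev_unchosen_value = lag1(unchosen_val),
                mean_value = lat$mean_value)
  loc_list <- lapply(1:4, function(L) {
    here <- locs == L
    occupied <- rowSums(here) > 0L
    j <- max.col(here, ties.method = "first")
    v_here <- ifelse(occupied, vals[cbind(seq_len(n), j)], 0)
    chosen_here <- occupied & j == session$chosen_idx
    cbind(chosen = as.numeric(chosen_here),
          value_chosen = ifelse(chosen_here, v_here, 0),
          value_unchosen = ifelse(occupied & !chosen_here, v_here, 0))
  })
  list(global = glob, local = loc_list)
}

# baseline-subtracted, per-bin z-scored rates
preprocess_rates <- function(pop, baseline_bins = 1L) {
  d <- dim(pop$rates)
  base <- apply(pop$rates[, , baseline_bins, drop = FALSE], c(1, 2), mean)
  out <- array(0, d)
  for (b in seq_len(d[3])) {
    out[, , b] <- scale(pop$rates[, , b] - base)
  }
  out[!is.finite(out)] <- 0
  out
}

#' Per-neuron value GLM weights
#'
#' Fits, for every neuron and time bin, a linear model of the
#' baseline-subtracted z-scored firing rate on the value regressors
#' ([value_regressors()]): the "global" scope uses all trials, the
#' "local" scope the stimulus at one screen location. Neurons recorded on
#' fewer than `min_trials` trials, or whose design is rank deficient, are
#' excluded.
#'
#' @param pop A `population_recording`.
#' @param scope `"global"` or `"local"`.
#' @param location Screen location 1–4 for the local scope.
#' @param params Agent parameters for the latent values.
#' @param baseline_bins Bins of the pre-target baseline subtracted from
#'   every window.
#' @param min_trials Inclusion threshold (500).
#' @param trials Optional trial subset (indices) to fit on.
#' @return A tibble: `neuron`, `bin`, `time_ms`, `term`, `weight`.
#' @export
value_glm <- function(pop, scope = c("global", "local"), location = 1L,
                      params = attr(pop$trials, "agent_params"),
                      baseline_bins = 1L, min_trials = 500L,
                      trials = NULL) {
  scope <- match.arg(scope)
  reg <- value_regressors(pop$trials, params)
  x <- if (scope == "global") reg$global else reg$local[[location]]
  rates <- preprocess_rates(pop, baseline_bins)
  d <- dim(rates)
  keep_tr <- which(stats::complete.cases(x))
  if (!is.null(trials)) keep_tr <- intersect(keep_tr, trials)
  if (d[1] < min_trials) {
    stop("population has fewer than min_trials trials", call. = FALSE)
  }
  xx <- cbind(`(Intercept)` = 1, x[keep_tr, , drop = FALSE])
  if (qr(xx)$rank < ncol(xx)) {
    stop("rank-deficient design: collinear regressors", call. = FALSE)
  }
  rows <- vector("list", d[3])
  for (b in seq_len(d[3])) {
    cf <- stats::lm.fit(xx, rates[keep_tr, , b])$coefficients
    rows[[b]] <- tibble::tibble(
      neuron = rep(seq_len(d[2]), each = ncol(xx)),
      bin = b, time_ms = pop$time[b],
      term = rep(rownames(cf) %||% colnames(xx), d[2]),
      weight = as.vector(cf))
  }
  dplyr::bind_rows(rows) |>
    dplyr::filter(.data$term != "(Intercept)")
}

# split-half weight vectors: for each split s and half h, the per-neuron
# weights of `factor`; local scope concatenates the given locations
split_half_weights <- function(pop, factor, scope = "global",
                               locations = 1L, n_splits = 10L,
                               params = attr(pop$trials, "agent_params"),
                               baseline_bins = 1L, min_trials = 500L,
                               trials = NULL) {
  pool <- trials %||% seq_len(nrow(pop$trials))
  n_bins <- dim(pop$rates)[3]
  halves <- lapply(seq_len(n_splits), function(s) {
    h1 <- sample(pool, floor(length(pool) / 2))
    list(h1, setdiff(pool, h1))
  })
  get_w <- function(tr) {
    if (scope == "global") {
      w <- value_glm(pop, "global", params = params,
                     baseline_bins = baseline_bins,
                     min_trials = min_trials, trials = tr) |>
        dplyr::filter(.data$term == factor)
      matrix(w$weight, ncol = n_bins)       # neurons x bins
    } else {
      do.call(rbind, lapply(locations, function(L) {
        w <- value_glm(pop, "local", location = L, params = params,
                       baseline_bins = baseline_bins,
                       min_trials = min_trials, trials = tr) |>
          dplyr::filter(.data$term == factor)
        matrix(w$weight, ncol = n_bins)
      }))                                    # (neurons*|locs|) x bins
    }
  }
  lapply(halves, function(h) list(get_w(h[[1]]), get_w(h[[2]])))
}

#' Split-half reliability of a value representation
#'
#' The representation of a factor at a time bin is the vector of its GLM
#' weights across neurons. Reliability is the Pearson correlation between
#' the vectors estimated on two disjoint halves of the trials, averaged
#' over random splits; neuron bootstrap gives confidence intervals and a
#' one-sided z-test against 0, Bonferroni corrected over time bins. This
#' is the ceiling for any cross-factor alignment.
#'
#' @param pop A `population_recording`.
#' @param factor Regressor name (see [value_regressors()]).
#' @param scope `"global"` or `"local"`.
#' @param locations Locations concatenated for the local scope.
#' @param n_splits Random trial splits (10).
#' @param n_boot Neuron bootstraps (5000).
#' @param ... Passed to the GLM ([value_glm()]).
#' @return A tibble per time bin: `bin`, `time_ms`, `r`, `ci_lo`,
#'   `ci_hi`, `z`, `p`, `p_bonf`.
#' @export
split_half_reliability <- function(pop, factor, scope = "global",
                                   locations = 1L, n_splits = 10L,
                                   n_boot = 5000L, ...) {
  W <- split_half_weights(pop, factor, scope, locations, n_splits, ...)
  n_bins <- ncol(W[[1]][[1]])
  nn <- nrow(W[[1]][[1]])
  out <- lapply(seq_len(n_bins), function(b) {
    r_split <- vapply(W, function(h) {
      suppressWarnings(stats::cor(h[[1]][, b], h[[2]][, b]))
    }, numeric(1))
    boot <- vapply(seq_len(n_boot), function(i) {
      ix <- sample.int(nn, nn, replace = TRUE)
      mean(vapply(W, function(h) {
        suppressWarnings(stats::cor(h[[1]][ix, b], h[[2]][ix, b]))
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    zt <- bootstrap_z(boot)
    tibble::tibble(bin = b, r = mean(r_split),
                   ci_lo = stats::quantile(boot, 0.025, na.rm = TRUE),
                   ci_hi = stats::quantile(boot, 0.975, na.rm = TRUE),
                   z = zt$z, p = zt$p)
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(time_ms = pop$time[.data$bin],
                  p_bonf = pmin(.data$p * n_bins, 1),
                  .after = "bin")
}

#' Disattenuated alignment between two representations
#'
#' `gamma = r_XY / sqrt(r_XX * r_YY)`: the cross-factor (or
#' cross-location) correlation normalized by the geometric mean of the
#' split-half reliabilities, estimating the alignment free of estimation
#' noise. X and Y are always taken from different halves of the trials,
#' and bins where either reliability is non-positive are reported as
#' `NA` (masked, not clipped).
#'
#' @param pop A `population_recording`.
#' @param factor_x,factor_y Regressor names.
#' @param scope_x,scope_y `"global"` or `"local"`.
#' @param locations_x,locations_y Locations for local scopes.
#' @param n_splits,n_boot Splits and neuron bootstraps.
#' @param ... Passed to the GLM.
#' @return A tibble per bin: `bin`, `time_ms`, `r_xy`, `r_xx`, `r_yy`,
#'   `gamma`, `ci_lo`, `ci_hi`, `z`, `p`, `p_bonf`, `masked`.
#' @export
disattenuated_alignment <- function(pop, factor_x, factor_y,
                                    scope_x = "global",
                                    scope_y = "global",
                                    locations_x = 1L, locations_y = 1L,
                                    n_splits = 10L, n_boot = 5000L,
                                    ...) {
  WX <- split_half_weights(pop, factor_x, scope_x, locations_x,
                           n_splits, ...)
  WY <- split_half_weights(pop, factor_y, scope_y, locations_y,
                           n_splits, ...)
  # a concatenated multi-location representation (k*N) can be aligned
  # with a single global vector (N) by tiling the global weights per
  # location, matching how per-location and global vectors are compared
  nx <- nrow(WX[[1]][[1]]); ny <- nrow(WY[[1]][[1]])
  tile <- function(W, k) {
    lapply(W, function(h) lapply(h, function(m) {
      m[rep(seq_len(nrow(m)), k), , drop = FALSE]
    }))
  }
  if (nx != ny) {
    if (nx > ny && nx %% ny == 0L) {
      WY <- tile(WY, nx %/% ny)
    } else if (ny > nx && ny %% nx == 0L) {
      WX <- tile(WX, ny %/% nx)
    } else {
      stop("representations must have the same (or multiple) dimension",
           call. = FALSE)
    }
  }
  n_bins <- ncol(WX[[1]][[1]])
  nn <- nrow(WX[[1]][[1]])
  gamma_of <- function(ix, b) {
    rxy <- mean(vapply(seq_along(WX), function(s) {
      mean(c(suppressWarnings(stats::cor(WX[[s]][[1]][ix, b],
                                         WY[[s]][[2]][ix, b])),
             suppressWarnings(stats::cor(WX[[s]][[2]][ix, b],
                                         WY[[s]][[1]][ix, b]))))
    }, numeric(1)))
    rxx <- mean(vapply(WX, function(h) {
      suppressWarnings(stats::cor(h[[1]][ix, b], h[[2]][ix, b]))
    }, numeric(1)))
    ryy <- mean(vapply(WY, function(h) {
      suppressWarnings(stats::cor(h[[1]][ix, b], h[[2]][ix, b]))
    }, numeric(1)))
    c(rxy = rxy, rxx = rxx, ryy = ryy,
      gamma = if (is.na(rxx) || is.na(ryy) || rxx <= 0 || ryy <= 0) {
        NA_real_
      } else rxy / sqrt(rxx * ryy))
  }
  all_ix <- seq_len(nn)
  out <- lapply(seq_len(n_bins), function(b) {
    g <- gamma_of(all_ix, b)
    boot <- vapply(seq_len(n_boot), function(i) {
      gamma_of(sample.int(nn, nn, replace = TRUE), b)[["gamma"]]
    }, numeric(1))
    ok <- is.finite(boot)
    zt <- if (sum(ok) >= 3L) bootstrap_z(boot[ok]) else
      list(z = NA_real_, p = NA_real_)
    tibble::tibble(bin = b, r_xy = g[["rxy"]], r_xx = g[["rxx"]],
                   r_yy = g[["ryy"]], gamma = g[["gamma"]],
                   ci_lo = stats::quantile(boot[ok], 0.025,
                                           na.rm = TRUE,
                                           names = FALSE),
                   ci_hi = stats::quantile(boot[ok], 0.975,
                                           na.rm = TRUE,
                                           names = FALSE),
                   z = zt$z, p = zt$p, masked = is.na(g[["gamma"]]))
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(time_ms = pop$time[.data$bin],
                  p_bonf = pmin(.data$p * n_bins, 1), .after = "bin")
}

#' Area under a reliability or alignment curve
#'
#' Sums a curve over time bins — the overall-alignment summary used to
#' compare location pairs (the "distance index 0" case is the plain
#' reliability AUC).
#'
#' @param curve A tibble from [split_half_reliability()] (column `r`) or
#'   [disattenuated_alignment()] (column `gamma`).
#' @param bins Optional bin subset (e.g. an early window).
#' @return The AUC (sum over bins, NA-removed).
#' @export
alignment_auc <- function(curve, bins = NULL) {
  val <- if ("gamma" %in% names(curve)) curve$gamma else curve$r
  if (!is.null(bins)) val <- val[curve$bin %in% bins]
  sum(val, na.rm = TRUE)
}

#' Receptive-field map from stimulus-presence modulation
#'
#' Only 3 of the 4 screen locations are occupied on each trial, so a
#' location is flagged "in" a neuron's receptive field when a linear
#' model of the early visual-window rate on the stimulus-presence
#' indicator at that location is significant (`p < 0.005`); several
#' locations may be flagged.
#'
#' @param pop A `population_recording`.
#' @param window_bins Bins of the early window (default bin 4, 0–200 ms).
#' @param p_threshold Significance threshold (0.005).
#' @return A tibble: `neuron`, `location`, `estimate`, `p`, `in_rf`.
#' @export
receptive_field_map <- function(pop, window_bins = 4L,
                                p_threshold = 0.005) {
  trials <- pop$trials
  n <- nrow(trials)
  locs <- cbind(trials$loc1, trials$loc2, trials$loc3)
  x <- apply(pop$rates[, , window_bins, drop = FALSE], c(1, 2), mean)
  rows <- list()
  for (L in 1:4) {
    on <- as.numeric(rowSums(locs == L) > 0L)
    if (stats::var(on) == 0) next
    X <- cbind(1, on)
    for (i in seq_len(ncol(x))) {
      f <- stats::lm.fit(X, x[, i])
      se <- sqrt(sum(f$residuals^2) / (n - 2) /
                   sum((on - mean(on))^2))
      tval <- f$coefficients[2] / se
      p <- 2 * stats::pt(-abs(tval), n - 2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        neuron = i, location = L, estimate = f$coefficients[2],
        p = p, in_rf = p < p_threshold)
    }
  }
  dplyr::bind_rows(rows)
}

#' Effective dimensionality of a set of eigenvalues
#'
#' The participation ratio `(sum(ev))^2 / sum(ev^2)`: M equal eigenvalues
#' give M, a single nonzero eigenvalue gives 1.
#'
#' @param ev Non-negative eigenvalues.
#' @return A scalar in `[1, length(ev)]`.
#' @export
effective_dimensionality <- function(ev) {
  ev <- ev[is.finite(ev) & ev > 0]
  if (!length(ev)) return(NA_real_)
  sum(ev)^2 / sum(ev^2)
}

#' PCA geometry of condition means
#'
#' Eigen-decomposes the covariance (across conditions) of a
#' condition x neuron mean-activity matrix, reporting components,
#' explained variance, and the effective (participation-ratio)
#' dimensionality, with optional neuron bootstraps for a confidence
#' interval. Optionally removes the per-time-point mean across conditions
#' first (the "time-removed" variant).
#'
#' @param condition_means Condition x neuron matrix.
#' @param time Optional per-condition time labels; when given, the mean
#'   across conditions sharing a time point is subtracted.
#' @param n_boot Neuron bootstraps for the dimensionality CI (0 = none).
#' @return A list: `eigenvalues`, `explained` (fractions),
#'   `components` (neuron loadings), `scores`, `eff_dim`, `eff_dim_ci`.
#' @export
pca_geometry <- function(condition_means, time = NULL, n_boot = 0L) {
  x <- as.matrix(condition_means)
  if (nrow(x) < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (!is.null(time)) {
    stopifnot(length(time) == nrow(x))
    for (tt in unique(time)) {
      ix <- time == tt
      x[ix, ] <- sweep(x[ix, , drop = FALSE], 2L,
                       colMeans(x[ix, , drop = FALSE]))
    }
  }
  xc <- scale(x, scale = FALSE)
  sv <- svd(xc)
  ev <- sv$d^2 / (nrow(x) - 1L)
  dim_boot <- if (n_boot > 0L) {
    vapply(seq_len(n_boot), function(i) {
      ix <- sample.int(ncol(x), ncol(x), replace = TRUE)
      xb <- scale(x[, ix, drop = FALSE], scale = FALSE)
      effective_dimensionality(svd(xb)$d^2 / (nrow(x) - 1L))
    }, numeric(1))
  } else NULL
  list(eigenvalues = ev, explained = ev / sum(ev),
       components = sv$v, scores = xc %*% sv$v,
       eff_dim = effective_dimensionality(ev),
       eff_dim_ci = if (!is.null(dim_boot)) {
         stats::quantile(dim_boot, c(0.025, 0.975), names = FALSE)
       } else NULL)
}

#' Low-dimensional embedding of condition means
#'
#' Classical (metric) multidimensional scaling of the pairwise Euclidean
#' distances between condition means, with the (metric) stress of the
#' embedding. Identical conditions give a degenerate zero-distance
#' embedding rather than an error.
#'
#' @param condition_means Condition x neuron matrix (>= 3 conditions).
#' @param n_dims Embedding dimension (2).
#' @return A list: `points` (condition x n_dims), `stress`, `dist`.
#' @export
mds_embedding <- function(condition_means, n_dims = 2L) {
  x <- as.matrix(condition_means)
  stopifnot(nrow(x) >= 3L)
  d <- stats::dist(x)
  if (all(d < 1e-12)) {
    return(list(points = matrix(0, nrow(x), n_dims), stress = 0,
                dist = d))
  }
  pts <- stats::cmdscale(d, k = n_dims)
  if (ncol(pts) < n_dims) {
    pts <- cbind(pts, matrix(0, nrow(pts), n_dims - ncol(pts)))
  }
  de <- stats::dist(pts)
  stress <- sqrt(sum((de - d)^2) / sum(d^2))
  list(points = pts, stress = stress, dist = d)
}

#' Plot a reliability or alignment curve
#'
#' @param curve Output of [split_half_reliability()] or
#'   [disattenuated_alignment()].
#' @return A ggplot object.
#' @export
plot_reliability <- function(curve) {
  yvar <- if ("gamma" %in% names(curve)) "gamma" else "r"
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$time_ms,
                               y = .data[[yvar]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from target onset (ms)",
                  y = if (yvar == "gamma") {
                    "Disattenuated alignment"
                  } else "Split-half reliability") +
    ggplot2::theme_minimal()
}
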
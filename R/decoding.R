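#' Color bins on the wheel
#'
#' Splits the wheel into `n_bins` equal arcs with the first bin centered
#' on the "red" anchor at 0 radians.
#'
#' @param theta Angles, radians.
#' @param n_bins Number of bins (3 for the template analyses).
#' @return Integer bin labels 1..n_bins.
#' @export
color_bin <- function(theta, n_bins = 3L) {
  w <- 2 * pi / n_bins
  (as.integer(floor((canonical_angle(theta) + w / 2) / w)) %% n_bins) + 1L
}

#' Build balanced pseudo-populations
#'
#' Assembles bootstrap pseudo-population activity matrices from one or
#' more recordings: `n_neurons` neurons sampled with replacement from all
#' neurons that have at least `n_trials` trials in every condition, and
#' for each neuron `n_trials` trials per condition sampled with
#' replacement (trials are independent across neurons, as in any
#' across-session pseudo-population). A balanced 20% of trials per
#' condition is withheld for validation.
#'
#' @param pops A `population_recording` or list of them (sessions).
#' @param labels_fn Function mapping a session's `trials` tibble to a
#'   per-trial condition label vector (`NA` drops the trial).
#' @param n_neurons Neurons per pseudo-population.
#' @param n_trials Trials per condition per neuron.
#' @param n_bootstraps Number of independent pseudo-populations (100).
#' @param window_bins Time bins averaged into the activity value.
#' @param val_frac Withheld fraction per condition (0.2).
#' @return A list of `n_bootstraps` pseudo-populations, each a list with
#'   `x` (trial x neuron matrix, z-scored per neuron), `label`
#'   (condition per row), `is_val` (withheld 20%), `neurons` (sampled
#'   session/neuron index tibble).
#' @export
build_pseudopopulation <- function(pops, labels_fn, n_neurons = 100L,
                                   n_trials = 60L, n_bootstraps = 100L,
                                   window_bins = NULL, val_frac = 0.2) {
  if (inherits(pops, "population_recording")) pops <- list(pops)
  acts <- list(); labs <- list(); pool <- list()
  for (s in seq_along(pops)) {
    p <- pops[[s]]
    wb <- window_bins %||% seq_len(dim(p$rates)[3])
    a <- apply(p$rates[, , wb, drop = FALSE], c(1, 2), mean)
    l <- labels_fn(p$trials)
    stopifnot(length(l) == nrow(a))
    acts[[s]] <- a; labs[[s]] <- l
    cnt <- table(l[!is.na(l)])
    if (length(cnt) && all(cnt >= n_trials)) {
      pool[[s]] <- tibble::tibble(session = s,
                                  neuron = seq_len(ncol(a)))
    }
  }
  pool <- dplyr::bind_rows(pool)
  if (nrow(pool) == 0L) {
    short <- names(which(table(unlist(labs)) < n_trials))
    stop("no session has ", n_trials, " trials in every condition",
         if (length(short)) paste0(" (short: ",
                                   paste(short, collapse = ", "), ")"),
         call. = FALSE)
  }
  conds <- sort(unique(unlist(lapply(labs, function(l) l[!is.na(l)]))))
  n_val <- max(1L, round(val_frac * n_trials))
  lapply(seq_len(n_bootstraps), function(bs) {
    sel <- pool[sample.int(nrow(pool), n_neurons, replace = TRUE), ]
    x <- matrix(0, n_trials * length(conds), n_neurons)
    for (i in seq_len(n_neurons)) {
      a <- acts[[sel$session[i]]][, sel$neuron[i]]
      l <- labs[[sel$session[i]]]
      for (ci in seq_along(conds)) {
        tr <- sample(which(!is.na(l) & l == conds[ci]), n_trials,
                     replace = TRUE)
        x[(ci - 1L) * n_trials + seq_len(n_trials), i] <- a[tr]
      }
    }
    x <- scale(x)
    x[!is.finite(x)] <- 0
    label <- rep(conds, each = n_trials)
    is_val <- rep(FALSE, length(label))
    for (ci in seq_along(conds)) {
      is_val[(ci - 1L) * n_trials + sample.int(n_trials, n_val)] <- TRUE
    }
    list(x = x, label = label, is_val = is_val, neurons = sel,
         bootstrap = bs)
  })
}

# seeded grid-CV cost selection for a linear max-margin classifier
tune_linear_svm <- function(x, y, cost_grid = 10^(-3:3), cross = 10L,
                            probability = TRUE) {
  y <- factor(y)
  n <- length(y)
  cross <- min(cross, n)
  fid <- make_folds(n, cross)
  acc <- vapply(cost_grid, function(cc) {
    ok <- vapply(seq_len(cross), function(f) {
      tr <- fid != f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = cc, scale = FALSE)
      mean(stats::predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(ok, na.rm = TRUE)
  }, numeric(1))
  best <- cost_grid[which.max(acc)]
  m <- e1071::svm(x, y, kernel = "linear", cost = best, scale = FALSE,
                  probability = probability)
  attr(m, "cv_accuracy") <- max(acc)
  attr(m, "cost") <- best
  m
}

#' Train the one-vs-rest template decoder ensemble
#'
#' One linear max-margin classifier per color bin, each separating "in
#' bin" from a randomly subsampled equal number of trials of the other
#' bins; regularization strength is chosen by seeded inner
#' cross-validation and margins are calibrated to posteriors by a fitted
#' sigmoid.
#'
#' @param x Trial x neuron activity matrix (training trials only).
#' @param label Condition label per row (the color bin).
#' @param cost_grid Regularization grid.
#' @param cross Inner CV folds.
#' @return A `decoder_bundle`: list of per-class svms, `classes`.
#' @export
train_template_decoder <- function(x, label, cost_grid = 10^(-3:3),
                                   cross = 10L) {
  classes <- sort(unique(label))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  models <- lapply(classes, function(cl) {
    pos <- which(label == cl)
    neg_pool <- which(label != cl)
    # equal subsample from each other class
    neg <- unlist(lapply(split(neg_pool, label[neg_pool]), function(ix) {
      sample(ix, min(length(ix), ceiling(length(pos) /
                                           (length(classes) - 1L))))
    }))
    xx <- x[c(pos, neg), , drop = FALSE]
    yy <- factor(rep(c("in", "out"), c(length(pos), length(neg))),
                 levels = c("in", "out"))
    tune_linear_svm(xx, yy, cost_grid, cross)
  })
  structure(list(models = models, classes = classes),
            class = "decoder_bundle")
}

#' Posterior probabilities from a decoder bundle
#'
#' @param bundle A `decoder_bundle`.
#' @param x Trial x neuron activity matrix.
#' @return Trial x class matrix of calibrated "in class" posteriors.
#' @export
decoder_posteriors <- function(bundle, x) {
  out <- vapply(bundle$models, function(m) {
    pr <- stats::predict(m, x, probability = TRUE)
    attr(pr, "probabilities")[, "in"]
  }, numeric(nrow(x)))
  colnames(out) <- as.character(bundle$classes)
  out
}

#' Multi-class readout over classifier posteriors
#'
#' Trains a small fully connected network on the per-class posterior
#' probabilities (withholding the validation trials) and reports its
#' validation accuracy next to the plain argmax-posterior accuracy (the
#' deterministic fallback).
#'
#' @param posteriors Trial x class posterior matrix.
#' @param label True class per trial.
#' @param is_val Logical: validation trials (excluded from training).
#' @param size Hidden units.
#' @param maxit Training iterations.
#' @return A list: `accuracy` (network, on validation trials),
#'   `accuracy_argmax`, `fit` (the nnet object), `predicted`.
#' @export
multiclass_readout <- function(posteriors, label, is_val, size = 8L,
                               maxit = 200L) {
  lab <- factor(label)
  if (is.null(colnames(posteriors))) {
    stopifnot(ncol(posteriors) == nlevels(lab))
    colnames(posteriors) <- levels(lab)
  }
  argmax <- factor(colnames(posteriors)[max.col(posteriors,
                                                ties.method = "first")],
                   levels = levels(lab))
  acc_arg <- mean(argmax[is_val] == lab[is_val])
  net <- nnet::nnet(posteriors[!is_val, , drop = FALSE],
                    nnet::class.ind(lab[!is_val]), size = size,
                    softmax = TRUE, maxit = maxit, trace = FALSE)
  pred <- factor(colnames(net$fitted.values)[
    max.col(stats::predict(net, posteriors[is_val, , drop = FALSE]),
            ties.method = "first")], levels = levels(lab))
  acc_net <- mean(pred == lab[is_val])
  list(accuracy = acc_net, accuracy_argmax = acc_arg, fit = net,
       predicted = pred)
}

#' Template decoding accuracy of one pseudo-population
#'
#' Convenience wrapper: trains the one-vs-rest ensemble on the training
#' split, applies the multi-class readout, and returns both accuracies.
#'
#' @param pp One pseudo-population from [build_pseudopopulation()].
#' @param ... Passed to [train_template_decoder()].
#' @return A one-row tibble: `accuracy`, `accuracy_argmax`, `chance`.
#' @export
decode_template_accuracy <- function(pp, ...) {
  bundle <- train_template_decoder(pp$x[!pp$is_val, , drop = FALSE],
                                   pp$label[!pp$is_val], ...)
  post <- decoder_posteriors(bundle, pp$x)
  ro <- multiclass_readout(post, pp$label, pp$is_val)
  tibble::tibble(accuracy = ro$accuracy,
                 accuracy_argmax = ro$accuracy_argmax,
                 chance = 1 / length(bundle$classes))
}

#' Within- vs across-condition generalization of a binary decoder
#'
#' Trains a linear classifier on a binary target using trials of one
#' condition and compares accuracy on withheld trials of the same
#' condition ("within") against trials of the other conditions
#' ("across"). Equal within and across accuracy indicates a code for the
#' target that generalizes across conditions; across below chance
#' indicates a condition-locked remapping.
#'
#' @param x Trial x neuron activity matrix.
#' @param target Binary target per trial (e.g. high/low chosen value).
#' @param condition Condition label per trial (e.g. template bin).
#' @param train_condition The condition trained on.
#' @param val_frac Withheld fraction of training-condition trials.
#' @param cost_grid,cross Classifier tuning grid and inner folds.
#' @return A one-row tibble: `train_condition`, `within`, `across`.
#' @export
cross_generalization <- function(x, target, condition, train_condition,
                                 val_frac = 0.2, cost_grid = 10^(-3:3),
                                 cross = 5L) {
  target <- factor(target)
  stopifnot(nlevels(target) == 2L)
  in_cond <- condition == train_condition
  idx <- which(in_cond)
  # balanced withheld split within the training condition
  val <- unlist(lapply(split(idx, target[idx]), function(ix) {
    sample(ix, max(1L, round(val_frac * length(ix))))
  }))
  tr <- setdiff(idx, val)
  m <- tune_linear_svm(x[tr, , drop = FALSE], target[tr], cost_grid,
                       cross, probability = FALSE)
  acc <- function(ix) {
    if (!length(ix)) return(NA_real_)
    mean(stats::predict(m, x[ix, , drop = FALSE]) == target[ix])
  }
  tibble::tibble(train_condition = train_condition,
                 within = acc(val), across = acc(which(!in_cond)))
}

#' One-sided bootstrap z-test
#'
#' `p = 1 - pnorm(mean(y) / sd(y))` — the z-form used with bootstrap
#' distributions, where the sample size is set arbitrarily by the number
#' of bootstraps (hence a z rather than a t test).
#'
#' @param y Bootstrap statistic values (e.g. within - across).
#' @param mu Hypothesized mean (0).
#' @param two_sided Double the tail.
#' @return A list: `z`, `p`.
#' @export
bootstrap_z <- function(y, mu = 0, two_sided = FALSE) {
  z <- (mean(y) - mu) / stats::sd(y)
  p <- 1 - stats::pnorm(z)
  if (two_sided) p <- 2 * min(p, 1 - p)
  list(z = z, p = p)
}

# --- trial-by-trial circular template decoding -----------------------------

# small fully connected net: inputs -> relu hidden -> 2 linear outputs
# (cos, sin); trained by BFGS on squared error. Hand-written because the
# readout needs a rectified-linear hidden layer with linear outputs.
relu_mlp_fit <- function(x, y2, hidden = 10L, maxit = 300L,
                         lambda = 1e-4) {
  d <- ncol(x); h <- hidden
  n_w1 <- d * h
  unpack <- function(p) {
    list(w1 = matrix(p[seq_len(n_w1)], d, h),
         b1 = p[n_w1 + seq_len(h)],
         w2 = matrix(p[n_w1 + h + seq_len(h * 2L)], h, 2L),
         b2 = p[n_w1 + h + h * 2L + 1:2])
  }
  fwd <- function(pp, x) {
    a <- sweep(x %*% pp$w1, 2L, pp$b1, "+")
    r <- pmax(a, 0)
    list(a = a, r = r,
         out = sweep(r %*% pp$w2, 2L, pp$b2, "+"))
  }
  loss <- function(p) {
    pp <- unpack(p)
    f <- fwd(pp, x)
    mean((f$out - y2)^2) + lambda * sum(p^2)
  }
  grad <- function(p) {
    pp <- unpack(p)
    f <- fwd(pp, x)
    n <- nrow(x)
    dout <- 2 * (f$out - y2) / (n * 2)
    gw2 <- t(f$r) %*% dout
    gb2 <- colSums(dout)
    dr <- dout %*% t(pp$w2)
    dr[f$a <= 0] <- 0
    gw1 <- t(x) %*% dr
    gb1 <- colSums(dr)
    c(as.vector(gw1), gb1, as.vector(gw2), gb2) + 2 * lambda * p
  }
  p0 <- stats::rnorm(n_w1 + h + h * 2L + 2L, 0, 0.5)
  opt <- stats::optim(p0, loss, grad, method = "BFGS",
                      control = list(maxit = maxit))
  pp <- unpack(opt$par)
  structure(list(par = pp, value = opt$value, hidden = h,
                 predict = function(newx) fwd(pp, newx)$out),
            class = "relu_mlp")
}

#' Trial-by-trial circular template decoding
#'
#' For a simultaneously recorded session: withholds the first
#' `withheld_trials` trials of every block, trains the one-vs-rest color
#' bin ensemble plus a feedforward readout (one hidden layer of 10
#' rectified-linear units, 2 linear outputs for cosine and sine) on the
#' remaining trials, and decodes the template color of the withheld
#' trials as `atan2(sin, cos)`. Accuracy is the circular correlation and
#' mean absolute circular distance between decoded and behavioral
#' estimated templates, z-scored against a permutation null that
#' shuffles the template labels.
#'
#' @param pop A `population_recording` of one session.
#' @param template Behavioral estimated-template trace (defaults to the
#'   fitted/generative trace stored in the session).
#' @param window_bins Time bins averaged into the decoded activity.
#' @param withheld_trials Leading trials per block to withhold (35).
#' @param n_perm Permutations for the null of the mean circular distance.
#' @param n_bins Color bins for the classifier stage.
#' @param hidden Hidden units of the readout.
#' @param cost_grid,cross Classifier tuning settings.
#' @return A list: `decoded` tibble (`trial`, `decoded`, `behavioral`,
#'   `withheld`), `circ_corr`, `mean_abs_distance`, `z`, `p_perm`,
#'   `bundle`, `readout`.
#' @export
decode_trialwise_template <- function(pop, template = NULL,
                                      window_bins = NULL,
                                      withheld_trials = 35L,
                                      n_perm = 1000L, n_bins = 3L,
                                      hidden = 10L,
                                      cost_grid = 10^(-1:2), cross = 5L) {
  trials <- pop$trials
  if (is.null(template)) template <- trials$est_template
  stopifnot(!is.null(template), length(template) == nrow(trials))
  if (length(unique(trials$block)) < 3L) {
    stop("need at least 3 blocks for trial-wise decoding", call. = FALSE)
  }
  wb <- window_bins %||% seq_len(dim(pop$rates)[3])
  x <- apply(pop$rates[, , wb, drop = FALSE], c(1, 2), mean)
  x <- scale(x); x[!is.finite(x)] <- 0
  withheld <- trials$trial_in_block <= withheld_trials
  if (sum(!withheld) < 30L) stop("too few training trials", call. = FALSE)
  lab <- color_bin(template, n_bins)
  bundle <- train_template_decoder(x[!withheld, , drop = FALSE],
                                   lab[!withheld], cost_grid, cross)
  post <- decoder_posteriors(bundle, x)
  y2 <- cbind(cos(template), sin(template))
  readout <- relu_mlp_fit(post[!withheld, , drop = FALSE],
                          y2[!withheld, , drop = FALSE], hidden = hidden)
  pred <- readout$predict(post)
  decoded <- canonical_angle(atan2(pred[, 2], pred[, 1]))
  dvec <- abs(angular_distance(decoded[withheld], template[withheld]))
  obs <- mean(dvec)
  null <- vapply(seq_len(n_perm), function(i) {
    mean(abs(angular_distance(decoded[withheld],
                              sample(template[withheld]))))
  }, numeric(1))
  z <- (obs - mean(null)) / stats::sd(null)
  list(decoded = tibble::tibble(trial = trials$trial, decoded = decoded,
                                behavioral = template,
                                withheld = withheld),
       circ_corr = circular_correlation(decoded[withheld],
                                        template[withheld]),
       mean_abs_distance = obs, z = z,
       p_perm = (1 + sum(null <= obs)) / (1 + n_perm),
       bundle = bundle, readout = readout)
}

#' Signed template update toward or away from the chosen color
#'
#' `update = sign(RPE) * sign(d(ET_prev, CC_prev)) * d(ET_prev, ET_now)`:
#' positive when the template moved toward the previously chosen color
#' after a positive RPE, or away from it after a negative RPE.
#'
#' @param et_prev,et_now Estimated template on the previous/current
#'   trial, radians.
#' @param chosen_prev Color chosen on the previous trial.
#' @param rpe_prev RPE of the previous trial.
#' @return Signed update values, radians.
#' @export
update_statistic <- function(et_prev, et_now, chosen_prev, rpe_prev) {
  sign(rpe_prev) * sign(angular_distance(et_prev, chosen_prev)) *
    angular_distance(et_prev, et_now)
}
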
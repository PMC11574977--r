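test_that("the value GLM recovers a pure chosen-value coder", {
  ses <- cached_session()
  set.seed(71)
  reg <- value_regressors(ses)
  n <- nrow(ses)
  gain <- 1.5
  # bin 1 is a signal-free baseline; bins 2-3 carry the value signal
  rates <- array(0, c(n, 2, 3))
  rates[, 1, 1] <- 5 + rnorm(n, 0, 0.1)
  rates[, 2, 1] <- 5 + rnorm(n, 0, 0.1)
  for (b in 2:3) {
    rates[, 1, b] <- 5 + gain * reg$global[, "chosen_value"] + rnorm(n, 0, 0.1)
    rates[, 2, b] <- 5 + rnorm(n, 0, 0.1)  # untuned
  }
  pop <- structure(list(rates = rates, trials = ses,
                        time = time_bins(3)),
                   class = "population_recording")
  w <- value_glm(pop, "global", baseline_bins = 1L, min_trials = 100)
  w2 <- w[w$bin == 2 & w$neuron == 1, ]
  cv <- w2$weight[w2$term == "chosen_value"]
  others <- w2$weight[!w2$term %in% c("chosen_value")]
  expect_gt(abs(cv), 5 * max(abs(others)))
  # untuned neuron: all weights small
  w_u <- w[w$bin == 2 & w$neuron == 2, ]
  expect_lt(max(abs(w_u$weight)), abs(cv) / 3)
})

test_that("shuffled trials yield near-zero GLM weights in expectation", {
  ses <- cached_session()
  set.seed(72)
  n <- nrow(ses)
  reg <- value_regressors(ses)
  rates <- array(5 + rnorm(n * 1 * 2), c(n, 1, 2))
  pop <- structure(list(rates = rates, trials = ses,
                        time = time_bins(2)),
                   class = "population_recording")
  w <- value_glm(pop, "global", baseline_bins = 1L, min_trials = 100)
  # weights are noise: small individually (collinear regressors widen
  # the standard errors) and centered on zero
  expect_lt(max(abs(w$weight[w$bin == 2])), 0.6)
  expect_lt(abs(mean(w$weight[w$bin == 2])), 0.2)
})

test_that("split-half reliability hits 1 for noiseless and ~0 for noise", {
  ses <- cached_session()
  set.seed(73)
  n <- nrow(ses)
  reg <- value_regressors(ses)
  rates <- array(0, c(n, 15, 2))
  w_true <- rnorm(15)
  for (i in 1:15) {
    rates[, i, 1] <- 5
    rates[, i, 2] <- 5 + w_true[i] * reg$global[, "chosen_value"]
  }
  pop <- structure(list(rates = rates, trials = ses,
                        time = time_bins(2)),
                   class = "population_recording")
  rel <- split_half_reliability(pop, "chosen_value", n_splits = 3,
                                n_boot = 200, min_trials = 100,
                                baseline_bins = 1L)
  expect_gt(rel$r[2], 0.999)
  # pure noise population
  set.seed(74)
  rates_n <- array(rnorm(n * 15 * 2), c(n, 15, 2))
  pop_n <- structure(list(rates = rates_n, trials = ses,
                          time = time_bins(2)),
                     class = "population_recording")
  rel_n <- split_half_reliability(pop_n, "chosen_value", n_splits = 4,
                                  n_boot = 200, min_trials = 100,
                                  baseline_bins = 1L)
  expect_lt(abs(rel_n$r[2]), 0.5)
  expect_gt(rel_n$p[2], 0.01)
})

test_that("reliability grows with the trial count", {
  ses <- cached_session()
  set.seed(75)
  reg <- value_regressors(ses)
  r_at <- function(n_tr) {
    n <- nrow(ses)
    w_true <- rnorm(20)
    rates <- array(0, c(n, 20, 2))
    for (i in 1:20) {
      rates[, i, 2] <- 5 + 0.3 * w_true[i] * reg$global[, "chosen_value"] +
        rnorm(n, 0, 1)
    }
    pop <- structure(list(rates = rates, trials = ses,
                          time = time_bins(2)),
                     class = "population_recording")
    rel <- split_half_reliability(pop, "chosen_value", n_splits = 4,
                                  n_boot = 50, min_trials = 50,
                                  baseline_bins = 1L,
                                  trials = sample(n, n_tr))
    rel$r[2]
  }
  # monotone in expectation: average over a couple of draws per size
  r_small <- mean(replicate(2, r_at(60)))
  r_mid <- mean(replicate(2, r_at(240)))
  r_big <- mean(replicate(2, r_at(880)))
  expect_gt(r_mid, r_small - 0.1)
  expect_gt(r_big, r_small)
})

test_that("disattenuation is ~1 for matched-noise twins and ~0 when orthogonal", {
  ses <- cached_session()
  set.seed(76)
  n <- nrow(ses)
  reg <- value_regressors(ses)
  w_shared <- rnorm(20); w_orth <- rnorm(20)
  mk_pop <- function(w_cv, w_rw) {
    rates <- array(0, c(n, 20, 2))
    for (i in 1:20) {
      rates[, i, 2] <- 5 + 0.5 * w_cv[i] * reg$global[, "chosen_value"] +
        0.5 * w_rw[i] * reg$global[, "reward"] + rnorm(n, 0, 1)
    }
    structure(list(rates = rates, trials = ses, time = time_bins(2)),
              class = "population_recording")
  }
  # same loading vector for both factors: gamma ~ 1 despite noise
  pop_tw <- mk_pop(w_shared, w_shared)
  al_tw <- disattenuated_alignment(pop_tw, "chosen_value", "reward",
                                   n_splits = 4, n_boot = 200,
                                   min_trials = 100, baseline_bins = 1L)
  expect_gt(al_tw$gamma[2], 0.75)
  # orthogonal loadings: gamma ~ 0
  pop_or <- mk_pop(w_shared, w_orth)
  al_or <- disattenuated_alignment(pop_or, "chosen_value", "reward",
                                   n_splits = 4, n_boot = 200,
                                   min_trials = 100, baseline_bins = 1L)
  expect_lt(abs(al_or$gamma[2]), 0.45)
  # scale invariance: gamma unchanged when one factor's loadings scale
  al_sc <- disattenuated_alignment(mk_pop(w_shared, 3 * w_shared),
                                   "chosen_value", "reward",
                                   n_splits = 4, n_boot = 100,
                                   min_trials = 100, baseline_bins = 1L)
  expect_equal(al_sc$gamma[2], al_tw$gamma[2], tolerance = 0.25)
})

test_that("the lagged local-to-global fixture aligns at the configured lag", {
  ses <- cached_session()
  set.seed(77)
  hp <- generate_hemifield_value_population(ses, n_neurons = 60,
                                            lag_bins = 2, sigma = 0.5)
  al <- disattenuated_alignment(hp, "value_chosen", "chosen_value",
                                scope_x = "local", locations_x = c(1, 4),
                                scope_y = "global", n_splits = 3,
                                n_boot = 200, min_trials = 100)
  rel <- split_half_reliability(hp, "value_chosen", scope = "local",
                                locations = c(1, 4), n_splits = 3,
                                n_boot = 100, min_trials = 100)
  # local reliability is significant from the onset bin (3)
  expect_gt(rel$r[3], 0.5)
  # alignment to global only becomes significant 2 bins later (bin 5)
  expect_true(is.na(al$gamma[3]) || abs(al$gamma[3]) < 0.4)
  expect_gt(al$gamma[5], 0.7)
  expect_lt(al$p[5], 0.001)
})

test_that("receptive fields are flagged by stimulus presence at ~the test level", {
  ses <- cached_session()
  set.seed(78)
  n <- nrow(ses)
  locs <- cbind(ses$loc1, ses$loc2, ses$loc3)
  on2 <- rowSums(locs == 2) > 0
  rates <- array(rnorm(n * 12 * 4, 5), c(n, 12, 4))
  rates[, 1, ] <- rates[, 1, ] + 2 * on2    # gated by location 2
  rates[, 2, ] <- rates[, 2, ] + 1.5        # all-location gain, no gating
  pop <- structure(list(rates = rates, trials = ses,
                        time = time_bins(4)),
                   class = "population_recording")
  rf <- receptive_field_map(pop, window_bins = 2L)
  expect_true(rf$in_rf[rf$neuron == 1 & rf$location == 2])
  # occupancy is anticorrelated across locations (3 of 4 filled), so the
  # gated neuron shows weaker *negative* modulation elsewhere; its RF
  # location must carry the strongest, positive, modulation
  est1 <- rf$estimate[rf$neuron == 1]
  expect_equal(unname(which.max(abs(est1))), 2L)
  expect_gt(est1[2], 0)
  expect_true(all(est1[-2] < 0))
  # untuned neurons: false positives near the 0.005 level
  fp <- mean(rf$in_rf[rf$neuron >= 3])
  expect_lt(fp, 0.05)
})

test_that("effective dimensionality matches its closed forms", {
  expect_equal(effective_dimensionality(rep(2.5, 7)), 7)
  expect_equal(effective_dimensionality(c(3, 0, 0)), 1)
  expect_equal(effective_dimensionality(c(2, 1)), 1.8)
  # via pca_geometry on constructed data with known eigenvalues
  set.seed(79)
  q <- qr.Q(qr(matrix(rnorm(100), 10)))
  x <- matrix(rnorm(40 * 10), 40) %*% diag(sqrt(c(2, 1, rep(0, 8)))) %*%
    t(q)
  g <- pca_geometry(x)
  ev <- g$eigenvalues[1:2]
  expect_equal(effective_dimensionality(g$eigenvalues),
               sum(ev)^2 / sum(ev^2), tolerance = 0.05)
  expect_error(pca_geometry(x[1, , drop = FALSE]), "2 conditions")
})

test_that("the time-removed PCA variant subtracts per-time condition means", {
  x <- rbind(c(1, 2), c(3, 4), c(10, 20), c(30, 40))
  tt <- c(1, 1, 2, 2)
  g <- pca_geometry(x, time = tt)
  # after per-time centering both time groups have zero mean
  expect_equal(colMeans(g$scores[1:2, , drop = FALSE]),
               colMeans(g$scores[3:4, , drop = FALSE]), tolerance = 1e-9)
})

test_that("MDS embeds planar configurations up to rotation and handles ties", {
  set.seed(80)
  pts <- cbind(cos(seq(0, 2 * pi, length.out = 7)[-7]),
               sin(seq(0, 2 * pi, length.out = 7)[-7]))
  x <- cbind(pts %*% matrix(c(2, 1, -1, 2), 2), matrix(0, 6, 5))
  emb <- mds_embedding(x)
  # distances preserved (classical MDS on truly 2-D data)
  expect_equal(as.vector(stats::dist(emb$points)),
               as.vector(stats::dist(x)), tolerance = 1e-8)
  expect_lt(emb$stress, 1e-8)
  # circular order preserved: walking the embedding by angle visits the
  # original indices in cyclic order (up to rotation and reflection)
  ang <- atan2(emb$points[, 2], emb$points[, 1])
  ord <- order(ang)
  start <- which(ord == 1L)
  fwd <- c(ord[start:6], ord[seq_len(start - 1L)])
  expect_true(identical(fwd, 1:6) ||
                identical(fwd, c(1L, 6:2)))
  # degenerate identical conditions do not crash
  emb0 <- mds_embedding(matrix(1, 4, 3))
  expect_equal(emb0$points, matrix(0, 4, 2))
})

test_that("the alignment AUC reduces to the reliability AUC for (loc, loc)", {
  ses <- cached_session()
  set.seed(81)
  hp <- generate_hemifield_value_population(ses, n_neurons = 40,
                                            lag_bins = 0, sigma = 0.5)
  rel <- split_half_reliability(hp, "value_chosen", scope = "local",
                                locations = 1L, n_splits = 3,
                                n_boot = 50, min_trials = 100)
  auc <- alignment_auc(rel)
  expect_equal(auc, sum(rel$r, na.rm = TRUE))
  expect_equal(alignment_auc(rel, bins = 3:6),
               sum(rel$r[3:6], na.rm = TRUE))
})
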
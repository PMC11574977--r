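test_that("color bins are thirds of the wheel anchored at red = 0", {
  # bin 1 is centered on the red anchor: [-pi/3, pi/3)
  expect_equal(color_bin(0), 1L)
  expect_equal(color_bin(c(-0.9, 0.9)), c(1L, 1L))
  expect_equal(color_bin(c(1.5, -1.5)), c(2L, 3L))
  w <- color_wheel()
  expect_equal(sort(unique(color_bin(w))), 1:3)
  expect_equal(sort(as.integer(table(color_bin(w)))), c(33L, 33L, 34L))
})

test_that("pseudo-populations are balanced and reproducible under a seed", {
  ses <- cached_session()
  set.seed(61)
  specs <- neuron_specs(12, mix = c(template = 1), sigma = 0.5)
  pop <- generate_population(ses, specs)
  lf <- function(tr) color_bin(tr$est_template)
  set.seed(7)
  pps <- build_pseudopopulation(pop, lf, n_neurons = 10, n_trials = 30,
                                n_bootstraps = 3)
  expect_length(pps, 3L)
  for (pp in pps) {
    expect_equal(as.integer(table(pp$label)), rep(30L, 3L))
    # validation split balanced per condition
    expect_equal(as.integer(table(pp$label[pp$is_val])), rep(6L, 3L))
    expect_equal(dim(pp$x), c(90L, 10L))
  }
  set.seed(7)
  pps2 <- build_pseudopopulation(pop, lf, n_neurons = 10, n_trials = 30,
                                 n_bootstraps = 3)
  expect_identical(pps[[1]]$x, pps2[[1]]$x)
  # insufficient trials per condition names the problem
  expect_error(build_pseudopopulation(pop, lf, n_trials = 10000),
               "every condition")
})

test_that("a tuned population decodes the template; untuned sits at chance", {
  ses <- cached_session()
  set.seed(62)
  tuned <- generate_population(ses, neuron_specs(
    24, mix = c(template = 1), sigma = 0.3, latency = 1, width = 6))
  untuned <- generate_population(ses, neuron_specs(
    24, mix = c(untuned = 1), sigma = 1))
  lf <- function(tr) color_bin(tr$est_template)
  set.seed(8)
  pp_t <- build_pseudopopulation(tuned, lf, n_neurons = 24,
                                 n_trials = 40, n_bootstraps = 1)[[1]]
  acc_t <- decode_template_accuracy(pp_t, cost_grid = 10^(-1:1),
                                    cross = 4)
  expect_gt(acc_t$accuracy, 0.8)
  accs <- replicate(4, {
    pp_u <- build_pseudopopulation(untuned, lf, n_neurons = 24,
                                   n_trials = 40, n_bootstraps = 1)[[1]]
    decode_template_accuracy(pp_u, cost_grid = 10^(-1:1),
                             cross = 4)$accuracy
  })
  expect_lt(abs(mean(accs) - 1 / 3), 0.18)
})

test_that("decoding accuracy rises with tuning gain", {
  ses <- cached_session()
  lf <- function(tr) color_bin(tr$est_template)
  mean_acc <- vapply(c(0, 1, 3), function(g) {
    set.seed(63)
    pop <- generate_population(ses, neuron_specs(
      20, mix = c(template = 1), gain = g, sigma = 1,
      latency = 1, width = 6))
    set.seed(9)
    pp <- build_pseudopopulation(pop, lf, n_neurons = 20, n_trials = 40,
                                 n_bootstraps = 1)[[1]]
    decode_template_accuracy(pp, cost_grid = 10^(-1:1),
                             cross = 4)$accuracy_argmax
  }, numeric(1))
  expect_true(all(diff(mean_acc) >= -0.05))  # monotone up to noise
  expect_gt(mean_acc[3], mean_acc[1] + 0.2)
})

test_that("the multi-class readout matches argmax on one-hot posteriors", {
  set.seed(64)
  n <- 120
  lab <- sample(1:3, n, replace = TRUE)
  post <- diag(3)[lab, ] |> (\(m) m + 0)() # one-hot
  is_val <- seq_len(n) <= 30
  ro <- multiclass_readout(post, lab, is_val)
  expect_equal(ro$accuracy_argmax, 1)
  expect_equal(ro$accuracy, 1)
  # random posteriors decode at chance
  post_r <- matrix(runif(n * 3), n)
  ro_r <- multiclass_readout(post_r, sample(1:3, n, replace = TRUE),
                             is_val)
  expect_lt(abs(ro_r$accuracy - 1 / 3), 0.35)
})

test_that("cross-condition generalization separates shared from remapped codes", {
  ses <- cached_session()
  set.seed(65)
  n <- nrow(ses)
  cond <- color_bin(ses$est_template)
  value <- rnorm(n)
  target <- factor(ifelse(value > 0, "hi", "lo"))
  # shared code: same loading vector under every condition
  w <- rnorm(20)
  x_shared <- outer(value, w) + matrix(rnorm(n * 20, 0, 0.5), n)
  g1 <- cross_generalization(x_shared, target, cond, train_condition = 1)
  expect_gt(g1$within, 0.75)
  expect_gt(g1$across, 0.75)
  expect_lt(abs(g1$within - g1$across), 0.2)
  # condition-locked remapping: loading sign flips across conditions
  flip <- ifelse(cond == 1, 1, -1)
  x_remap <- outer(value, w) * flip + matrix(rnorm(n * 20, 0, 0.5), n)
  g2 <- cross_generalization(x_remap, target, cond, train_condition = 1)
  expect_gt(g2$within, 0.75)
  expect_lt(g2$across, 0.4)   # below chance: anti-generalizing
  # shuffled labels: both near 1/2
  g3 <- cross_generalization(x_shared, sample(target), cond, 1)
  expect_lt(abs(g3$within - 0.5), 0.3)
  expect_lt(abs(g3$across - 0.5), 0.12)
})

test_that("the update statistic has the documented sign conventions", {
  # toward the chosen color after a positive RPE
  expect_equal(update_statistic(0, 0.1, 0.5, +1), 0.1)
  # away from the chosen color after a negative RPE
  expect_equal(update_statistic(0, -0.1, 0.5, -1), 0.1)
  # no movement, no update
  expect_equal(update_statistic(0.3, 0.3, -1, 1), 0)
  # vectorized and wrap-safe
  expect_equal(update_statistic(c(0, 0), c(0.1, -0.1), c(0.5, 0.5),
                                c(1, -1)), c(0.1, 0.1))
})

test_that("trial-wise circular decoding recovers the template on withheld trials", {
  ses <- cached_session()
  set.seed(66)
  pop <- generate_population(ses, neuron_specs(
    30, mix = c(template = 1), sigma = 0.2, latency = 1, width = 6))
  set.seed(10)
  dec <- decode_trialwise_template(pop, n_perm = 100,
                                   cost_grid = 10^(0:1), cross = 3)
  expect_gt(dec$circ_corr, 0.7)
  expect_lt(dec$z, -3)  # observed distance far below the shuffle null
  expect_true(all(dec$decoded$decoded >= -pi & dec$decoded$decoded < pi))
  # permutation z near zero for an untuned population
  set.seed(67)
  pop_u <- generate_population(ses, neuron_specs(
    30, mix = c(untuned = 1), sigma = 1))
  set.seed(11)
  dec_u <- decode_trialwise_template(pop_u, n_perm = 100,
                                     cost_grid = 10^(0:1), cross = 3)
  expect_lt(abs(dec_u$z), 3)
})
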
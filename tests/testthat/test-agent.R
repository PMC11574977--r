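test_that("parameter counts match the model variants", {
  expect_equal(attr(agent_params("no_reset"), "n_params"), 10L)
  expect_equal(attr(agent_params("reset"), "n_params"), 12L)
  expect_equal(attr(agent_params("dual_alpha"), "n_params"), 13L)
  expect_equal(attr(agent_params("wslf"), "n_params"), 8L)
  expect_equal(attr(agent_params("wsls"), "n_params"), 8L)
  expect_error(agent_params("reset", location_bias = c(1, 0, 0, 0)),
               "pinned")
})

test_that("the value function is linear in the basis and shift-equivariant", {
  p <- agent_params("reset", kappa_basis = 2, n_basis = 6)
  s <- agent_init(p)
  th <- seq(-pi, pi, length.out = 17)
  expect_equal(value_function(s, p, th), rep(0, 17))
  # one-hot weight peaks at the basis center
  s$weights[3] <- 1
  mu3 <- templateRL:::basis_centers(6)[3]
  grid <- color_wheel(1000)
  expect_equal(grid[which.max(value_function(s, p, grid))], mu3,
               tolerance = 2 * pi / 1000)
  # rotating theta and all centers together leaves v unchanged:
  # a rotation by one basis step equals rotating the weights
  s2 <- s
  s2$weights <- s$weights[c(6, 1:5)]
  delta <- 2 * pi / 6
  expect_equal(value_function(s2, p, th + delta),
               value_function(s, p, th), tolerance = 1e-12)
})

test_that("expected value adds the documented biases", {
  p <- agent_params("reset", pref_color_bias = 0.4, theta_pref = 0.9,
                    location_bias = c(0, 0.3, 0, 0),
                    size_bias = c(-0.2, 0.5))
  s <- agent_init(p)
  # v = 0, only biases: at theta_pref the proximity term is b * pi
  ev <- expected_value(s, p, colors = 0.9, locations = 1L, sizes = 0L)
  expect_equal(ev, 0.4 * pi)
  # location and size biases add
  ev2 <- expected_value(s, p, colors = 0.9, locations = 2L, sizes = 2L)
  expect_equal(ev2, 0.4 * pi + 0.3 + 0.5)
  # two identical options get identical EV
  ev3 <- expected_value(s, p, colors = c(2, 2), locations = c(3, 3),
                        sizes = c(0, 0))
  expect_equal(ev3[1], ev3[2])
  # prev-color term absent on the first trial
  p2 <- agent_params("reset", prev_color_bias = 1)
  expect_equal(expected_value(agent_init(p2), p2, 1, 1L, 0L), 0)
})

test_that("softmax probabilities normalize and are shift invariant", {
  expect_equal(choice_probabilities(c(2, 2, 2), 0.3), rep(1 / 3, 3))
  # hand-evaluated: EV = (1,0,0), beta = 0.3
  p <- choice_probabilities(c(1, 0, 0), 0.3)
  expect_equal(p, c(0.93340354, 0.03329823, 0.03329823),
               tolerance = 1e-7)
  set.seed(3)
  for (i in 1:20) {
    ev <- rnorm(3, 0, 2)
    pp <- choice_probabilities(ev, 0.3)
    expect_equal(sum(pp), 1, tolerance = 1e-12)
    expect_equal(choice_probabilities(ev + 7.3, 0.3), pp,
                 tolerance = 1e-12)
  }
  expect_error(choice_probabilities(c(Inf, 0, 0), 0.3), "finite")
})

test_that("the update rule follows the RPE and reset dynamics", {
  p <- agent_params("reset", alpha = 0, beta_reset = 1e4,
                    reset_threshold0 = 100)  # no reset, no learning
  s <- agent_init(p)
  u <- agent_update(s, p, chosen = 1, reward = 3)
  expect_equal(u$state$weights, rep(0, 6))
  expect_equal(u$rpe, 3)
  # reset branch: k = 1 gives w_i = R * x_i(chosen) exactly
  p2 <- agent_params("reset", alpha = 0.25, reset_threshold0 = 1e-9,
                     volatility = 10)  # always reset
  s2 <- agent_init(p2)
  set.seed(4)
  s2$weights <- rnorm(6)
  u2 <- agent_update(s2, p2, chosen = 0.7, reward = 3)
  x <- drop(templateRL:::basis_activation(0.7, p2))
  expect_equal(u2$state$weights, 3 * x, tolerance = 1e-8)
  expect_true(u2$reset)
  expect_equal(u2$state$trials_since_reset, 1L)
  # incremental branch: from zero weights, new v(chosen) = a*R*sum(x^2)
  p3 <- agent_params("no_reset", alpha = 0.25, kappa_basis = 2)
  s3 <- agent_init(p3)
  u3 <- agent_update(s3, p3, chosen = -0.4, reward = 2)
  x3 <- drop(templateRL:::basis_activation(-0.4, p3))
  expect_equal(value_function(u3$state, p3, -0.4),
               0.25 * 2 * sum(x3^2), tolerance = 1e-10)
  expect_equal(u3$state$trials_since_reset, 2L)
})

test_that("reset fraction is effectively binary at beta_reset = 1e4", {
  p <- agent_params("reset", reset_threshold0 = 0.5, volatility = 10)
  s <- agent_init(p)
  s$trials_since_reset <- 1000L  # threshold ~ threshold0
  # |RPE| more than 0.01 away from the threshold: k is 0 or 1
  for (r in c(0, 0.2, 0.48, 0.52, 1, 3)) {
    u <- agent_update(s, p, chosen = 0, reward = r)
    if (abs(abs(u$rpe) - 0.5) > 0.01) {
      expect_true(u$k_reset < 1e-6 || u$k_reset > 1 - 1e-6)
    }
  }
})

test_that("the estimated template is the argmax with lowest-index ties", {
  p <- agent_params("reset")
  s <- agent_init(p)
  wheel <- color_wheel()
  # all-zero values: first grid point by the tie rule
  expect_equal(estimated_template(s, p, wheel), wheel[1])
  # one-hot weight: nearest grid point to that basis center
  s$weights[4] <- 1
  mu4 <- templateRL:::basis_centers(6)[4]
  expect_lt(abs(angular_distance(estimated_template(s, p, wheel), mu4)),
            2 * pi / 100)
})

test_that("template converges to a repeatedly rewarded color", {
  p <- agent_params("reset", alpha = 0.3, kappa_basis = 2)
  s <- agent_init(p)
  target <- 0.83
  for (i in 1:60) {
    r <- reward_function(target, target, 2.5, 6)
    s <- agent_update(s, p, chosen = target, reward = r)$state
  }
  expect_lt(abs(angular_distance(estimated_template(s, p), target)),
            2 * pi / 100 + 1e-9)
})

test_that("value entropy has the uniform closed form and expected behavior", {
  p <- agent_params("reset")
  s <- agent_init(p)
  # flat value function: differential entropy log(2*pi)
  expect_equal(value_entropy(s, p), log(2 * pi), tolerance = 1e-9)
  # concentrating the value function lowers the entropy monotonically
  ents <- vapply(c(0.5, 1, 2, 4, 8), function(k) {
    p2 <- agent_params("reset", kappa_basis = k, n_basis = 8)
    s2 <- agent_init(p2)
    s2$weights[1] <- 1
    value_entropy(s2, p2)
  }, numeric(1))
  expect_true(all(diff(ents) < 0))
  # invariant to adding a constant to v (via a uniform weight shift the
  # basis cannot produce exactly, so test through the definition)
  s3 <- agent_init(p)
  set.seed(5)
  s3$weights <- rnorm(6)
  wheel <- color_wheel()
  v <- value_function(s3, p, wheel)
  ent_of <- function(v) {
    pm <- v - min(v) + 1 / length(v)
    pm <- pm / sum(pm * 2 * pi / length(v))
    -sum(pm * log(pm)) * 2 * pi / length(v)
  }
  expect_equal(value_entropy(s3, p), ent_of(v), tolerance = 1e-10)
  expect_equal(ent_of(v + 5), ent_of(v), tolerance = 1e-10)
})

test_that("win-stay-lose-forget and lose-shift follow their rules", {
  for (variant in c("wslf", "wsls")) {
    p <- agent_params(variant, reward_threshold = 2)
    s <- agent_init(p)
    # win: remembered template becomes the chosen color
    u <- agent_update(s, p, chosen = 0.5, reward = 3)
    ev <- expected_value(u$state, p, colors = c(0.5, 2.5, -2),
                         locations = 1:3)
    expect_equal(which.max(ev), 1L)
    # lose
    u2 <- agent_update(u$state, p, chosen = 0.5, reward = 1)
    if (variant == "wslf") {
      expect_true(is.na(u2$state$wsl_template))
      ev2 <- expected_value(u2$state, p, colors = c(0.5, 2.5, -2),
                            locations = 1:3)
      expect_equal(choice_probabilities(ev2, 0.3), rep(1 / 3, 3),
                   tolerance = 1e-12)
    } else {
      # shift: template is the opposite color
      expect_equal(u2$state$wsl_template, canonical_angle(0.5 + pi))
      ev2 <- expected_value(u2$state, p,
                            colors = c(0.5, canonical_angle(0.5 + pi), 2),
                            locations = 1:3)
      expect_equal(which.max(ev2), 2L)
    }
  }
})

test_that("learning raises the best-choice rate above chance soon after a switch", {
  set.seed(11)
  ses <- simulate_trials(monkey_params(), 1500)
  lc <- learning_curve(ses, max_trial = 35)
  # well above 1/3 chance within ~15 trials of the (uncued) switch
  expect_gt(mean(lc$p_best[12:18]), 0.5)
  expect_gt(mean(ses$best_chosen), 0.6)
})
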
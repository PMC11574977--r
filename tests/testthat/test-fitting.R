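# slow R reference forward pass: step the exported agent over the
# recorded choices, accumulating the softmax log likelihood
nll_reference <- function(params, session) {
  state <- agent_init(params)
  nll <- 0
  for (t in seq_len(nrow(session))) {
    colors <- c(session$color1[t], session$color2[t], session$color3[t])
    locs <- c(session$loc1[t], session$loc2[t], session$loc3[t])
    sizes <- rep(0L, 3L)
    if (session$size_stim[t] > 0L) {
      sizes[session$size_stim[t]] <- session$size_type[t]
    }
    ev <- expected_value(state, params, colors, locs, sizes)
    pr <- choice_probabilities(ev, params$beta_softmax)
    nll <- nll - log(pr[session$chosen_idx[t]])
    state <- agent_update(state, params, colors[session$chosen_idx[t]],
                          session$reward[t])$state
  }
  nll
}

test_that("an all-zero agent yields the uniform-policy likelihood", {
  set.seed(31)
  ses <- simulate_trials(monkey_params(), 300)
  p0 <- agent_params("no_reset", alpha = 0, kappa_basis = 1)
  expect_equal(negative_log_likelihood(p0, ses), 300 * log(3),
               tolerance = 1e-9)
  tr <- negative_log_likelihood(p0, ses, traces = TRUE)
  expect_equal(tr$mean_lik, 1 / 3, tolerance = 1e-9)
})

test_that("the fast forward pass matches the reference agent exactly", {
  set.seed(32)
  ses <- simulate_trials(monkey_params(), 250)
  for (p in list(monkey_params("reset", reset_threshold0 = 0.4),
                 monkey_params("no_reset"),
                 monkey_params("dual_alpha", alpha_neg = 0.15),
                 agent_params("wslf", reward_threshold = 2,
                              pref_color_bias = 0.1, theta_pref = 0.5,
                              location_bias = c(0, 0.2, 0, -0.1)),
                 agent_params("wsls", reward_threshold = 2))) {
    expect_equal(negative_log_likelihood(p, ses), nll_reference(p, ses),
                 tolerance = 1e-8, info = p$variant)
  }
})

test_that("likelihood is deterministic and favors the generative parameters", {
  set.seed(33)
  p <- monkey_params()
  ses <- simulate_trials(p, 800)
  n1 <- negative_log_likelihood(p, ses)
  expect_identical(n1, negative_log_likelihood(p, ses))
  # heavily perturbed parameters do worse across several seeds
  worse <- 0L
  for (s in 1:5) {
    set.seed(330 + s)
    ses_s <- simulate_trials(p, 600)
    pp <- monkey_params(alpha = 0.75, kappa_basis = 8)
    worse <- worse + (negative_log_likelihood(pp, ses_s) >
                        negative_log_likelihood(p, ses_s))
  }
  expect_gte(worse, 4L)
})

test_that("per-trial likelihoods and BIC obey their identities", {
  set.seed(34)
  ses <- simulate_trials(monkey_params(), 600)
  f <- fit_session(ses, "no_reset", n_starts = 4L, maxit_nm = 150L,
                   maxit_polish = 25L)
  expect_equal(f$bic, f$n_params * log(f$n_trials) + 2 * f$neg_log_lik)
  expect_equal(f$neg_log_lik, -sum(f$loglik), tolerance = 1e-8)
  lik <- exp(f$loglik)
  expect_true(all(lik > 0 & lik <= 1))
  expect_gte(f$mean_lik, 1 / 3 - 0.01)
  g <- glance(f)
  expect_equal(g$bic, f$bic)
  td <- tidy(f)
  expect_equal(nrow(td), 10L)
  expect_true(all(c("term", "estimate") %in% names(td)))
})

test_that("fitting is reproducible under a fixed seed", {
  set.seed(35)
  ses <- simulate_trials(monkey_params(), 500)
  set.seed(99)
  f1 <- fit_session(ses, "no_reset", n_starts = 3L, maxit_nm = 100L,
                    maxit_polish = 20L)
  set.seed(99)
  f2 <- fit_session(ses, "no_reset", n_starts = 3L, maxit_nm = 100L,
                    maxit_polish = 20L)
  expect_identical(f1$neg_log_lik, f2$neg_log_lik)
  expect_identical(tidy(f1)$estimate, tidy(f2)$estimate)
})

test_that("model comparison tabulates BIC differences with a single winner", {
  set.seed(36)
  ses <- simulate_trials(monkey_params(), 700)
  set.seed(100)
  cmp <- compare_models(ses, variants = c("no_reset", "reset"),
                        n_starts = 4L, maxit_nm = 150L,
                        maxit_polish = 25L)
  expect_equal(nrow(cmp), 2L)
  expect_equal(sum(cmp$winner), 1L)
  expect_equal(cmp$delta_bic[1], 0)
  expect_true(all(cmp$delta_bic >= 0))
  # antisymmetry: delta of A vs B is minus delta of B vs A
  d <- diff(cmp$bic)
  expect_equal(cmp$delta_bic[2], abs(d))
})

test_that("the dual-learning-rate extension is penalized on nested data", {
  set.seed(37)
  ses <- simulate_trials(monkey_params(reset_threshold0 = 0.4), 900)
  set.seed(101)
  cmp <- compare_models(ses, variants = c("reset", "dual_alpha"),
                        n_starts = 4L, maxit_nm = 150L,
                        maxit_polish = 25L)
  # dual_alpha nests reset (alpha_neg = alpha): its NLL can only match,
  # so the extra parameter costs BIC
  nll <- cmp$neg_log_lik[match(c("reset", "dual_alpha"), cmp$variant)]
  expect_gte(nll[1] + 1e-6, nll[2] - 2)   # near-nested likelihoods
  expect_equal(cmp$variant[cmp$winner][1], "reset")
})

test_that("theta_pref canonicalization removes the sign degeneracy", {
  # the two representations must give identical likelihoods
  set.seed(38)
  ses <- simulate_trials(monkey_params(), 300)
  p_pos <- agent_params("reset", pref_color_bias = 0.3, theta_pref = 0.8)
  p_neg <- agent_params("reset", pref_color_bias = -0.3,
                        theta_pref = canonical_angle(0.8 + pi))
  expect_equal(negative_log_likelihood(p_pos, ses),
               negative_log_likelihood(p_neg, ses), tolerance = 1e-9)
})
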
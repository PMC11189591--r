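test_that("delta rule arithmetic and limits", {
  expect_equal(rl_update(0.5, 1, 0.2), 0.6)
  expect_equal(rl_update(0.3, 0.9, 1), 0.9)   # full update
  expect_equal(rl_update(0.3, 0.9, 0), 0.3)   # no learning
})

test_that("speed classification uses the running mean including the current trial", {
  expect_equal(classify_speed(1.0, 1.0), "fast")          # first trial
  expect_equal(classify_speed(2, c(1, 1, 2)), "slow")     # 2 > 4/3
  expect_equal(classify_speed(1, c(2, 2, 1)), "fast")
})

test_that("condition-specific outcomes follow the printed rules", {
  # choice visible: selfishness of the chosen allocation
  expect_equal(outcome_choice(0.8, 0.2, "left"), 1)
  expect_equal(outcome_choice(0.8, 0.2, "right"), 0)
  expect_equal(outcome_choice(0.4, 0.6, "right"), 1)
  # RT only: slow teaches the midpoint
  expect_equal(outcome_rt(0.3, 0.7, "slow", P_prev = 0.9), 0.5)
  # RT only, fast: inferred choice under the current estimate
  expect_equal(outcome_rt(0.4, 0.6, "fast", P_prev = 0.8), 1)
  expect_equal(outcome_rt(0.4, 0.6, "fast", P_prev = 0.2), 0)
  # both visible, unweighted rule
  expect_equal(outcome_both(0.2, 0.6, "left", "slow"), 0.4)
  expect_equal(outcome_both(0.2, 0.6, "right", "fast"), 1)
  expect_equal(outcome_both(0.2, 0.6, "left", "fast"), 0)
  # nothing visible: midpoint
  expect_equal(outcome_none(0.3, 0.7), 0.5)
  expect_equal(outcome_none(0.1, 0.2), 0.15)
  # weighted mixture
  expect_equal(combined_outcome(1, 0.5, 0), 1)
  expect_equal(combined_outcome(1, 0.5, 1), 0.5)
  expect_equal(combined_outcome(1, 0.5, 0.5), 0.75)
})

test_that("the forward pass agrees with the granular outcome operations", {
  set.seed(60)
  for (cond in c("none", "rt_only", "choice_only", "both")) {
    n <- 12L
    obs <- data.frame(left = runif(n), right = runif(n),
                      choice = sample(c("left", "right"), n, TRUE),
                      rt = runif(n, 0.3, 4))
    pars <- rl_params(alpha = 0.35, P0 = 0.4, omega = 0.6)
    traj <- rl_forward(obs, cond, pars)
    # reference trajectory built from the exported single-trial operations
    P <- pars$P0
    rts <- numeric(0)
    for (t in seq_len(n)) {
      speed <- NULL
      if (cond %in% c("rt_only", "both")) {
        rts <- c(rts, obs$rt[t])
        speed <- classify_speed(obs$rt[t], rts)
      }
      o <- switch(cond,
        none = outcome_none(obs$left[t], obs$right[t]),
        choice_only = outcome_choice(obs$left[t], obs$right[t],
                                     obs$choice[t]),
        rt_only = outcome_rt(obs$left[t], obs$right[t], speed, P),
        both = combined_outcome(
          outcome_choice(obs$left[t], obs$right[t], obs$choice[t]),
          outcome_rt(obs$left[t], obs$right[t], speed, P),
          pars$omega))
      P <- rl_update(P, o, pars$alpha)
      expect_equal(traj[t + 1], P)
    }
  }
})

test_that("the estimate trajectory never leaves the unit interval", {
  set.seed(61)
  for (cond in c("none", "rt_only", "choice_only", "both")) {
    for (i in 1:10) {
      n <- 12L
      obs <- data.frame(left = runif(n), right = runif(n),
                        choice = sample(c("left", "right"), n, TRUE),
                        rt = runif(n, 0.3, 4))
      pars <- rl_params(alpha = runif(1), P0 = runif(1), omega = runif(1))
      traj <- rl_forward(obs, cond, pars)
      expect_true(all(traj >= 0 & traj <= 1))
      expect_equal(traj[1], pars$P0)
    }
  }
})

test_that("with slow observations the estimate converges to the mean midpoint", {
  n <- 60L
  obs <- data.frame(left = rep(0.3, n), right = rep(0.7, n),
                    choice = NA_character_,
                    rt = c(0.1, rep(10, n - 1))) # all but the first are slow
  traj <- rl_forward(obs, "rt_only", rl_params(alpha = 0.3, P0 = 0.9))
  expect_lt(abs(traj[n + 1] - 0.5), 0.01)
})

test_that("estimation likelihood is a symmetric well around the model estimate", {
  nll0 <- estimation_negloglik(0.4, 0.4, sigma = 0.1)
  expect_equal(nll0, -dnorm(0, sd = 0.1, log = TRUE))
  expect_equal(estimation_negloglik(0.5, 0.4, 0.1),
               estimation_negloglik(0.3, 0.4, 0.1))
  expect_lt(nll0, estimation_negloglik(0.45, 0.4, 0.1))
  expect_lt(estimation_negloglik(0.45, 0.4, 0.1),
            estimation_negloglik(0.6, 0.4, 0.1))
})

test_that("prediction likelihood is the negative log softmax probability", {
  # equal values: -log(1/2)
  expect_equal(prediction_negloglik(0.3, 0.7, 0.5, beta_p = 5), -log(0.5))
  # strongly preferred choice at high temperature: objective tends to zero
  expect_lt(prediction_negloglik(0.81, 0.1, 0.8, beta_p = 50), 1e-4)
  # agrees with the softmax choice probability
  p <- choice_prob_left(0.2, 0.9, 0.35, beta = 7)
  expect_equal(prediction_negloglik(0.2, 0.9, 0.35, beta_p = 7), -log(p))
  # literal variant is the negated probability itself
  expect_equal(prediction_negloglik(0.2, 0.9, 0.35, beta_p = 7,
                                    literal = TRUE), -p)
})

test_that("observer simulation reports P0 at slot zero and respects the seed", {
  ch <- test_cohort()
  ses <- ch$sessions[[2]]
  pars <- rl_params(alpha = 0.3, P0 = 0.42)
  sim <- simulate_observer(ses, pars, report_noise = FALSE)
  expect_equal(sim$estimates[ses$estimation_slots == 0], 0.42)
  expect_true(all(sim$predictions %in% c("left", "right")))
  set.seed(77)
  a <- simulate_observer(ses, pars)
  set.seed(77)
  b <- simulate_observer(ses, pars)
  expect_identical(a, b)
})

test_that("both-condition observers learn that a selfish dictator is selfish", {
  ch <- test_cohort()
  both_ses <- Filter(function(s) s$condition == "both", ch$sessions)
  selfish <- both_ses[[which.max(sapply(both_ses, `[[`, "true_pref"))]]
  finals <- replicate(100, {
    sim <- simulate_observer(selfish, rl_params(), report_noise = FALSE)
    sim$traj[length(sim$traj)]
  })
  expect_gt(median(finals), 0.5)
})

test_that("RL fitting is seed-reproducible and at least as good as the truth", {
  ch <- test_cohort()
  set.seed(62)
  truth <- rl_params(alpha = 0.4, P0 = 0.5, omega = 0.3, beta_p = 6)
  ses_obs <- simulate_observer_sessions(ch$sessions[1:8], truth)
  set.seed(63)
  f1 <- fit_rl(ses_obs, n_starts = 5)
  set.seed(63)
  f2 <- fit_rl(ses_obs, n_starts = 5)
  expect_identical(f1, f2)
  expect_lte(f1$nll, speedpref:::rl_negloglik(ses_obs, truth))
})
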
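test_that("parameter constructors validate their inputs", {
  expect_error(ddm_params(boundary = -1, nondecision = 0.3, drift_scale = 5),
               "> 0")
  expect_error(ddm_params(boundary = 2, nondecision = -0.1, drift_scale = 5),
               ">= 0")
  expect_error(ddm_params(boundary = 2, nondecision = 0.3, drift_scale = 5,
                          start_bias = 1.2), "\\(0, 1\\)")
  p <- ddm_params(boundary = 2, nondecision = 0.3, drift_scale = 5)
  expect_equal(p$noise_sd, 1)
  expect_equal(p$start_bias, 0.5)
})

test_that("drift rate is the scaled signed value difference", {
  p <- ddm_params(boundary = 2, nondecision = 0.3, drift_scale = 5)
  v <- trial_drift(0.2, 0.8, 0.3, p)
  expect_equal(v, 5 * (subjective_value(0.2, 0.3) -
                         subjective_value(0.8, 0.3)))
  expect_gt(v, 0) # left option closer to the preference
})

test_that("wfpt density is symmetric at zero drift and zero before the non-decision time", {
  p <- ddm_params(boundary = 2, nondecision = 0.3, drift_scale = 5)
  ts <- seq(0.35, 3, by = 0.05)
  expect_equal(wfpt_density(ts, "upper", p, v = 0),
               wfpt_density(ts, "lower", p, v = 0))
  expect_equal(wfpt_density(c(0.1, 0.3), "upper", p, v = 1), c(0, 0))
  expect_true(all(wfpt_density(ts, "upper", p, v = 2) >= 0))
  expect_error(wfpt_density(1, "upper", p, v = NaN), "finite")
})

test_that("single-boundary mass matches the closed-form absorption probability", {
  for (setting in list(c(v = 0.7, b = 2), c(v = -1.2, b = 1.5),
                       c(v = 2.0, b = 3))) {
    p <- ddm_params(boundary = setting["b"], nondecision = 0.3,
                    drift_scale = 1)
    m_up <- integrate(function(t) wfpt_density(t, "upper", p, setting["v"]),
                      0.3, Inf, rel.tol = 1e-8)$value
    m_lo <- integrate(function(t) wfpt_density(t, "lower", p, setting["v"]),
                      0.3, Inf, rel.tol = 1e-8)$value
    expect_lt(abs(m_up - ddm_absorption_prob(setting[["v"]],
                                             setting[["b"]])), 1e-3)
    expect_lt(abs(m_up + m_lo - 1), 1e-3)
  }
})

test_that("simulated choice frequencies match the closed form", {
  p <- ddm_params(boundary = 2, nondecision = 0.3, drift_scale = 5)
  set.seed(5)
  n <- 4000L
  # moderate positive drift: left favoured
  sims <- replicate(n, simulate_decision(0.2, 0.8, 0.3, p)$choice)
  v <- trial_drift(0.2, 0.8, 0.3, p)
  p_left <- ddm_absorption_prob(v, 2)
  se <- sqrt(p_left * (1 - p_left) / n)
  expect_lt(abs(mean(sims == "left") - p_left), 3 * se)
  # all response times exceed the non-decision time
  rts <- replicate(200, simulate_decision(0.4, 0.6, 0.5, p)$rt)
  expect_true(all(rts > p$nondecision))
})

test_that("RT-only likelihood sums both boundaries and respects reflection symmetry", {
  p <- ddm_params(boundary = 2, nondecision = 0.3, drift_scale = 5)
  one <- data.frame(left = 0.3, right = 0.7, rt = 1.2)
  # symmetric pair at the symmetric preference: zero drift, equal densities
  ll <- rt_only_loglik(one, 0.5, p)
  expect_equal(ll, log(2 * wfpt_density(1.2, "upper", p, 0)))
  expect_true(is.finite(rt_only_loglik(one, 0.9, p)))
  # relabeling left/right while reflecting the preference leaves it unchanged
  set.seed(8)
  trials <- data.frame(left = runif(30), right = runif(30),
                       rt = runif(30, 0.5, 3))
  mirrored <- data.frame(left = 1 - trials$right, right = 1 - trials$left,
                         rt = trials$rt)
  for (pref in c(0.2, 0.5, 0.8)) {
    expect_equal(rt_only_loglik(trials, pref, p),
                 rt_only_loglik(mirrored, 1 - pref, p))
  }
})

test_that("joint likelihood decomposes into the RT-only integrand", {
  p <- ddm_params(boundary = 2, nondecision = 0.3, drift_scale = 5)
  tr <- data.frame(left = 0.2, right = 0.9, rt = 1.1)
  ll_left <- joint_loglik(cbind(tr, choice = "left"), 0.4, p)
  ll_right <- joint_loglik(cbind(tr, choice = "right"), 0.4, p)
  expect_equal(exp(ll_left) + exp(ll_right),
               exp(rt_only_loglik(tr, 0.4, p)))
  # zero drift: recorded choice is irrelevant
  sym <- data.frame(left = 0.3, right = 0.7, rt = 1.5)
  expect_equal(joint_loglik(cbind(sym, choice = "left"), 0.5, p),
               joint_loglik(cbind(sym, choice = "right"), 0.5, p))
})

test_that("joint likelihood peaks near the generating preference", {
  p <- ddm_params(boundary = 2, nondecision = 0.3, drift_scale = 5)
  set.seed(14)
  design <- make_design(study_config())
  trials <- generate_dictator_dataset(
    list(id = 1, pref = 0.3, params = p), design)
  grid <- seq(0.05, 0.95, by = 0.05)
  ll <- vapply(grid, function(q) joint_loglik(trials, q, p), numeric(1))
  expect_lt(abs(grid[which.max(ll)] - 0.3), 0.1)
})

test_that("RT-only preference fitting recovers a simulated dictator", {
  p <- ddm_params(boundary = 2, nondecision = 0.3, drift_scale = 5)
  set.seed(15)
  design <- make_design(study_config())
  errs <- replicate(5, {
    trials <- generate_dictator_dataset(
      list(id = 1, pref = 0.3, params = p), design)
    fit <- fit_preference_rt(trials, n_starts = 10)
    fit$pref - 0.3
  })
  expect_lt(abs(median(errs)), 0.1)
})

test_that("constant response times give a flagged degenerate fit", {
  trials <- data.frame(left = runif(30, 0, 0.4), right = runif(30, 0.6, 1),
                       rt = rep(1.2, 30))
  expect_warning(fit <- fit_preference_rt(trials, n_starts = 2),
                 "degenerate")
  expect_true(fit$degenerate)
})
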
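test_that("RT regression recovers exact linear structure", {
  pref <- 0.3
  set.seed(31)
  trials <- data.frame(left = runif(20, 0, 0.45), right = runif(20, 0.55, 1))
  difficulty <- sv_difference(trials$left, trials$right, pref)
  trials$rt <- 2 - 1 * difficulty
  fit <- fit_rt_regression(trials, pref)
  expect_equal(fit$b0, 2)
  expect_equal(fit$b1, -1)
  # two distinct points: exact interpolation
  two <- trials[1:2, ]
  two$rt <- c(1.1, 1.7)
  fit2 <- suppressWarnings(fit_rt_regression(rbind(two, two[1, ]), pref))
  expect_s3_class(fit2, "rt_regression")
  const <- trials
  const$left <- 0.3; const$right <- 0.7
  expect_error(fit_rt_regression(const, 0.5), "variance")
})

test_that("a simulated diffusion dictator shows the negative RT-difficulty slope", {
  ch <- test_cohort()
  fit <- fit_rt_regression(ch$datasets[[5]], ch$dictators[[5]]$pref)
  expect_lt(fit$b1, 0)
})

test_that("trials are categorized by the printed thresholds", {
  fit <- structure(list(b0 = 1.5, b1 = -1), class = "rt_regression")
  tr <- data.frame(left = c(0.2, 0.2, 0.2), right = c(0.8, 0.8, 0.8),
                   rt = c(2.0, 1.0, 1.3))
  expect_equal(categorize_trials(tr, fit),
               c("slow", "fast", "uninformative"))
  # with a negative slope fast and slow cannot overlap
  set.seed(32)
  tr2 <- data.frame(left = runif(200), right = runif(200),
                    rt = runif(200, 0.2, 3))
  cats <- categorize_trials(tr2, fit)
  expect_true(all(cats %in% c("fast", "slow", "uninformative")))
})

test_that("inconsistent choices are removed, ties survive", {
  tr <- data.frame(trial = 1:3,
                   left = c(0.2, 0.8, 0.2), right = c(0.8, 0.2, 0.4),
                   choice = c("left", "left", "left"),
                   rt = 1)
  kept <- filter_inconsistent(tr, 0.3)
  expect_equal(kept$trial, c(1L, 3L))
})

test_that("observation selection returns 12 consistent trials with optimal slow picks", {
  ch <- test_cohort()
  d <- ch$dictators[[3]]
  data <- ch$datasets[[3]]
  reg <- fit_rt_regression(data, d$pref)
  consistent <- filter_inconsistent(data, d$pref)
  sel <- select_observation_trials(consistent, d$pref, reg)
  expect_equal(nrow(sel), 12L)
  expect_equal(sum(sel$category == "fast"), 6L)
  expect_equal(sum(sel$category == "slow"), 6L)
  # every selected slow trial is at least as close to the preference as any
  # unselected slow trial
  cats <- categorize_trials(consistent, reg)
  slow_all <- consistent[cats == "slow", ]
  unpicked <- slow_all[!slow_all$trial %in% sel$trial, ]
  d_sel <- abs((sel$left[sel$category == "slow"] +
                  sel$right[sel$category == "slow"]) / 2 - d$pref)
  d_un <- abs((unpicked$left + unpicked$right) / 2 - d$pref)
  expect_lte(max(d_sel), min(d_un) + 1e-12)
  # the fast picks are the fastest fast trials
  fast_all <- consistent[cats == "fast", ]
  expect_lte(max(sel$rt[sel$category == "fast"]),
             min(fast_all$rt[!fast_all$trial %in% sel$trial]))
  # shortfall is reported by name
  expect_error(select_observation_trials(consistent[1:4, ], d$pref, reg),
               "fast|slow")
})

test_that("prediction selection is disjoint from the observation set", {
  ch <- test_cohort()
  for (ses in ch$sessions[1:4]) {
    expect_equal(nrow(ses$pred_pairs), 4L)
    expect_length(intersect(ses$pred_pairs$trial, ses$obs$trial), 0L)
  }
})

test_that("trial-order search respects its budget and seed", {
  ch <- test_cohort()
  sel <- ch$sessions[[1]]$obs
  sel$choice <- "left"; sel$rt <- seq(0.8, 3, length.out = nrow(sel))
  pref <- ch$sessions[[1]]$true_pref
  # budget 1 returns the input order
  res1 <- optimize_trial_order(sel, pref, budget = 1L)
  expect_equal(res1$order, seq_len(nrow(sel)))
  set.seed(55)
  res_a <- optimize_trial_order(sel, pref, budget = 40L)
  set.seed(55)
  res_b <- optimize_trial_order(sel, pref, budget = 40L)
  expect_identical(res_a$order, res_b$order)
  expect_lte(res_a$criterion, res1$criterion)
  expect_error(optimize_trial_order(sel, pref, budget = 0L), "budget")
})

test_that("exact order search finds the optimum on a tiny input", {
  ch <- test_cohort()
  sel <- ch$sessions[[1]]$obs_full[1:4, ]
  pref <- ch$sessions[[1]]$true_pref
  res <- optimize_trial_order(sel, pref, exact = TRUE)
  # exhaustive check: no random order beats the exact optimum
  set.seed(56)
  for (i in 1:50) {
    ord <- sample.int(4)
    alt <- optimize_trial_order(sel[ord, ], pref, budget = 1L)
    expect_gte(alt$criterion, res$criterion - 1e-12)
  }
})

test_that("selected slow trials are slower than selected fast trials on simulated data", {
  ch <- test_cohort()
  for (ses in ch$sessions) {
    data <- ch$datasets[[ses$dictator_id]]
    sel_rt <- data$rt[match(ses$obs$trial, data$trial)]
    d <- ch$dictators[[ses$dictator_id]]
    reg <- fit_rt_regression(data, d$pref)
    cats <- categorize_trials(data[match(ses$obs$trial, data$trial), ], reg)
    expect_gt(mean(sel_rt[cats == "slow"]), mean(sel_rt[cats == "fast"]))
  }
})
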
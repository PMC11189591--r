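# Synthetic-study generator: allocation designs, diffusion-model dictators,
# observer session construction, and forward-simulated observer cohorts.
# All randomness flows through R's RNG, so a single set.seed() call makes a
# whole study reproducible.

#' Study configuration
#'
#' Default values reproduce the study conditions the analysis assumes: 11
#' allocation levels in 10% steps presented in all 55 distinct pairs, 3
#' repeats (165 dictator trials), truncated-normal presentation noise
#' (SD 0.02, bounded at +/-0.05), 16 dictators observed for 12 trials each
#' in blocks of 4 per condition, preference estimates before observation
#' and after trials 4, 8 and 12, 4 prediction trials (2 fast, 2 slow), and
#' 46 observers.
#'
#' @param n_dictators Number of dictators (must be divisible by 4).
#' @param n_observers Number of observers.
#' @param allocation_step Spacing of the base allocation levels.
#' @param repeats_per_pair Presentations of each pair in the dictator task.
#' @param noise_sd,noise_bound Truncated-normal presentation noise SD and
#'   bound.
#' @param observed_trials Observation trials per dictator.
#' @param estimation_slots Trial counts after which an estimate is reported
#'   (0 = before any observation).
#' @param prediction_trials Prediction trials per dictator.
#' @param order_budget Random-search budget for trial-order optimization.
#' @return A list with class `"study_config"`.
#' @export
study_config <- function(n_dictators = 16L, n_observers = 46L,
                         allocation_step = 0.1, repeats_per_pair = 3L,
                         noise_sd = 0.02, noise_bound = 0.05,
                         observed_trials = 12L,
                         estimation_slots = c(0L, 4L, 8L, 12L),
                         prediction_trials = 4L,
                         order_budget = 50L) {
  stopifnot(n_dictators >= 4L, n_dictators %% 4L == 0L, n_observers >= 1L,
            allocation_step > 0, repeats_per_pair >= 1L,
            noise_bound >= noise_sd, observed_trials >= 1L,
            prediction_trials >= 1L)
  structure(list(n_dictators = n_dictators, n_observers = n_observers,
                 allocation_step = allocation_step,
                 repeats_per_pair = repeats_per_pair,
                 noise_sd = noise_sd, noise_bound = noise_bound,
                 observed_trials = observed_trials,
                 estimation_slots = estimation_slots,
                 prediction_trials = prediction_trials,
                 order_budget = order_budget),
            class = "study_config")
}

# truncated normal via rejection (mean 0, given sd, |x| <= bound)
rtrunc_norm <- function(n, sd, bound) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), 0, sd)
    ok <- abs(draw) <= bound
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Build the allocation-pair design of the dictator task
#'
#' Base allocation levels from 0 to 1 in `allocation_step` steps are
#' combined into all distinct unordered pairs, each presented
#' `repeats_per_pair` times with counterbalanced left/right assignment and
#' independent truncated-normal noise added to each allocation (clipped to
#' `[0, 1]`; the rare post-noise exact tie is resampled). Trial order is
#' shuffled.
#'
#' @param config A [study_config()] object.
#' @return Data frame with `trial`, `base_left`, `base_right`, `left`,
#'   `right`.
#' @export
make_design <- function(config = study_config()) {
  levels <- seq(0, 1, by = config$allocation_step)
  pairs <- utils::combn(levels, 2L)
  n_pairs <- ncol(pairs)
  rows <- list()
  for (r in seq_len(config$repeats_per_pair)) {
    # alternate which member of the pair is shown on the left across repeats
    flip <- (seq_len(n_pairs) + r) %% 2L == 0L
    rows[[r]] <- data.frame(
      base_left = ifelse(flip, pairs[2, ], pairs[1, ]),
      base_right = ifelse(flip, pairs[1, ], pairs[2, ])
    )
  }
  design <- do.call(rbind, rows)
  design <- design[sample.int(nrow(design)), , drop = FALSE]
  n <- nrow(design)
  repeat {
    left <- pmin(pmax(design$base_left +
                        rtrunc_norm(n, config$noise_sd, config$noise_bound),
                      0), 1)
    right <- pmin(pmax(design$base_right +
                         rtrunc_norm(n, config$noise_sd, config$noise_bound),
                       0), 1)
    if (all(left != right)) break
  }
  data.frame(trial = seq_len(n), base_left = design$base_left,
             base_right = design$base_right, left = left, right = right,
             row.names = NULL)
}

#' Sample a cohort of generative dictator agents
#'
#' Preferences are spread evenly over `[0.05, 0.95]` with a small jitter,
#' so that every condition block can span the whole prosocial-to-selfish
#' range; diffusion parameters are drawn from realistic ranges well inside
#' the benchmark observer's prior bounds.
#'
#' @param config A [study_config()] object.
#' @return List of dictators, each a list with `id`, `pref`, and `params`
#'   ([ddm_params()]).
#' @export
sample_dictators <- function(config = study_config()) {
  n <- config$n_dictators
  prefs <- seq(0.05, 0.95, length.out = n) +
    stats::runif(n, -0.01, 0.01)
  prefs <- pmin(pmax(prefs, 0.02), 0.98)
  lapply(seq_len(n), function(i) {
    list(id = i,
         pref = prefs[i],
         params = ddm_params(boundary = stats::runif(1, 1.5, 2.5),
                             nondecision = stats::runif(1, 0.25, 0.35),
                             drift_scale = stats::runif(1, 4, 8)))
  })
}

#' Simulate one dictator's full Dictator-Game dataset
#'
#' One diffusion-model decision per design trial.
#'
#' @param dictator One element of [sample_dictators()].
#' @param design A [make_design()] data frame.
#' @return Data frame with `dictator_id`, `trial`, `left`, `right`,
#'   `choice`, `rt`.
#' @export
generate_dictator_dataset <- function(dictator, design) {
  n <- nrow(design)
  choice <- character(n)
  rt <- numeric(n)
  for (i in seq_len(n)) {
    dec <- simulate_decision(design$left[i], design$right[i],
                             dictator$pref, dictator$params)
    choice[i] <- dec$choice
    rt[i] <- dec$rt
  }
  data.frame(dictator_id = dictator$id, trial = design$trial,
             left = design$left, right = design$right,
             choice = choice, rt = rt)
}

#' Hide the decision features a condition masks
#'
#' @param obs Observation data frame with `choice` and `rt` columns.
#' @param condition One of `"none"`, `"rt_only"`, `"choice_only"`,
#'   `"both"`.
#' @return `obs` with the hidden columns set to `NA`.
#' @export
mask_observations <- function(obs, condition) {
  if (!condition %in% c("choice_only", "both")) obs$choice <- NA_character_
  if (!condition %in% c("rt_only", "both")) obs$rt <- NA_real_
  obs
}

# stratified assignment of dictators to conditions: rank dictators by
# preference and deal ranks across conditions so each block spans the range
assign_conditions <- function(prefs) {
  conds <- c("none", "rt_only", "choice_only", "both")
  n <- length(prefs)
  stopifnot(n %% 4L == 0L)
  rk <- order(prefs)
  assignment <- character(n)
  for (g in seq_len(n / 4L)) {
    block <- rk[((g - 1L) * 4L + 1L):(g * 4L)]
    assignment[block] <- sample(conds)
  }
  assignment
}

#' Build the observer session templates from dictator datasets
#'
#' For each dictator: fit the RT regression, drop inconsistent trials,
#' pick the 12 observation trials (6 fast + 6 slow), optimize their order
#' with the forward-RL criterion, pick the 4 prediction trials from the
#' remainder, and mask the choice/RT columns according to the dictator's
#' assigned condition. Conditions are assigned 4 dictators each,
#' stratified by preference.
#'
#' @param dictators Output of [sample_dictators()].
#' @param datasets List of [generate_dictator_dataset()] data frames,
#'   parallel to `dictators`.
#' @param config A [study_config()] object.
#' @param use_pref `"true"` to select trials against the generative
#'   preference, `"fitted"` to use the choice-only fit.
#' @return List of sessions; each is a list with `dictator_id`,
#'   `condition`, `true_pref`, `obs` (masked observation stream),
#'   `pred_pairs`, `pred_truth` (the dictator's simulated choices on the
#'   prediction pairs), and `estimation_slots`.
#' @export
build_observer_sessions <- function(dictators, datasets,
                                    config = study_config(),
                                    use_pref = c("true", "fitted")) {
  use_pref <- match.arg(use_pref)
  prefs <- vapply(dictators, `[[`, numeric(1), "pref")
  conditions <- assign_conditions(prefs)
  n_obs_fast <- config$observed_trials %/% 2L
  n_pred_fast <- config$prediction_trials %/% 2L
  sessions <- vector("list", length(dictators))
  for (i in seq_along(dictators)) {
    d <- dictators[[i]]
    data <- datasets[[i]]
    pref <- if (use_pref == "true") d$pref else {
      fit_preference_choices(data)$pref
    }
    reg <- fit_rt_regression(data, pref)
    consistent <- filter_inconsistent(data, pref)
    obs_sel <- select_observation_trials(consistent, pref, reg,
                                         n_fast = n_obs_fast,
                                         n_slow = config$observed_trials -
                                           n_obs_fast)
    ord <- optimize_trial_order(obs_sel, pref, budget = config$order_budget)
    obs <- ord$trials
    remaining <- consistent[!consistent$trial %in% obs$trial, , drop = FALSE]
    pred_sel <- select_prediction_trials(remaining, pref, reg,
                                         n_fast = n_pred_fast,
                                         n_slow = config$prediction_trials -
                                           n_pred_fast)
    pred_sel <- pred_sel[sample.int(nrow(pred_sel)), , drop = FALSE]
    cond <- conditions[i]
    full <- obs[, c("trial", "left", "right", "choice", "rt")]
    sessions[[i]] <- list(
      dictator_id = d$id,
      condition = cond,
      true_pref = d$pref,
      obs = mask_observations(full, cond),
      obs_full = full,
      pred_pairs = pred_sel[, c("trial", "left", "right")],
      pred_truth = pred_sel$choice,
      pred_category = pred_sel$category,
      estimation_slots = config$estimation_slots
    )
  }
  sessions
}

#' Simulate one observer's behavior and attach it to the sessions
#'
#' Convenience wrapper for parameter-recovery studies: runs
#' [simulate_observer()] on every session template and stores the
#' simulated reports in the `reported_estimates` / `reported_predictions`
#' fields that [fit_rl()] consumes.
#'
#' @param sessions Output of [build_observer_sessions()].
#' @param params An [rl_params()] object (the generating parameters).
#' @return The sessions with reported behavior filled in.
#' @export
simulate_observer_sessions <- function(sessions, params) {
  lapply(sessions, function(ses) {
    sim <- simulate_observer(ses, params)
    ses$reported_estimates <- sim$estimates
    ses$reported_predictions <- sim$predictions
    ses
  })
}

#' Forward-simulate a cohort of observers over the session templates
#'
#' The dictator-to-condition assignment is redrawn for every observer
#' (stratified by preference, 4 dictators per condition), mirroring the
#' pseudo-randomization of dictator order across participants, so that
#' across the cohort every dictator contributes to every condition. For the
#' RL agent each observer gets independent report noise and prediction
#' sampling; the Bayes-optimal trajectory is deterministic given a
#' (dictator, condition) stream, so it is computed once per combination and
#' reused, with per-observer report noise and prediction sampling on top.
#'
#' @param sessions Output of [build_observer_sessions()].
#' @param config A [study_config()] object.
#' @param agent `"rl"` or `"bo"`.
#' @param params An [rl_params()] object (RL agent; also supplies the
#'   report-noise SD for the BO agent).
#' @param resolution Grid resolution (BO agent).
#' @param reassign_conditions Redraw the condition assignment per observer
#'   (default `TRUE`); `FALSE` keeps each template's own condition.
#' @return A list of two data frames: `estimates` (observer_id,
#'   dictator_id, condition, slot, estimate, true_pref) and `predictions`
#'   (observer_id, dictator_id, condition, trial, left, right, prediction,
#'   dictator_choice).
#' @export
simulate_observer_cohort <- function(sessions, config = study_config(),
                                     agent = c("rl", "bo"),
                                     params = rl_params(),
                                     resolution = 15L,
                                     reassign_conditions = TRUE) {
  agent <- match.arg(agent)
  prefs <- vapply(sessions, `[[`, numeric(1), "true_pref")
  est_rows <- list()
  pred_rows <- list()
  bo_cache <- new.env(parent = emptyenv())
  bo_for <- function(ses) {
    key <- paste(ses$dictator_id, ses$condition)
    if (is.null(bo_cache[[key]])) {
      bo_cache[[key]] <- bo_run_session(ses, resolution = resolution)
    }
    bo_cache[[key]]
  }
  k <- 0L
  for (o in seq_len(config$n_observers)) {
    assignment <- if (reassign_conditions) assign_conditions(prefs)
    for (s in seq_along(sessions)) {
      ses <- sessions[[s]]
      if (reassign_conditions) {
        ses$condition <- assignment[s]
        ses$obs <- mask_observations(ses$obs_full, ses$condition)
      }
      if (agent == "rl") {
        sim <- simulate_observer(ses, params)
        est <- sim$estimates
        pred <- sim$predictions
      } else {
        bo <- bo_for(ses)
        est <- pmin(pmax(bo$estimates +
                           stats::rnorm(length(bo$estimates), 0,
                                        params$sigma), 0), 1)
        pred <- ifelse(stats::runif(length(bo$p_left)) < bo$p_left,
                       "left", "right")
      }
      k <- k + 1L
      est_rows[[k]] <- data.frame(
        observer_id = o, dictator_id = ses$dictator_id,
        condition = ses$condition, slot = ses$estimation_slots,
        estimate = est, true_pref = ses$true_pref)
      pred_rows[[k]] <- data.frame(
        observer_id = o, dictator_id = ses$dictator_id,
        condition = ses$condition, trial = ses$pred_pairs$trial,
        left = ses$pred_pairs$left, right = ses$pred_pairs$right,
        prediction = pred, dictator_choice = ses$pred_truth)
    }
  }
  list(estimates = do.call(rbind, est_rows),
       predictions = do.call(rbind, pred_rows))
}
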
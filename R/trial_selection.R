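# Informative-trial selection: RT regression, fast/slow/uninformative
# categorization, consistency filtering, observation/prediction picks, and
# trial-order optimization.

#' Linear regression of RT on trial difficulty
#'
#' Ordinary least squares of response time on the absolute subjective-value
#' difference `|s(left) - s(right)|` under the dictator's fitted
#' preference. On diffusion-like data the slope is expected to be negative
#' (easier trials are faster); a positive slope triggers a warning.
#'
#' @param trials Data frame with columns `left`, `right`, `rt`.
#' @param pref Dictator's preference in `[0, 1]`.
#' @return A list with class `"rt_regression"`: `b0` (intercept, seconds)
#'   and `b1` (seconds per unit difficulty).
#' @export
fit_rt_regression <- function(trials, pref) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 3)
  difficulty <- sv_difference(trials$left, trials$right, pref)
  if (stats::sd(difficulty) < .Machine$double.eps^0.5) {
    stop("zero variance in the difficulty regressor", call. = FALSE)
  }
  fit <- stats::lm(trials$rt ~ difficulty)
  b <- unname(stats::coef(fit))
  if (b[2] > 0) {
    warning("RT increases with subjective-value difference; data do not ",
            "look diffusion-like", call. = FALSE)
  }
  structure(list(b0 = b[1], b1 = b[2]), class = "rt_regression")
}

#' Categorize trials as fast, slow, or uninformative
#'
#' A trial is slow when `rt > b0` (the intercept: the RT expected for a
#' maximally difficult trial, whose options straddle the preference), fast
#' when `rt < b0 + b1 * (left - right)^2` (faster than expected even if the
#' preference lay outside the option interval), and uninformative
#' otherwise. With a negative slope the two classes cannot overlap.
#'
#' @param trials Data frame with columns `left`, `right`, `rt`.
#' @param fit An [fit_rt_regression()] result.
#' @return Character vector: `"fast"`, `"slow"`, or `"uninformative"`.
#' @export
categorize_trials <- function(trials, fit) {
  stopifnot(inherits(fit, "rt_regression"))
  fast_thresh <- fit$b0 + fit$b1 * (trials$left - trials$right)^2
  ifelse(trials$rt > fit$b0, "slow",
         ifelse(trials$rt < fast_thresh, "fast", "uninformative"))
}

#' Drop trials with an inconsistent choice
#'
#' Removes trials where the dictator chose the allocation strictly farther
#' from their preference than the unchosen one. Trials whose options are
#' equidistant from the preference are kept (neither option is the worse
#' one).
#'
#' @param trials Data frame with columns `left`, `right`, `choice`.
#' @param pref Dictator's preference in `[0, 1]`.
#' @return The consistent subset of `trials`.
#' @export
filter_inconsistent <- function(trials, pref) {
  chosen <- ifelse(trials$choice == "left", trials$left, trials$right)
  unchosen <- ifelse(trials$choice == "left", trials$right, trials$left)
  keep <- abs(chosen - pref) <= abs(unchosen - pref)
  trials[keep, , drop = FALSE]
}

# stable ordering helper: primary key, ties broken by trial index
order_with_ties <- function(key, trial_index) {
  order(key, trial_index)
}

#' Select the 12 observation trials for one dictator
#'
#' From the consistent, categorized trials: the `n_fast` fastest fast
#' trials, and the `n_slow` slow trials whose options' midpoint lies
#' closest to the preference. Ties are broken by trial index so the
#' selection is deterministic.
#'
#' @param trials Data frame with columns `trial`, `left`, `right`,
#'   `choice`, `rt` (already consistency-filtered).
#' @param pref Dictator's preference in `[0, 1]`.
#' @param fit An [fit_rt_regression()] result.
#' @param n_fast,n_slow Number of fast and slow picks (defaults 6 and 6).
#' @return `trials` rows of the selection, with a `category` column, fast
#'   picks first.
#' @export
select_observation_trials <- function(trials, pref, fit, n_fast = 6L,
                                      n_slow = 6L) {
  cat <- categorize_trials(trials, fit)
  fast <- trials[cat == "fast", , drop = FALSE]
  slow <- trials[cat == "slow", , drop = FALSE]
  if (nrow(fast) < n_fast) {
    stop(sprintf("only %d fast trials available, need %d", nrow(fast),
                 n_fast), call. = FALSE)
  }
  if (nrow(slow) < n_slow) {
    stop(sprintf("only %d slow trials available, need %d", nrow(slow),
                 n_slow), call. = FALSE)
  }
  fast <- fast[order_with_ties(fast$rt, fast$trial), , drop = FALSE]
  mid_dist <- abs((slow$left + slow$right) / 2 - pref)
  slow <- slow[order_with_ties(mid_dist, slow$trial), , drop = FALSE]
  picked <- rbind(cbind(fast[seq_len(n_fast), , drop = FALSE],
                        category = "fast"),
                  cbind(slow[seq_len(n_slow), , drop = FALSE],
                        category = "slow"))
  rownames(picked) <- NULL
  picked
}

#' Select the 4 prediction trials for one dictator
#'
#' Applied to the trials remaining after the observation picks were
#' removed: the next `n_fast` fastest fast trials and the next `n_slow`
#' best slow trials by midpoint distance to the preference.
#'
#' @inheritParams select_observation_trials
#' @param n_fast,n_slow Number of fast and slow picks (defaults 2 and 2).
#' @return Selected rows with a `category` column.
#' @export
select_prediction_trials <- function(trials, pref, fit, n_fast = 2L,
                                     n_slow = 2L) {
  select_observation_trials(trials, pref, fit, n_fast = n_fast,
                            n_slow = n_slow)
}

#' Optimize the presentation order of the observation trials
#'
#' Searches orderings of the selected observation trials for the one whose
#' forward RL estimate, run separately under every condition, ends closest
#' to the dictator's true preference (summed absolute error over
#' conditions). The full search over all block orderings is combinatorially
#' huge, so a seeded random search over `budget` candidate orders (plus the
#' input order) is used; `exact = TRUE` enumerates all permutations and is
#' only feasible for very small inputs.
#'
#' @param trials The selected observation trials (data frame).
#' @param pref Dictator's true preference.
#' @param rl An [rl_params()] object used for the forward-model criterion.
#' @param budget Number of random candidate orders (default 200).
#' @param conditions Conditions over which the criterion is summed.
#' @param exact Enumerate all permutations instead (requires
#'   `nrow(trials) <= 7`).
#' @return A list with `trials` (reordered), `criterion`, and `order`
#'   (permutation of input rows).
#' @export
optimize_trial_order <- function(trials, pref, rl = rl_params(),
                                 budget = 200L,
                                 conditions = c("none", "rt_only",
                                                "choice_only", "both"),
                                 exact = FALSE) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1)
  if (budget < 1L) stop("`budget` must be >= 1", call. = FALSE)
  n <- nrow(trials)
  crit <- function(ord) {
    obs <- trials[ord, , drop = FALSE]
    total <- 0
    for (cond in conditions) {
      traj <- rl_forward(obs, cond, rl)
      total <- total + abs(traj[length(traj)] - pref)
    }
    total
  }
  if (exact) {
    if (n > 7L) stop("exact search is only feasible for <= 7 trials",
                     call. = FALSE)
    perms <- all_permutations(n)
    vals <- vapply(perms, crit, numeric(1))
    best <- perms[[which.min(vals)]]
    return(list(trials = trials[best, , drop = FALSE],
                criterion = min(vals), order = best))
  }
  best_ord <- seq_len(n)
  best_val <- crit(best_ord)
  if (budget > 1L) {
    for (b in seq_len(budget - 1L)) {
      ord <- sample.int(n)
      val <- crit(ord)
      if (val < best_val) {
        best_val <- val
        best_ord <- ord
      }
    }
  }
  list(trials = trials[best_ord, , drop = FALSE], criterion = best_val,
       order = best_ord)
}

# all permutations of 1..n as a list (n small)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in sub) {
      q <- integer(n)
      q[i] <- n
      q[-i] <- p
      k <- k + 1L
      out[[k]] <- q
    }
  }
  out
}
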
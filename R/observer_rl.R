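# Observational reinforcement-learning model: an observer tracks another
# person's preferred allocation with a delta rule whose teaching signal
# depends on which decision features (choice, response time) are visible.

#' Observer RL model parameters
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param P0 Initial preference estimate in `[0, 1]`.
#' @param omega Weight of RT-derived over choice-derived information in the
#'   both-visible condition, in `[0, 1]`.
#' @param sigma Standard deviation of the slider-report noise around the
#'   model's running estimate (> 0). Held fixed during fitting.
#' @param beta_p Observer's inverse temperature for prediction choices
#'   (> 0).
#' @return A list with class `"rl_params"`.
#' @examples
#' rl_params(alpha = 0.4, P0 = 0.5, omega = 0.5)
#' @export
rl_params <- function(alpha = 0.2, P0 = 0.5, omega = 0.3, sigma = 0.1,
                      beta_p = 6) {
  assert_proportion(alpha)
  assert_proportion(P0)
  assert_proportion(omega)
  assert_positive(sigma)
  assert_positive(beta_p)
  structure(list(alpha = alpha, P0 = P0, omega = omega, sigma = sigma,
                 beta_p = beta_p),
            class = "rl_params")
}

#' Delta-rule update of the preference estimate
#'
#' `P_t = P_{t-1} + alpha * (outcome - P_{t-1})`. Because the outcome lies
#' in `[0, 1]` and `alpha` in `[0, 1]`, the update is a convex combination
#' and the estimate can never leave `[0, 1]`.
#'
#' @param P_prev Previous estimate in `[0, 1]`.
#' @param outcome Teaching signal in `[0, 1]`.
#' @param alpha Learning rate in `[0, 1]`.
#' @return Updated estimate.
#' @export
rl_update <- function(P_prev, outcome, alpha) {
  assert_proportion(P_prev)
  assert_proportion(outcome)
  assert_proportion(alpha)
  P_prev + alpha * (outcome - P_prev)
}

#' Classify an observed decision as fast or slow
#'
#' A trial counts as slow when its RT strictly exceeds the running mean of
#' all RTs observed from this dictator so far, the current trial included.
#' The first observed trial equals its own mean and is therefore never
#' slow.
#'
#' @param rt Current trial's RT in seconds.
#' @param rt_history RTs observed so far from this dictator, including the
#'   current trial.
#' @return `"slow"` or `"fast"`.
#' @export
classify_speed <- function(rt, rt_history) {
  stopifnot(rt %in% rt_history || any(abs(rt_history - rt) < 1e-12))
  if (rt > mean(rt_history)) "slow" else "fast"
}

#' Choice-derived outcome: was the more selfish allocation chosen?
#'
#' @param left,right Allocations in `[0, 1]`.
#' @param choice `"left"` or `"right"`.
#' @return 1 if the chosen allocation is the larger (more selfish) of the
#'   two, else 0.
#' @export
outcome_choice <- function(left, right, choice) {
  stopifnot(choice %in% c("left", "right"))
  chosen <- if (choice == "left") left else right
  as.numeric(chosen == max(left, right))
}

#' RT-derived outcome when the choice is hidden
#'
#' Slow trials teach the options' midpoint (both options were probably
#' about equally attractive). Fast trials teach 1 or 0 under the assumption
#' that the dictator chose the option with the higher subjective value
#' given the observer's current estimate `P_prev`: 1 if that option is the
#' more selfish one, else 0.
#'
#' @param left,right Allocations in `[0, 1]`.
#' @param speed `"fast"` or `"slow"` (from [classify_speed()]).
#' @param P_prev Observer's current preference estimate.
#' @return Outcome in `[0, 1]`.
#' @export
outcome_rt <- function(left, right, speed, P_prev) {
  stopifnot(speed %in% c("fast", "slow"))
  if (speed == "slow") return((left + right) / 2)
  s_left <- subjective_value(left, P_prev)
  s_right <- subjective_value(right, P_prev)
  inferred <- if (s_left >= s_right) left else right
  as.numeric(inferred == max(left, right))
}

#' Outcome when both choice and RT are visible (unweighted rule)
#'
#' Slow trials teach the midpoint; fast trials defer to the actual choice
#' via [outcome_choice()].
#'
#' @inheritParams outcome_rt
#' @param choice `"left"` or `"right"`.
#' @return Outcome in `[0, 1]`.
#' @export
outcome_both <- function(left, right, choice, speed) {
  stopifnot(speed %in% c("fast", "slow"))
  if (speed == "slow") return((left + right) / 2)
  outcome_choice(left, right, choice)
}

#' Outcome when no decision information is visible: the options' midpoint
#'
#' @param left,right Allocations in `[0, 1]`.
#' @return `(left + right) / 2`.
#' @export
outcome_none <- function(left, right) {
  (left + right) / 2
}

#' Weighted combination of choice- and RT-derived outcomes
#'
#' `O = (1 - omega) * O_choice + omega * O_rt`; applies only when both
#' information sources exist (the both-visible condition).
#'
#' @param o_choice,o_rt Component outcomes in `[0, 1]`.
#' @param omega Weight in `[0, 1]`.
#' @return Combined outcome in `[0, 1]`.
#' @export
combined_outcome <- function(o_choice, o_rt, omega) {
  assert_proportion(omega)
  o_choice * (1 - omega) + o_rt * omega
}

# teaching signal for one observed trial under a given condition
compute_outcome <- function(condition, left, right, choice, rt, speed,
                            P_prev, omega) {
  switch(condition,
         none = outcome_none(left, right),
         choice_only = outcome_choice(left, right, choice),
         rt_only = outcome_rt(left, right, speed, P_prev),
         both = combined_outcome(outcome_choice(left, right, choice),
                                 outcome_rt(left, right, speed, P_prev),
                                 omega),
         stop("unknown condition: ", condition, call. = FALSE))
}

#' Forward pass of the observer RL model over one observation stream
#'
#' Runs the condition-specific teaching signal through the delta rule and
#' returns the estimate trajectory, starting at `P0` before any trial.
#'
#' @param obs Data frame of observed trials with columns `left`, `right`,
#'   and (as visible) `choice`, `rt`.
#' @param condition One of `"none"`, `"rt_only"`, `"choice_only"`,
#'   `"both"`.
#' @param params An [rl_params()] object.
#' @return Numeric vector of length `nrow(obs) + 1`: the estimate before
#'   each trial and after the last.
#' @export
rl_forward <- function(obs, condition, params) {
  stopifnot(is.data.frame(obs),
            condition %in% c("none", "rt_only", "choice_only", "both"))
  cond_code <- match(condition, c("none", "rt_only", "choice_only",
                                  "both")) - 1L
  chose_left <- ifelse(is.na(obs$choice), -1L,
                       as.integer(obs$choice == "left"))
  rt <- ifelse(is.na(obs$rt), -1, obs$rt)
  if (cond_code %in% c(1L, 3L) && any(rt < 0)) {
    stop("RTs are required in RT-visible conditions", call. = FALSE)
  }
  if (cond_code %in% c(2L, 3L) && any(chose_left < 0L)) {
    stop("choices are required in choice-visible conditions", call. = FALSE)
  }
  as.numeric(rl_traj_cpp(obs$left, obs$right, as.integer(chose_left), rt,
                         cond_code, params$alpha, params$P0, params$omega))
}

#' Simulate an observer's reports for one session
#'
#' Runs [rl_forward()], reads out the estimate at the requested slots
#' (slider reports get zero-mean Gaussian noise with SD `sigma`, clipped to
#' `[0, 1]`), and samples prediction choices from the softmax rule at the
#' final estimate with inverse temperature `beta_p`.
#'
#' @param session An observer session as built by
#'   [build_observer_sessions()]: a list with `condition`, `obs`,
#'   `pred_pairs`, and `estimation_slots`.
#' @param params An [rl_params()] object.
#' @param report_noise Add slider noise to the reported estimates
#'   (default `TRUE`).
#' @return A list with `estimates` (one per slot), `slots`, `predictions`
#'   (`"left"`/`"right"` per prediction pair), and `traj`.
#' @export
simulate_observer <- function(session, params, report_noise = TRUE) {
  traj <- rl_forward(session$obs, session$condition, params)
  slots <- session$estimation_slots
  est <- traj[slots + 1]
  if (report_noise) {
    est <- pmin(pmax(est + stats::rnorm(length(est), 0, params$sigma), 0), 1)
  }
  p_final <- traj[length(traj)]
  pp <- session$pred_pairs
  pl <- choice_prob_left(pp$left, pp$right, p_final, params$beta_p)
  pred <- ifelse(stats::runif(nrow(pp)) < pl, "left", "right")
  list(estimates = est, slots = slots, predictions = pred, traj = traj)
}

#' Negative log-likelihood of one slider report
#'
#' `-log phi(reported; modeled, sigma)` where `phi` is the normal density:
#' minimal when the report equals the model's running estimate and
#' symmetric and increasing in their distance.
#'
#' @param reported Reported preference estimate.
#' @param modeled Model's running estimate at that slot.
#' @param sigma Report-noise SD (> 0).
#' @return Nonnegative-shifted negative log density (can be negative when
#'   `sigma < 1/sqrt(2*pi)`; it is a density, not a probability).
#' @export
estimation_negloglik <- function(reported, modeled, sigma) {
  assert_positive(sigma)
  -stats::dnorm(reported, mean = modeled, sd = sigma, log = TRUE)
}

#' Negative log-likelihood of one prediction choice
#'
#' By default the negative log of the softmax probability of the chosen
#' option at the observer's final estimate. `literal = TRUE` instead
#' returns the negated softmax probability itself (not its log), an
#' alternative reading of the model's stated prediction objective.
#'
#' @param chosen,unchosen Allocations in `[0, 1]`.
#' @param pref Observer's final preference estimate.
#' @param beta_p Inverse temperature (> 0).
#' @param literal Use the negated-probability variant (default `FALSE`).
#' @return Scalar objective contribution.
#' @export
prediction_negloglik <- function(chosen, unchosen, pref, beta_p,
                                 literal = FALSE) {
  assert_positive(beta_p)
  p <- stats::plogis(beta_p * (subjective_value(chosen, pref) -
                               subjective_value(unchosen, pref)))
  if (literal) -p else -log(pmax(p, 1e-300))
}

# flatten sessions into plain vectors once, so the fitting objective can
# be evaluated without data-frame access or per-trial function calls
compile_sessions <- function(sessions) {
  lapply(sessions, function(ses) {
    obs <- ses$obs
    cond_code <- match(ses$condition, c("none", "rt_only", "choice_only",
                                        "both")) - 1L
    keep <- !is.na(ses$reported_estimates)
    pp <- ses$pred_pairs
    pred <- ses$reported_predictions
    jj <- which(!is.na(pred))
    chosen <- ifelse(pred[jj] == "left", pp$left[jj], pp$right[jj])
    unchosen <- ifelse(pred[jj] == "left", pp$right[jj], pp$left[jj])
    list(left = as.numeric(obs$left), right = as.numeric(obs$right),
         chose_left = ifelse(is.na(obs$choice), -1L,
                             as.integer(obs$choice == "left")),
         rt = ifelse(is.na(obs$rt), -1, as.numeric(obs$rt)),
         cond = cond_code,
         slot_idx = ses$estimation_slots[keep] + 1L,
         reported = as.numeric(ses$reported_estimates[keep]),
         pred_chosen = as.numeric(chosen),
         pred_unchosen = as.numeric(unchosen))
  })
}

# lean objective over precompiled sessions; identical arithmetic to the
# exported per-trial operations
rl_negloglik_compiled <- function(compiled, alpha, P0, omega, sigma,
                                  beta_p, literal_prediction = FALSE) {
  total <- 0
  for (cs in compiled) {
    traj <- rl_traj_cpp(cs$left, cs$right, cs$chose_left, cs$rt, cs$cond,
                        alpha, P0, omega)
    total <- total - sum(stats::dnorm(cs$reported, traj[cs$slot_idx],
                                      sigma, log = TRUE))
    if (length(cs$pred_chosen)) {
      pf <- traj[length(traj)]
      sdiff <- (cs$pred_unchosen - pf)^2 - (cs$pred_chosen - pf)^2
      p <- stats::plogis(beta_p * sdiff)
      total <- total + if (literal_prediction) sum(-p)
        else -sum(log(pmax(p, 1e-300)))
    }
  }
  total
}

# summed objective of the RL model over one observer's sessions
rl_negloglik <- function(sessions, params, literal_prediction = FALSE) {
  rl_negloglik_compiled(compile_sessions(sessions), params$alpha,
                        params$P0, params$omega, params$sigma,
                        params$beta_p,
                        literal_prediction = literal_prediction)
}

#' Fit the observer RL model to one observer's sessions
#'
#' Minimises the summed estimation and prediction negative log-likelihoods
#' over (`alpha`, `P0`, `omega`, `beta_p`) with `sigma` held fixed.
#' Restarts are drawn from Beta(1.1, 1.1) for `alpha`, Gamma(1.2, scale 5)
#' for `beta_p` (truncated to the search bound), and uniforms for `P0` and
#' `omega`.
#'
#' @param sessions List of observer sessions carrying
#'   `reported_estimates` and `reported_predictions`.
#' @param n_starts Number of random restarts (default 50).
#' @param sigma Fixed report-noise SD (default 0.1).
#' @param beta_max Upper bound of the `beta_p` search (default 100).
#' @param literal_prediction Use the negated-probability prediction
#'   objective (default `FALSE`).
#' @return A list with `params` ([rl_params()]), `nll`, `converged`.
#' @export
fit_rl <- function(sessions, n_starts = 50L, sigma = 0.1, beta_max = 100,
                   literal_prediction = FALSE) {
  stopifnot(length(sessions) > 0)
  lower <- c(alpha = 0, P0 = 0, omega = 0, beta_p = 0.01)
  upper <- c(alpha = 1, P0 = 1, omega = 1, beta_p = beta_max)
  compiled <- compile_sessions(sessions)
  obj <- function(theta) {
    rl_negloglik_compiled(compiled, theta[1], theta[2], theta[3], sigma,
                          theta[4], literal_prediction = literal_prediction)
  }
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    init <- c(stats::rbeta(1, 1.1, 1.1),
              stats::runif(1),
              stats::runif(1),
              min(stats::rgamma(1, shape = 1.2, scale = 5), beta_max))
    fit <- tryCatch(
      stats::optim(init, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 100, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all RL fitting restarts failed", call. = FALSE)
  list(params = rl_params(alpha = best$par[1], P0 = best$par[2],
                          omega = best$par[3], sigma = sigma,
                          beta_p = best$par[4]),
       nll = best$value,
       converged = any_conv)
}
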
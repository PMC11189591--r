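# Softmax choice model: choice probabilities, likelihood, and choice-only
# preference estimation.

#' Softmax probability of choosing the left option
#'
#' Logistic choice rule on the subjective-value difference:
#' `P(left) = 1 / (1 + exp(beta * (s(right) - s(left))))`. As `beta -> 0`
#' choices become random; large `beta` makes the higher-valued option
#' near-certain.
#'
#' @param left,right Allocations in `[0, 1]` (vectorised).
#' @param pref Preference in `[0, 1]`.
#' @param beta Inverse temperature (> 0).
#' @return Probability/ies in (0, 1).
#' @export
choice_prob_left <- function(left, right, pref, beta) {
  assert_positive(beta)
  stats::plogis(beta * sv_signed_difference(left, right, pref))
}

#' Choice-only log-likelihood of a preference
#'
#' Sum of log softmax probabilities of the recorded choices.
#'
#' @param trials Data frame with columns `left`, `right`, `choice`
#'   (`"left"`/`"right"`).
#' @param pref Candidate preference in `[0, 1]`.
#' @param beta Inverse temperature (> 0).
#' @return Scalar log-likelihood.
#' @export
choice_loglik <- function(trials, pref, beta) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0,
            all(trials$choice %in% c("left", "right")))
  p_left <- choice_prob_left(trials$left, trials$right, pref, beta)
  p <- ifelse(trials$choice == "left", p_left, 1 - p_left)
  sum(log(pmax(p, 1e-300)))
}

#' Estimate a preference from choices alone
#'
#' Maximum-likelihood fit of (preference, inverse temperature) to recorded
#' choices under the softmax rule, with random multi-start. The inverse
#' temperature search is capped at `beta_max`; a fit on that cap is flagged.
#'
#' @param trials Data frame with columns `left`, `right`, `choice`.
#' @param n_starts Number of random restarts (default 10).
#' @param beta_max Upper bound of the inverse-temperature search
#'   (default 100).
#' @return A list with `pref`, `beta`, `loglik`, `converged`, and
#'   `at_beta_cap`.
#' @export
fit_preference_choices <- function(trials, n_starts = 10L, beta_max = 100) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  if (nrow(trials) < 20) {
    warning("fewer than 20 trials; choice-only estimates may be unstable",
            call. = FALSE)
  }
  lower <- c(pref = 0.001, beta = 0.01)
  upper <- c(pref = 0.999, beta = beta_max)
  negll <- function(theta) -choice_loglik(trials, theta[1], theta[2])
  best <- multistart_optim(negll, lower, upper, n_starts)
  at_cap <- best$par[2] >= beta_max * 0.999
  if (at_cap) {
    warning("inverse temperature hit its search cap; choices are ",
            "near-deterministic", call. = FALSE)
  }
  list(pref = best$par[1], beta = best$par[2], loglik = -best$value,
       converged = best$converged, at_beta_cap = at_cap)
}
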
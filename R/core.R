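#' speedpref: social preference inference from choices and decision speed
#'
#' Computational machinery for a Dictator-Game observational-learning
#' paradigm: a quadratic subjective-value model, drift-diffusion (Wiener
#' first-passage time) likelihoods so a preference can be estimated from
#' response times alone, a softmax likelihood for choice-only estimation,
#' an observational reinforcement-learning model, a Bayes-optimal grid
#' observer, informative-trial selection, and a seeded synthetic-study
#' generator.
#'
#' Allocations are proportions-for-self in `[0, 1]` throughout (0 = fully
#' prosocial, 1 = fully selfish); all I/O converts percentages at the
#' boundary.
#'
#' @keywords internal
#' @useDynLib speedpref, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# ---- validation helpers ------------------------------------------------

assert_proportion <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be numeric in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_positive <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Allocation pair for one Dictator-Game trial
#'
#' Bundles the two on-screen allocations (proportion of points kept for
#' "self") after per-trial presentation noise. The two sides must differ:
#' exact ties carry no choice information and are rejected (the generator
#' resamples noise instead of ever producing one).
#'
#' @param left,right Proportion-for-self of each option, in `[0, 1]`.
#' @param trial_index Ordinal position of the trial (used for stable
#'   tie-breaking downstream).
#' @return A list with class `"allocation_pair"`.
#' @examples
#' allocation_pair(0.3, 0.7)
#' @export
allocation_pair <- function(left, right, trial_index = NA_integer_) {
  assert_proportion(left)
  assert_proportion(right)
  if (isTRUE(all.equal(left, right))) {
    stop("`left` and `right` must differ", call. = FALSE)
  }
  structure(list(left = left, right = right, trial_index = trial_index),
            class = "allocation_pair")
}

# ---- subjective value model --------------------------------------------

#' Quadratic subjective value of an allocation
#'
#' The subjective value of keeping proportion `x` for oneself, for an agent
#' whose preferred allocation is `pref`, is `1 - (x - pref)^2`: maximal (1)
#' exactly at the preferred split and falling off quadratically with
#' distance from it.
#'
#' @param x Allocation(s), proportion-for-self in `[0, 1]`.
#' @param pref Preferred allocation in `[0, 1]`.
#' @return Subjective value(s) in `[0, 1]`.
#' @examples
#' subjective_value(0.2, 0.5) # 0.91
#' @export
subjective_value <- function(x, pref) {
  assert_proportion(x)
  assert_proportion(pref)
  1 - (x - pref)^2
}

#' Trial difficulty: absolute subjective-value difference
#'
#' `|s(left) - s(right)|` under [subjective_value()]. Zero exactly when the
#' two options are equidistant from the preference (maximally difficult);
#' large when one option is clearly better.
#'
#' @param left,right Allocations in `[0, 1]` (or an `allocation_pair` as
#'   `left`, with `right` missing).
#' @param pref Preferred allocation in `[0, 1]`.
#' @return Nonnegative difficulty value(s).
#' @export
sv_difference <- function(left, right, pref) {
  if (inherits(left, "allocation_pair")) {
    right <- left$right
    left <- left$left
  }
  abs(subjective_value(left, pref) - subjective_value(right, pref))
}

#' Signed subjective-value difference s(left) - s(right)
#' @inheritParams sv_difference
#' @return Signed value difference(s).
#' @export
sv_signed_difference <- function(left, right, pref) {
  if (inherits(left, "allocation_pair")) {
    right <- left$right
    left <- left$left
  }
  subjective_value(left, pref) - subjective_value(right, pref)
}

# ---- behavioral metrics ------------------------------------------------

#' Estimation accuracy
#'
#' One minus the absolute distance between an estimated and a true
#' preference, so that 1 is a perfect estimate and 0 the worst possible.
#'
#' @param estimate,truth Preferences in `[0, 1]` (vectorised).
#' @return Accuracy value(s) in `[0, 1]`.
#' @export
estimation_accuracy <- function(estimate, truth) {
  assert_proportion(estimate)
  assert_proportion(truth)
  1 - abs(estimate - truth)
}

#' Prediction consistency with the last reported estimate
#'
#' A predicted choice is consistent when the chosen allocation lies strictly
#' closer to the observer's last preference estimate than the unchosen one.
#' Equidistant options are reported as `"tie"` rather than forced into
#' either class; consistency rates should exclude ties.
#'
#' @param chosen,unchosen Allocations in `[0, 1]`.
#' @param estimate Last reported preference estimate in `[0, 1]`.
#' @return `"consistent"`, `"inconsistent"`, or `"tie"` (vectorised).
#' @export
prediction_consistency <- function(chosen, unchosen, estimate) {
  assert_proportion(chosen)
  assert_proportion(unchosen)
  assert_proportion(estimate)
  d_ch <- abs(chosen - estimate)
  d_un <- abs(unchosen - estimate)
  # exact ties up to floating-point noise are their own category
  tie <- abs(d_ch - d_un) < 1e-9
  ifelse(tie, "tie", ifelse(d_ch < d_un, "consistent", "inconsistent"))
}

#' Expected accuracy of a uniform random guesser (closed form)
#'
#' For a true preference `pref`, a guess drawn uniformly on `[0, 1]` has
#' expected accuracy `1 - (pref^2 + (1 - pref)^2) / 2`. This is the analytic
#' counterpart of [empirical_chance_level()].
#'
#' @param pref True preference(s) in `[0, 1]`.
#' @return Expected accuracy in `[0.5, 0.75]`.
#' @export
expected_chance_accuracy <- function(pref) {
  assert_proportion(pref)
  1 - (pref^2 + (1 - pref)^2) / 2
}

#' Empirical chance level of preference estimation
#'
#' Monte-Carlo version of the chance benchmark: for each true preference,
#' draw `n_samples` uniform guesses, average their accuracy, then average
#' over the set of true preferences. This is the accuracy an observer who
#' guesses blindly would reach on the estimation task.
#'
#' @param truths Vector of true preferences in `[0, 1]`.
#' @param n_samples Number of uniform guesses per truth (default 10000).
#' @return Scalar chance-level accuracy.
#' @export
empirical_chance_level <- function(truths, n_samples = 10000L) {
  assert_proportion(truths)
  if (length(truths) == 0L) stop("`truths` must be non-empty", call. = FALSE)
  if (n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)
  per_truth <- vapply(truths, function(p) {
    mean(estimation_accuracy(stats::runif(n_samples), p))
  }, numeric(1))
  mean(per_truth)
}
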
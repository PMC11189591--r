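# Drift-diffusion machinery: Wiener first-passage-time densities, forward
# simulation of dictators, and RT-only / joint likelihoods for preference
# estimation.

#' Drift-diffusion model parameters
#'
#' Parameters of the generative diffusion for one dictator. The per-trial
#' drift rate is `drift_scale` times the signed subjective-value difference
#' between the left and right options; the upper boundary corresponds to
#' choosing the left option.
#'
#' @param boundary Boundary separation (> 0), evidence units.
#' @param nondecision Non-decision time in seconds (>= 0).
#' @param drift_scale Nonnegative scale mapping subjective-value differences
#'   to drift rates.
#' @param noise_sd Diffusion coefficient; fixed at 1 by convention (the
#'   model is identified only up to this scale).
#' @param start_bias Relative start point in (0, 1); 0.5 = unbiased.
#' @return A list with class `"ddm_params"`.
#' @examples
#' ddm_params(boundary = 2, nondecision = 0.3, drift_scale = 5)
#' @export
ddm_params <- function(boundary, nondecision, drift_scale,
                       noise_sd = 1, start_bias = 0.5) {
  assert_positive(boundary)
  if (!is.numeric(nondecision) || nondecision < 0 || !is.finite(nondecision)) {
    stop("`nondecision` must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(drift_scale) || drift_scale < 0 || !is.finite(drift_scale)) {
    stop("`drift_scale` must be finite and >= 0", call. = FALSE)
  }
  assert_positive(noise_sd)
  if (start_bias <= 0 || start_bias >= 1) {
    stop("`start_bias` must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(boundary = boundary, nondecision = nondecision,
                 drift_scale = drift_scale, noise_sd = noise_sd,
                 start_bias = start_bias),
            class = "ddm_params")
}

#' Per-trial drift rate
#'
#' Linear mapping from the signed subjective-value difference
#' `s(left) - s(right)` to the drift rate: positive drift pushes the
#' diffusion toward the upper (= left) boundary.
#'
#' @param left,right Allocations in `[0, 1]`.
#' @param pref Preference in `[0, 1]`.
#' @param params A [ddm_params()] object.
#' @return Drift rate(s).
#' @export
trial_drift <- function(left, right, pref, params) {
  params$drift_scale * sv_signed_difference(left, right, pref)
}

#' Wiener first-passage-time density
#'
#' Density of the observed response time `t` at the named boundary, for a
#' diffusion with drift `v`, boundary separation, start bias, and
#' non-decision time taken from `params`. Returns 0 for `t` at or below the
#' non-decision time. The density uses the standard pair of series
#' expansions (small-time and large-time), switching by the usual accuracy
#' criterion with truncation error at most `eps`.
#'
#' @param t Response time(s) in seconds.
#' @param boundary `"upper"` (left option) or `"lower"` (right option).
#' @param params A [ddm_params()] object.
#' @param v Drift rate.
#' @param eps Series truncation tolerance (default 1e-6).
#' @return Nonnegative density value(s).
#' @export
wfpt_density <- function(t, boundary = c("upper", "lower"), params, v,
                         eps = 1e-6) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "ddm_params"))
  if (!is.finite(v)) stop("`v` must be finite", call. = FALSE)
  # rescale so the diffusion coefficient is 1
  s <- params$noise_sd
  a <- params$boundary / s
  vv <- v / s
  w <- params$start_bias
  td <- t - params$nondecision
  out <- numeric(length(t))
  ok <- is.finite(td) & td > 0
  if (any(ok)) {
    if (boundary == "lower") {
      out[ok] <- wfpt_lower_cpp(td[ok], vv, a, w, eps)
    } else {
      # upper-boundary density by reflection
      out[ok] <- wfpt_lower_cpp(td[ok], -vv, a, 1 - w, eps)
    }
  }
  out
}

#' Probability that the diffusion is absorbed at the upper boundary
#'
#' Closed-form absorption probability for drift `v`, boundary separation
#' `a`, relative start `w` and unit diffusion. With an unbiased start this
#' reduces to `1 / (1 + exp(-v * a))`.
#'
#' @param v Drift rate.
#' @param a Boundary separation.
#' @param w Relative start point (default 0.5).
#' @return Probability in (0, 1).
#' @export
ddm_absorption_prob <- function(v, a, w = 0.5) {
  if (abs(v) < 1e-12) return(w)
  expm1(-2 * v * a * w) / expm1(-2 * v * a)
}

#' Simulate one Dictator-Game decision from the diffusion model
#'
#' Draws a (choice, response time) pair by Euler-Maruyama simulation of the
#' diffusion whose drift is [trial_drift()] for this pair of allocations.
#' The upper boundary maps to the left option. Paths that have not been
#' absorbed by `max_t` seconds of decision time are resampled with a
#' warning.
#'
#' @param left,right Allocations in `[0, 1]`.
#' @param pref Dictator's preference in `[0, 1]`.
#' @param params A [ddm_params()] object.
#' @param dt Euler time step in seconds (default 1e-3).
#' @param max_t Decision-time cap in seconds (default 20).
#' @return A list with `choice` (`"left"` or `"right"`) and `rt` (seconds,
#'   including non-decision time).
#' @export
simulate_decision <- function(left, right, pref, params, dt = 1e-3,
                              max_t = 20) {
  if (inherits(left, "allocation_pair")) {
    right <- left$right
    left <- left$left
  }
  v <- trial_drift(left, right, pref, params)
  s <- params$noise_sd
  for (attempt in 1:100) {
    sim <- ddm_sim_cpp(1L, v / s, params$boundary / s, params$start_bias,
                       dt, max_t)
    if (sim$boundary[1] != 0L) {
      return(list(choice = if (sim$boundary[1] == 1L) "left" else "right",
                  rt = sim$rt[1] + params$nondecision))
    }
    warning("diffusion path exceeded `max_t`; resampling", call. = FALSE)
  }
  stop("diffusion failed to absorb within `max_t` after 100 resamples",
       call. = FALSE)
}

# density floor used during fitting so RTs at or below a candidate
# non-decision time do not produce -Inf and freeze the optimizer
.density_floor <- 1e-10

#' RT-only log-likelihood of a preference
#'
#' Log-likelihood of observed response times when the choices are unknown:
#' each trial contributes the log of the summed first-passage densities over
#' both boundaries, `log(f(rt, left) + f(rt, right))`, with the trial's
#' drift rate derived from the candidate preference. Response times at or
#' below the candidate non-decision time contribute a floor density rather
#' than `-Inf`.
#'
#' @param trials Data frame with columns `left`, `right`, `rt`.
#' @param pref Candidate preference in `[0, 1]`.
#' @param params A [ddm_params()] object.
#' @return Scalar log-likelihood.
#' @export
rt_only_loglik <- function(trials, pref, params) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  dens <- rt_both_boundary_density(trials, pref, params)
  sum(log(pmax(dens$upper + dens$lower, .density_floor)))
}

#' Joint choice + RT log-likelihood of a preference
#'
#' Log-likelihood when both the choice and the response time are observed:
#' each trial contributes the log first-passage density at the boundary
#' actually hit (`upper` = left).
#'
#' @param trials Data frame with columns `left`, `right`, `choice`
#'   (`"left"`/`"right"`), `rt`.
#' @inheritParams rt_only_loglik
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(trials, pref, params) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0,
            all(trials$choice %in% c("left", "right")))
  dens <- rt_both_boundary_density(trials, pref, params)
  d <- ifelse(trials$choice == "left", dens$upper, dens$lower)
  sum(log(pmax(d, .density_floor)))
}

# per-trial first-passage densities at both boundaries (vectorised over
# trials; the drift differs per trial)
rt_both_boundary_density <- function(trials, pref, params, eps = 1e-6) {
  n <- nrow(trials)
  s <- params$noise_sd
  v <- trial_drift(trials$left, trials$right, pref, params) / s
  a <- rep(params$boundary / s, n)
  w <- params$start_bias
  td <- trials$rt - params$nondecision
  list(upper = wfpt_lower_vec_cpp(td, -v, a, 1 - w, eps),
       lower = wfpt_lower_vec_cpp(td, v, a, w, eps))
}

#' Estimate a preference from response times alone
#'
#' Maximum-likelihood fit of (preference, boundary, non-decision time,
#' drift scale) to a set of Dictator-Game trials using only the response
#' times, via [rt_only_loglik()]. A bounded quasi-Newton search is restarted
#' from `n_starts` random initial points drawn uniformly within the bounds;
#' the best converged fit is kept.
#'
#' @param trials Data frame with columns `left`, `right`, `rt`.
#' @param n_starts Number of random restarts (default 10).
#' @param bounds Named list of `c(lower, upper)` bounds for `pref`,
#'   `boundary`, `nondecision`, `drift_scale`.
#' @return A list with `pref`, `params` ([ddm_params()]), `loglik`,
#'   `converged`, and `degenerate` (no usable RT variance).
#' @export
fit_preference_rt <- function(trials, n_starts = 10L,
                              bounds = list(pref = c(0.001, 0.999),
                                            boundary = c(0.1, 10.1),
                                            nondecision = c(0.05, 0.5),
                                            drift_scale = c(0.01, 20))) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  if (nrow(trials) < 20) {
    warning("fewer than 20 trials; RT-only estimates may be unstable",
            call. = FALSE)
  }
  degenerate <- stats::sd(trials$rt) < .Machine$double.eps^0.5
  if (degenerate) {
    warning("response times are constant; fit is degenerate", call. = FALSE)
  }
  # never let the candidate non-decision time exceed the fastest RT
  bounds$nondecision[2] <- min(bounds$nondecision[2], min(trials$rt) * 0.99)
  bounds$nondecision[1] <- min(bounds$nondecision[1], bounds$nondecision[2])
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  negll <- function(theta) {
    p <- ddm_params(boundary = theta[2], nondecision = theta[3],
                    drift_scale = theta[4])
    -rt_only_loglik(trials, theta[1], p)
  }
  best <- multistart_optim(negll, lower, upper, n_starts)
  list(pref = best$par[1],
       params = ddm_params(boundary = best$par[2],
                           nondecision = best$par[3],
                           drift_scale = best$par[4]),
       loglik = -best$value,
       converged = best$converged,
       degenerate = degenerate)
}

# bounded quasi-Newton with random uniform restarts; keeps the best value
# over all starts and reports whether any start converged cleanly
multistart_optim <- function(fn, lower, upper, n_starts) {
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    init <- lower + stats::runif(length(lower)) * (upper - lower)
    fit <- tryCatch(
      stats::optim(init, fn, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization restarts failed", call. = FALSE)
  best$converged <- any_conv
  best
}
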
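# Bayes-optimal benchmark observer: sequential grid posterior over the
# 5-parameter generative diffusion model (preference, inverse temperature,
# boundary separation, drift scale, non-decision time), with per-condition
# trial likelihoods.

# prior specification: bounds and log densities at the cell centers
.bo_axes_spec <- function() {
  list(
    pref = list(lo = 0, hi = 1,
                logd = function(x) stats::dbeta(x, 3.5, 3, log = TRUE)),
    beta = list(lo = 0, hi = 100,
                logd = function(x) stats::dgamma(x, shape = 1.2, scale = 5,
                                                 log = TRUE)),
    bound = list(lo = 0.1, hi = 10.1,
                 logd = function(x) stats::dgamma(x, shape = 2, scale = 2,
                                                  log = TRUE)),
    drift = list(lo = 0, hi = 20,
                 logd = function(x) stats::dnorm(x, 0, 5, log = TRUE)),
    ter = list(lo = 0.1, hi = 0.5,
               logd = function(x) stats::dunif(x, 0.1, 0.5, log = TRUE))
  )
}

#' Initialise the Bayes-optimal observer's parameter grid
#'
#' Discretizes the joint prior over (preference, inverse temperature,
#' boundary separation, drift scale, non-decision time) on a regular grid:
#' Beta(3.5, 3) on (0, 1), Gamma(1.2, scale 5) on (0, 100), Gamma(2,
#' scale 2) on (0.1, 10.1), Normal(0, 5) truncated to (0, 20), and uniform
#' on (0.1, 0.5). Cell centers sit at the midpoints of equal-width bins;
#' weights are the prior density at the centers, renormalized over the
#' truncated ranges.
#'
#' @param resolution Cells per axis: a single integer or a named vector
#'   over `pref`, `beta`, `bound`, `drift`, `ter` (default 15 each).
#' @return A list with class `"bo_grid"`: `axes` (cell centers), `dims`,
#'   `logw` (normalized log weights over the flattened grid), and internal
#'   index vectors.
#' @export
bo_grid <- function(resolution = 15L) {
  spec <- .bo_axes_spec()
  nm <- names(spec)
  if (length(resolution) == 1L) {
    resolution <- stats::setNames(rep(as.integer(resolution), 5L), nm)
  }
  if (any(resolution < 2L)) stop("`resolution` must be >= 2", call. = FALSE)
  axes <- lapply(nm, function(k) {
    s <- spec[[k]]
    width <- (s$hi - s$lo) / resolution[[k]]
    s$lo + (seq_len(resolution[[k]]) - 0.5) * width
  })
  names(axes) <- nm
  dims <- vapply(axes, length, integer(1))
  n <- prod(dims)
  # column-major subscript vectors for the flattened grid
  idx <- vector("list", 5L)
  stride <- 1L
  for (d in 1:5) {
    idx[[d]] <- ((seq_len(n) - 1L) %/% stride) %% dims[d] + 1L
    stride <- stride * dims[d]
  }
  names(idx) <- nm
  logw <- numeric(n)
  for (d in 1:5) {
    logw <- logw + spec[[d]]$logd(axes[[d]])[idx[[d]]]
  }
  logw <- logw - logsumexp(logw)
  structure(list(axes = axes, dims = dims, logw = logw, idx = idx),
            class = "bo_grid")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Per-cell likelihood of one observed trial
#'
#' Condition-specific likelihood of an observation for every grid cell:
#' both visible, the Wiener first-passage density at the observed choice
#' and RT; RT only, that density summed over both boundaries; choice only,
#' the softmax choice probability; none, a constant (the posterior equals
#' the prior).
#'
#' @param grid A [bo_grid()] object.
#' @param obs A list with `left`, `right`, `condition`, and (as visible)
#'   `choice`, `rt`.
#' @return Log-likelihood vector over the flattened grid.
#' @export
bo_trial_loglik <- function(grid, obs) {
  stopifnot(inherits(grid, "bo_grid"))
  cond <- obs$condition
  if (cond == "none") return(numeric(length(grid$logw)))
  ax <- grid$axes
  i <- grid$idx
  sdiff <- subjective_value(obs$left, ax$pref) -
    subjective_value(obs$right, ax$pref)
  if (cond == "choice_only") {
    # depends on (pref, beta) only
    p_left <- outer(sdiff, ax$beta, function(sd, b) stats::plogis(b * sd))
    p <- if (obs$choice == "left") p_left else 1 - p_left
    lidx <- i$pref + grid$dims[1] * (i$beta - 1L)
    return(log(pmax(as.vector(p), 1e-300))[lidx])
  }
  if (!cond %in% c("rt_only", "both")) {
    stop("unknown condition: ", cond, call. = FALSE)
  }
  v <- ax$drift[i$drift] * sdiff[i$pref]
  a <- ax$bound[i$bound]
  td <- rep(obs$rt, length(v)) - ax$ter[i$ter]
  if (cond == "both") {
    dens <- if (obs$choice == "left") {
      wfpt_lower_vec_cpp(td, -v, a, 0.5, 1e-6)
    } else {
      wfpt_lower_vec_cpp(td, v, a, 0.5, 1e-6)
    }
  } else {
    dens <- wfpt_lower_vec_cpp(td, -v, a, 0.5, 1e-6) +
      wfpt_lower_vec_cpp(td, v, a, 0.5, 1e-6)
  }
  log(pmax(dens, 1e-300))
}

#' Single Bayesian update of the grid posterior
#'
#' Adds the trial's log-likelihood to the log weights and renormalizes.
#' The posterior after one trial is the prior for the next.
#'
#' @param grid A [bo_grid()] object.
#' @param obs Observation as in [bo_trial_loglik()].
#' @return The updated `bo_grid`.
#' @export
bo_update <- function(grid, obs) {
  lw <- grid$logw + bo_trial_loglik(grid, obs)
  z <- logsumexp(lw)
  if (!is.finite(z)) {
    stop(sprintf("all grid cells have zero likelihood at trial (left=%.3f, right=%.3f)",
                 obs$left, obs$right), call. = FALSE)
  }
  grid$logw <- lw - z
  grid
}

#' Marginal posterior over one axis
#'
#' @param grid A [bo_grid()] object.
#' @param axis One of `"pref"`, `"beta"`, `"bound"`, `"drift"`, `"ter"`.
#' @return Data frame with `value` (cell centers) and `weight`.
#' @export
bo_marginal <- function(grid, axis = "pref") {
  stopifnot(axis %in% names(grid$axes))
  w <- exp(grid$logw - max(grid$logw))
  w <- w / sum(w)
  marg <- as.vector(rowsum(w, grid$idx[[axis]]))
  data.frame(value = grid$axes[[axis]], weight = marg)
}

#' Point estimate of the preference from the grid posterior
#'
#' Default: mean of the marginal posterior over the preference axis
#' (stable on coarse grids). `method = "map"` instead returns the
#' preference coordinate of the joint-posterior mode.
#'
#' @param grid A [bo_grid()] object.
#' @param method `"mean"` or `"map"`.
#' @return Preference estimate in (0, 1).
#' @export
bo_estimate <- function(grid, method = c("mean", "map")) {
  method <- match.arg(method)
  if (method == "map") {
    j <- which.max(grid$logw)
    return(grid$axes$pref[grid$idx$pref[j]])
  }
  m <- bo_marginal(grid, "pref")
  sum(m$value * m$weight)
}

#' Posterior-predictive probability that the dictator chooses left
#'
#' Mixture over grid cells of the softmax choice probability at each
#' cell's (preference, inverse temperature).
#'
#' @param grid A [bo_grid()] object.
#' @param left,right Allocations in `[0, 1]`.
#' @return Probability in (0, 1).
#' @export
bo_predict_choice <- function(grid, left, right) {
  ax <- grid$axes
  w <- exp(grid$logw - max(grid$logw))
  w <- w / sum(w)
  lidx <- grid$idx$pref + grid$dims[1] * (grid$idx$beta - 1L)
  w2 <- as.vector(rowsum(w, lidx))
  sdiff <- subjective_value(left, ax$pref) - subjective_value(right, ax$pref)
  p2 <- outer(sdiff, ax$beta, function(sd, b) stats::plogis(b * sd))
  sum(w2 * as.vector(p2))
}

#' Run the Bayes-optimal observer over one session
#'
#' Sequentially updates the grid over the session's observation stream and
#' reads out the preference estimate at each estimation slot; after the
#' last trial, computes posterior-predictive left-choice probabilities for
#' the prediction pairs.
#'
#' @param session An observer session (see [build_observer_sessions()]).
#' @param resolution Grid resolution passed to [bo_grid()].
#' @param method Point-estimate rule passed to [bo_estimate()].
#' @return A list with `estimates` (one per slot), `slots`, `p_left`
#'   (per prediction pair), `marginal_sd` (posterior SD of the preference
#'   at the end), and the final `grid`.
#' @export
bo_run_session <- function(session, resolution = 15L,
                           method = c("mean", "map")) {
  method <- match.arg(method)
  grid <- bo_grid(resolution)
  slots <- session$estimation_slots
  est <- numeric(length(slots))
  if (any(slots == 0)) est[slots == 0] <- bo_estimate(grid, method)
  obs <- session$obs
  for (t in seq_len(nrow(obs))) {
    grid <- bo_update(grid, list(left = obs$left[t], right = obs$right[t],
                                 choice = obs$choice[t], rt = obs$rt[t],
                                 condition = session$condition))
    hit <- which(slots == t)
    if (length(hit)) est[hit] <- bo_estimate(grid, method)
  }
  m <- bo_marginal(grid, "pref")
  msd <- sqrt(max(sum(m$value^2 * m$weight) - sum(m$value * m$weight)^2, 0))
  pp <- session$pred_pairs
  p_left <- vapply(seq_len(nrow(pp)), function(j) {
    bo_predict_choice(grid, pp$left[j], pp$right[j])
  }, numeric(1))
  list(estimates = est, slots = slots, p_left = p_left,
       marginal_sd = msd, grid = grid)
}
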
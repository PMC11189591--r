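# Orchestration and generic helpers: Spearman correlation, the
# repeated-measures power computation, CSV schemas, and the end-to-end
# synthetic study.

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks; ties receive their mean rank.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Coefficient in `[-1, 1]`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Analytic power of a one-group repeated-measures ANOVA
#'
#' Noncentral-F power under the within-factors convention used by standard
#' power software: noncentrality `lambda = f^2 * n * m / (1 - rho)`,
#' numerator df `(m - 1) * eps`, denominator df `(n - 1) * (m - 1) * eps`,
#' where `f` is Cohen's effect size, `m` the number of measurements, `rho`
#' the correlation among repeated measures, and `eps` the nonsphericity
#' correction.
#'
#' @param n Sample size.
#' @param effect_f Cohen's f.
#' @param n_measurements Number of repeated measurements `m`.
#' @param alpha Type-I error rate.
#' @param corr_among_measures Correlation `rho` among measurements.
#' @param nonsphericity Nonsphericity correction `eps` in (1/(m-1), 1].
#' @return Power in (0, 1).
#' @export
power_rm_anova_at <- function(n, effect_f, n_measurements, alpha = 0.05,
                              corr_among_measures = 0.5,
                              nonsphericity = 1) {
  m <- n_measurements
  lambda <- effect_f^2 * n * m / (1 - corr_among_measures)
  df1 <- (m - 1) * nonsphericity
  df2 <- (n - 1) * (m - 1) * nonsphericity
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Required sample size for a repeated-measures ANOVA
#'
#' Smallest `n` whose analytic power ([power_rm_anova_at()]) reaches the
#' target.
#'
#' @inheritParams power_rm_anova_at
#' @param power_target Desired power in (0, 1).
#' @param n_max Search cap.
#' @return A list with `n` and the achieved `power`.
#' @export
power_rm_anova <- function(effect_f, n_measurements, alpha = 0.05,
                           power_target = 0.9, corr_among_measures = 0.5,
                           nonsphericity = 1, n_max = 1e6) {
  assert_positive(effect_f)
  stopifnot(power_target > 0, power_target < 1)
  n <- 2
  while (n <= n_max) {
    pw <- power_rm_anova_at(n, effect_f, n_measurements, alpha,
                            corr_among_measures, nonsphericity)
    if (pw >= power_target) return(list(n = n, power = pw))
    n <- n + 1
  }
  stop("power target unreachable within `n_max`", call. = FALSE)
}

# ---- CSV schemas -------------------------------------------------------

.schemas <- list(
  dictator_trials = list(
    cols = c("dictator_id", "trial", "left", "right", "choice", "rt"),
    check = function(df) {
      bad <- which(df$left < 0 | df$left > 1 | df$right < 0 | df$right > 1)
      if (length(bad)) return(sprintf("allocation out of [0, 1] at row %d",
                                      bad[1]))
      bad <- which(!is.na(df$rt) & df$rt <= 0)
      if (length(bad)) return(sprintf("non-positive rt at row %d", bad[1]))
      bad <- which(!is.na(df$choice) & !df$choice %in% c("left", "right"))
      if (length(bad)) return(sprintf("invalid choice at row %d", bad[1]))
      NULL
    }),
  selection_manifest = list(
    cols = c("dictator_id", "trial", "category", "role", "order_index"),
    check = function(df) {
      bad <- which(!df$role %in% c("observation", "prediction"))
      if (length(bad)) return(sprintf("invalid role at row %d", bad[1]))
      bad <- which(!df$category %in% c("fast", "slow", "uninformative"))
      if (length(bad)) return(sprintf("invalid category at row %d", bad[1]))
      NULL
    }),
  estimates = list(
    cols = c("observer_id", "dictator_id", "condition", "slot",
             "estimate", "true_pref"),
    check = function(df) {
      bad <- which(df$estimate < 0 | df$estimate > 1)
      if (length(bad)) return(sprintf("estimate out of [0, 1] at row %d",
                                      bad[1]))
      NULL
    }),
  fits = list(
    cols = c("entity_id", "model", "param", "value"),
    check = function(df) NULL)
)

#' Write a schema-checked CSV table
#'
#' @param df Data frame conforming to one of the package schemas.
#' @param path Output file path.
#' @param schema One of `"dictator_trials"`, `"selection_manifest"`,
#'   `"estimates"`, `"fits"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path,
                        schema = c("dictator_trials", "selection_manifest",
                                   "estimates", "fits")) {
  schema <- match.arg(schema)
  validate_schema(df, schema)
  utils::write.csv(df[, .schemas[[schema]]$cols, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a schema-checked CSV table
#'
#' Column order in the file is irrelevant; missing columns and out-of-range
#' values are reported with their row number.
#'
#' @param path CSV file path.
#' @inheritParams write_table
#' @return Data frame in canonical column order.
#' @export
read_table <- function(path,
                       schema = c("dictator_trials", "selection_manifest",
                                  "estimates", "fits")) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_schema(df, schema)
  df[, .schemas[[schema]]$cols, drop = FALSE]
}

validate_schema <- function(df, schema) {
  sc <- .schemas[[schema]]
  missing <- setdiff(sc$cols, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  msg <- sc$check(df)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  invisible(df)
}

# ---- end-to-end study --------------------------------------------------

#' Accuracy learning curves by condition and estimation slot
#'
#' @param estimates The `estimates` table from
#'   [simulate_observer_cohort()].
#' @return Data frame with `condition`, `slot`, `mean_accuracy`, `se`.
#' @export
learning_curves <- function(estimates) {
  acc <- estimation_accuracy(estimates$estimate, estimates$true_pref)
  agg <- stats::aggregate(acc,
                          by = list(condition = estimates$condition,
                                    slot = estimates$slot),
                          FUN = function(z) c(mean = mean(z),
                                              se = stats::sd(z) /
                                                sqrt(length(z))))
  data.frame(condition = agg$condition, slot = agg$slot,
             mean_accuracy = agg$x[, "mean"], se = agg$x[, "se"])
}

#' Run a complete synthetic study end to end
#'
#' Design, dictator simulation, preference fitting from RTs and from
#' choices, trial selection, session construction, RL-cohort forward
#' simulation, Bayes-optimal trajectories, and summary tables. Fully
#' reproducible given the RNG state at entry.
#'
#' @param config A [study_config()] object.
#' @param rl An [rl_params()] object for the simulated RL cohort.
#' @param fit_preferences Also run the (slower) RT-only and choice-only
#'   preference fits per dictator (default `TRUE`).
#' @param run_bo Also run the Bayes-optimal observer per session
#'   (default `FALSE`; expensive).
#' @param bo_resolution Grid resolution for the Bayes-optimal runs.
#' @param n_starts Restarts for the preference fits.
#' @return A list with `dictator_trials`, `sessions`, `recovery_table`,
#'   `learning_curves`, `chance_level`, and (if requested)
#'   `bo_trajectories`.
#' @export
run_full_synthetic_study <- function(config = study_config(),
                                     rl = rl_params(),
                                     fit_preferences = TRUE,
                                     run_bo = FALSE,
                                     bo_resolution = 15L,
                                     n_starts = 5L) {
  dictators <- sample_dictators(config)
  design <- make_design(config)
  datasets <- lapply(dictators, generate_dictator_dataset, design = design)
  trials <- do.call(rbind, datasets)

  recovery <- NULL
  if (fit_preferences) {
    recovery <- do.call(rbind, lapply(seq_along(dictators), function(i) {
      fr <- fit_preference_rt(datasets[[i]], n_starts = n_starts)
      fc <- fit_preference_choices(datasets[[i]], n_starts = n_starts)
      data.frame(dictator_id = dictators[[i]]$id,
                 true_pref = dictators[[i]]$pref,
                 pref_rt = fr$pref, pref_choice = fc$pref)
    }))
  }

  sessions <- build_observer_sessions(dictators, datasets, config)
  cohort <- simulate_observer_cohort(sessions, config, agent = "rl",
                                     params = rl)
  curves <- learning_curves(cohort$estimates)
  prefs <- vapply(dictators, `[[`, numeric(1), "pref")
  chance <- empirical_chance_level(prefs)

  out <- list(dictator_trials = trials, sessions = sessions,
              recovery_table = recovery, cohort = cohort,
              learning_curves = curves, chance_level = chance)
  if (run_bo) {
    out$bo_trajectories <- lapply(sessions, bo_run_session,
                                  resolution = bo_resolution)
  }
  out
}
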
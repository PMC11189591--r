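# Shared synthetic fixtures, built once per test run under a fixed seed.

# full-size cohort: 16 diffusion dictators, 165-trial design, observer
# session templates (used by several test files; cached after first build)
test_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(1)
      cfg <- study_config()
      design <- make_design(cfg)
      dictators <- sample_dictators(cfg)
      datasets <- lapply(dictators, generate_dictator_dataset,
                         design = design)
      sessions <- suppressWarnings(
        build_observer_sessions(dictators, datasets, cfg))
      cache <<- list(config = cfg, design = design, dictators = dictators,
                     datasets = datasets, sessions = sessions)
    }
    cache
  }
})

# small hand-rolled trial table for cheap unit tests
tiny_trials <- function() {
  data.frame(
    trial = 1:6,
    left = c(0.2, 0.8, 0.3, 0.6, 0.1, 0.45),
    right = c(0.7, 0.3, 0.65, 0.25, 0.9, 0.55),
    choice = c("left", "right", "left", "right", "left", "right"),
    rt = c(0.9, 1.4, 2.1, 0.8, 1.1, 2.6)
  )
}
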
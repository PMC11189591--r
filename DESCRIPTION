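Package: speedpref
Title: Inferring Social Preferences from Choices and Decision Speed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how social preferences in the Dictator Game
    can be inferred from choices, response times, or both. Implements a
    quadratic subjective-value model with drift-diffusion (Wiener
    first-passage time) likelihoods for response-time-only preference
    estimation, a softmax likelihood for choice-only estimation, an
    observational reinforcement-learning model of how third-party observers
    track another person's preference, a benchmark Bayes-optimal grid
    observer over the generative diffusion parameters, informative-trial
    selection, and a fully seeded synthetic-study generator so that every
    stage of the analysis pipeline can be exercised end to end without
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
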
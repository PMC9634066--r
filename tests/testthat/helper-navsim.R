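# Shared fixtures: built once per test run.

default_map <- build_default_map()
default_base <- build_complete_rulebase(default_map)

# Fast oscillator settings for closed-loop tests: a 20-time-unit perception
# window at dt = 0.01 (dt * 9 = 0.09, inside the step guard) keeps every
# matched/mismatched envelope margin comfortably on the right side of the
# unity threshold (verified in test-what-stream resonance checks).
fast_osc <- function(lam = 0.2) {
  list(lam = lam, t_end = 20, dt = 0.01)
}

# Independent naive implementation of product inference + center-average
# defuzzification: explicit double loop over rules and input dimensions.
# Used as the oracle the engine is compared against.
brute_force_infer <- function(base, here, goal, attention,
                              rules = base$rules) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(rules))) {
    w <- 1
    for (j in 1:3) {
      mu <- switch(j,
        evaluate_mf(base$mfs$here[[as.character(rules$here[i])]], here),
        evaluate_mf(base$mfs$goal[[as.character(rules$goal[i])]], goal),
        evaluate_mf(base$mfs$attention[[rules$attention_label[i]]], attention)
      )
      w <- w * mu
    }
    num <- num + rules$next_step[i] * w
    den <- den + w
  }
  num / den
}

# The two printed route tables, shipped as fixtures.
route1_table <- read_rulebase_csv(
  system.file("extdata", "rules_route1.csv", package = "navsim")
)
route2_table <- read_rulebase_csv(
  system.file("extdata", "rules_route2.csv", package = "navsim")
)
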
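test_that("membership functions evaluate to their closed forms", {
  g <- mf_gaussian(4, 0.15)
  expect_equal(evaluate_mf(g, 4), 1)
  expect_equal(evaluate_mf(g, 4.2), exp(-0.04 / (2 * 0.15^2)))
  expect_equal(evaluate_mf(g, 4.2), 0.4111, tolerance = 1e-4)
  expect_error(mf_gaussian(4, 0), "sigma")
  s <- mf_s(1, 2); z <- mf_z(1, 2)
  expect_equal(evaluate_mf(s, 2.3), 1)
  expect_equal(evaluate_mf(z, 2.3), 0)
  expect_equal(evaluate_mf(s, 0.5), 0)
  expect_equal(evaluate_mf(z, 0.5), 1)
  expect_equal(evaluate_mf(s, 1.5), 0.5)   # deficit threshold crossover
  expect_equal(evaluate_mf(z, 1.5), 0.5)
  x <- seq(0, 3, by = 0.01)
  expect_true(all(evaluate_mf(s, x) >= 0 & evaluate_mf(s, x) <= 1))
  expect_true(all(diff(evaluate_mf(s, x)) >= 0))
})

test_that("the complete rule base enumerates the map's input space", {
  expect_equal(nrow(default_base$rules), 72)
  expect_equal(nrow(unique(default_base$rules[, c("here", "goal")])), 36)
  tiny <- build_complete_rulebase(build_default_map(n_route = 1),
                                  attention_states = "with")
  expect_equal(nrow(tiny$rules), 1)
  expect_equal(tiny$rules$next_step, 1)  # stay: here == goal
})

test_that("active route rules reproduce the printed tables", {
  a1 <- active_rules(default_base, 1, 6)
  expect_equal(nrow(a1), 10)
  expect_equal(a1[, c("here", "goal", "attention_label", "next_step")],
               route1_table, ignore_attr = TRUE)
  a2 <- active_rules(default_base, 4, 1)
  expect_equal(nrow(a2), 6)
  expect_equal(a2[, c("here", "goal", "attention_label", "next_step")],
               route2_table, ignore_attr = TRUE)
  both <- unique(rbind(a1, a2))
  expect_equal(nrow(both), 16)
  expect_error(active_rules(default_base, 1, 99))
})

test_that("the ambiguous route-2 low-attention consequent is overridable", {
  base5 <- build_complete_rulebase(
    default_map,
    overrides = data.frame(here = 4, goal = 1, attention_label = "without",
                           next_step = 5)
  )
  a2 <- active_rules(base5, 4, 1)
  expect_equal(a2$next_step[a2$here == 4 & a2$attention_label == "without"], 5)
})

test_that("crisp inference reproduces every printed table row", {
  for (tab in list(route1_table, route2_table)) {
    for (i in seq_len(nrow(tab))) {
      att <- if (tab$attention_label[i] == "with") 2 else 1
      inf <- infer_next_step(default_base, tab$here[i], tab$goal[i], att)
      expect_equal(inf$next_step, tab$next_step[i])
      expect_equal(inf$raw, tab$next_step[i], tolerance = 1e-6)
    }
  }
})

test_that("a single firing rule returns its consequent exactly", {
  one <- default_base$rules[default_base$rules$here == 3 &
                              default_base$rules$goal == 6 &
                              default_base$rules$attention_label == "with", ]
  inf <- infer_next_step(default_base, 3, 6, 2, rules = one)
  expect_identical(inf$raw, 4)
  expect_error(infer_next_step(default_base, 3, 6, 0.5, rules = one),
               "no rule fires")
})

test_that("frequency-code inputs are absorbed by the membership functions", {
  inf <- infer_next_step(default_base, 4.2, 9, 2.3, input = "code")
  expect_equal(inf$next_step, 2)
  expect_equal(infer_next_step(default_base, 2, 1, 2)$next_step, 1)
})

test_that("output interpolates continuously and is robust to appearance shifts", {
  for (tab in list(route1_table, route2_table)) {
    for (i in seq_len(nrow(tab))) {
      att <- if (tab$attention_label[i] == "with") 2 else 1
      for (d in c(-0.2, 0.2)) {
        inf <- infer_next_step(default_base, tab$here[i] + d, tab$goal[i], att)
        expect_equal(inf$next_step, tab$next_step[i])
      }
    }
  }
  # continuity: small input change, small raw-output change
  r1 <- infer_next_step(default_base, 2.0, 6, 2)$raw
  r2 <- infer_next_step(default_base, 2.01, 6, 2)$raw
  expect_lt(abs(r1 - r2), 0.05)
})

test_that("the rule base is complete over the operating region", {
  for (here in seq(3.8, 9.2, by = 0.4)) {
    for (goal in seq(3.8, 9.2, by = 0.4)) {
      for (att in seq(0.5, 2.5, by = 0.5)) {
        inf <- infer_next_step(default_base, here, goal, att, input = "code")
        expect_true(is.finite(inf$raw))
      }
    }
  }
})

test_that("inference stays a convex combination of firing consequents", {
  set.seed(7)
  for (k in 1:200) {
    here <- runif(1, 0.8, 6.2)
    goal <- runif(1, 0.8, 6.2)
    att <- runif(1, 0.5, 2.5)
    inf <- infer_next_step(default_base, here, goal, att)
    fired <- default_base$rules$next_step[inf$strengths > 0]
    expect_gte(inf$raw, min(fired))
    expect_lte(inf$raw, max(fired))
  }
})

test_that("degree pruning keeps the strongest rule per antecedent", {
  rules <- data.frame(here = c(1, 1, 2), goal = 6, attention_label = "with",
                      next_step = c(2, 7, 3), degree = c(0.9, 0.4, 1))
  pruned <- prune_by_degree(rules)
  expect_equal(nrow(pruned), 2)
  expect_equal(pruned$next_step[pruned$here == 1], 2)
  # no duplicates: unchanged
  expect_equal(prune_by_degree(pruned), pruned)
  tie <- data.frame(here = 1, goal = 6, attention_label = "with",
                    next_step = c(7, 2), degree = 0.5)
  expect_warning(kept <- prune_by_degree(tie), "tie")
  expect_equal(kept$next_step, 2)
})

test_that("rule tables round-trip through CSV", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_rulebase_csv(default_base$rules, path)
  back <- read_rulebase_csv(path)
  expect_equal(back, default_base$rules[, names(back)], ignore_attr = TRUE)
  writeLines("here,goal\n1,2", path)
  expect_error(read_rulebase_csv(path), "missing column")
})
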
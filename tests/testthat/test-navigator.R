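test_that("expectation checking distinguishes match, mismatch, and failure", {
  expect_equal(check_expectation(5, 5), "match")
  expect_equal(check_expectation(5, 8), "mismatch")
  expect_equal(check_expectation(NA, 5), "match")       # empty buffer
  expect_equal(check_expectation(5, NA), "retrieval_failure")
})

test_that("path competition weighs code similarity, then geometry, then id", {
  m <- default_map
  # neighbors of LM2: LM1 (code 4), LM3 (code 6), LM8 (code 11)
  expect_equal(choose_by_competition(m, 2, lost_code = 6.4), 3)
  expect_equal(choose_by_competition(m, 2, lost_code = 11), 8)
  # 1/(1+|5-6|) = 1/2 beats 1/(1+|9-6|) = 1/4: weights favor code 5 (LM2)
  # among LM5's neighbors {LM4 (7), LM6 (9), LM11 (14)} for lost code 6,
  # LM4 wins with weight 1/2
  expect_equal(choose_by_competition(m, 5, lost_code = 6), 4)
  # equidistant codes: smallest angle to the previous heading
  expect_equal(choose_by_competition(m, 2, lost_code = 5,
                                     prev_heading = c(1, 0)), 3)
  expect_equal(choose_by_competition(m, 2, lost_code = 5,
                                     prev_heading = c(-1, 0)), 1)
  # no heading: lowest id among tied candidates
  expect_equal(choose_by_competition(m, 2, lost_code = 5), 1)
  # single candidate
  expect_equal(choose_by_competition(m, 7, lost_code = 99), 1)
})

test_that("perception recognizes route landmarks and fails in the AD regime", {
  cache <- new.env()
  osc <- utils::modifyList(default_oscillator(), fast_osc())
  expect_equal(perceive(default_map, 3, osc, cache), 6)
  expect_equal(perceive(default_map, 1, osc, cache), 4)
  osc_ad <- utils::modifyList(default_oscillator(), fast_osc(lam = 15.2))
  expect_true(is.na(perceive(default_map, 3, osc_ad, cache)))
})

test_that("a trivial start == goal scenario succeeds with an empty trace", {
  cfg <- scenario_config(start = 2, goal = 2, oscillator = fast_osc())
  tr <- run_scenario(cfg)
  expect_equal(nrow(tr), 0)
  expect_equal(attr(tr, "status"), "goal_reached")
})

test_that("healthy attentive runs reach the goal in route-length steps", {
  for (pair in list(c(1, 6), c(4, 1), c(2, 5), c(6, 1))) {
    cfg <- scenario_config(start = pair[1], goal = pair[2],
                           attention = list(default = 2),
                           oscillator = fast_osc())
    tr <- run_scenario(cfg)
    route <- find_route(default_map, pair[1], pair[2])
    expect_equal(attr(tr, "status"), "goal_reached")
    expect_equal(nrow(tr), length(route) - 1)
    expect_equal(attr(tr, "visited"), route)
    expect_true(all(tr$action == "move"))
    # where-stream guided movement lands within half a grid bin
    expect_true(all(tr$where_error < 1, na.rm = TRUE))
  }
})

test_that("short-term memory buffers shift on every decision", {
  cfg <- scenario_preset("fig13")
  cfg$oscillator <- utils::modifyList(cfg$oscillator, fast_osc())
  tr <- run_scenario(cfg)
  expect_equal(attr(tr, "status"), "goal_reached")
  for (i in 2:nrow(tr)) {
    if (tr$action[i] != "stay") {
      expect_equal(tr$stm_prev_id[i], tr$stm_next_id[i - 1])
    }
  }
  # wrong-branch flags are consistent with the branch's role
  entered <- tr$next_step[tr$entered_wrong_branch]
  roles <- default_map$landmarks$role[match(entered,
                                            default_map$landmarks$id)]
  expect_true(all(roles == "wrong_path"))
})

test_that("an attention drop changes the trace only from that landmark on", {
  osc <- fast_osc()
  base_run <- run_scenario(scenario_config(
    start = 1, goal = 6, attention = list(default = 2), oscillator = osc))
  drop_run <- run_scenario(scenario_config(
    start = 1, goal = 6,
    attention = list(default = 2,
                     drops = list(list(at_landmark = 3, value = 1,
                                       steps = 1))),
    oscillator = osc))
  # identical up to the decision at LM3 (first two decisions)
  a <- as.data.frame(base_run)[1:2, ]
  b <- as.data.frame(drop_run)[1:2, ]
  expect_equal(a, b, ignore_attr = TRUE)
  expect_equal(drop_run$next_step[3], 9)  # wrong branch at LM3
  expect_true(any(drop_run$entered_wrong_branch))
  expect_true(any(drop_run$corrected))
  expect_equal(attr(drop_run, "status"), "goal_reached")
})

test_that("identical configurations yield identical traces", {
  cfg <- scenario_preset("fig13")
  cfg$oscillator <- utils::modifyList(cfg$oscillator, fast_osc())
  t1 <- run_scenario(cfg)
  t2 <- run_scenario(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "visited"), attr(t2, "visited"))
})

test_that("the AD regime wanders by competition and never reaches the goal", {
  cfg <- scenario_preset("ad")
  cfg$oscillator <- utils::modifyList(cfg$oscillator, fast_osc(lam = 15.2))
  tr <- run_scenario(cfg)
  expect_equal(attr(tr, "status"), "lost")
  expect_true(all(is.na(tr$recognized_code)))
  expect_true(all(tr$action == "competition"))
  expect_gte(nrow(tr), 4 * 6)
})

test_that("lesioned landmarks trigger competition instead of retrieval", {
  m <- lesion(default_map, 3)
  cfg <- scenario_config(map = m, start = 1, goal = 6,
                         attention = list(default = 2),
                         oscillator = fast_osc())
  tr <- run_scenario(cfg)
  expect_true(any(tr$action == "competition"))
})

test_that("traces export to CSV and JSON", {
  cfg <- scenario_config(start = 1, goal = 3,
                         attention = list(default = 2),
                         oscillator = fast_osc())
  tr <- run_scenario(cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(f1, f2)))
  write_trace(tr, f1)
  write_trace(tr, f2)
  expect_equal(nrow(utils::read.csv(f1)), nrow(tr))
  js <- jsonlite::read_json(f2)
  expect_equal(js$status, "goal_reached")
  expect_equal(length(js$steps), nrow(tr))
})

test_that("scenario configs are validated with field names", {
  expect_error(scenario_config(start = 1, goal = 99), "99")
  expect_error(scenario_config(start = 1, goal = 6,
                               attention = list(value = 2)), "default")
  expect_error(
    scenario_config(start = 1, goal = 6,
                    attention = list(default = 2,
                                     drops = list(list(value = 1)))),
    "at_landmark"
  )
  expect_error(scenario_preset("nonexistent"), "unknown")
})
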
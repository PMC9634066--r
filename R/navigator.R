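#' Perceive the landmark at the agent's position
#'
#' Drives the oscillator bank with the landmark's stimulus and applies
#' resonance recognition. Returns the recognized frequency code (the natural
#' frequency of the uniquely resonating unit) or `NA` when no unit -- or
#' more than one, the Alzheimer regime -- crosses the threshold.
#'
#' @param map a [cognitive_map()].
#' @param landmark_id id of the landmark being perceived.
#' @param osc oscillator/perception parameters: `lam`, `B`, `As`,
#'   `threshold`, `bank_P`, `t_end`, `dt` (see [default_oscillator()]).
#' @param cache optional environment memoizing bank runs by stimulus code.
#' @return Recognized code (numeric) or `NA`.
#' @export
perceive <- function(map, landmark_id, osc = default_oscillator(),
                     cache = NULL) {
  code <- landmark_info(map, landmark_id)$freq_code
  key <- sprintf("%.8g|%.8g", code, osc$lam)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  bank <- vdp_bank(P = osc$bank_P, lam = osc$lam, B = osc$B)
  resp <- bank_response(bank, code, t_end = osc$t_end, dt = osc$dt,
                        As = osc$As)
  k <- recognize_landmark(resp, threshold = osc$threshold)
  out <- if (is.na(k)) NA_real_ else osc$bank_P[k]
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Default oscillator and perception parameters
#'
#' The printed healthy parameter set (`lam = 0.2`, `B = 1.5`, `As = 1`,
#' bank `P = 4..9`, unity threshold) with a 30-time-unit perception window
#' at `dt = 0.005` -- long enough for the resonant unit's envelope to settle
#' above threshold, short enough to keep closed-loop runs fast.
#'
#' @param lam,B,As,threshold,bank_P,t_end,dt overrides.
#' @return Named list.
#' @export
default_oscillator <- function(lam = 0.2, B = 1.5, As = 1, threshold = 1,
                               bank_P = 4:9, t_end = 30, dt = 0.005) {
  list(lam = lam, B = B, As = As, threshold = threshold, bank_P = bank_P,
       t_end = t_end, dt = dt)
}

#' Compare a recognized code against the expected next landmark
#'
#' @param expected_code code held in the next-subgoal buffer (`NA` when the
#'   buffer is empty).
#' @param recognized_code code returned by [perceive()] (`NA` on retrieval
#'   failure).
#' @return `"match"`, `"mismatch"` (raises the wrong-path message), or
#'   `"retrieval_failure"`.
#' @export
check_expectation <- function(expected_code, recognized_code) {
  if (is.na(recognized_code)) return("retrieval_failure")
  if (is.na(expected_code)) return("match")
  if (isTRUE(all.equal(expected_code, recognized_code))) "match" else
    "mismatch"
}

#' Choose an outgoing path by weighted code competition
#'
#' When a landmark's stored information cannot be retrieved, candidate
#' outgoing paths compete with weights `1 / (1 + |code - lost_code|)` -- the
#' most familiar-seeming (closest-code) path wins. Ties break by the
#' smallest angle to the previous heading, then by lowest landmark id.
#'
#' @param map a [cognitive_map()].
#' @param current_id landmark id the agent stands on.
#' @param lost_code the code of the information that failed to be retrieved.
#' @param prev_heading optional unit vector of the previous step direction.
#' @return The chosen neighbor landmark id, or `NA` when there is no
#'   outgoing path (stuck).
#' @export
choose_by_competition <- function(map, current_id, lost_code,
                                  prev_heading = NULL) {
  cand <- neighbors_of(map, current_id)
  if (length(cand) == 0) return(NA_integer_)
  if (length(cand) == 1) return(cand)
  codes <- landmark_info(map, cand)$freq_code
  w <- 1 / (1 + abs(codes - lost_code))
  best <- cand[w == max(w)]
  if (length(best) == 1) return(best)
  if (!is.null(prev_heading)) {
    here_xy <- landmark_info(map, current_id)
    ang <- vapply(best, function(id) {
      to <- landmark_info(map, id)
      v <- c(to$x - here_xy$x, to$y - here_xy$y)
      v <- v / sqrt(sum(v^2))
      acos(pmin(1, pmax(-1, sum(v * prev_heading))))
    }, numeric(1))
    best <- best[ang == min(ang)]
  }
  min(best)
}

#' Scenario configuration
#'
#' Validates and normalizes a closed-loop scenario: map, rule base, start
#' and goal, the attention profile, oscillator parameters, and run limits.
#'
#' @param map a [cognitive_map()] (default map if omitted).
#' @param rulebase a [build_complete_rulebase()] or `"auto"`.
#' @param start,goal landmark ids.
#' @param here_code optional initial perceived code of the start landmark
#'   (e.g. 4.2 for a slightly changed landmark appearance); defaults to the
#'   start landmark's exact code.
#' @param goal_code optional goal code; defaults to the goal landmark's code.
#' @param attention list with `default` (attention level) and optional
#'   `drops`, each `list(at_landmark =, value =, steps =)`: when the agent
#'   first makes a decision at `at_landmark`, attention drops to `value` for
#'   that decision and the following `steps - 1` decisions.
#' @param oscillator see [default_oscillator()].
#' @param step_budget_factor run limit as a multiple of the route length
#'   (default 4).
#' @param use_where_stream encode/decode each movement target through the
#'   polar grid (default TRUE; records the decode error in the trace).
#' @param grid a [polar_grid()] for the where stream.
#' @return Validated config list of class `scenario_config`.
#' @export
scenario_config <- function(map = build_default_map(), rulebase = "auto",
                            start, goal, here_code = NULL, goal_code = NULL,
                            attention = list(default = 2.3),
                            oscillator = default_oscillator(),
                            step_budget_factor = 4,
                            use_where_stream = TRUE,
                            grid = polar_grid()) {
  stopifnot(inherits(map, "cognitive_map"))
  if (identical(rulebase, "auto")) rulebase <- build_complete_rulebase(map)
  stopifnot(inherits(rulebase, "fuzzy_rulebase"))
  start <- as.integer(start); goal <- as.integer(goal)
  landmark_info(map, c(start, goal))
  if (is.null(attention$default)) stop("attention profile needs a 'default'")
  for (d in attention$drops) {
    for (f in c("at_landmark", "value", "steps")) {
      if (is.null(d[[f]])) stop("attention drop is missing field '", f, "'")
    }
  }
  osc <- utils::modifyList(default_oscillator(), oscillator)
  if (is.null(here_code)) here_code <- landmark_info(map, start)$freq_code
  if (is.null(goal_code)) goal_code <- landmark_info(map, goal)$freq_code
  structure(
    list(map = map, rulebase = rulebase, start = start, goal = goal,
         here_code = here_code, goal_code = goal_code, attention = attention,
         oscillator = osc, step_budget_factor = step_budget_factor,
         use_where_stream = isTRUE(use_where_stream), grid = grid),
    class = "scenario_config"
  )
}

#' Run a closed-loop navigation scenario
#'
#' Executes the perception -> expectation check -> fuzzy retrieval ->
#' short-term-memory load -> movement cycle until the goal is recognized,
#' the agent gets stuck, or the step budget is exhausted ("lost"). The run
#' is fully deterministic.
#'
#' At each decision the agent perceives the landmark it stands on through
#' the oscillator bank. A unique resonance gives the landmark's code; the
#' controller then retrieves the next step by fuzzy inference and loads the
#' retrieved memory row into the next-subgoal buffer (shifting the old
#' content to the previous-subgoal buffer). An attention level below the
#' deficit threshold at a decision landmark makes the low-attention rule
#' fire, sending the agent onto the attached wrong-path branch, where it
#' stays until attention recovers and it backtracks. When perception or
#' retrieval fails (Alzheimer regime, lesioned map), weighted code
#' competition over the outgoing paths decides the move instead.
#'
#' @param config a [scenario_config()] or preset name
#'   (`"fig12"`, `"fig13"`, `"ad"` -- see [scenario_preset()]).
#' @return A `navigation_trace`: data.frame with one row per decision step
#'   (position, attention, recognized code, raw and snapped controller
#'   output, buffer contents, flags) with attributes `status`
#'   (`"goal_reached"`, `"lost"`, `"stuck"`), `visited` (landmark id
#'   sequence), and the config.
#' @examples
#' \donttest{
#' tr <- run_scenario(scenario_preset("fig12"))
#' attr(tr, "status")
#' attr(tr, "visited")
#' }
#' @export
run_scenario <- function(config) {
  if (is.character(config)) config <- scenario_preset(config)
  stopifnot(inherits(config, "scenario_config"))
  map <- config$map
  base <- config$rulebase
  thr <- base$attention_threshold
  cache <- new.env(parent = emptyenv())

  route <- find_route(map, config$start, config$goal)
  budget <- max(8, ceiling(config$step_budget_factor * length(route)))

  rec <- list()
  visited <- config$start
  cur <- config$start
  pos <- unlist(landmark_info(map, cur)[, c("x", "y")])
  heading <- c(1, 0)
  stm_next <- list(id = NA_integer_, code = NA_real_)
  stm_prev <- list(id = NA_integer_, code = NA_real_)
  on_wrong_path <- FALSE
  drop_state <- list(active = FALSE, remaining = 0, value = NA_real_,
                     used = integer())
  status <- "lost"
  here_input <- code_to_id(map, config$here_code)
  goal_input <- code_to_id(map, config$goal_code)
  first_decision <- TRUE

  if (config$start == config$goal) {
    tr <- empty_trace()
    return(finish_trace(tr, "goal_reached", visited, config))
  }

  add <- function(landmark, att, recognized, raw, snapped, action,
                  flags = character(), where_error = NA_real_) {
    info <- landmark_info(map, landmark)
    rec[[length(rec) + 1]] <<- data.frame(
      step = length(rec) + 1, landmark = landmark, x = info$x, y = info$y,
      attention = att, recognized_code = recognized,
      raw_output = raw, next_step = snapped, action = action,
      stm_next_id = stm_next$id, stm_prev_id = stm_prev$id,
      wrong_path_message = "wrong_path_message" %in% flags,
      entered_wrong_branch = "entered_wrong_branch" %in% flags,
      corrected = "corrected" %in% flags,
      where_error = where_error
    )
  }

  move_to <- function(target_id) {
    to <- landmark_info(map, target_id)
    v <- c(to$x - pos[1], to$y - pos[2])
    d <- sqrt(sum(v^2))
    err <- NA_real_
    if (config$use_where_stream && d > 0 && d <= config$grid$r_max) {
      theta_global <- atan2(v[2], v[1])
      theta_ego <- wrap_angle(theta_global - atan2(heading[2], heading[1]))
      fld <- encode_egocentric(config$grid, d, theta_ego %% (2 * pi))
      dec <- decode_position(config$grid, fld)
      theta_back <- dec["theta"] + atan2(heading[2], heading[1])
      guess <- pos + dec["r"] * c(cos(theta_back), sin(theta_back))
      err <- sqrt(sum((guess - c(to$x, to$y))^2))
    }
    if (d > 0) heading <<- v / d
    pos <<- c(to$x, to$y)
    cur <<- target_id
    visited <<- c(visited, target_id)
    err
  }

  for (iter in seq_len(budget)) {
    # attention profile
    if (!drop_state$active) {
      for (d in config$attention$drops) {
        if (cur == d$at_landmark && !(d$at_landmark %in% drop_state$used)) {
          drop_state$active <- TRUE
          drop_state$remaining <- d$steps
          drop_state$value <- d$value
          drop_state$used <- c(drop_state$used, d$at_landmark)
          break
        }
      }
    }
    att <- if (drop_state$active) drop_state$value else
      config$attention$default
    if (drop_state$active) {
      drop_state$remaining <- drop_state$remaining - 1
      if (drop_state$remaining <= 0) drop_state$active <- FALSE
    }

    # on a wrong-path branch: stay while inattentive, backtrack on recovery
    if (on_wrong_path) {
      if (att < thr) {
        add(cur, att, NA_real_, NA_real_, cur, "stay")
        next
      }
      parent <- as.integer(names(map$wrong_branches)[
        map$wrong_branches == cur])
      if (length(parent) == 0) parent <- stm_prev$id
      on_wrong_path <- FALSE
      stm_prev <- stm_next
      stm_next <- list(id = parent, code = landmark_info(map, parent)$freq_code)
      add(cur, att, NA_real_, NA_real_, parent, "backtrack",
          flags = c("wrong_path_message", "corrected"))
      move_to(parent)
      next
    }

    recognized <- perceive(map, cur, config$oscillator, cache)
    if (first_decision && !is.na(recognized)) {
      # a changed landmark appearance shifts the initially perceived code
      recognized <- recognized + (config$here_code -
        landmark_info(map, config$start)$freq_code)
    }

    # goal test: arrival must be confirmed by recognition
    if (cur == config$goal &&
        !is.na(recognized) &&
        abs(recognized - config$goal_code) < 1) {
      status <- "goal_reached"
      break
    }

    verdict <- check_expectation(stm_next$code, recognized)

    if (verdict == "retrieval_failure") {
      lost_code <- if (!is.na(stm_next$code)) stm_next$code else
        config$goal_code
      nxt <- choose_by_competition(map, cur, lost_code, heading)
      if (is.na(nxt)) {
        add(cur, att, recognized, NA_real_, NA_integer_, "stuck")
        status <- "stuck"
        break
      }
      had_expectation <- !is.na(stm_next$code)
      stm_prev <- stm_next
      stm_next <- list(id = nxt, code = landmark_info(map, nxt)$freq_code)
      add(cur, att, recognized, NA_real_, nxt, "competition",
          flags = if (had_expectation) "wrong_path_message")
      move_to(nxt)
      first_decision <- FALSE
      next
    }

    if (verdict == "mismatch") {
      # wrong landmark underfoot: backtrack to the previous subgoal
      back <- if (!is.na(stm_prev$id)) stm_prev$id else cur
      stm_prev <- stm_next
      stm_next <- list(id = back, code = landmark_info(map, back)$freq_code)
      add(cur, att, recognized, NA_real_, back, "backtrack",
          flags = c("wrong_path_message", "corrected"))
      if (back != cur) move_to(back)
      next
    }

    # match: fuzzy retrieval of the next step
    here_val <- if (first_decision) here_input else
      code_to_id(map, recognized)
    inf <- infer_next_step(base, here_val, goal_input, att)
    first_decision <- FALSE
    nxt <- inf$next_step
    if (nxt == cur) {
      add(cur, att, recognized, inf$raw, nxt, "stay")
      next
    }
    row <- retrieve_row(map, nxt)
    if (is.null(row)) {
      lost_code <- id_to_code(map, nxt)
      alt <- choose_by_competition(map, cur, lost_code, heading)
      if (is.na(alt)) {
        add(cur, att, recognized, inf$raw, NA_integer_, "stuck")
        status <- "stuck"
        break
      }
      stm_prev <- stm_next
      stm_next <- list(id = alt, code = landmark_info(map, alt)$freq_code)
      add(cur, att, recognized, inf$raw, alt, "competition")
      move_to(alt)
      next
    }
    stm_prev <- stm_next
    stm_next <- list(id = nxt, code = row$w_lm_next)
    flags <- character()
    role_next <- landmark_info(map, nxt)$role
    if (role_next == "wrong_path") {
      flags <- "entered_wrong_branch"
      on_wrong_path <- TRUE
    }
    decision_lm <- cur
    err <- move_to(nxt)
    add(decision_lm, att, recognized, inf$raw, nxt, "move", flags = flags,
        where_error = err)
  }

  tr <- if (length(rec) == 0) empty_trace() else do.call(rbind, rec)
  finish_trace(tr, status, visited, config)
}

empty_trace <- function() {
  data.frame(step = integer(0), landmark = integer(0), x = numeric(0),
             y = numeric(0), attention = numeric(0),
             recognized_code = numeric(0), raw_output = numeric(0),
             next_step = integer(0), action = character(0),
             stm_next_id = integer(0), stm_prev_id = integer(0),
             wrong_path_message = logical(0),
             entered_wrong_branch = logical(0), corrected = logical(0),
             where_error = numeric(0))
}

finish_trace <- function(tr, status, visited, config) {
  rownames(tr) <- NULL
  structure(tr, status = status, visited = visited, config = config,
            class = c("navigation_trace", class(tr)))
}

#' Packaged scenario presets
#'
#' * `fig12`: healthy run, start LM1 (initially perceived code 4.2), goal
#'   LM6 (code 9), attention 2.3.
#' * `fig13`: the same run with an attention drop to 1.0 at LM4 lasting two
#'   decisions, sending the agent onto the LM10 branch before recovery.
#' * `ad`: the Alzheimer regime (`lam = 15.2`): no landmark is recognized
#'   and the agent wanders by path competition until the step budget ends.
#'
#' @param name `"fig12"`, `"fig13"` or `"ad"`, or a path to a scenario YAML
#'   file with the same schema (`navsim-scenario/1`).
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets", paste0(name, ".yaml"),
                package = "navsim")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown scenario preset or file: ", name)
  }
  doc <- yaml::read_yaml(path)
  if (!is.list(doc) || !identical(doc$schema, "navsim-scenario/1")) {
    stop("scenario file '", path, "': missing or unsupported schema header")
  }
  map <- if (is.null(doc$map) || identical(doc$map, "default")) {
    build_default_map()
  } else {
    read_map(doc$map)
  }
  if (length(doc$lesion) > 0) map <- lesion(map, unlist(doc$lesion))
  osc <- doc$oscillator
  if (is.null(osc)) osc <- list()
  scenario_config(
    map = map, rulebase = "auto", start = doc$start, goal = doc$goal,
    here_code = doc$here_code, goal_code = doc$goal_code,
    attention = if (is.null(doc$attention)) list(default = 2.3) else
      doc$attention,
    oscillator = osc,
    step_budget_factor = if (is.null(doc$step_budget_factor)) 4 else
      doc$step_budget_factor
  )
}

#' Export a navigation trace
#'
#' CSV (one row per decision step) or JSON (full record incl. status and
#' visited sequence).
#'
#' @param trace a `navigation_trace`.
#' @param path output file; format chosen by extension (`.csv` / `.json`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "navigation_trace"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(status = attr(trace, "status"),
           visited = attr(trace, "visited"),
           steps = as.data.frame(trace)),
      path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  } else {
    utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.navigation_trace <- function(x, ...) {
  cat("<navigation_trace>", nrow(x), "decision step(s), status:",
      attr(x, "status"), "\n  visited:",
      paste(attr(x, "visited"), collapse = " -> "), "\n")
  invisible(x)
}
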
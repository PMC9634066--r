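#' Membership functions for the retrieval controller
#'
#' The controller's three inputs are the current landmark ("here"), the goal
#' landmark, and the attention level. Landmark dimensions use narrow Gaussian
#' membership functions, one per landmark, with standard deviation 0.15 on
#' the landmark-id axis -- narrow enough that adjacent landmarks effectively
#' do not overlap, wide enough to absorb small changes in a landmark's
#' appearance (a perceived code 4.2 still fires landmark 1's rule). The
#' attention dimension uses a pair of saturating S/Z functions whose
#' crossover at 1.5 is the attention-deficit threshold.
#'
#' * `mf_gaussian`: `exp(-(x - center)^2 / (2 sigma^2))`.
#' * `mf_s`: 0 at/below `foot`, 1 at/above `shoulder`, quadratic spline
#'   between ("with attention").
#' * `mf_z`: the mirror image ("without attention").
#'
#' @param center,sigma Gaussian parameters (`sigma > 0`).
#' @param foot,shoulder S/Z breakpoints (`foot < shoulder`).
#' @return An object of class `membership_function`.
#' @examples
#' evaluate_mf(mf_gaussian(4), 4.2)  # ~0.4111
#' @export
mf_gaussian <- function(center, sigma = 0.15) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  structure(list(shape = "gaussian", center = center, sigma = sigma),
            class = "membership_function")
}

#' @rdname mf_gaussian
#' @export
mf_s <- function(foot, shoulder) {
  stopifnot(foot < shoulder)
  structure(list(shape = "s_shape", foot = foot, shoulder = shoulder),
            class = "membership_function")
}

#' @rdname mf_gaussian
#' @export
mf_z <- function(foot, shoulder) {
  stopifnot(foot < shoulder)
  structure(list(shape = "z_shape", foot = foot, shoulder = shoulder),
            class = "membership_function")
}

#' Evaluate a membership function
#'
#' @param mf a [mf_gaussian()], [mf_s()] or [mf_z()].
#' @param x numeric vector.
#' @return Membership values in `[0, 1]`.
#' @export
evaluate_mf <- function(mf, x) {
  stopifnot(inherits(mf, "membership_function"))
  switch(mf$shape,
    gaussian = exp(-(x - mf$center)^2 / (2 * mf$sigma^2)),
    s_shape = smf_eval(x, mf$foot, mf$shoulder),
    z_shape = 1 - smf_eval(x, mf$foot, mf$shoulder),
    stop("unknown membership shape: ", mf$shape)
  )
}

# standard quadratic-spline S curve
smf_eval <- function(x, a, b) {
  mid <- (a + b) / 2
  out <- numeric(length(x))
  out[x >= b] <- 1
  i <- x > a & x <= mid
  out[i] <- 2 * ((x[i] - a) / (b - a))^2
  i <- x > mid & x < b
  out[i] <- 1 - 2 * ((x[i] - b) / (b - a))^2
  out
}

#' Build the complete fuzzy lookup-table rule base for a map
#'
#' Enumerates every rule `(here, goal, attention) -> next step` over the
#' map's route landmarks: one rule per ordered (here, goal) landmark pair
#' per attention state. The consequents follow the learned routes:
#'
#' * with attention: the next landmark along the route from `here` toward
#'   `goal` (`here` itself when `here == goal` -- stay);
#' * without attention: the wrong-path branch attached at `here` (the
#'   erroneous straight-ahead continuation); landmarks without a branch
#'   stay put.
#'
#' For the default six-landmark map this yields 6 x 6 x 2 = 72 rules over 36
#' distinct (here, goal) antecedent pairs. Individual consequents can be
#' overridden through `overrides` (e.g. the alternative reading of the
#' route-2 low-attention rule at here = 4, goal = 1, next step 5 instead of
#' the branch 10).
#'
#' @param map a [cognitive_map()].
#' @param sigma Gaussian width of the landmark membership functions.
#' @param attention_foot,attention_shoulder breakpoints of the attention
#'   S/Z pair; their midpoint is the attention-deficit threshold.
#' @param overrides optional data.frame (`here`, `goal`, `attention_label`,
#'   `next_step`) replacing individual consequents.
#' @param attention_states attention labels to enumerate (default both).
#' @return An object of class `fuzzy_rulebase`: `rules` (data.frame `here`,
#'   `goal`, `attention_label`, `next_step`), membership families in `mfs`,
#'   and the generating map.
#' @export
build_complete_rulebase <- function(map, sigma = 0.15, attention_foot = 1,
                                    attention_shoulder = 2,
                                    overrides = NULL,
                                    attention_states = c("with", "without")) {
  stopifnot(inherits(map, "cognitive_map"),
            all(attention_states %in% c("with", "without")))
  route_ids <- sort(map$landmarks$id[map$landmarks$role == "route"])
  if (length(route_ids) < 1) stop("map has no route landmarks")
  wb <- map$wrong_branches
  grid <- expand.grid(here = route_ids, goal = route_ids,
                      attention_label = attention_states,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$goal, grid$here, grid$attention_label), ]
  rownames(grid) <- NULL
  grid$next_step <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    h <- grid$here[i]; g <- grid$goal[i]
    if (grid$attention_label[i] == "with") {
      grid$next_step[i] <- if (h == g) h else find_route(map, h, g)[2]
    } else {
      key <- as.character(h)
      grid$next_step[i] <- if (key %in% names(wb)) wb[[key]] else h
    }
  }
  if (!is.null(overrides)) {
    stopifnot(all(c("here", "goal", "attention_label", "next_step") %in%
                    names(overrides)))
    for (i in seq_len(nrow(overrides))) {
      j <- which(grid$here == overrides$here[i] &
                   grid$goal == overrides$goal[i] &
                   grid$attention_label == overrides$attention_label[i])
      if (length(j) != 1) stop("override ", i, " matches ", length(j),
                               " rules (must match exactly one)")
      grid$next_step[j] <- overrides$next_step[i]
    }
  }
  consequent_ids <- sort(unique(c(route_ids, grid$next_step)))
  structure(
    list(
      rules = grid,
      mfs = list(
        here = lapply(stats::setNames(route_ids, route_ids), mf_gaussian,
                      sigma = sigma),
        goal = lapply(stats::setNames(route_ids, route_ids), mf_gaussian,
                      sigma = sigma),
        attention = list(with = mf_s(attention_foot, attention_shoulder),
                         without = mf_z(attention_foot, attention_shoulder)),
        next_step = lapply(stats::setNames(consequent_ids, consequent_ids),
                           mf_gaussian, sigma = sigma)
      ),
      attention_threshold = (attention_foot + attention_shoulder) / 2,
      map = map
    ),
    class = "fuzzy_rulebase"
  )
}

#' Rules active on one route
#'
#' Subset of the complete rule base exercised when navigating from `start`
#' to `goal`: both attention states of every decision landmark on the route
#' (all route landmarks except the goal itself).
#'
#' @param base a [build_complete_rulebase()].
#' @param start,goal landmark ids.
#' @return The active rules as a data.frame (subset of `base$rules`).
#' @export
active_rules <- function(base, start, goal) {
  stopifnot(inherits(base, "fuzzy_rulebase"))
  route <- find_route(base$map, start, goal)
  here_ids <- route[route != goal]
  out <- base$rules[base$rules$goal == goal & base$rules$here %in% here_ids, ]
  out <- out[order(match(out$here, here_ids),
                   out$attention_label == "without"), ]
  rownames(out) <- NULL
  out
}

#' Retrieve the next-step code by fuzzy inference
#'
#' Implements the controller's retrieval step: product (multiplication)
#' inference over the three input dimensions and center-average
#' defuzzification,
#' \deqn{Y = \frac{\sum_i \bar Y_i \prod_j \mu_{i,j}}
#'                {\sum_i \prod_j \mu_{i,j}},}
#' a convex combination of the firing rules' consequent centers. The raw
#' defuzzified value is returned alongside its snap to the nearest
#' consequent center (the discrete routing decision).
#'
#' @param base a [build_complete_rulebase()].
#' @param here,goal current and goal landmark, on the id axis by default or
#'   on the frequency-code axis with `input = "code"` (converted through the
#'   base's map, so a perceived code 4.2 becomes 1.2).
#' @param attention attention level (tables use 2 = attentive, 1 =
#'   inattentive; the deficit threshold is the S/Z crossover, 1.5).
#' @param rules optional rule subset (e.g. from [active_rules()]); default
#'   all rules.
#' @param input scale of `here`/`goal`.
#' @return A list of class `fuzzy_inference`: `next_step` (snapped id),
#'   `raw` (defuzzified value), `strengths` (per-rule firing strengths).
#' @examples
#' base <- build_complete_rulebase(build_default_map())
#' infer_next_step(base, here = 1, goal = 6, attention = 2)$next_step  # 2
#' @export
infer_next_step <- function(base, here, goal, attention, rules = NULL,
                            input = c("id", "code")) {
  stopifnot(inherits(base, "fuzzy_rulebase"))
  input <- match.arg(input)
  if (input == "code") {
    here <- code_to_id(base$map, here)
    goal <- code_to_id(base$map, goal)
  }
  if (is.null(rules)) rules <- base$rules
  mu_here <- vapply(as.character(rules$here), function(k) {
    evaluate_mf(base$mfs$here[[k]], here)
  }, numeric(1))
  mu_goal <- vapply(as.character(rules$goal), function(k) {
    evaluate_mf(base$mfs$goal[[k]], goal)
  }, numeric(1))
  mu_att <- vapply(rules$attention_label, function(lab) {
    evaluate_mf(base$mfs$attention[[lab]], attention)
  }, numeric(1))
  w <- mu_here * mu_goal * mu_att
  if (sum(w) == 0) {
    stop("no rule fires for (here = ", here, ", goal = ", goal,
         ", attention = ", attention, "): rule-base completeness violated")
  }
  raw <- sum(rules$next_step * w) / sum(w)
  centers <- sort(unique(rules$next_step))
  snapped <- centers[which.min(abs(centers - raw))]
  structure(list(next_step = snapped, raw = raw,
                 strengths = stats::setNames(w, NULL)),
            class = "fuzzy_inference")
}

#' Prune duplicate-antecedent rules by degree
#'
#' When candidate rules are generated from input-output exemplars, several
#' may share an antecedent. Per antecedent `(here, goal, attention_label)`,
#' only the rule with the highest degree (antecedent membership times
#' consequent membership of its exemplar) is kept; exact ties keep the
#' lowest consequent center and emit a warning.
#'
#' @param rules data.frame with columns `here`, `goal`, `attention_label`,
#'   `next_step`, `degree`.
#' @return The pruned data.frame.
#' @export
prune_by_degree <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("here", "goal", "attention_label", "next_step", "degree")
                %in% names(rules)))
  key <- interaction(rules$here, rules$goal, rules$attention_label,
                     drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(rules)), key), function(idx) {
    d <- rules$degree[idx]
    best <- idx[d == max(d)]
    if (length(best) > 1) {
      warning("degree tie among rules with shared antecedent; ",
              "keeping lowest consequent center")
      best <- best[order(rules$next_step[best])][1]
    }
    best
  }), use.names = FALSE)
  out <- rules[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' Read and write rule tables as CSV
#'
#' Columns `here`, `goal`, `attention_label`, `next_step`; the shipped
#' fixtures mirror the two printed route tables.
#'
#' @param rules data.frame of rules.
#' @param path file path.
#' @return `read_rulebase_csv` returns the rules data.frame.
#' @export
write_rulebase_csv <- function(rules, path) {
  utils::write.csv(
    rules[, c("here", "goal", "attention_label", "next_step")], path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_rulebase_csv
#' @export
read_rulebase_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("here", "goal", "attention_label", "next_step")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("rule table '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df[, need]
}

#' @export
print.fuzzy_rulebase <- function(x, ...) {
  cat("<fuzzy_rulebase>", nrow(x$rules), "rules over",
      nrow(unique(x$rules[, c("here", "goal")])), "antecedent pairs;",
      "attention threshold", x$attention_threshold, "\n")
  invisible(x)
}

#' @export
print.fuzzy_inference <- function(x, ...) {
  cat("<fuzzy_inference> next step:", x$next_step,
      "(raw", signif(x$raw, 6), ",", sum(x$strengths > 0), "rules firing)\n")
  invisible(x)
}
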
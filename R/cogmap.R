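#' Cognitive map: landmarks, routes, and the long-term-memory step matrix
#'
#' A `cognitive_map` holds the allocentric knowledge the agent acquired during
#' learning: the landmark set (grid coordinates plus a symbolic identification
#' frequency per landmark), the learned route orderings, the wrong-path
#' branches attached at turning points, and -- per route step -- a row of the
#' long-term-memory matrix giving the next expected landmark's coordinates
#' `(x_lm_next, y_lm_next)`, its frequency code `w_lm_next`, and the agent's
#' own coordinates `(x_motor, y_motor)` at that step.
#'
#' @param landmarks data.frame with columns `id`, `x`, `y`, `freq_code`,
#'   `role` (one of `"route"`, `"wrong_path"`, `"distractor"`).
#' @param routes named list of integer vectors, each an ordered landmark-id
#'   sequence the agent has learned.
#' @param wrong_branches named integer vector mapping a decision landmark id
#'   (name) to the wrong-path landmark id attached there.
#'
#' @return An object of class `cognitive_map` with elements `landmarks`,
#'   `routes`, `wrong_branches`, `rows` (one step-matrix data.frame per
#'   route), and `lesioned` (ids whose memory rows are zeroed).
#' @seealso [build_default_map()], [lesion()], [read_map()]
#' @export
cognitive_map <- function(landmarks, routes, wrong_branches = integer()) {
  stopifnot(is.data.frame(landmarks))
  need <- c("id", "x", "y", "freq_code", "role")
  miss <- setdiff(need, names(landmarks))
  if (length(miss) > 0) {
    stop("landmarks is missing column(s): ", paste(miss, collapse = ", "))
  }
  landmarks <- landmarks[, need]
  rownames(landmarks) <- NULL
  landmarks$id <- as.integer(landmarks$id)
  if (anyDuplicated(landmarks$id)) stop("landmark ids must be unique")
  if (any(landmarks$id <= 0)) stop("landmark ids must be positive")
  if (any(!is.finite(landmarks$freq_code)) || any(landmarks$freq_code <= 0)) {
    stop("every landmark needs a positive freq_code")
  }
  if (!all(landmarks$role %in% c("route", "wrong_path", "distractor"))) {
    stop("landmark role must be one of route, wrong_path, distractor")
  }
  routes <- lapply(routes, as.integer)
  for (nm in names(routes)) {
    unknown <- setdiff(routes[[nm]], landmarks$id)
    if (length(unknown) > 0) {
      stop("route '", nm, "' references unknown landmark id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  wb <- as.integer(wrong_branches)
  names(wb) <- names(wrong_branches)
  if (length(wb) > 0) {
    ids <- c(as.integer(names(wb)), wb)
    unknown <- setdiff(ids, landmarks$id)
    if (length(unknown) > 0) {
      stop("wrong_branches references unknown landmark id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  m <- structure(
    list(landmarks = landmarks, routes = routes, wrong_branches = wb,
         lesioned = integer()),
    class = "cognitive_map"
  )
  m$rows <- lapply(routes, function(seq_ids) map_rows_for(m, seq_ids))
  m
}

# One long-term-memory row per route step: target coordinates + code, and the
# agent's coordinates at the step's origin.
map_rows_for <- function(map, seq_ids) {
  n <- length(seq_ids)
  if (n < 2) {
    return(data.frame(x_lm_next = numeric(0), y_lm_next = numeric(0),
                      w_lm_next = numeric(0), x_motor = numeric(0),
                      y_motor = numeric(0)))
  }
  from <- landmark_info(map, seq_ids[-n])
  to <- landmark_info(map, seq_ids[-1])
  data.frame(x_lm_next = to$x, y_lm_next = to$y, w_lm_next = to$freq_code,
             x_motor = from$x, y_motor = from$y)
}

landmark_info <- function(map, ids) {
  idx <- match(ids, map$landmarks$id)
  if (anyNA(idx)) {
    stop("unknown landmark id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  map$landmarks[idx, , drop = FALSE]
}

#' Default six-landmark map
#'
#' Builds the default cognitive map: six route landmarks LM1--LM6 carrying
#' identification frequency codes 4--9, laid out as an orthogonal path with a
#' turn at every landmark, plus five wrong-path branch landmarks LM7--LM11
#' (codes 10--14) attached at the decision points LM1--LM5. Two routes are
#' learned: `route1 = LM1..LM6` and `route2 = LM4,LM3,LM2,LM1`. All geometry
#' is overridable through `coords`.
#'
#' @param coords optional data.frame with columns `id`, `x`, `y` overriding
#'   the default grid coordinates of any subset of landmarks.
#' @param n_route number of route landmarks (default 6; smaller values give
#'   truncated maps, `n_route = 1` a degenerate map with zero route steps).
#'
#' @return A [cognitive_map()].
#' @examples
#' m <- build_default_map()
#' m$landmarks
#' @export
build_default_map <- function(coords = NULL, n_route = 6) {
  stopifnot(n_route >= 1, n_route <= 6)
  route_xy <- matrix(c(0, 0, 4, 0, 4, 4, 8, 4, 8, 8, 12, 8),
                     ncol = 2, byrow = TRUE)
  # each branch continues straight where the correct path turns
  branch_xy <- matrix(c(0, 3, 7, 0, 4, 7, 11, 4, 8, 11),
                      ncol = 2, byrow = TRUE)
  n_branch <- min(5, max(0, n_route - 1))
  lm <- data.frame(
    id = seq_len(n_route),
    x = route_xy[seq_len(n_route), 1],
    y = route_xy[seq_len(n_route), 2],
    freq_code = seq_len(n_route) + 3,
    role = "route"
  )
  if (n_branch > 0) {
    lm <- rbind(lm, data.frame(
      id = 6 + seq_len(n_branch),
      x = branch_xy[seq_len(n_branch), 1],
      y = branch_xy[seq_len(n_branch), 2],
      freq_code = 6 + seq_len(n_branch) + 3,
      role = "wrong_path"
    ))
  }
  if (!is.null(coords)) {
    stopifnot(is.data.frame(coords), all(c("id", "x", "y") %in% names(coords)))
    idx <- match(coords$id, lm$id)
    if (anyNA(idx)) stop("coords references unknown landmark id(s)")
    lm$x[idx] <- coords$x
    lm$y[idx] <- coords$y
  }
  routes <- list(route1 = seq_len(n_route))
  if (n_route >= 4) routes$route2 <- 4:1
  wb <- 6 + seq_len(n_branch)
  names(wb) <- seq_len(n_branch)
  cognitive_map(lm, routes, wb)
}

#' Zero the memory rows of selected landmarks (amnesia lesion)
#'
#' Models hippocampal loss of stored landmark information: every
#' long-term-memory row whose target is a lesioned landmark has its entries
#' set to zero. The landmark itself remains in the environment -- it still
#' emits its stimulus and can be perceived -- but its stored coordinates and
#' code can no longer be retrieved.
#'
#' @param map a [cognitive_map()].
#' @param landmark_ids integer ids to lesion (may be empty).
#' @return A modified copy of `map`.
#' @export
lesion <- function(map, landmark_ids) {
  stopifnot(inherits(map, "cognitive_map"))
  landmark_ids <- as.integer(landmark_ids)
  unknown <- setdiff(landmark_ids, map$landmarks$id)
  if (length(unknown) > 0) {
    stop("cannot lesion unknown landmark id(s): ",
         paste(unknown, collapse = ", "))
  }
  if (length(landmark_ids) == 0) return(map)
  lesioned_codes <- landmark_info(map, landmark_ids)$freq_code
  for (nm in names(map$rows)) {
    hit <- map$rows[[nm]]$w_lm_next %in% lesioned_codes
    map$rows[[nm]][hit, ] <- 0
  }
  map$lesioned <- sort(unique(c(map$lesioned, landmark_ids)))
  map
}

#' Retrieve the memory row for stepping onto a landmark
#'
#' Looks up the long-term-memory row whose target is `id`. Returns `NULL`
#' when the landmark's stored information has been zeroed (lesioned) or never
#' existed -- a retrieval failure.
#'
#' @param map a [cognitive_map()].
#' @param id target landmark id.
#' @return A one-row data.frame (`x_lm_next`, `y_lm_next`, `w_lm_next`,
#'   `x_motor`, `y_motor`) or `NULL`.
#' @export
retrieve_row <- function(map, id) {
  id <- as.integer(id)
  if (id %in% map$lesioned) return(NULL)
  code <- landmark_info(map, id)$freq_code
  for (nm in names(map$rows)) {
    hit <- which(map$rows[[nm]]$w_lm_next == code)
    if (length(hit) > 0) return(map$rows[[nm]][hit[1], , drop = FALSE])
  }
  # landmark known to the environment but not on any learned route step:
  # synthesize a row from the landmark table (branches are learned as
  # low-attention consequents, so their geometry is available)
  info <- landmark_info(map, id)
  data.frame(x_lm_next = info$x, y_lm_next = info$y, w_lm_next = info$freq_code,
             x_motor = NA_real_, y_motor = NA_real_)
}

#' Map between landmark ids and identification frequency codes
#'
#' The rule tables index landmarks by id (1--11 on the default map) while the
#' oscillator bank and stimuli speak frequency codes (4--14). These helpers
#' convert between the two axes via the map's landmark table. `code_to_id`
#' matches the nearest landmark code and preserves the fractional offset, so
#' a perceived code 4.2 maps to 1.2 on the id axis (the controller's fuzzy
#' membership functions absorb the offset).
#'
#' @param map a [cognitive_map()].
#' @param code,id numeric values on the code / id axis.
#' @return Numeric vector on the other axis.
#' @export
code_to_id <- function(map, code) {
  lms <- map$landmarks
  vapply(code, function(cc) {
    k <- which.min(abs(lms$freq_code - cc))
    lms$id[k] + (cc - lms$freq_code[k])
  }, numeric(1))
}

#' @rdname code_to_id
#' @export
id_to_code <- function(map, id) {
  lms <- map$landmarks
  vapply(id, function(ii) {
    k <- which.min(abs(lms$id - ii))
    lms$freq_code[k] + (ii - lms$id[k])
  }, numeric(1))
}

# Undirected adjacency of the map: consecutive route pairs + branch attachments.
map_edges <- function(map) {
  e <- matrix(integer(0), ncol = 2)
  for (seq_ids in map$routes) {
    if (length(seq_ids) >= 2) {
      e <- rbind(e, cbind(seq_ids[-length(seq_ids)], seq_ids[-1]))
    }
  }
  if (length(map$wrong_branches) > 0) {
    e <- rbind(e, cbind(as.integer(names(map$wrong_branches)),
                        map$wrong_branches))
  }
  e <- rbind(e, e[, 2:1, drop = FALSE])
  unique(e)
}

neighbors_of <- function(map, id) {
  e <- map_edges(map)
  sort(unique(e[e[, 1] == id, 2]))
}

#' Route between two landmarks
#'
#' Shortest landmark sequence from `start` to `goal` along learned route
#' edges (wrong-path branches excluded), by breadth-first search.
#'
#' @param map a [cognitive_map()].
#' @param start,goal landmark ids.
#' @return Integer vector of ids from `start` to `goal` inclusive.
#' @export
find_route <- function(map, start, goal) {
  start <- as.integer(start); goal <- as.integer(goal)
  landmark_info(map, c(start, goal))
  if (start == goal) return(start)
  e <- matrix(integer(0), ncol = 2)
  for (seq_ids in map$routes) {
    if (length(seq_ids) >= 2) {
      e <- rbind(e, cbind(seq_ids[-length(seq_ids)], seq_ids[-1]))
    }
  }
  e <- unique(rbind(e, e[, 2:1, drop = FALSE]))
  prev <- integer(0)
  frontier <- start
  seen <- start
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in e[e[, 1] == v, 2]) {
        if (!(w %in% seen)) {
          seen <- c(seen, w)
          prev[as.character(w)] <- v
          nxt <- c(nxt, w)
        }
      }
    }
    if (goal %in% nxt) break
    frontier <- nxt
  }
  if (!(goal %in% seen)) {
    stop("goal landmark ", goal, " is not reachable from ", start,
         " along learned routes")
  }
  path <- goal
  while (path[1] != start) path <- c(prev[[as.character(path[1])]], path)
  path
}

#' @export
print.cognitive_map <- function(x, ...) {
  cat("<cognitive_map> ", nrow(x$landmarks), " landmarks (",
      sum(x$landmarks$role == "route"), " route, ",
      sum(x$landmarks$role == "wrong_path"), " wrong-path), ",
      length(x$routes), " route(s)\n", sep = "")
  if (length(x$lesioned) > 0) {
    cat("  lesioned ids:", paste(x$lesioned, collapse = ", "), "\n")
  }
  invisible(x)
}
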
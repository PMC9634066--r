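#' Read and write cognitive-map config files
#'
#' Maps serialize to a versioned YAML document with three sections:
#' `landmarks` (list of `{id, x, y, freq_code, role}`), `routes` (named
#' ordered id sequences) and `wrong_branches` (decision id -> branch id).
#' `read_map(write_map(path, m))` reproduces `m` exactly, including any
#' lesioned ids.
#'
#' @param path file path.
#' @param map a [cognitive_map()].
#' @return `read_map` returns a [cognitive_map()]; `write_map` returns
#'   `path` invisibly.
#' @export
write_map <- function(path, map) {
  stopifnot(inherits(map, "cognitive_map"))
  doc <- list(
    schema = "navsim-map/1",
    landmarks = lapply(seq_len(nrow(map$landmarks)), function(i) {
      as.list(map$landmarks[i, ])
    }),
    routes = lapply(map$routes, as.integer),
    wrong_branches = as.list(stats::setNames(
      as.integer(map$wrong_branches), names(map$wrong_branches)
    )),
    lesioned = as.integer(map$lesioned)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed map file '", path, "': ", conditionMessage(e))
  })
  if (!is.list(doc) || !identical(doc$schema, "navsim-map/1")) {
    stop("map file '", path, "': missing or unsupported schema header ",
         "(expected 'navsim-map/1')")
  }
  if (is.null(doc$landmarks) || length(doc$landmarks) == 0) {
    stop("map file '", path, "': no landmarks")
  }
  lm <- do.call(rbind, lapply(seq_along(doc$landmarks), function(i) {
    entry <- doc$landmarks[[i]]
    for (f in c("id", "x", "y", "freq_code", "role")) {
      if (is.null(entry[[f]])) {
        stop("map file '", path, "': landmark entry ", i,
             " is missing field '", f, "'")
      }
    }
    data.frame(id = as.integer(entry$id), x = as.numeric(entry$x),
               y = as.numeric(entry$y),
               freq_code = as.numeric(entry$freq_code),
               role = as.character(entry$role))
  }))
  wb <- unlist(doc$wrong_branches)
  if (is.null(wb)) wb <- integer()
  m <- cognitive_map(lm, doc$routes, wb)
  if (length(doc$lesioned) > 0) m <- lesion(m, unlist(doc$lesioned))
  m
}
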